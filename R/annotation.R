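#' Singly charged adduct conventions
#'
#' The adduct set used for putative identification: protonated,
#' sodiated and potassiated ions in positive mode, deprotonated in
#' negative mode. Mass shifts in Da: proton 1.007276; Na-H +21.981944;
#' K-H +37.955881.
#'
#' @param ion_mode optionally restrict to `"positive"` or `"negative"`.
#' @return data.frame with `label`, `mass_shift`, `polarity`.
#' @export
default_adducts <- function(ion_mode = NULL) {
  ad <- data.frame(
    label = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M-H]-"),
    mass_shift = c(1.007276, 1.007276 + 21.981944, 1.007276 + 37.955881,
                   -1.007276),
    polarity = c("positive", "positive", "positive", "negative"),
    stringsAsFactors = FALSE
  )
  if (!is.null(ion_mode)) ad <- ad[ad$polarity == ion_mode, , drop = FALSE]
  ad
}

#' Theoretical adduct m/z of a neutral molecule
#'
#' @param monoisotopic_mass neutral monoisotopic mass in Da (> 0).
#' @param adduct an adduct label (looked up in [default_adducts()]) or a
#'   one-row data.frame with a `mass_shift` column.
#' @return the singly charged adduct m/z in Da.
#' @examples
#' adduct_mz(100, "[M+H]+")   # 101.007276
#' @export
adduct_mz <- function(monoisotopic_mass, adduct) {
  stopifnot(all(monoisotopic_mass > 0))
  if (is.character(adduct)) {
    ad <- default_adducts()
    i <- match(adduct, ad$label)
    if (anyNA(i)) stop("unknown adduct label: ", adduct[is.na(i)][1L])
    shift <- ad$mass_shift[i]
  } else {
    shift <- adduct$mass_shift
  }
  monoisotopic_mass + shift
}

#' Read a local compound mass table
#'
#' CSV with columns `name`, `formula` (optional) and `monoisotopic_mass`
#' (Da), used as the local reference for putative annotation in place of
#' online database queries.
#'
#' @param path path to the CSV.
#' @return data.frame of compound records.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("compound table not found: ", path)
  cp <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("name", "monoisotopic_mass")
  miss <- setdiff(need, names(cp))
  if (length(miss)) stop("compound table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(cp$monoisotopic_mass) | cp$monoisotopic_mass <= 0)) {
    stop("monoisotopic_mass must be finite and > 0")
  }
  cp
}

#' Match features against a compound table under a ppm tolerance
#'
#' Emits every (feature, compound, adduct) triple whose observed m/z lies
#' within `tol_ppm` of the theoretical adduct m/z — putative
#' identifications; a feature may match several compounds. The tolerance
#' is evaluated on the adduct m/z. Adducts are restricted to the table's
#' ion mode.
#'
#' @param ft a `feature_table`.
#' @param compounds data.frame of `name`, optional `formula`,
#'   `monoisotopic_mass`.
#' @param adducts adduct data.frame (default: [default_adducts()] for the
#'   table's ion mode).
#' @param tol_ppm mass tolerance in ppm (default 5).
#' @return data.frame `feature_id`, `mz`, `rt`, `compound`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, sorted by `ppm_error`.
#' @export
match_features <- function(ft, compounds, adducts = NULL, tol_ppm = 5) {
  stopifnot(inherits(ft, "feature_table"), tol_ppm > 0)
  if (is.null(adducts)) adducts <- default_adducts(ft$ion_mode)
  adducts <- adducts[adducts$polarity == ft$ion_mode, , drop = FALSE]
  empty <- data.frame(
    feature_id = character(0), mz = numeric(0), rt = numeric(0),
    compound = character(0), adduct = character(0),
    theoretical_mz = numeric(0), ppm_error = numeric(0),
    stringsAsFactors = FALSE
  )
  if (nrow(compounds) == 0L) {
    warning("empty compound table; no annotation possible")
    return(empty)
  }
  out <- list()
  for (a in seq_len(nrow(adducts))) {
    theo <- compounds$monoisotopic_mass + adducts$mass_shift[a]
    for (k in seq_along(theo)) {
      ppm <- ppm_deviation(ft$features$mz, theo[k])
      hit <- which(ppm <= tol_ppm)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          feature_id = ft$features$feature_id[hit],
          mz = ft$features$mz[hit], rt = ft$features$rt[hit],
          compound = compounds$name[k], adduct = adducts$label[a],
          theoretical_mz = theo[k], ppm_error = ppm[hit],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$ppm_error), , drop = FALSE]
}
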