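#' Read an aligned LC-MS feature table
#'
#' Reads a CSV of aligned untargeted LC-MS features in the dialect written
#' by XCMS-style preprocessing: first column `feature_id`, then `mz`
#' (mass-to-charge ratio, Da) and `rt` (retention time, minutes), followed
#' by one intensity column per specimen. UTF-8, `.` decimal; an empty cell
#' is a missing intensity (peak not detected).
#'
#' @param path path to the CSV file.
#' @param ion_mode acquisition polarity of the table, `"positive"` or
#'   `"negative"`.
#' @return a `feature_table` object: a list with `features` (data.frame of
#'   `feature_id`, `mz`, `rt`), `intensities` (numeric matrix, features x
#'   specimens; `NA` = missing), and `ion_mode`.
#' @export
read_feature_table <- function(path, ion_mode = c("positive", "negative")) {
  ion_mode <- match.arg(ion_mode)
  if (!file.exists(path)) stop("feature table file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 4L) stop("expected columns feature_id, mz, rt and >= 1 specimen")
  if (!identical(names(raw)[1:3], c("feature_id", "mz", "rt"))) {
    stop("header must start with feature_id, mz, rt (got: ",
         paste(names(raw)[1:3], collapse = ", "), ")")
  }
  specimens <- names(raw)[-(1:3)]
  if (anyDuplicated(specimens)) {
    stop("duplicate specimen column(s): ",
         paste(unique(specimens[duplicated(specimens)]), collapse = ", "))
  }
  parse_num <- function(x, col) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad)) {
      stop("malformed numeric cell at row ", bad[1L], ", column '", col,
           "': '", x[bad[1L]], "'")
    }
    out[!nzchar(x)] <- NA_real_
    out
  }
  mz <- parse_num(raw$mz, "mz")
  rt <- parse_num(raw$rt, "rt")
  inten <- vapply(specimens, function(s) parse_num(raw[[s]], s),
                  numeric(nrow(raw)))
  if (nrow(raw) == 1L) inten <- matrix(inten, nrow = 1L, dimnames = list(NULL, specimens))
  rownames(inten) <- raw$feature_id
  ft <- new_feature_table(
    data.frame(feature_id = raw$feature_id, mz = mz, rt = rt,
               stringsAsFactors = FALSE),
    inten, ion_mode
  )
  validate_feature_table(ft)
  ft
}

new_feature_table <- function(features, intensities, ion_mode) {
  structure(
    list(features = features, intensities = intensities, ion_mode = ion_mode),
    class = "feature_table"
  )
}

#' Validate a feature table
#'
#' Checks the structural invariants: finite `mz > 0`, `rt >= 0`,
#' intensities `>= 0` or missing, unique feature and specimen identifiers.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly; errors describe the first offending cell.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  fe <- ft$features
  if (anyDuplicated(fe$feature_id)) {
    stop("duplicate feature_id: ", fe$feature_id[duplicated(fe$feature_id)][1L])
  }
  bad <- which(!is.finite(fe$mz) | fe$mz <= 0)
  if (length(bad)) stop("feature row ", bad[1L], " ('", fe$feature_id[bad[1L]],
                        "'): mz must be finite and > 0")
  bad <- which(!is.finite(fe$rt) | fe$rt < 0)
  if (length(bad)) stop("feature row ", bad[1L], " ('", fe$feature_id[bad[1L]],
                        "'): rt must be finite and >= 0")
  neg <- which(ft$intensities < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative intensity at row ", neg[1L, 1L], " ('",
         fe$feature_id[neg[1L, 1L]], "'), column '",
         colnames(ft$intensities)[neg[1L, 2L]], "'")
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("LC-MS feature table (", x$ion_mode, " mode): ",
      nrow(x$features), " features x ", ncol(x$intensities), " specimens\n",
      sep = "")
  cat("  mz range: [", min(x$features$mz), ", ", max(x$features$mz),
      "]  rt range: [", min(x$features$rt), ", ", max(x$features$rt), "] min\n",
      sep = "")
  invisible(x)
}

#' Write a feature table CSV
#'
#' Inverse of [read_feature_table()]; missing intensities are written as
#' empty cells, so read - write round-trips value-identically.
#'
#' @param ft a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  # 17 significant digits keeps doubles exact across the round trip
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  df <- data.frame(
    feature_id = ft$features$feature_id,
    mz = fmt(ft$features$mz),
    rt = fmt(ft$features$rt),
    `dim<-`(fmt(ft$intensities), dim(ft$intensities)) |>
      `dimnames<-`(dimnames(ft$intensities)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample manifest
#'
#' CSV with columns `specimen_id`, `patient_id`, `role` (one of `outgroup`,
#' `pre_RT`, `post_RT`) and an optional free-text `note`. Outgroup
#' specimens are healthy individuals that define the ancestral state.
#'
#' @param path path to the CSV file.
#' @return a data.frame with one row per specimen.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_manifest(mf)
  mf
}

#' Validate a sample manifest
#'
#' @param mf manifest data.frame (`specimen_id`, `patient_id`, `role`).
#' @return `mf`, invisibly.
#' @export
validate_manifest <- function(mf) {
  need <- c("specimen_id", "patient_id", "role")
  miss <- setdiff(need, names(mf))
  if (length(miss)) stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(mf$specimen_id)) {
    stop("duplicate specimen_id: ", mf$specimen_id[duplicated(mf$specimen_id)][1L])
  }
  bad <- setdiff(unique(mf$role), c("outgroup", "pre_RT", "post_RT"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  invisible(mf)
}

#' @rdname read_sample_manifest
#' @param mf manifest data.frame.
#' @export
write_sample_manifest <- function(mf, path) {
  utils::write.csv(mf, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict a feature table to an m/z window
#'
#' Keeps exactly the features with `lo <= mz <= hi` (closed interval).
#' The acquisition window of the assay this package targets is 50-850 Da,
#' which is the default.
#'
#' @param ft a `feature_table`.
#' @param lo,hi window bounds in Da, `lo < hi`.
#' @return the filtered `feature_table`, row order preserved.
#' @export
filter_mass_range <- function(ft, lo = 50, hi = 850) {
  stopifnot(inherits(ft, "feature_table"))
  if (!(lo < hi)) stop("invalid mass range: lo (", lo, ") must be < hi (", hi, ")")
  keep <- ft$features$mz >= lo & ft$features$mz <= hi
  new_feature_table(
    ft$features[keep, , drop = FALSE],
    ft$intensities[keep, , drop = FALSE],
    ft$ion_mode
  )
}

#' Relative mass deviation in parts per million
#'
#' @param observed,expected m/z values in Da; `expected > 0`.
#' @return `|observed - expected| / expected * 1e6`.
#' @export
ppm_deviation <- function(observed, expected) {
  abs(observed - expected) / expected * 1e6
}

#' Internal standards of the assay
#'
#' The spiked-in internal standards used to check mass and retention-time
#' stability: debrisoquine (positive mode, m/z 176.117, RT 1.705 min) and
#' 4-nitrobenzoic acid (negative mode, m/z 166.014, RT 4.063 min).
#'
#' @return a data.frame with columns `name`, `expected_mz`, `expected_rt`,
#'   `ion_mode`.
#' @export
default_internal_standards <- function() {
  data.frame(
    name = c("debrisoquine", "4-nitrobenzoic acid"),
    expected_mz = c(176.117, 166.014),
    expected_rt = c(1.705, 4.063),
    ion_mode = c("positive", "negative"),
    stringsAsFactors = FALSE
  )
}

#' Check internal standards in a feature table
#'
#' For each standard of the table's ion mode, reports the closest feature
#' within both the ppm and the retention-time tolerance, or marks it
#' missing. The table is never modified; a missing standard is a report
#' outcome, not an error.
#'
#' @param ft a `feature_table`.
#' @param standards data.frame as returned by
#'   [default_internal_standards()].
#' @param mz_tol_ppm mass tolerance in ppm (> 0).
#' @param rt_tol_min retention-time tolerance in minutes (> 0).
#' @return a data.frame with one row per applicable standard: `name`,
#'   `found`, `feature_id`, `observed_mz`, `ppm_dev`, `rt_dev`.
#' @export
check_internal_standards <- function(ft, standards = default_internal_standards(),
                                     mz_tol_ppm = 10, rt_tol_min = 0.1) {
  stopifnot(inherits(ft, "feature_table"))
  if (mz_tol_ppm <= 0 || rt_tol_min <= 0) stop("tolerances must be > 0")
  standards <- standards[standards$ion_mode == ft$ion_mode, , drop = FALSE]
  out <- lapply(seq_len(nrow(standards)), function(i) {
    st <- standards[i, ]
    if (nrow(ft$features) == 0L) {
      return(data.frame(name = st$name, found = FALSE, feature_id = NA_character_,
                        observed_mz = NA_real_, ppm_dev = NA_real_, rt_dev = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ppm <- ppm_deviation(ft$features$mz, st$expected_mz)
    rtd <- abs(ft$features$rt - st$expected_rt)
    ok <- ppm <= mz_tol_ppm & rtd <= rt_tol_min
    if (!any(ok)) {
      data.frame(name = st$name, found = FALSE, feature_id = NA_character_,
                 observed_mz = NA_real_, ppm_dev = NA_real_, rt_dev = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      j <- which(ok)[which.min(ppm[ok])]
      data.frame(name = st$name, found = TRUE,
                 feature_id = ft$features$feature_id[j],
                 observed_mz = ft$features$mz[j],
                 ppm_dev = ppm[j], rt_dev = rtd[j], stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
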