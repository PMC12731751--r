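#' Estimate per-feature normal ranges from the healthy outgroup
#'
#' The outgroup specimens define the "normal" (ancestral) intensity range
#' of every feature. The default and most literal reading of a normal
#' range is the outgroup min-max; a parametric alternative
#' (`mean +/- k * sd`, clipped at 0) is offered for small or noisy
#' outgroups. Missing outgroup intensities are treated as 0 (peak not
#' detected).
#'
#' @param ft a `feature_table`.
#' @param manifest sample manifest; must contain at least 2 specimens with
#'   role `outgroup` (3 or more recommended; a warning is issued below 3).
#' @param method `"minmax"` (default) or `"mean_k_sd"`.
#' @param k half-width in sample standard deviations for `mean_k_sd`
#'   (default 2).
#' @return a data.frame with one row per feature: `feature_id`, `lo`, `hi`,
#'   `outgroup_detected` (detected in at least one outgroup specimen),
#'   `method`.
#' @export
compute_normal_ranges <- function(ft, manifest, method = c("minmax", "mean_k_sd"), k = 2) {
  method <- match.arg(method)
  stopifnot(inherits(ft, "feature_table"))
  validate_manifest(manifest)
  og <- manifest$specimen_id[manifest$role == "outgroup"]
  if (length(og) == 0L) stop("no outgroup specimens in manifest")
  if (length(og) < 2L) stop("need >= 2 outgroup specimens, got ", length(og))
  if (length(og) < 3L) warning("fewer than 3 outgroup specimens; normal ranges will be wide")
  miss <- setdiff(og, colnames(ft$intensities))
  if (length(miss)) stop("outgroup specimen(s) absent from feature table: ",
                         paste(miss, collapse = ", "))
  X <- ft$intensities[, og, drop = FALSE]
  X[is.na(X)] <- 0
  if (method == "minmax") {
    lo <- apply(X, 1L, min)
    hi <- apply(X, 1L, max)
  } else {
    mu <- rowMeans(X)
    sdv <- apply(X, 1L, stats::sd)
    lo <- pmax(mu - k * sdv, 0)
    hi <- mu + k * sdv
  }
  data.frame(
    feature_id = ft$features$feature_id,
    lo = unname(lo), hi = unname(hi),
    outgroup_detected = unname(apply(X, 1L, function(x) any(x > 0))),
    method = method,
    stringsAsFactors = FALSE
  )
}

#' Polarize feature intensities into ancestral/derived character states
#'
#' Codes each patient-specimen x feature cell against the outgroup normal
#' range: intensities within `[lo, hi]` are ancestral (state 0); values
#' above `hi` are derived upregulation (`up`), or a `novel` peak when the
#' feature was never detected in the outgroup; positive values below `lo`
#' are derived downregulation (`down`); an undetected peak (0 or missing)
#' where the outgroup did detect the feature is a `vanished` peak (derived);
#' an undetected peak the outgroup also lacked is ancestral. The character
#' matrix itself is strictly binary — the direction channel is metadata.
#'
#' Outgroup specimens are excluded from the output rows: they define the
#' ancestral state rather than being classified against it.
#'
#' @param ft a `feature_table`.
#' @param ranges output of [compute_normal_ranges()]; must cover every
#'   feature of `ft`.
#' @param manifest sample manifest.
#' @param min_intensity detection floor: intensities `<= min_intensity`
#'   count as not detected (default 0).
#' @return a `polarized_matrix`: list with `states` (specimens x features
#'   integer 0/1 matrix), `direction` (character matrix, one of `none`,
#'   `up`, `down`, `novel`, `vanished`), `ranges`, and `outgroup`
#'   (specimen ids that defined the range).
#' @export
polarize <- function(ft, ranges, manifest, min_intensity = 0) {
  stopifnot(inherits(ft, "feature_table"))
  validate_manifest(manifest)
  idx <- match(ft$features$feature_id, ranges$feature_id)
  if (anyNA(idx)) {
    stop("feature(s) missing from ranges: ",
         paste(ft$features$feature_id[is.na(idx)][1:min(5, sum(is.na(idx)))],
               collapse = ", "))
  }
  ranges <- ranges[idx, , drop = FALSE]
  pats <- manifest$specimen_id[manifest$role != "outgroup"]
  pats <- intersect(colnames(ft$intensities), pats)  # preserve table order
  if (!length(pats)) stop("no patient specimens shared between manifest and table")
  X <- ft$intensities[, pats, drop = FALSE]
  X[is.na(X)] <- 0
  nf <- nrow(X)
  states <- matrix(0L, length(pats), nf,
                   dimnames = list(pats, ft$features$feature_id))
  direction <- matrix("none", length(pats), nf,
                      dimnames = list(pats, ft$features$feature_id))
  for (j in seq_len(nf)) {
    v <- X[j, ]
    detected <- v > min_intensity
    lo <- ranges$lo[j]; hi <- ranges$hi[j]
    og_det <- ranges$outgroup_detected[j]
    up <- detected & v > hi
    dn <- detected & v < lo
    vanish <- !detected & og_det
    states[up | dn | vanish, j] <- 1L
    direction[up, j] <- if (og_det) "up" else "novel"
    direction[dn, j] <- "down"
    direction[vanish, j] <- "vanished"
  }
  structure(
    list(states = states, direction = direction, ranges = ranges,
         outgroup = manifest$specimen_id[manifest$role == "outgroup"]),
    class = "polarized_matrix"
  )
}

#' @export
print.polarized_matrix <- function(x, ...) {
  cat("Polarized character matrix: ", nrow(x$states), " specimens x ",
      ncol(x$states), " characters; ", sum(x$states), " derived cells (",
      round(100 * mean(x$states), 1), "%)\n", sep = "")
  tab <- table(x$direction[x$states == 1L])
  if (length(tab)) {
    cat("  directions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Append the all-ancestral hypothetical taxon
#'
#' Adds one all-zero row to the polarized matrix: a hypothetical ancestor
#' carrying the outgroup-normal state at every character. It is used
#' downstream to root the cladogram ([root_on_outgroup()]).
#'
#' @param pm a `polarized_matrix`.
#' @param label taxon label for the hypothetical ancestor (must not clash
#'   with a specimen id).
#' @return the `polarized_matrix` with one extra row.
#' @export
append_hypothetical_ancestor <- function(pm, label = "HTU") {
  stopifnot(inherits(pm, "polarized_matrix"))
  if (label %in% rownames(pm$states)) {
    stop("label already present in matrix: ", label)
  }
  pm$states <- rbind(pm$states, matrix(0L, 1, ncol(pm$states), dimnames = list(label)))
  pm$direction <- rbind(pm$direction,
                        matrix("none", 1, ncol(pm$direction), dimnames = list(label)))
  pm$ancestor_label <- label
  pm
}

#' Drop uninformative characters
#'
#' The default pipeline keeps every character (no a priori selection); this
#' optional filter removes characters that cannot influence tree choice.
#' `constant_only` removes all-0 and all-1 columns; `parsimony_uninformative`
#' additionally removes singletons (derived in exactly one specimen), which
#' contribute a constant 1 to every tree length. The removed characters are
#' returned so autapomorphy accounting can re-attach them.
#'
#' @param pm a `polarized_matrix`.
#' @param mode `"constant_only"` or `"parsimony_uninformative"`.
#' @return a list with `matrix` (the filtered `polarized_matrix`) and
#'   `removed` (data.frame of `feature_id` and `reason`).
#' @export
drop_uninformative_characters <- function(pm, mode = c("constant_only", "parsimony_uninformative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pm, "polarized_matrix"))
  csums <- colSums(pm$states)
  n <- nrow(pm$states)
  reason <- rep(NA_character_, ncol(pm$states))
  reason[csums == 0L] <- "constant_0"
  reason[csums == n] <- "constant_1"
  if (mode == "parsimony_uninformative") {
    reason[csums == 1L] <- "singleton"
    reason[csums == n - 1L & csums > 0L] <- "singleton"
  }
  drop <- !is.na(reason)
  removed <- data.frame(feature_id = colnames(pm$states)[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  pm$states <- pm$states[, !drop, drop = FALSE]
  pm$direction <- pm$direction[, !drop, drop = FALSE]
  pm$ranges <- pm$ranges[!drop, , drop = FALSE]
  list(matrix = pm, removed = removed)
}

#' Write / read a polarized matrix
#'
#' `write_polarized_csv()` writes the binary states as a specimens x
#' characters CSV. `write_phylip_matrix()` writes a PHYLIP-style relaxed
#' sequential character matrix (taxon name, whitespace, 0/1 string) for
#' interoperability with legacy parsimony programs;
#' `read_phylip_matrix()` reads it back as a binary matrix.
#'
#' @param pm a `polarized_matrix` (or binary matrix for the PHYLIP writer).
#' @param path file path.
#' @return `path` (writers) or a binary integer matrix (reader), invisibly
#'   for writers.
#' @export
write_polarized_csv <- function(pm, path) {
  states <- if (inherits(pm, "polarized_matrix")) pm$states else pm
  df <- data.frame(specimen_id = rownames(states), states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_polarized_csv
#' @export
write_phylip_matrix <- function(pm, path) {
  states <- if (inherits(pm, "polarized_matrix")) pm$states else pm
  lines <- c(
    paste(nrow(states), ncol(states)),
    paste0(rownames(states), "  ", apply(states, 1L, paste, collapse = ""))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_polarized_csv
#' @export
read_polarized_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  m
}

#' @rdname write_polarized_csv
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr[1L]) {
    stop("PHYLIP matrix: header declares ", hdr[1L], " taxa, found ", length(body))
  }
  parts <- strsplit(trimws(body), "\\s+")
  taxa <- vapply(parts, `[[`, character(1), 1L)
  seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1))
  if (any(nchar(seqs) != hdr[2L])) stop("PHYLIP matrix: sequence length mismatch")
  m <- t(vapply(strsplit(seqs, ""), function(s) as.integer(s), integer(hdr[2L])))
  rownames(m) <- taxa
  colnames(m) <- paste0("char", seq_len(hdr[2L]))
  m
}
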