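# In-code fixtures shared across test files.

# A minimal hand-written feature table: 3 features x 2 specimens.
tiny_feature_csv <- function(path) {
  writeLines(c(
    "feature_id,mz,rt,S1,S2",
    "F1,176.117,1.705,1000,1200",
    "F2,300.5,5.2,50,",
    "F3,849.9,9.9,0,10"
  ), path)
  path
}

tiny_manifest <- function() {
  data.frame(
    specimen_id = c("OG1", "OG2", "OG3", "S1", "S2"),
    patient_id = c("OG1", "OG2", "OG3", "P1", "P2"),
    role = c("outgroup", "outgroup", "outgroup", "pre_RT", "post_RT"),
    stringsAsFactors = FALSE
  )
}

# Build a feature_table directly from an intensity matrix (features x
# specimens); mz/rt synthesized deterministically.
make_ft <- function(intensities, mz = NULL, rt = NULL, ion_mode = "positive") {
  nf <- nrow(intensities)
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- sprintf("F%03d", seq_len(nf))
  }
  if (is.null(mz)) mz <- seq(100, 800, length.out = nf)
  if (is.null(rt)) rt <- seq(0.5, 9.5, length.out = nf)
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(feature_id = rownames(intensities), mz = mz, rt = rt,
                   intensities, check.names = FALSE)
  utils::write.csv(df, tmp, row.names = FALSE, na = "")
  read_feature_table(tmp, ion_mode)
}

# Independent five-case polarization oracle, written cell-by-cell without
# reusing any package code paths.
oracle_polarize_cell <- function(value, lo, hi, og_detected) {
  v <- if (is.na(value)) 0 else value
  if (v == 0) {
    if (og_detected) c(1L, "vanished") else c(0L, "none")
  } else if (v > hi) {
    if (og_detected) c(1L, "up") else c(1L, "novel")
  } else if (v < lo) {
    c(1L, "down")
  } else {
    c(0L, "none")
  }
}

# Brute-force Fitch oracle: enumerate every internal-node labeling of a
# rooted binary tree and count edge changes, minimized over labelings.
oracle_min_changes <- function(phy, char_states) {
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    lab <- integer(ntip + nint)
    lab[seq_len(ntip)] <- char_states[phy$tip.label]
    lab[ntip + seq_len(nint)] <- bitwAnd(bitwShiftR(mask, seq_len(nint) - 1L), 1L)
    changes <- sum(lab[phy$edge[, 1]] != lab[phy$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

random_binary_matrix <- function(n_taxa, n_chars, p = 0.5) {
  matrix(as.integer(stats::runif(n_taxa * n_chars) < p), n_taxa, n_chars,
         dimnames = list(paste0("t", seq_len(n_taxa)),
                         paste0("c", seq_len(n_chars))))
}

# Perfect-phylogeny matrix for a ladder tree over the given taxa: character
# j is derived exactly in taxa j..n (plus an all-zero outgroup row "HTU").
ladder_matrix <- function(taxa, reps = 1) {
  n <- length(taxa)
  cols <- list()
  for (j in 2:(n - 1)) {
    for (r in seq_len(reps)) {
      v <- as.integer(seq_len(n) >= j)
      cols[[paste0("c", j, "_", r)]] <- v
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  m
}
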