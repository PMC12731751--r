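make_outgroup_ft <- function(og_values, patient_values) {
  # one feature per row of og_values; patients appended as extra columns
  inten <- cbind(og_values, patient_values)
  colnames(inten) <- c(paste0("OG", seq_len(ncol(og_values))),
                       paste0("S", seq_len(ncol(patient_values))))
  make_ft(inten)
}

range_manifest <- function(n_og, n_pat) {
  data.frame(
    specimen_id = c(paste0("OG", seq_len(n_og)), paste0("S", seq_len(n_pat))),
    patient_id = c(paste0("OG", seq_len(n_og)), paste0("P", seq_len(n_pat))),
    role = c(rep("outgroup", n_og), rep("pre_RT", n_pat)),
    stringsAsFactors = FALSE
  )
}

test_that("normal ranges match min-max and mean +/- k*sd arithmetic", {
  ft <- make_ft(matrix(c(10, 20, 30, 5,
                         0, 0, 0, 7), 2, 4, byrow = TRUE,
                dimnames = list(NULL, c("OG1", "OG2", "OG3", "S1"))))
  mf <- range_manifest(3, 1)
  rng <- compute_normal_ranges(ft, mf, method = "minmax")
  expect_equal(rng$lo, c(10, 0))
  expect_equal(rng$hi, c(30, 0))
  expect_equal(rng$outgroup_detected, c(TRUE, FALSE))

  rng2 <- compute_normal_ranges(ft, mf, method = "mean_k_sd", k = 2)
  s <- sqrt(((10 - 20)^2 + 0 + (30 - 20)^2) / 2)  # sample sd by hand
  expect_equal(rng2$lo[1], max(20 - 2 * s, 0))
  expect_equal(rng2$hi[1], 20 + 2 * s)

  mf0 <- mf[mf$role != "outgroup", ]
  expect_error(compute_normal_ranges(ft, mf0), "no outgroup")
})

test_that("polarization matches the five-case oracle cell by cell", {
  set.seed(77)
  n_og <- 4; n_pat <- 10; n_feat <- 20
  og <- matrix(rlnorm(n_feat * n_og, 5, 1), n_feat, n_og)
  og[1:3, ] <- 0                              # novel candidates
  pat <- matrix(rlnorm(n_feat * n_pat, 5, 1.5), n_feat, n_pat)
  pat[2, ] <- 0                               # stays ancestral (og absent too)
  pat[5, 1:4] <- 0                            # vanished cells
  pat[6, 2] <- NA                             # missing == not detected
  ft <- make_outgroup_ft(og, pat)
  mf <- range_manifest(n_og, n_pat)
  rng <- compute_normal_ranges(ft, mf)
  pm <- polarize(ft, rng, mf)

  expect_equal(rownames(pm$states), paste0("S", seq_len(n_pat)))
  for (j in seq_len(n_feat)) {
    lo <- min(og[j, ]); hi <- max(og[j, ])
    og_det <- any(og[j, ] > 0)
    for (i in seq_len(n_pat)) {
      oc <- oracle_polarize_cell(pat[j, i], lo, hi, og_det)
      expect_identical(pm$states[i, j], as.integer(oc[1]))
      expect_identical(pm$direction[i, j], oc[2])
    }
  }
  # every derived cell carries a direction; every ancestral cell none
  expect_true(all((pm$states == 1L) == (pm$direction != "none")))
})

test_that("outgroup specimens polarize to all zeros against their own range", {
  set.seed(5)
  og <- matrix(rlnorm(30 * 5, 6, 0.8), 30, 5)
  ft <- make_outgroup_ft(og, og)  # patients are copies of the outgroup
  mf <- range_manifest(5, 5)
  rng <- compute_normal_ranges(ft, mf)
  pm <- polarize(ft, rng, mf)
  expect_true(all(pm$states == 0L))
})

test_that("polarization is independent of specimen order", {
  set.seed(9)
  og <- matrix(rlnorm(12 * 3, 5, 1), 12, 3)
  pat <- matrix(rlnorm(12 * 4, 5, 1.4), 12, 4)
  ft <- make_outgroup_ft(og, pat)
  mf <- range_manifest(3, 4)
  pm1 <- polarize(ft, compute_normal_ranges(ft, mf), mf)
  mf2 <- mf[rev(seq_len(nrow(mf))), ]
  pm2 <- polarize(ft, compute_normal_ranges(ft, mf2), mf2)
  expect_identical(pm1$states, pm2$states[rownames(pm1$states), ])
})

test_that("hypothetical ancestor is an all-zero extra row, added once", {
  set.seed(2)
  og <- matrix(rlnorm(8 * 3, 5, 1), 8, 3)
  pat <- matrix(rlnorm(8 * 4, 5, 1.4), 8, 4)
  ft <- make_outgroup_ft(og, pat)
  mf <- range_manifest(3, 4)
  pm <- polarize(ft, compute_normal_ranges(ft, mf), mf)
  pm2 <- append_hypothetical_ancestor(pm, "ROOT")
  expect_equal(nrow(pm2$states), nrow(pm$states) + 1L)
  expect_equal(sum(pm2$states["ROOT", ]), 0L)
  expect_identical(pm2$states[rownames(pm$states), ], pm$states)
  expect_error(append_hypothetical_ancestor(pm2, "ROOT"), "already present")
})

test_that("uninformative-character filters match a brute-force recount", {
  set.seed(13)
  m <- random_binary_matrix(6, 40, p = 0.25)
  pm <- structure(
    list(states = m, direction = matrix("none", 6, 40, dimnames = dimnames(m)),
         ranges = data.frame(feature_id = colnames(m))),
    class = "polarized_matrix"
  )
  res_c <- drop_uninformative_characters(pm, "constant_only")
  keep_c <- colSums(m) > 0 & colSums(m) < 6
  expect_identical(colnames(res_c$matrix$states), colnames(m)[keep_c])

  res_p <- drop_uninformative_characters(pm, "parsimony_uninformative")
  keep_p <- colSums(m) >= 2 & colSums(m) <= 4
  expect_identical(colnames(res_p$matrix$states), colnames(m)[keep_p])
  expect_setequal(res_p$removed$feature_id, colnames(m)[!keep_p])

  # all-zero matrix retains nothing
  z <- pm; z$states[] <- 0L
  expect_equal(ncol(drop_uninformative_characters(z, "constant_only")$matrix$states), 0L)
})

test_that("PHYLIP matrix writer and reader round-trip the binary states", {
  set.seed(4)
  m <- random_binary_matrix(5, 12)
  path <- tempfile(fileext = ".phy")
  write_phylip_matrix(m, path)
  back <- read_phylip_matrix(path)
  expect_identical(unname(back), unname(m))
  expect_identical(rownames(back), rownames(m))
})
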