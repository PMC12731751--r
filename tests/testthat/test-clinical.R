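test_that("prevalence uses half-up rounding to one decimal", {
  expect_equal(prevalence(7, 11), 63.6)
  expect_equal(prevalence(5, 11), 45.5)
  expect_equal(prevalence(5, 7), 71.4)
  expect_equal(prevalence(6, 7), 85.7)
  expect_equal(prevalence(13, 55), 23.6)
  expect_equal(prevalence(0, 7), 0.0)
  expect_equal(prevalence(7, 7), 100.0)
  expect_equal(prevalence(1, 16), 6.3)   # 6.25 rounds half-up
  expect_error(prevalence(1, 0), "empty group")
  expect_error(prevalence(8, 7), "between 0 and group_size")
})

test_that("clinical fixture reproduces every printed cohort margin", {
  clin <- load_table1_fixture()
  expect_equal(nrow(clin), 55L)
  expect_equal(unname(table(clin$race)[c("Black", "White", "other")]),
               c(15L, 37L, 3L), ignore_attr = TRUE)
  expect_equal(unname(table(clin$t_stage)[c("T1c", "T2a-b", "T2c")]),
               c(40L, 12L, 3L), ignore_attr = TRUE)
  expect_equal(unname(table(clin$gleason)[c("6", "7", "8", "9")]),
               c(20L, 30L, 4L, 1L), ignore_attr = TRUE)
  expect_equal(unname(table(clin$risk)[c("low", "intermediate", "high")]),
               c(14L, 34L, 7L), ignore_attr = TRUE)
  expect_equal(sum(clin$adt), 13L)
  expect_equal(unname(table(clin$protocol)[c("SBRT_35", "SBRT_36.25",
                                             "SBRT_IMRT_45", "SBRT_IMRT_50.4")]),
               c(6L, 36L, 9L, 4L), ignore_attr = TRUE)
  # metastatic subgroup: 11 patients, 3 low / 6 intermediate / 2 high, 4 on ADT
  met <- clin[clin$metastasis, ]
  expect_equal(nrow(met), 11L)
  expect_equal(unname(table(met$risk)[c("low", "intermediate", "high")]),
               c(3L, 6L, 2L), ignore_attr = TRUE)
  expect_equal(sum(met$adt), 4L)
  expect_equal(sum(met$adt & met$risk == "intermediate" &
                     met$protocol_group == "SBRT_IMRT"), 1L)
  # printed ranges and medians
  expect_equal(range(clin$age), c(52, 90))
  expect_equal(median(clin$age), 68)
  expect_equal(range(clin$psa_pre), c(1.9, 25.6))
  expect_equal(median(clin$psa_pre), 8.1)
  # metastatic low/intermediate: pre-RT PSA > 4, post-RT < 4
  mli <- clin[clin$metastasis & clin$risk != "high", ]
  expect_true(all(mli$psa_pre > 4))
  expect_true(all(mli$psa_post < 4))
  # deterministic
  expect_identical(clin, load_table1_fixture())
})

test_that("biosignature fixture reproduces the printed prevalences", {
  fx <- load_table2_fixture()
  rep_met <- biosignature_prevalence_report(
    fx$metastatic$markers, list(metastatic = fx$metastatic$patients)
  )
  g <- function(char) rep_met$prevalence_pct[rep_met$character == char]
  expect_equal(g("pre:D-tryptophan"), 63.6)
  expect_equal(g("pre:hypoxanthine"), 100.0)
  expect_equal(g("post:phosphoric acid"), 45.5)
  expect_equal(g("post:m/z 416.91035669"), 63.6)
  expect_equal(g("post:bilirubin"), 100.0)
  expect_equal(g("post:PC"), 100.0)
  expect_equal(g("post:phthalic acid"), 100.0)
  expect_equal(g("post:5'-benzoylphosphoadenosine"), 100.0)

  rep_hr <- biosignature_prevalence_report(
    fx$high_risk$markers, list(high_risk = fx$high_risk$patients)
  )
  expect_true(all(rep_hr$prevalence_pct == 100.0))
  expect_equal(nrow(fx$high_risk$markers), 7L)

  pc <- fx$printed_counts
  expect_equal(pc$prevalence_pct[pc$biosignature == "carbamic acid" &
                                   pc$group == "metastatic_subgroup"], 85.7)
  expect_equal(pc$prevalence_pct[pc$biosignature == "phosphoric acid" &
                                   pc$group == "metastatic_subgroup"], 71.4)
  expect_equal(pc$prevalence_pct[pc$biosignature == "ADT"], 23.6)
})

test_that("prevalence report counts match a brute-force recount on random data", {
  set.seed(55)
  m <- random_binary_matrix(20, 8, p = 0.4)
  groups <- split(rownames(m), rep(c("g1", "g2", "g3"), length.out = 20))
  rep <- biosignature_prevalence_report(m, groups)
  for (r in seq_len(nrow(rep))) {
    ids <- groups[[rep$group[r]]]
    manual <- sum(m[ids, rep$character[r]])
    expect_equal(rep$carriers[r], manual)
    expect_equal(rep$group_size[r], length(ids))
    expect_equal(rep$prevalence_pct[r],
                 floor(1000 * manual / length(ids) + 0.5 + 1e-9) / 10)
  }
  expect_true(all(rep$prevalence_pct >= 0 & rep$prevalence_pct <= 100))
  expect_true(all(rep$carriers <= rep$group_size))
  # row permutation of the carriage matrix leaves the report unchanged
  rep2 <- biosignature_prevalence_report(m[sample(rownames(m)), ], groups)
  expect_identical(rep, rep2)
  expect_error(biosignature_prevalence_report(m, list(g = c("nobody"))),
               "unresolvable")
  allc <- biosignature_prevalence_report(
    matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "x")), NULL)
  expect_equal(allc$prevalence_pct, 100.0)
})

test_that("clade-covariate matrix summarises and scales covariates", {
  clin <- data.frame(
    patient_id = paste0("P", 1:4),
    psa_pre = c(4, 6, 10, 12),
    risk = c("low", "low", "high", "high"),
    stringsAsFactors = FALSE
  )
  clades <- setNames(c("c1", "c1", "c2", "c2"), clin$patient_id)
  cm <- clade_covariate_matrix(clades, clin, c("psa_pre", "risk"))
  s <- cm$summaries
  expect_equal(s$median[s$clade == "c1" & s$covariate == "psa_pre"], 5)
  expect_equal(s$median[s$clade == "c2" & s$covariate == "psa_pre"], 11)
  expect_equal(range(cm$scaled[, "psa_pre"]), c(0, 1))

  # single clade: summaries equal whole-cohort summaries
  one <- setNames(rep("c1", 4), clin$patient_id)
  s1 <- clade_covariate_matrix(one, clin, "psa_pre")$summaries
  expect_equal(s1$median, median(clin$psa_pre))

  # a missing covariate cell is kept and flagged NA
  clin$psa_pre[2] <- NA
  cm2 <- clade_covariate_matrix(clades, clin, "psa_pre")
  expect_true(is.na(cm2$raw$psa_pre[cm2$raw$patient_id == "P2"]))
  expect_equal(nrow(cm2$raw), 4L)
})

test_that("independently generated ADT shows no clade enrichment at large n", {
  # covariates are drawn independently of the planted clades, so per-clade
  # ADT proportions must sit within binomial sampling bounds of the rate
  ids <- sprintf("P%02d", 1:400)
  plan <- list(
    list(label = "left", members = ids[1:200], n_syn = 2, directions = "up"),
    list(label = "right", members = ids[201:400], n_syn = 2, directions = "up")
  )
  coh <- generate_cohort(cohort_config(
    n_outgroup = 3, n_patients = 400, clade_plan = plan,
    n_noise_features = 2, noise_sd = 0, seed = 808
  ))
  clades <- coh$truth$clade_assignment
  clin <- coh$clinical
  adt <- clin$adt[match(names(clades), clin$patient_id)]
  p_global <- mean(adt)
  for (g in unique(clades)) {
    sel <- clades == g
    se <- sqrt(p_global * (1 - p_global) / sum(sel))
    expect_lt(abs(mean(adt[sel]) - p_global), 4 * se + 1e-9)
  }
})

test_that("association test matches the exact hypergeometric oracle", {
  clin <- data.frame(
    patient_id = paste0("P", 1:10),
    grp = rep(c("x", "y"), each = 5),
    stringsAsFactors = FALSE
  )
  clades <- setNames(rep(c("c1", "c2"), each = 5), clin$patient_id)
  a <- clade_covariate_association(clades, clin, "grp")
  expect_equal(a$test, "fisher")
  # two-sided Fisher p for [[5,0],[0,5]] by direct enumeration: the table
  # probability under fixed margins is choose(5,k)*choose(5,5-k)/choose(10,5);
  # both extreme tables (k=0, k=5) are equally likely
  p_exact <- 2 * (choose(5, 5) * choose(5, 0) / choose(10, 5))
  expect_equal(a$p_value, p_exact, tolerance = 1e-12)

  # degenerate: a covariate level nobody has
  clin$grp <- factor(clin$grp, levels = c("x", "y", "z"))
  b <- clade_covariate_association(clades, clin, "grp")
  expect_true(is.na(b$p_value) || !b$degenerate)  # empty level dropped by table()

  clin2 <- data.frame(patient_id = paste0("P", 1:10), grp = "x",
                      stringsAsFactors = FALSE)
  d <- clade_covariate_association(clades, clin2, "grp")
  expect_true(d$degenerate)
  expect_true(is.na(d$p_value))
})

test_that("balanced clade cut yields two non-trivial groups", {
  tr <- ape::read.tree(text = "(HTU,(t1,(t2,(t3,(t4,(t5,t6))))));")
  r <- root_on_outgroup(tr, "HTU")
  cl <- clade_membership(r, 2, method = "balanced")
  expect_equal(as.integer(sort(table(cl))), c(3L, 3L))
  cl_root <- clade_membership(r, 2, method = "root")
  expect_setequal(names(cl_root), paste0("t", 1:6))
})
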