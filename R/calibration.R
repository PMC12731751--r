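#' Calibration of clade-covariate association tests on null cohorts
#'
#' Repeatedly generates a null cohort ([generate_null_cohort()]), infers a
#' cladogram, cuts it into its two major clades
#' ([clade_membership()] with the balanced cut), draws a three-level
#' categorical covariate (risk-group-like, levels equiprobable)
#' independently of the data, and records the association p-value
#' (chi-square branch of [clade_covariate_association()], whose p-values
#' are approximately uniform under the null — unlike conditionally exact
#' tests, which are discrete and conservative by construction). Because
#' the covariate is independent of the intensities, the null hypothesis
#' holds in every run and the returned p-values should be approximately
#' uniform on (0, 1).
#'
#' The per-run problem size (30 patients, 5 outgroup specimens, 60
#' features, one random-addition replicate with NNI swapping) keeps a
#' 200-run calibration inside a few minutes on one core while leaving the
#' contingency tables large enough for the chi-square approximation.
#'
#' @param n_runs number of simulated cohorts (default 200).
#' @param seed master seed.
#' @param n_outgroup,n_patients,n_noise_features,noise_sd cohort settings
#'   passed to [cohort_config()].
#' @return data.frame with `run`, `p_value`, `min_clade_size`.
#' @export
null_association_calibration <- function(n_runs = 200, seed = 1,
                                         n_outgroup = 5, n_patients = 30,
                                         n_noise_features = 60, noise_sd = 0.3) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  cohort_seeds <- sample.int(2^30, n_runs)
  covariates <- matrix(sample(c("low", "intermediate", "high"),
                              n_runs * n_patients, replace = TRUE), n_runs)
  ps <- numeric(n_runs)
  msz <- integer(n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- cohort_config(n_outgroup = n_outgroup, n_patients = n_patients,
                         n_noise_features = n_noise_features,
                         noise_sd = noise_sd, seed = cohort_seeds[i])
    coh <- generate_null_cohort(cfg)
    rng <- compute_normal_ranges(coh$feature_table, coh$manifest)
    pm <- polarize(coh$feature_table, rng, coh$manifest)
    pm <- append_hypothetical_ancestor(pm)
    hs <- heuristic_search(pm, n_replicates = 1, seed = cohort_seeds[i] %% 100000L,
                           swap = "nni", keep_max = 1)
    cl <- clade_membership(root_on_outgroup(hs$trees[[1L]], "HTU"),
                           n_clades = 2, method = "balanced")
    covar <- data.frame(
      patient_id = coh$clinical$patient_id,
      grp = covariates[i, ],
      stringsAsFactors = FALSE
    )
    a <- clade_covariate_association(cl, covar, "grp", test = "chisq")
    ps[i] <- a$p_value
    msz[i] <- min(table(cl))
  }
  data.frame(run = seq_len(n_runs), p_value = ps, min_clade_size = msz)
}
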