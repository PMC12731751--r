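#' Configure a synthetic cohort
#'
#' Defines the statistical structure the analysis assumes: a healthy
#' outgroup that fixes per-feature normal ranges, patients organised into
#' planted clades each carrying planted synapomorphic features, nuisance
#' noise features, and clinical covariates generated (by default)
#' independently of the clade structure — emulating a cohort of 55
#' patients in which hormonal treatment, risk group, metastasis and PSA
#' did not track clade membership. Baseline intensities are log-normal
#' (the conventional LC-MS abundance model, a declared assumption);
#' planted effects shift clade members multiplicatively outside the
#' outgroup min-max.
#'
#' @param n_outgroup number of healthy outgroup specimens (default 10).
#' @param n_patients number of patients (default 55).
#' @param paired if `TRUE`, each patient contributes a `_pre` and a
#'   `_post` specimen; clade plans then address specimen ids.
#' @param clade_plan list of planted clades, each
#'   `list(label =, members =, n_syn =, directions =)` with `members` a
#'   vector of specimen ids; `NULL` for the default nested ladder built
#'   by [default_clade_plan()].
#' @param n_clades,syn_per_clade parameters of the default plan (5 clades
#'   of 5 synapomorphies, echoing a five-subclade cladogram).
#' @param n_noise_features number of unplanted features (default 200).
#' @param baseline_log_range range of the per-feature log-normal location
#'   parameter (natural log of intensity; default log(1e3)..log(1e6)).
#' @param noise_sd log-normal scale parameter in natural-log units
#'   (default 0.3); 0 gives noise-free intensities.
#' @param effect_up,effect_down multiplicative shift of derived cells
#'   relative to the outgroup max (up, default 3) or min (down,
#'   default 1/3).
#' @param direction_weights sampling weights over planted-effect
#'   directions `up`, `down`, `novel`, `vanished`.
#' @param missing_rate probability that a patient cell is recorded as
#'   missing (default 0).
#' @param mz_range,rt_range ranges for feature m/z (Da) and retention
#'   time (minutes); defaults 50-850 Da and 0-10 min, the acquisition
#'   window of the assay.
#' @param risk_probs,adt_rate,metastasis_rate clinical covariate model,
#'   defaulting to the cohort margins 14/34/7 risk, 13/55 ADT,
#'   11/55 metastasis.
#' @param metastasis_clade optional clade label to couple metastasis to
#'   (members then have probability `metastasis_rate_coupled`).
#' @param metastasis_rate_coupled coupled metastasis probability
#'   (default 0.7).
#' @param seed master seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_outgroup = 10, n_patients = 55, paired = FALSE,
                          clade_plan = NULL, n_clades = 5, syn_per_clade = 5,
                          n_noise_features = 200,
                          baseline_log_range = c(log(1e3), log(1e6)),
                          noise_sd = 0.3, effect_up = 3, effect_down = 1 / 3,
                          direction_weights = c(up = 0.4, down = 0.3,
                                                novel = 0.2, vanished = 0.1),
                          missing_rate = 0,
                          mz_range = c(50, 850), rt_range = c(0, 10),
                          risk_probs = c(low = 14 / 55, intermediate = 34 / 55,
                                         high = 7 / 55),
                          adt_rate = 13 / 55, metastasis_rate = 11 / 55,
                          metastasis_clade = NULL, metastasis_rate_coupled = 0.7,
                          seed = 1) {
  stopifnot(n_outgroup >= 2, n_patients >= 3, effect_up > 1, effect_down < 1,
            effect_down > 0, missing_rate >= 0, missing_rate <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Default nested clade plan
#'
#' Builds a laddered hierarchy of planted clades over the given specimens:
#' clade j contains specimens j..n (j = 1 is the whole ingroup). Every
#' internal edge of the implied ladder tree receives `n_syn` planted
#' synapomorphies, so with `n_clades = length(specimens) - 2` the planted
#' topology is fully resolved and — in the absence of noise — the unique
#' maximum-parsimony tree.
#'
#' @param specimens specimen ids (ingroup).
#' @param n_clades number of clades (capped at `length(specimens) - 1`).
#' @param n_syn planted synapomorphies per clade.
#' @param directions candidate directions for planted effects.
#' @return list of clade descriptions.
#' @export
default_clade_plan <- function(specimens, n_clades = 5, n_syn = 5,
                               directions = c("up", "down", "novel", "vanished")) {
  n <- length(specimens)
  n_clades <- min(n_clades, n - 1L)
  lapply(seq_len(n_clades), function(j) {
    list(label = paste0("clade_", j),
         members = specimens[j:n],
         n_syn = n_syn,
         directions = directions)
  })
}

validate_clade_plan <- function(plan, specimens) {
  for (cl in plan) {
    if (!all(cl$members %in% specimens)) {
      stop("clade '", cl$label, "' has members outside the cohort: ",
           paste(setdiff(cl$members, specimens), collapse = ", "))
    }
    if (length(cl$members) < 2L) stop("clade '", cl$label, "' has < 2 members")
  }
  # clades must be pairwise nested or disjoint
  for (i in seq_along(plan)) {
    for (j in seq_along(plan)) {
      if (i >= j) next
      a <- plan[[i]]$members; b <- plan[[j]]$members
      ov <- length(intersect(a, b))
      if (ov > 0L && ov < min(length(a), length(b))) {
        stop("clades '", plan[[i]]$label, "' and '", plan[[j]]$label,
             "' overlap without nesting")
      }
    }
  }
  invisible(plan)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  invisible(old)
}

restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Generate a synthetic cohort with planted clade structure
#'
#' Draws outgroup intensities i.i.d. per feature from the log-normal
#' baseline; shifts planted synapomorphic features outside the outgroup
#' min-max for every clade member (direction per plan: `up` above the
#' outgroup max, `down` below the min but positive, `novel` absent from
#' the outgroup and present in members, `vanished` present in the
#' outgroup and absent from members); draws noise features from the
#' baseline for everyone. Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list: `feature_table`, `manifest`,
#'   `clinical`, `truth` (planted Newick, per-clade synapomorphy lists
#'   with directions, planted binary matrix).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))

  og_ids <- sprintf("OG%02d", seq_len(config$n_outgroup))
  pat_ids <- sprintf("P%02d", seq_len(config$n_patients))
  spec_ids <- if (config$paired) {
    as.vector(t(outer(pat_ids, c("_pre", "_post"), paste0)))
  } else pat_ids
  manifest <- data.frame(
    specimen_id = c(og_ids, spec_ids),
    patient_id = c(og_ids, if (config$paired) rep(pat_ids, each = 2L) else pat_ids),
    role = c(rep("outgroup", length(og_ids)),
             if (config$paired) rep(c("pre_RT", "post_RT"), config$n_patients)
             else rep("pre_RT", length(spec_ids))),
    stringsAsFactors = FALSE
  )

  plan <- config$clade_plan
  if (is.null(plan)) {
    plan <- default_clade_plan(spec_ids, config$n_clades, config$syn_per_clade)
  }
  validate_clade_plan(plan, spec_ids)

  n_syn_total <- sum(vapply(plan, function(cl) cl$n_syn, numeric(1)))
  n_feat <- n_syn_total + config$n_noise_features
  if (n_feat < 1L) stop("infeasible plan: no features to generate")

  feature_id <- sprintf("F%04d", seq_len(n_feat))
  mz <- sort(stats::runif(n_feat, config$mz_range[1L], config$mz_range[2L]))
  rt <- stats::runif(n_feat, config$rt_range[1L], config$rt_range[2L])
  meanlog <- stats::runif(n_feat, config$baseline_log_range[1L],
                          config$baseline_log_range[2L])

  all_ids <- c(og_ids, spec_ids)
  X <- matrix(NA_real_, n_feat, length(all_ids),
              dimnames = list(feature_id, all_ids))
  truth_matrix <- matrix(0L, length(spec_ids), n_feat,
                         dimnames = list(spec_ids, feature_id))

  rl <- function(n, ml) {
    if (config$noise_sd == 0) rep(exp(ml), n) else stats::rlnorm(n, ml, config$noise_sd)
  }
  jit <- function(n) {
    if (config$noise_sd == 0) rep(1, n) else exp(stats::rnorm(n, 0, config$noise_sd / 3))
  }

  syn_records <- list()
  f <- 0L
  for (cl in plan) {
    members <- cl$members
    nonmembers <- setdiff(spec_ids, members)
    dirs <- rep_len(cl$directions, cl$n_syn)
    for (s in seq_len(cl$n_syn)) {
      f <- f + 1L
      d <- dirs[s]
      if (d == "novel") {
        X[f, og_ids] <- 0
        X[f, nonmembers] <- 0
        X[f, members] <- rl(length(members), meanlog[f])
      } else if (d == "vanished") {
        X[f, og_ids] <- rl(length(og_ids), meanlog[f])
        X[f, nonmembers] <- rl(length(nonmembers), meanlog[f])
        X[f, members] <- 0
      } else {
        og_vals <- rl(length(og_ids), meanlog[f])
        X[f, og_ids] <- og_vals
        X[f, nonmembers] <- rl(length(nonmembers), meanlog[f])
        X[f, members] <- if (d == "up") {
          config$effect_up * max(og_vals) * jit(length(members))
        } else {
          config$effect_down * min(og_vals) * jit(length(members))
        }
      }
      truth_matrix[members, f] <- 1L
      syn_records[[length(syn_records) + 1L]] <- data.frame(
        clade = cl$label, feature_id = feature_id[f], direction = d,
        stringsAsFactors = FALSE
      )
    }
  }
  if (config$n_noise_features > 0L) {
    for (k in seq_len(config$n_noise_features)) {
      f <- f + 1L
      X[f, ] <- rl(length(all_ids), meanlog[f])
    }
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n_feat * length(spec_ids)) < config$missing_rate,
                   n_feat, length(spec_ids))
    X[, spec_ids][drop] <- NA_real_
  }

  ft <- new_feature_table(
    data.frame(feature_id = feature_id, mz = mz, rt = rt, stringsAsFactors = FALSE),
    X, "positive"
  )

  clade_of <- clade_assignment_from_plan(plan, spec_ids)
  clinical <- generate_clinical(config, pat_ids, spec_ids, clade_of)

  truth <- list(
    tree_newick = planted_newick(plan, spec_ids),
    synapomorphies = do.call(rbind, syn_records),
    matrix = truth_matrix,
    clade_assignment = clade_of
  )
  structure(
    list(feature_table = ft, manifest = manifest, clinical = clinical,
         truth = truth, config = config),
    class = "synthetic_cohort"
  )
}

# innermost clade containing each specimen (or NA)
clade_assignment_from_plan <- function(plan, spec_ids) {
  out <- rep(NA_character_, length(spec_ids))
  names(out) <- spec_ids
  if (!length(plan)) return(out)
  sizes <- vapply(plan, function(cl) length(cl$members), integer(1))
  for (i in order(-sizes)) {       # small (inner) clades overwrite large
    out[plan[[i]]$members] <- plan[[i]]$label
  }
  out
}

planted_newick <- function(plan, spec_ids, root_label = "HTU") {
  clades <- lapply(plan, `[[`, "members")
  clades <- clades[vapply(clades, function(m) length(m) < length(spec_ids), logical(1))]
  paste0("(", root_label, ",", build_from_clades(spec_ids, clades), ");")
}

generate_clinical <- function(config, pat_ids, spec_ids, clade_of) {
  n <- length(pat_ids)
  risk <- sample(names(config$risk_probs), n, replace = TRUE,
                 prob = config$risk_probs)
  adt <- ifelse(risk == "low", FALSE,
                stats::runif(n) < config$adt_rate / sum(config$risk_probs[c("intermediate", "high")]))
  if (is.null(config$metastasis_clade)) {
    metastasis <- stats::runif(n) < config$metastasis_rate
  } else {
    # couple metastasis to one planted clade (any specimen of the patient)
    in_clade <- vapply(pat_ids, function(p) {
      sp <- spec_ids[startsWith(spec_ids, p)]
      any(clade_of[sp] == config$metastasis_clade, na.rm = TRUE)
    }, logical(1))
    metastasis <- stats::runif(n) < ifelse(in_clade, config$metastasis_rate_coupled,
                                           config$metastasis_rate)
  }
  data.frame(
    patient_id = pat_ids,
    age = round(stats::runif(n, 52, 90)),
    race = sample(c("Black", "White", "other"), n, replace = TRUE,
                  prob = c(15, 37, 3) / 55),
    psa_pre = round(exp(stats::runif(n, log(1.9), log(25.6))), 1),
    psa_post = NA_real_,
    testosterone = NA_real_,
    adt = adt, risk = risk,
    gleason = sample(c("6", "7", "8", "9"), n, replace = TRUE,
                     prob = c(20, 30, 4, 1) / 55),
    t_stage = sample(c("T1c", "T2a-b", "T2c"), n, replace = TRUE,
                     prob = c(40, 12, 3) / 55),
    metastasis = metastasis,
    protocol = sample(c("SBRT_35", "SBRT_36.25", "SBRT_IMRT_45", "SBRT_IMRT_50.4"),
                      n, replace = TRUE, prob = c(6, 36, 9, 4) / 55),
    stringsAsFactors = FALSE
  )
}

#' Generate a null cohort (no planted structure)
#'
#' All patient intensities are drawn from the same log-normal baseline as
#' the outgroup, so any derived call is a rank artefact of min-max
#' polarization: with `n` outgroup specimens, a patient cell exceeds the
#' outgroup max (or falls below the min) with probability `1/(n+1)` per
#' side, i.e. an expected derived rate of `2/(n_outgroup+1)` per cell.
#' Used to calibrate association tests and false-synapomorphy rates.
#'
#' @param config a [cohort_config()]; any clade plan is ignored.
#' @return a `synthetic_cohort` whose ground-truth tree is the star tree.
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$clade_plan <- list()
  config$n_clades <- 0L
  cohort <- generate_cohort(config)
  spec_ids <- rownames(cohort$truth$matrix)
  cohort$truth$tree_newick <- paste0(
    "(HTU,", paste(spec_ids, collapse = ","), ");"
  )
  cohort
}

#' Write a synthetic cohort to disk
#'
#' Writes the same CSV dialects the readers consume, plus the ground
#' truth as Newick and JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(cohort$feature_table, file.path(dir, "features.csv"))
  write_sample_manifest(cohort$manifest, file.path(dir, "manifest.csv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  writeLines(cohort$truth$tree_newick, file.path(dir, "truth_tree.nwk"))
  jsonlite::write_json(
    list(
      synapomorphies = cohort$truth$synapomorphies,
      clade_assignment = as.list(cohort$truth$clade_assignment)
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  write_polarized_csv(cohort$truth$matrix, file.path(dir, "truth_matrix.csv"))
  invisible(dir)
}
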