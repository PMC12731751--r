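round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Prevalence of a biosignature in a patient group
#'
#' Percentage of carriers, rounded half-up to one decimal (so 7/11 gives
#' 63.6 and 5/11 gives 45.5).
#'
#' @param carriers number of carriers, `0 <= carriers <= group_size`.
#' @param group_size group size, `> 0`.
#' @return percentage in `[0, 100]` with one decimal.
#' @export
prevalence <- function(carriers, group_size) {
  if (any(group_size == 0)) stop("prevalence undefined for empty group")
  if (any(carriers < 0) || any(carriers > group_size)) {
    stop("carriers must be between 0 and group_size")
  }
  round_half_up(100 * carriers / group_size, 1)
}

#' Biosignature prevalence report
#'
#' Counts, for every (group, character) pair, how many patients in the
#' group carry the derived state, and reports the carrier prevalence.
#'
#' @param carriage binary matrix (patients x characters, row names =
#'   patient ids) or a [polarize()] result.
#' @param groups named list of patient-id vectors defining the groups, or
#'   `NULL` for a single group of all rows.
#' @param characters optional character ids to restrict to.
#' @return data.frame with columns `group`, `character`, `carriers`,
#'   `group_size`, `prevalence_pct`.
#' @export
biosignature_prevalence_report <- function(carriage, groups = NULL, characters = NULL) {
  if (inherits(carriage, "polarized_matrix")) carriage <- carriage$states
  if (is.null(groups)) groups <- list(all = rownames(carriage))
  if (!is.null(characters)) carriage <- carriage[, characters, drop = FALSE]
  rows <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    miss <- setdiff(ids, rownames(carriage))
    if (length(miss)) {
      stop("unresolvable patient id(s) in group '", g, "': ",
           paste(miss, collapse = ", "))
    }
    sub <- carriage[ids, , drop = FALSE]
    carriers <- colSums(sub > 0)
    rows[[g]] <- data.frame(
      group = g, character = colnames(sub),
      carriers = as.integer(carriers), group_size = length(ids),
      prevalence_pct = prevalence(as.integer(carriers), length(ids)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Clade-by-covariate matrix and summaries
#'
#' Joins a clade assignment with the clinical table and produces (a) a
#' per-patient covariate matrix scaled for gradient rendering (numeric
#' covariates min-max scaled per covariate; categorical covariates coded
#' as level indices) alongside the raw values, and (b) per-clade summaries
#' (median and IQR for numeric covariates, level proportions for
#' categorical ones). Missing covariate cells are flagged `NA`, never
#' dropped.
#'
#' @param clades named vector: patient id -> clade label.
#' @param clinical clinical covariate table (one row per patient, with a
#'   `patient_id` column).
#' @param covariates column names of `clinical` to include.
#' @return list with `raw` (data.frame, patients ordered by clade then
#'   input order), `scaled` (numeric matrix in `[0, 1]`), `summaries`
#'   (data.frame of per-clade statistics).
#' @export
clade_covariate_matrix <- function(clades, clinical, covariates) {
  miss <- setdiff(names(clades), clinical$patient_id)
  if (length(miss)) stop("patients missing from clinical table: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(covariates, names(clinical))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  ord <- order(factor(clades, levels = unique(clades)))
  ids <- names(clades)[ord]
  cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  raw <- data.frame(patient_id = ids, clade = clades[ord],
                    cl[, covariates, drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  scaled <- sapply(covariates, function(v) {
    x <- cl[[v]]
    if (is.numeric(x)) {
      rng <- range(x, na.rm = TRUE)
      if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1L]) / diff(rng)
    } else {
      f <- as.integer(factor(x))
      if (max(f, na.rm = TRUE) == 1L) rep(0.5, length(f))
      else (f - 1) / (max(f, na.rm = TRUE) - 1)
    }
  })
  scaled <- matrix(scaled, nrow = length(ids),
                   dimnames = list(ids, covariates))
  sums <- list()
  for (g in unique(raw$clade)) {
    sub <- raw[raw$clade == g, , drop = FALSE]
    for (v in covariates) {
      x <- sub[[v]]
      if (is.numeric(x)) {
        sums[[length(sums) + 1L]] <- data.frame(
          clade = g, covariate = v, level = NA_character_,
          median = stats::median(x, na.rm = TRUE),
          iqr = stats::IQR(x, na.rm = TRUE),
          proportion = NA_real_, n = nrow(sub), stringsAsFactors = FALSE
        )
      } else {
        tab <- table(x, useNA = "no")
        for (lv in names(tab)) {
          sums[[length(sums) + 1L]] <- data.frame(
            clade = g, covariate = v, level = lv,
            median = NA_real_, iqr = NA_real_,
            proportion = as.numeric(tab[[lv]]) / nrow(sub),
            n = nrow(sub), stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  list(raw = raw, scaled = scaled, summaries = do.call(rbind, sums))
}

#' Test association between clade membership and a categorical covariate
#'
#' Builds the clade x covariate contingency table and returns a two-sided
#' p-value: Fisher's exact test for 2 x 2 tables, Pearson's chi-square
#' (without continuity correction) otherwise. `test` can force either
#' branch; the chi-square branch is the calibrated choice for simulation
#' studies, since exact conditional p-values are discrete and
#' conservative by construction. No multiplicity correction is applied —
#' callers screening several covariates should correct externally.
#'
#' @param clades named vector patient id -> clade label (>= 2 clades).
#' @param clinical clinical table with `patient_id`.
#' @param covariate name of a categorical column of `clinical`.
#' @param test `"auto"` (default), `"fisher"`, or `"chisq"`.
#' @return list: `table`, `p_value` (`NA` when degenerate), `test`,
#'   `degenerate` (flag: empty row or column).
#' @export
clade_covariate_association <- function(clades, clinical, covariate,
                                        test = c("auto", "fisher", "chisq")) {
  test <- match.arg(test)
  miss <- setdiff(names(clades), clinical$patient_id)
  if (length(miss)) stop("patients missing from clinical table: ",
                         paste(miss, collapse = ", "))
  x <- clinical[[covariate]][match(names(clades), clinical$patient_id)]
  tab <- table(clade = as.character(clades), covariate = as.character(x))
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(table = tab, p_value = NA_real_, test = test, degenerate = TRUE))
  }
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(list(table = tab, p_value = NA_real_, test = test, degenerate = TRUE))
  }
  if (test == "auto") {
    test <- if (all(dim(tab) == 2L)) "fisher" else "chisq"
  }
  p <- if (test == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  list(table = tab, p_value = p, test = test, degenerate = FALSE)
}

#' Assign specimens to clades by cutting the cladogram
#'
#' Cuts the rooted cladogram into `n_clades` groups. With
#' `method = "root"` (default), starting from the children of the ingroup
#' root the largest group is repeatedly split at its own root until the
#' requested number of groups is reached. With `method = "balanced"` and
#' `n_clades = 2`, the tree is cut at its most balanced internal edge —
#' the "two major clades" reading of a cladogram, which avoids the
#' singleton groups a basal split can produce. The outgroup /
#' hypothetical-ancestor leaf is excluded.
#'
#' @param tree rooted `phylo`.
#' @param n_clades number of groups (>= 2).
#' @param exclude tip labels to leave out (e.g. the hypothetical ancestor).
#' @param method `"root"` or `"balanced"` (the latter for `n_clades = 2`).
#' @return named character vector: tip label -> clade label (`"clade_1"`,
#'   ... in tree traversal order).
#' @export
clade_membership <- function(tree, n_clades = 2, exclude = "HTU",
                             method = c("root", "balanced")) {
  method <- match.arg(method)
  if (method == "balanced") {
    if (n_clades != 2L) stop("balanced cut is defined for n_clades = 2")
    return(balanced_bipartition(tree, exclude))
  }
  ntip <- length(tree$tip.label)
  kids <- rooted_children(tree)
  sets <- node_tipsets(tree)
  groups <- list(ntip + 1L)  # start from the root
  expand <- function(v) kids[[v]]
  repeat {
    sizes <- vapply(groups, function(v) {
      length(setdiff(sets[[v]], exclude))
    }, integer(1))
    splittable <- vapply(groups, function(v) v > ntip, logical(1)) & sizes > 1L
    if (length(groups) >= n_clades || !any(splittable)) break
    i <- which(splittable)[which.max(sizes[splittable])]
    groups <- append(groups[-i], as.list(expand(groups[[i]])), after = i - 1L)
    # prune groups that contain only excluded leaves
    keep <- vapply(groups, function(v) length(setdiff(sets[[v]], exclude)) > 0L,
                   logical(1))
    groups <- groups[keep]
  }
  out <- character(0)
  for (i in seq_along(groups)) {
    leaves <- setdiff(sets[[groups[[i]]]], exclude)
    out[leaves] <- paste0("clade_", i)
  }
  out
}

balanced_bipartition <- function(tree, exclude) {
  ntip <- length(tree$tip.label)
  sets <- node_tipsets(tree)
  ingroup <- setdiff(tree$tip.label, exclude)
  n <- length(ingroup)
  best <- NULL
  best_gap <- Inf
  for (v in (ntip + 2L):(ntip + tree$Nnode)) {  # every non-root internal node
    a <- length(setdiff(sets[[v]], exclude))
    if (a == 0L || a == n) next
    gap <- abs(a - (n - a))
    if (gap < best_gap) { best_gap <- gap; best <- v }
  }
  if (is.null(best)) stop("no internal edge to cut")
  inside <- setdiff(sets[[best]], exclude)
  out <- stats::setNames(rep("clade_2", n), ingroup)
  out[inside] <- "clade_1"
  out
}

#' Clinical covariate fixture (cohort margins)
#'
#' A packaged 55-patient clinical table whose marginal counts match the
#' published cohort: race 15 Black / 37 White / 3 other; T-stage 40 T1c /
#' 12 T2a-b / 3 T2c; Gleason 20 / 30 / 4 / 1 (scores 6/7/8/9); D'Amico
#' risk 14 low / 34 intermediate / 7 high; ADT 13 yes / 42 no; treatment
#' protocol 6 / 36 / 9 / 4 (SBRT 35 Gy, SBRT 36.25 Gy, SBRT+IMRT 45 Gy,
#' SBRT+IMRT 50.4 Gy); 11 metastatic patients (3 low, 6 intermediate,
#' 2 high risk; 4 of them with ADT, exactly one of those on the SBRT+IMRT
#' protocol with intermediate risk). Ages (52-90, median 68) and PSA
#' (1.9-25.6 ng/mL, median 8.1) match the printed ranges and medians;
#' per-patient values within those constraints are synthetic, as are
#' testosterone levels (suppressed below 20 ng/dL under ADT). Metastatic
#' low/intermediate-risk patients have pre-RT PSA above 4 ng/mL and
#' post-RT PSA below 4 ng/mL, as reported for this cohort.
#'
#' @return data.frame with one row per patient: `patient_id`, `age`,
#'   `race`, `psa_pre`, `psa_post`, `testosterone`, `adt`, `risk`,
#'   `gleason`, `t_stage`, `metastasis`, `protocol`, `protocol_group`.
#' @export
load_table1_fixture <- function() {
  n <- 55L
  id <- sprintf("P%02d", 1:n)
  risk <- c(rep("low", 14), rep("intermediate", 34), rep("high", 7))
  metastasis <- rep(FALSE, n)
  metastasis[c(1:3, 15:20, 49:50)] <- TRUE  # 3 low, 6 intermediate, 2 high
  adt <- rep(FALSE, n)
  adt[c(15, 16, 17, 49)] <- TRUE            # 4 metastatic with ADT
  adt[c(21:27, 51, 52)] <- TRUE             # 9 further intermediate/high
  protocol <- rep("SBRT_36.25", n)
  protocol[1:6] <- "SBRT_35"
  protocol[c(7:14, 15)] <- "SBRT_IMRT_45"   # P15: the one metastatic ADT
  protocol[c(18, 28:30)] <- "SBRT_IMRT_50.4"  # patient on SBRT+IMRT
  race <- c(rep("Black", 15), rep("White", 37), rep("other", 3))
  t_stage <- c(rep("T1c", 40), rep("T2a-b", 12), rep("T2c", 3))
  gleason <- c(rep("6", 20), rep("7", 30), rep("8", 4), rep("9", 1))

  # synthetic per-patient values honouring the printed ranges and medians
  ages <- c(round(seq(52, 67, length.out = 27)), 68,
            round(seq(69, 90, length.out = 27)))
  psa <- c(round(seq(1.9, 8.0, length.out = 27), 1), 8.1,
           round(seq(8.3, 25.6, length.out = 27), 1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20260920L)
  age <- sample(ages)
  psa_pre <- sample(psa)
  # metastatic low/intermediate patients had pre-RT PSA > 4
  constrained <- which(metastasis & risk != "high")
  free <- setdiff(which(psa_pre > 4), constrained)
  for (i in constrained) {
    if (psa_pre[i] <= 4) {
      j <- free[1L]; free <- free[-1L]
      tmp <- psa_pre[i]; psa_pre[i] <- psa_pre[j]; psa_pre[j] <- tmp
    }
  }
  psa_post <- round(psa_pre * stats::runif(n, 0.05, 0.45), 2)
  psa_post[constrained] <- pmin(psa_post[constrained], 3.5)
  testosterone <- round(ifelse(adt, stats::runif(n, 5, 19),
                               stats::runif(n, 300, 700)))
  data.frame(
    patient_id = id, age = age, race = race,
    psa_pre = psa_pre, psa_post = psa_post, testosterone = testosterone,
    adt = adt, risk = risk, gleason = gleason, t_stage = t_stage,
    metastasis = metastasis, protocol = protocol,
    protocol_group = ifelse(grepl("IMRT", protocol), "SBRT_IMRT", "SBRT_only"),
    stringsAsFactors = FALSE
  )
}

#' Biosignature carriage fixture
#'
#' Packaged biosignature carriage flags reproducing the published
#' counts: among the 11 metastatic patients, pre-RT carriage of
#' D-tryptophan (7), hypoxanthine (11), tetrahydroisoquinoline (1),
#' dihydrosanguinarine (4), methylglutaric acid (3), PE (4) and PC (4),
#' and post-RT carriage of carbamic acid, bilirubin, PC, phthalic acid and
#' 5'-benzoylphosphoadenosine (all 11), phosphoric acid (5) and
#' m/z 416.91035669 (7); among the 7 high-risk patients, pre-RT carriage
#' of hypoxanthine, m/z 159.0093618, m/z 120.0038, m/z 380.772 and
#' m/z 197.08 (all 7). Per-patient flags are synthetic assignments
#' consistent with those counts.
#'
#' The printed-counts table additionally stores two subgroup records
#' exactly as published — carbamic acid 6 of 7 (85.7\%) and phosphoric
#' acid 5 of 7 (71.4\%) — whose 7-patient denominator is inconsistent
#' with the 11 metastatic patients reported elsewhere in the same source;
#' they are kept as printed, unreconciled.
#'
#' @return a list: `metastatic` (list of `patients` and binary `markers`
#'   matrix), `high_risk` (same structure), `printed_counts` (data.frame
#'   `group`, `group_size`, `phase`, `biosignature`, `carriers`,
#'   `prevalence_pct`).
#' @export
load_table2_fixture <- function() {
  clin <- load_table1_fixture()
  met <- clin$patient_id[clin$metastasis]            # 11 patients
  hr <- clin$patient_id[clin$risk == "high"]         # 7 patients
  flag <- function(ids, k) as.integer(seq_along(ids) <= k)
  met_markers <- cbind(
    `pre:D-tryptophan` = flag(met, 7),
    `pre:hypoxanthine` = flag(met, 11),
    `pre:tetrahydroisoquinoline` = flag(met, 1),
    `pre:dihydrosanguinarine` = flag(met, 4),
    `pre:methylglutaric acid` = flag(met, 3),
    `pre:PE` = flag(met, 4),
    `pre:PC` = flag(met, 4),
    `post:carbamic acid` = flag(met, 11),
    `post:phosphoric acid` = flag(met, 5),
    `post:bilirubin` = flag(met, 11),
    `post:PC` = flag(met, 11),
    `post:phthalic acid` = flag(met, 11),
    `post:5'-benzoylphosphoadenosine` = flag(met, 11),
    `post:m/z 416.91035669` = flag(met, 7)
  )
  rownames(met_markers) <- met
  hr_markers <- cbind(
    `pre:hypoxanthine` = flag(hr, 7),
    `pre:m/z 159.0093618` = flag(hr, 7),
    `pre:m/z 120.0038` = flag(hr, 7),
    `pre:m/z 380.772` = flag(hr, 7),
    `pre:m/z 197.08` = flag(hr, 7)
  )
  rownames(hr_markers) <- hr
  printed <- data.frame(
    group = c("metastatic", "metastatic", "metastatic_subgroup",
              "metastatic_subgroup", "metastatic", "metastatic",
              "metastatic", "metastatic", "metastatic", "metastatic",
              "high_risk", "all_patients"),
    group_size = c(11, 11, 7, 7, 11, 11, 11, 11, 11, 11, 7, 55),
    phase = c("pre_RT", "pre_RT", "post_RT", "post_RT", "post_RT", "post_RT",
              "post_RT", "post_RT", "post_RT", "post_RT", "pre_RT", NA),
    biosignature = c("D-tryptophan", "hypoxanthine", "carbamic acid",
                     "phosphoric acid", "phosphoric acid", "m/z 416.91035669",
                     "bilirubin", "PC", "phthalic acid",
                     "5'-benzoylphosphoadenosine", "hypoxanthine", "ADT"),
    carriers = c(7, 11, 6, 5, 5, 7, 11, 11, 11, 11, 7, 13),
    stringsAsFactors = FALSE
  )
  printed$prevalence_pct <- prevalence(printed$carriers, printed$group_size)
  list(
    metastatic = list(patients = met, markers = met_markers),
    high_risk = list(patients = hr, markers = hr_markers),
    printed_counts = printed
  )
}
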