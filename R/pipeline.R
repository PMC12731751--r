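#' Configure an end-to-end analysis run
#'
#' Collects every tunable of the read - polarize - search - synapomorphy -
#' clinical - annotation chain. Inputs may be in-memory objects (as
#' produced by [generate_cohort()]) or file paths in the package's CSV
#' dialects; paths are validated before any computation.
#'
#' @param feature_table a `feature_table` or path to a feature CSV.
#' @param manifest manifest data.frame or path.
#' @param clinical optional clinical table or path.
#' @param compounds optional compound table or path (enables annotation).
#' @param ion_mode acquisition polarity when reading from a path.
#' @param mass_range m/z window retained (default 50-850 Da).
#' @param polarization_method,k normal-range estimator (see
#'   [compute_normal_ranges()]).
#' @param min_intensity detection floor for [polarize()].
#' @param drop_uninformative `"none"` (default: all characters kept),
#'   `"constant_only"` or `"parsimony_uninformative"`.
#' @param n_replicates,seed,swap search settings (see
#'   [heuristic_search()]).
#' @param synapomorphy_mode `"strict"` or `"reconstructed"`.
#' @param n_clades clade count for clinical cross-tabulation (default 2).
#' @param tol_ppm annotation tolerance (default 5 ppm).
#' @param ancestor_label label of the appended hypothetical ancestor.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(feature_table, manifest, clinical = NULL,
                            compounds = NULL, ion_mode = "positive",
                            mass_range = c(50, 850),
                            polarization_method = "minmax", k = 2,
                            min_intensity = 0, drop_uninformative = "none",
                            n_replicates = 10, seed = 1, swap = "spr",
                            synapomorphy_mode = "strict", n_clades = 2,
                            tol_ppm = 5, ancestor_label = "HTU") {
  for (inp in c("feature_table", "manifest", "clinical", "compounds")) {
    v <- get(inp)
    if (is.character(v) && !file.exists(v)) {
      stop("input file for '", inp, "' not found: ", v)
    }
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full phylometabolomic analysis
#'
#' Executes the pipeline on a configuration and writes every stage
#' product into `out_dir`: the polarized character matrix (CSV and
#' PHYLIP), all most-parsimonious trees and the rooted cladogram
#' (Newick, with synapomorphy-count node labels), per-node synapomorphy
#' and autapomorphy tables, clade membership, clade-covariate association
#' screen, putative annotation, and a JSON run manifest recording the
#' seed and the counts at each stage. Deterministic given config + seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory stage products:
#'   `feature_table`, `matrix`, `search`, `cladogram`, `synapomorphies`,
#'   `clades`, `associations`, `annotation`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ft <- config$feature_table
  if (is.character(ft)) ft <- read_feature_table(ft, config$ion_mode)
  mf <- config$manifest
  if (is.character(mf)) mf <- read_sample_manifest(mf)
  validate_manifest(mf)
  clin <- config$clinical
  if (is.character(clin)) clin <- utils::read.csv(clin, stringsAsFactors = FALSE)
  cp <- config$compounds
  if (is.character(cp)) cp <- read_compound_table(cp)

  n_in <- nrow(ft$features)
  ft <- filter_mass_range(ft, config$mass_range[1L], config$mass_range[2L])
  standards <- check_internal_standards(ft)

  ranges <- compute_normal_ranges(ft, mf, method = config$polarization_method,
                                  k = config$k)
  pm <- polarize(ft, ranges, mf, min_intensity = config$min_intensity)
  pm <- append_hypothetical_ancestor(pm, config$ancestor_label)
  removed <- data.frame(feature_id = character(0), reason = character(0))
  if (config$drop_uninformative != "none") {
    dropped <- drop_uninformative_characters(pm, config$drop_uninformative)
    pm <- dropped$matrix
    removed <- dropped$removed
  }

  search <- heuristic_search(pm, n_replicates = config$n_replicates,
                             seed = config$seed, swap = config$swap)
  tree <- if (search$n_best > 1L) strict_consensus(search$trees) else search$trees[[1L]]
  cladogram <- root_on_outgroup(tree, config$ancestor_label)
  syn <- extract_synapomorphies(cladogram, pm, mode = config$synapomorphy_mode)
  ci <- consistency_index(cladogram, pm)

  clades <- clade_membership(cladogram, n_clades = config$n_clades,
                             exclude = config$ancestor_label)
  associations <- NULL
  if (!is.null(clin)) {
    # clade of a patient = clade of its specimen(s); paired specimens are
    # reported per specimen
    pat_clades <- stats::setNames(
      clades, mf$patient_id[match(names(clades), mf$specimen_id)]
    )
    covars <- intersect(c("adt", "risk", "metastasis", "protocol", "race",
                          "gleason", "t_stage"), names(clin))
    associations <- do.call(rbind, lapply(covars, function(v) {
      a <- clade_covariate_association(pat_clades, clin, v)
      data.frame(covariate = v, test = a$test, p_value = a$p_value,
                 degenerate = a$degenerate, stringsAsFactors = FALSE)
    }))
    if (!is.null(associations)) attr(associations, "n_tests") <- nrow(associations)
  }
  annotation <- if (!is.null(cp)) match_features(ft, cp, tol_ppm = config$tol_ppm) else NULL

  # ---- write stage products -----------------------------------------------
  write_feature_table(ft, file.path(out_dir, "features_filtered.csv"))
  utils::write.csv(standards, file.path(out_dir, "internal_standards.csv"),
                   row.names = FALSE)
  write_polarized_csv(pm, file.path(out_dir, "matrix.csv"))
  write_phylip_matrix(pm, file.path(out_dir, "matrix.phy"))
  ape::write.tree(search$trees, file.path(out_dir, "mp_trees.nwk"))
  writeLines(annotated_newick(cladogram, syn), file.path(out_dir, "cladogram.nwk"))
  write_synapomorphy_csv(syn, file.path(out_dir, "synapomorphies.csv"),
                         ft = ft, pm = pm)
  utils::write.csv(syn$autapomorphies, file.path(out_dir, "autapomorphies.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(specimen_id = names(clades), clade = unname(clades)),
    file.path(out_dir, "clade_membership.csv"), row.names = FALSE
  )
  if (!is.null(associations)) {
    utils::write.csv(associations, file.path(out_dir, "clinical_associations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(annotation)) {
    utils::write.csv(annotation, file.path(out_dir, "annotation.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    settings = list(
      mass_range = config$mass_range,
      polarization_method = config$polarization_method,
      drop_uninformative = config$drop_uninformative,
      n_replicates = config$n_replicates, swap = config$swap,
      synapomorphy_mode = config$synapomorphy_mode, tol_ppm = config$tol_ppm
    ),
    counts = list(
      features_in = n_in,
      features_in_mass_range = nrow(ft$features),
      specimens = ncol(ft$intensities),
      characters = ncol(pm$states),
      characters_removed = nrow(removed),
      derived_cells = sum(pm$states),
      tree_length = search$length,
      mp_tree_count = search$n_best,
      consistency_index = as.numeric(ci),
      synapomorphies_total = nrow(syn$clades),
      autapomorphies_total = nrow(syn$autapomorphies),
      annotated_features = if (is.null(annotation)) NA else
        length(unique(annotation$feature_id))
    ),
    versions = list(
      package = tryCatch(as.character(utils::packageVersion("phylometab")),
                         error = function(e) NA_character_),
      r = R.version.string
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    feature_table = ft, matrix = pm, search = search, cladogram = cladogram,
    synapomorphies = syn, consistency_index = ci, clades = clades,
    associations = associations, annotation = annotation, manifest = manifest,
    standards = standards
  ))
}
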