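#' @importFrom stats setNames
NULL

# Coerce a polarized matrix object or plain 0/1 matrix to the taxa x
# characters integer matrix used by the parsimony engine.
as_states_matrix <- function(x) {
  if (inherits(x, "polarized_matrix")) x <- x$states
  if (!is.matrix(x)) stop("`x` must be a matrix or a polarized_matrix")
  if (is.null(rownames(x))) stop("states matrix must have row names (taxa)")
  storage.mode(x) <- "integer"
  if (!all(x %in% c(0L, 1L))) stop("states matrix must be binary (0/1)")
  x
}

states_to_codes <- function(states) {
  codes <- states + 1L  # 1 = {0}, 2 = {1}
  rownames(codes) <- rownames(states)
  codes
}

check_leaf_match <- function(tree_labels, taxa) {
  miss_t <- setdiff(taxa, tree_labels)
  miss_m <- setdiff(tree_labels, taxa)
  if (length(miss_t) || length(miss_m)) {
    stop(
      "leaf/matrix mismatch; only in matrix: {",
      paste(miss_t, collapse = ", "), "}; only in tree: {",
      paste(miss_m, collapse = ", "), "}"
    )
  }
}

#' Parsimony length of a tree under Fitch counting
#'
#' Computes the minimum number of 0 <-> 1 character-state changes required on
#' the given topology, summed over characters (Fitch optimization). For
#' binary unordered characters this equals the Wagner parsimony length used
#' by classic maximum-parsimony programs, and is invariant to rooting.
#'
#' @param tree a `phylo` tree whose tip labels match the matrix rows.
#' @param matrix a binary taxa-by-characters matrix (0 = ancestral,
#'   1 = derived) with taxon row names, or a [polarize()] result.
#' @param per_character if `TRUE`, return the per-character change counts.
#' @return total change count (integer), or an integer vector per character.
#' @examples
#' m <- rbind(A = c(0, 0), B = c(0, 1), C = c(1, 0), D = c(1, 1))
#' colnames(m) <- c("f1", "f2")
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_length(tr, m)
#' @export
fitch_length <- function(tree, matrix, per_character = FALSE) {
  states <- as_states_matrix(matrix)
  check_leaf_match(tree$tip.label, rownames(states))
  ut <- ut_from_phylo(tree)
  res <- ut_fitch2(ut, states_to_codes(states), per_character = per_character)
  if (per_character) setNames(res, colnames(states)) else res
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates all distinct unrooted binary topologies — (2n-5)!! for n
#' taxa — scores each by [fitch_length()], and returns every
#' minimum-length topology. Intended as an exact oracle for small
#' instances; refuses to run above `max_taxa`.
#'
#' @param matrix binary character matrix (taxa x characters) or
#'   [polarize()] result.
#' @param max_taxa guard on the taxon count (default 9; 10395 topologies
#'   at 8 taxa, 135135 at 9).
#' @return a list with `trees` (a `multiPhylo` of all optimal topologies),
#'   `length` (the optimum), and `n_topologies` (number enumerated).
#' @export
exhaustive_search <- function(matrix, max_taxa = 9) {
  states <- as_states_matrix(matrix)
  n <- nrow(states)
  if (n < 3L) stop("need at least 3 taxa")
  if (n > max_taxa) {
    stop("exhaustive search refused: ", n, " taxa exceeds max_taxa = ", max_taxa)
  }
  codes <- states_to_codes(states)
  trees <- ut_all_topologies(rownames(states))
  lens <- vapply(trees, ut_fitch2, integer(1), codes = codes)
  best <- min(lens)
  opt <- trees[lens == best]
  phy <- lapply(opt, ut_to_phylo)
  class(phy) <- "multiPhylo"
  list(trees = phy, length = as.integer(best), n_topologies = length(trees))
}

#' Heuristic maximum-parsimony search
#'
#' Stepwise-addition search with branch swapping, in the spirit of the MIX
#' program run with randomized and non-randomized input orders. Replicate 0
#' adds taxa in matrix row order (the non-randomized input); replicates
#' 1..`n_replicates` use seeded random addition orders. Each replicate is
#' refined by first-improvement branch swapping (`nni` or `spr`) until no
#' improving move exists. All distinct best topologies encountered are
#' retained up to `keep_max`.
#'
#' Deterministic given (`matrix`, `n_replicates`, `seed`, `swap`):
#' per-replicate seeds are derived from the master seed, and ties in
#' stepwise addition are broken by the lowest-index attachment edge.
#'
#' @param matrix binary character matrix (taxa x characters) or
#'   [polarize()] result.
#' @param n_replicates number of random-addition replicates (in addition to
#'   the row-order replicate). Default 10.
#' @param seed master seed (integer).
#' @param swap branch-swapping move set: `"spr"` (default), `"nni"`, or
#'   `"none"`.
#' @param keep_max cap on the number of equally parsimonious trees retained.
#' @return a list of class `mp_search`: `trees` (`multiPhylo` of distinct
#'   best topologies), `length`, `n_best`, `replicate_lengths`, `seed`,
#'   `swap`.
#' @export
heuristic_search <- function(matrix, n_replicates = 10, seed = 1, swap = c("spr", "nni", "none"),
                             keep_max = 100) {
  swap <- match.arg(swap)
  states <- as_states_matrix(matrix)
  n <- nrow(states)
  if (n < 3L) stop("need at least 3 taxa")
  codes <- states_to_codes(states)
  taxa <- rownames(states)

  best_len <- Inf
  best <- list()   # split-key -> utree

  add_best <- function(ut, len) {
    if (len > best_len) return(invisible())
    if (len < best_len) {
      best_len <<- len
      best <<- list()
    }
    if (length(best) < keep_max) {
      k <- ut_key(ut)
      if (is.null(best[[k]])) best[[k]] <<- ut
    }
    invisible()
  }

  rep_lengths <- integer(0)
  orders <- list(seq_len(n))
  if (n_replicates > 0) {
    for (r in seq_len(n_replicates)) {
      # derived per-replicate seed, kept within 32-bit integer range
      rs <- (as.integer(seed) + 1009L * r) %% .Machine$integer.max
      orders[[r + 1L]] <- local({
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(rs)
        sample.int(n)
      })
    }
  }

  for (ord in orders) {
    ut <- stepwise_addition(taxa[ord], codes)
    len <- ut_fitch2(ut, codes)
    if (swap != "none") {
      res <- branch_swap(ut, len, codes, swap)
      ut <- res$ut
      len <- res$len
      rep_lengths <- c(rep_lengths, len)
      add_best(ut, len)
      for (eq in res$equal_best) add_best(eq, len)
    } else {
      rep_lengths <- c(rep_lengths, len)
      add_best(ut, len)
    }
  }

  phy <- lapply(unname(best), ut_to_phylo)
  class(phy) <- "multiPhylo"
  structure(
    list(
      trees = phy, length = as.integer(best_len), n_best = length(phy),
      replicate_lengths = rep_lengths, seed = seed, swap = swap,
      n_replicates = n_replicates
    ),
    class = "mp_search"
  )
}

#' @export
print.mp_search <- function(x, ...) {
  cat(
    "Maximum-parsimony search:", x$n_replicates, "random-addition replicates +",
    "1 input-order replicate, swap =", x$swap, "\n",
    "best length:", x$length, "  distinct best trees:", x$n_best, "\n"
  )
  invisible(x)
}

stepwise_addition <- function(taxa, codes) {
  ut <- ut_init(taxa[1:3])
  if (length(taxa) == 3L) return(ut)
  for (k in 4:length(taxa)) {
    sub <- codes[taxa[1:k], , drop = FALSE]
    best_len <- Inf
    best_edge <- 1L
    for (i in seq_len(nrow(ut$edges))) {
      cand <- ut_insert_tip(ut, taxa[k], i)
      len <- ut_fitch2(cand, sub)
      if (len < best_len) {     # ties: keep lowest-index edge
        best_len <- len
        best_edge <- i
      }
    }
    ut <- ut_insert_tip(ut, taxa[k], best_edge)
  }
  ut
}

branch_swap <- function(ut, len, codes, swap) {
  repeat {
    improved <- FALSE
    if (swap == "nni") {
      for (nb in ut_nni_neighbors(ut)) {
        l2 <- ut_fitch2(nb, codes)
        if (l2 < len) { ut <- nb; len <- l2; improved <- TRUE; break }
      }
    } else {
      res <- ut_spr_sweep(ut, function(nb) {
        l2 <- ut_fitch2(nb, codes)
        if (l2 < len) list(ut = nb, len = l2) else NULL
      })
      if (!is.null(res)) { ut <- res$ut; len <- res$len; improved <- TRUE }
    }
    if (!improved) break
  }
  # at the local optimum, collect equal-length neighbours so that sets of
  # equally parsimonious trees are reported
  equal_best <- list()
  if (swap == "nni") {
    for (nb in ut_nni_neighbors(ut)) {
      if (ut_fitch2(nb, codes) == len) equal_best[[length(equal_best) + 1L]] <- nb
    }
  } else {
    ut_spr_sweep(ut, function(nb) {
      if (ut_fitch2(nb, codes) == len) equal_best[[length(equal_best) + 1L]] <<- nb
      NULL
    })
  }
  list(ut = ut, len = len, equal_best = equal_best)
}

#' Root a tree on the outgroup (hypothetical ancestor) leaf
#'
#' Roots the cladogram on the edge subtending the given leaf, which is
#' conventionally the all-ancestral hypothetical taxon appended by
#' [append_hypothetical_ancestor()]. Ingroup clade structure is preserved.
#'
#' @param tree a `phylo`.
#' @param outgroup tip label to root on.
#' @return a rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup label not in tree: ", outgroup)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Strict consensus of equally parsimonious trees
#'
#' Retains exactly the splits present in every input tree; incompatible
#' resolution collapses to polytomies.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) sharing one leaf set.
#' @return a `phylo`, possibly multifurcating.
#' @export
strict_consensus <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("no trees given")
  labs <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), labs)) stop("trees have mismatched leaf sets")
  }
  if (length(trees) == 1L) return(trees[[1L]])
  splitsets <- lapply(trees, function(tr) ut_splits(ut_from_phylo(tr)))
  common <- Reduce(intersect, splitsets)
  anchor <- labs[1L]
  others <- setdiff(labs, anchor)
  clades <- lapply(common, function(s) strsplit(s, ",", fixed = TRUE)[[1L]])
  parts <- clade_parts(others, clades)
  nwk <- paste0("(", paste(c(ut_newick_label(anchor), parts), collapse = ","), ");")
  ape::read.tree(text = nwk)
}

# Newick strings for the maximal clades of a compatible family over
# `labels`, plus leftover singleton labels — the children of one node.
clade_parts <- function(labels, clades) {
  clades <- clades[vapply(clades, function(cl) length(cl) < length(labels), logical(1))]
  sizes <- vapply(clades, length, integer(1))
  ord <- order(-sizes)
  taken <- character(0)
  parts <- character(0)
  for (i in ord) {
    cl <- clades[[i]]
    if (any(cl %in% taken)) next   # nested inside an already-taken maximal clade
    sub <- clades[vapply(clades, function(x) all(x %in% cl) && length(x) < length(cl), logical(1))]
    parts <- c(parts, build_from_clades(cl, sub))
    taken <- c(taken, cl)
  }
  rest <- setdiff(labels, taken)
  c(parts, vapply(rest, ut_newick_label, character(1)))
}

# Build a Newick subtree string over `labels` from a compatible family of
# clades (each a subset of `labels`).
build_from_clades <- function(labels, clades) {
  if (length(labels) == 1L) return(ut_newick_label(labels))
  parts <- clade_parts(labels, clades)
  if (length(parts) == 1L) parts else paste0("(", paste(parts, collapse = ","), ")")
}

#' Consistency index of a character matrix on a tree
#'
#' CI = (minimum conceivable change count, i.e. the number of variable
#' characters for binary data) divided by the realized [fitch_length()].
#' CI = 1 indicates a homoplasy-free (perfect) character fit; lower values
#' indicate convergence or reversal.
#'
#' @inheritParams fitch_length
#' @return a single numeric in (0, 1], or `NA` (with attribute
#'   `defined = FALSE`) when the tree length is zero.
#' @export
consistency_index <- function(tree, matrix) {
  states <- as_states_matrix(matrix)
  len <- fitch_length(tree, states)
  m <- sum(apply(states, 2L, function(x) length(unique(x)) > 1L))
  if (len == 0L) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(m / len, defined = TRUE)
}
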