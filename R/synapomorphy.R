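# Helpers on rooted ape trees -----------------------------------------------

rooted_children <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2L])
  }
  kids
}

node_postorder <- function(phy) {
  # ape postorder guarantees every edge below a node precedes its stem edge,
  # so the child column lists children before parents; the root comes last
  po <- ape::reorder.phylo(phy, "postorder")
  c(po$edge[, 2L], length(phy$tip.label) + 1L)
}

# tip labels under every node (tips included), as a list indexed by node id
node_tipsets <- function(phy) {
  ntip <- length(phy$tip.label)
  kids <- rooted_children(phy)
  sets <- vector("list", ntip + phy$Nnode)
  for (v in node_postorder(phy)) {
    if (v <= ntip) sets[[v]] <- phy$tip.label[v]
    else sets[[v]] <- sort(unlist(sets[kids[[v]]]))
  }
  sets
}

#' Reconstruct ancestral character states on a rooted cladogram
#'
#' Minimum-change (Fitch/Sankoff) reconstruction of binary character states
#' at every internal node, with the root fixed to the all-ancestral state 0
#' (the hypothetical healthy ancestor). Where several minimum
#' reconstructions exist, ties are resolved by the chosen rule: `acctran`
#' accelerates transformations (places changes as close to the root as
#' possible, favouring reversals), `deltran` delays them (favouring
#' parallelisms).
#'
#' @param tree a rooted `phylo` whose tips match the matrix rows
#'   (conventionally including the hypothetical ancestor appended by
#'   [append_hypothetical_ancestor()]).
#' @param matrix binary taxa x characters matrix or [polarize()] result.
#' @param resolution `"acctran"` (default) or `"deltran"`.
#' @return a list: `states` (node x character 0/1 matrix over all tree
#'   nodes, ape numbering), `changes` (data.frame of `character`, `parent`,
#'   `child`, `from`, `to` for every state change), `n_changes`
#'   (per-character implied change counts).
#' @export
reconstruct_states <- function(tree, matrix, resolution = c("acctran", "deltran")) {
  resolution <- match.arg(resolution)
  if (!ape::is.rooted(tree)) stop("reconstruction requires a rooted tree")
  states <- as_states_matrix(matrix)
  check_leaf_match(tree$tip.label, rownames(states))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  kids <- rooted_children(tree)
  po <- node_postorder(tree)
  nc <- ncol(states)
  X <- states[tree$tip.label, , drop = FALSE]

  # Sankoff down-pass with unit costs: cost0/cost1 = minimum change count of
  # the subtree given the node's state
  BIG <- 1e9
  cost0 <- matrix(0, nnode, nc)
  cost1 <- matrix(0, nnode, nc)
  for (v in po) {
    if (v <= ntip) {
      cost0[v, ] <- ifelse(X[v, ] == 0L, 0, BIG)
      cost1[v, ] <- ifelse(X[v, ] == 1L, 0, BIG)
    } else {
      for (w in kids[[v]]) {
        cost0[v, ] <- cost0[v, ] + pmin(cost0[w, ], cost1[w, ] + 1)
        cost1[v, ] <- cost1[v, ] + pmin(cost1[w, ], cost0[w, ] + 1)
      }
    }
  }

  # pre-order traceback; root forced to state 0 (hypothetical ancestor)
  assign_states <- matrix(0L, nnode, nc)
  pre <- rev(po)
  for (v in pre) {
    if (v == root) { assign_states[v, ] <- 0L; next }
    p <- tree$edge[match(v, tree$edge[, 2L]), 1L]
    fp <- assign_states[p, ]
    stay <- ifelse(fp == 0L, cost0[v, ], cost1[v, ])
    move <- ifelse(fp == 0L, cost1[v, ], cost0[v, ]) + 1
    f <- fp
    switch_to <- move < stay | (move == stay & resolution == "acctran")
    f[switch_to] <- 1L - fp[switch_to]
    assign_states[v, ] <- f
  }

  # enumerate changes
  ch <- list()
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    d <- which(assign_states[p, ] != assign_states[v, ])
    if (length(d)) {
      ch[[length(ch) + 1L]] <- data.frame(
        character = colnames(states)[d],
        parent = p, child = v,
        from = assign_states[p, d], to = assign_states[v, d],
        stringsAsFactors = FALSE
      )
    }
  }
  changes <- if (length(ch)) do.call(rbind, ch) else
    data.frame(character = character(0), parent = integer(0), child = integer(0),
               from = integer(0), to = integer(0), stringsAsFactors = FALSE)
  n_changes <- stats::setNames(
    as.integer(pmin(cost0[root, ], BIG)), colnames(states)
  )
  list(states = assign_states, changes = changes, n_changes = n_changes)
}

#' Extract clade-defining synapomorphies
#'
#' Maps derived character states onto the rooted cladogram and lists, for
#' every internal node, the characters that define its clade. In `strict`
#' mode a character is a synapomorphy of a node if and only if it is
#' derived in every leaf of that clade and ancestral in every leaf outside
#' it (unique and unreversed); each character then annotates at most one
#' node. In `reconstructed` mode a character annotates every node on whose
#' stem edge the minimum-change reconstruction
#' ([reconstruct_states()]) places a 0 to 1 change, so homoplasious
#' characters may annotate several nodes.
#'
#' Autapomorphies — characters derived in exactly one specimen — never
#' label clades; they are reported in a separate per-specimen table.
#'
#' @param tree rooted `phylo` with the all-ancestral hypothetical taxon as
#'   outgroup leaf.
#' @param matrix binary taxa x characters matrix or [polarize()] result.
#' @param mode `"strict"` (default) or `"reconstructed"`.
#' @param resolution tie-break rule passed to [reconstruct_states()] in
#'   `reconstructed` mode.
#' @return a `synapomorphy_table`: list with `clades` (data.frame `node`,
#'   `n_leaves`, `leaves` (comma-separated), `character`), `counts`
#'   (per-node synapomorphy counts), `autapomorphies` (data.frame
#'   `specimen`, `character`), and `mode`.
#' @export
extract_synapomorphies <- function(tree, matrix, mode = c("strict", "reconstructed"),
                                   resolution = "acctran") {
  mode <- match.arg(mode)
  if (!ape::is.rooted(tree)) stop("requires a rooted cladogram")
  states <- as_states_matrix(matrix)
  check_leaf_match(tree$tip.label, rownames(states))
  ntip <- length(tree$tip.label)
  X <- states[tree$tip.label, , drop = FALSE]
  sets <- node_tipsets(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)

  rows <- list()
  if (mode == "strict") {
    csums <- colSums(X)
    for (v in internal) {
      leaves <- sets[[v]]
      if (length(leaves) < 2L || length(leaves) >= ntip) next
      inside <- rownames(X) %in% leaves
      # derived in all leaves under v, ancestral everywhere else
      hit <- which(colSums(X[inside, , drop = FALSE]) == length(leaves) &
                     csums == length(leaves))
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          node = v, n_leaves = length(leaves),
          leaves = paste(leaves, collapse = ","),
          character = colnames(X)[hit], stringsAsFactors = FALSE
        )
      }
    }
  } else {
    rec <- reconstruct_states(tree, states, resolution = resolution)
    gains <- rec$changes[rec$changes$from == 0L & rec$changes$to == 1L, , drop = FALSE]
    gains <- gains[gains$child > ntip, , drop = FALSE]  # internal stems only
    for (v in unique(gains$child)) {
      leaves <- sets[[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        node = v, n_leaves = length(leaves),
        leaves = paste(leaves, collapse = ","),
        character = gains$character[gains$child == v],
        stringsAsFactors = FALSE
      )
    }
  }
  clades <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), n_leaves = integer(0), leaves = character(0),
               character = character(0), stringsAsFactors = FALSE)

  # autapomorphies: derived in exactly one specimen
  auto_idx <- which(colSums(X) == 1L)
  autapomorphies <- data.frame(
    specimen = vapply(auto_idx, function(j) rownames(X)[X[, j] == 1L], character(1)),
    character = colnames(X)[auto_idx],
    stringsAsFactors = FALSE
  )
  counts <- if (nrow(clades)) table(clades$node) else table(integer(0))
  structure(
    list(clades = clades, counts = counts, autapomorphies = autapomorphies,
         mode = mode),
    class = "synapomorphy_table"
  )
}

#' @export
print.synapomorphy_table <- function(x, ...) {
  cat("Synapomorphy table (", x$mode, " mode): ", nrow(x$clades),
      " clade-defining characters across ", length(x$counts), " nodes; ",
      nrow(x$autapomorphies), " autapomorphies\n", sep = "")
  if (length(x$counts)) {
    for (nd in names(x$counts)) {
      first <- x$clades[x$clades$node == as.integer(nd), ][1L, ]
      cat("  node ", nd, " (", first$n_leaves, " leaves): ",
          x$counts[[nd]], " synapomorphies\n", sep = "")
    }
  }
  invisible(x)
}

# Resolve a clade argument (node id, or character vector of tip labels) to
# an internal node id.
resolve_clade_node <- function(tree, clade) {
  if (is.numeric(clade) && length(clade) == 1L) return(as.integer(clade))
  tips <- match(clade, tree$tip.label)
  if (anyNA(tips)) stop("unknown tip label(s): ",
                        paste(clade[is.na(tips)], collapse = ", "))
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(tree, tips)
}

#' Characters shared as derived states between two clades
#'
#' Returns the characters that are derived in every leaf of both clades —
#' the "shared synapomorphies" linking two sister or related groups (under
#' strict accounting these are the synapomorphies of their most recent
#' common ancestor when no leaf outside carries them).
#'
#' @param tree rooted `phylo`.
#' @param matrix binary taxa x characters matrix or [polarize()] result.
#' @param clade_a,clade_b internal node ids, or character vectors of tip
#'   labels (the clade is their MRCA's leaf set).
#' @return character vector of shared character ids.
#' @export
shared_synapomorphies <- function(tree, matrix, clade_a, clade_b) {
  states <- as_states_matrix(matrix)
  check_leaf_match(tree$tip.label, rownames(states))
  sets <- node_tipsets(tree)
  na <- resolve_clade_node(tree, clade_a)
  nb <- resolve_clade_node(tree, clade_b)
  nn <- length(tree$tip.label) + tree$Nnode
  if (is.na(na) || is.na(nb) || na > nn || nb > nn) stop("clade node outside tree")
  leaves <- union(sets[[na]], sets[[nb]])
  X <- states[leaves, , drop = FALSE]
  colnames(X)[colSums(X) == length(leaves)]
}

#' Write synapomorphy outputs
#'
#' `write_synapomorphy_csv()` exports the per-node synapomorphy list with
#' feature annotation (m/z, RT, direction) when a `feature_table` /
#' `polarized_matrix` is supplied. `annotated_newick()` returns the
#' cladogram with per-node synapomorphy counts as internal node labels
#' (the style used to annotate published cladograms).
#'
#' @param syn a `synapomorphy_table`.
#' @param path output CSV path.
#' @param ft optional `feature_table` to attach `mz` and `rt`.
#' @param pm optional `polarized_matrix` to attach the majority direction
#'   of each synapomorphy within its clade.
#' @return `path` invisibly, or a Newick string.
#' @export
write_synapomorphy_csv <- function(syn, path, ft = NULL, pm = NULL) {
  df <- syn$clades
  if (!is.null(ft)) {
    i <- match(df$character, ft$features$feature_id)
    df$mz <- ft$features$mz[i]
    df$rt <- ft$features$rt[i]
  }
  if (!is.null(pm)) {
    df$direction <- vapply(seq_len(nrow(df)), function(r) {
      leaves <- strsplit(df$leaves[r], ",", fixed = TRUE)[[1L]]
      leaves <- intersect(leaves, rownames(pm$direction))
      d <- pm$direction[leaves, df$character[r]]
      d <- d[d != "none"]
      if (!length(d)) return(NA_character_)
      names(sort(table(d), decreasing = TRUE))[1L]
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synapomorphy_csv
#' @param tree rooted `phylo` the table was computed on.
#' @export
annotated_newick <- function(tree, syn) {
  ntip <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  for (nd in names(syn$counts)) {
    lab[as.integer(nd) - ntip] <- as.character(syn$counts[[nd]])
  }
  tree$node.label <- lab
  ape::write.tree(tree)
}
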