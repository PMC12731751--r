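# Internal unrooted-tree representation used by the parsimony engine.
#
# A `utree` is a plain list:
#   labels  : named integer vector, tip label -> node id
#   edges   : integer matrix (m x 2) of undirected edges between node ids
#   next_id : next free node id
#
# Node ids are arbitrary positive integers (never renumbered by surgery),
# which keeps insertion/pruning cheap and deterministic. Trees are binary:
# every internal node has degree 3 once there are >= 3 tips. Conversion to
# ape's phylo goes through a Newick string.

ut_init <- function(labels) {
  stopifnot(length(labels) == 3L)
  list(
    labels = stats::setNames(1:3, labels),
    edges = cbind(c(4L, 4L, 4L), 1:3),
    next_id = 5L
  )
}

# Insert a new tip into edge `edge_i`, creating one internal node.
ut_insert_tip <- function(ut, label, edge_i) {
  t_id <- ut$next_id
  w_id <- ut$next_id + 1L
  uv <- ut$edges[edge_i, ]
  ut$edges[edge_i, ] <- c(uv[1L], w_id)
  ut$edges <- rbind(ut$edges, c(w_id, uv[2L]), c(w_id, t_id))
  ut$labels[[label]] <- t_id
  ut$next_id <- w_id + 1L
  ut
}

ut_adjacency <- function(ut) {
  maxid <- ut$next_id - 1L
  adj <- vector("list", maxid)
  for (i in seq_len(nrow(ut$edges))) {
    a <- ut$edges[i, 1L]; b <- ut$edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Postorder traversal rooted at the tip given (default: first tip inserted).
# Returns list(order = node ids in postorder, parent = parent id per node,
# root_tip, start) where `start` is the internal node adjacent to root_tip.
ut_postorder <- function(ut, root_tip = NULL) {
  adj <- ut_adjacency(ut)
  if (is.null(root_tip)) root_tip <- ut$labels[[1L]]
  start <- adj[[root_tip]][1L]
  maxid <- ut$next_id - 1L
  parent <- integer(maxid)
  parent[start] <- root_tip
  stack <- c(start)
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    for (w in adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  list(order = rev(out), parent = parent, root_tip = root_tip, start = start)
}

# Fitch scoring of binary characters on an unrooted tree.
# `codes` is an integer matrix (tips x characters) with values 1 ({0}),
# 2 ({1}) or 3 ({0,1}), rownames = tip labels. Returns total change count,
# or the per-character vector when per_character = TRUE.
ut_fitch <- function(ut, codes, per_character = FALSE) {
  po <- ut_postorder(ut)
  nc <- ncol(codes)
  maxid <- ut$next_id - 1L
  S <- matrix(0L, maxid, nc)
  tip_ids <- ut$labels
  S[tip_ids, ] <- codes[names(tip_ids), , drop = FALSE]
  changes <- integer(nc)
  is_tip <- logical(maxid)
  is_tip[tip_ids] <- TRUE
  parent <- po$parent
  for (v in po$order) {
    if (is_tip[v]) next
    first <- TRUE
    acc <- NULL
    for (w in which(parent == v)) {
      if (first) { acc <- S[w, ]; first <- FALSE; next }
      I <- bitwAnd(acc, S[w, ])
      z <- I == 0L
      if (any(z)) {
        changes[z] <- changes[z] + 1L
        I[z] <- bitwOr(acc, S[w, ])[z]
      }
      acc <- I
    }
    S[v, ] <- acc
  }
  rc <- codes[names(tip_ids)[match(po$root_tip, tip_ids)], ]
  z <- bitwAnd(rc, S[po$start, ]) == 0L
  changes[z] <- changes[z] + 1L
  if (per_character) changes else sum(changes)
}

# Faster child lookup variant of ut_fitch used in hot search loops: the
# `which(parent == v)` scan above is quadratic; precompute children lists.
ut_fitch2 <- function(ut, codes, per_character = FALSE) {
  po <- ut_postorder(ut)
  nc <- ncol(codes)
  maxid <- ut$next_id - 1L
  kids <- vector("list", maxid)
  for (v in seq_len(maxid)) kids[[v]] <- integer(0)
  for (w in po$order) {
    p <- po$parent[w]
    if (p != 0L && p != po$root_tip) kids[[p]] <- c(kids[[p]], w)
  }
  S <- matrix(0L, maxid, nc)
  tip_ids <- ut$labels
  S[tip_ids, ] <- codes[names(tip_ids), , drop = FALSE]
  changes <- integer(nc)
  for (v in po$order) {
    ch <- kids[[v]]
    if (!length(ch)) next
    acc <- S[ch[1L], ]
    for (w in ch[-1L]) {
      I <- bitwAnd(acc, S[w, ])
      z <- I == 0L
      if (any(z)) {
        changes[z] <- changes[z] + 1L
        I[z] <- bitwOr(acc, S[w, ])[z]
      }
      acc <- I
    }
    S[v, ] <- acc
  }
  rc <- codes[names(tip_ids)[match(po$root_tip, tip_ids)], ]
  z <- bitwAnd(rc, S[po$start, ]) == 0L
  changes[z] <- changes[z] + 1L
  if (per_character) changes else sum(changes)
}

# Non-trivial splits as canonical strings. Each split is represented by the
# sorted label set of the side NOT containing the anchor tip (the
# alphabetically first label), so identical topologies give identical keys.
ut_splits <- function(ut) {
  labs <- names(ut$labels)
  anchor <- sort(labs)[1L]
  po <- ut_postorder(ut, root_tip = ut$labels[[anchor]])
  maxid <- ut$next_id - 1L
  sets <- vector("list", maxid)
  id2lab <- character(maxid)
  id2lab[ut$labels] <- names(ut$labels)
  for (v in po$order) {
    if (id2lab[v] != "") {
      sets[[v]] <- id2lab[v]
    } else {
      kidsets <- sets[which(po$parent == v)]
      sets[[v]] <- sort(unlist(kidsets))
    }
  }
  n <- length(labs)
  out <- character(0)
  for (v in po$order) {
    s <- sets[[v]]
    if (length(s) >= 2L && length(s) <= n - 2L) {
      out <- c(out, paste(s, collapse = ","))
    }
  }
  sort(out)
}

ut_key <- function(ut) paste(ut_splits(ut), collapse = ";")

ut_newick_label <- function(lab) {
  if (grepl("[^A-Za-z0-9_.-]", lab)) paste0("'", gsub("'", "''", lab), "'") else lab
}

ut_to_newick <- function(ut) {
  adj <- ut_adjacency(ut)
  id2lab <- character(ut$next_id - 1L)
  id2lab[ut$labels] <- names(ut$labels)
  build <- function(v, parent) {
    if (id2lab[v] != "") return(ut_newick_label(id2lab[v]))
    parts <- vapply(setdiff(adj[[v]], parent), build, character(1), parent = v)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  start <- adj[[ut$labels[[1L]]]][1L]
  # unrooted convention: basal node joining the first tip and its two
  # remaining neighbour subtrees
  parts <- c(
    ut_newick_label(id2lab[ut$labels[[1L]]]),
    vapply(setdiff(adj[[start]], ut$labels[[1L]]), build, character(1), parent = start)
  )
  paste0("(", paste(parts, collapse = ","), ");")
}

ut_to_phylo <- function(ut) ape::read.tree(text = ut_to_newick(ut))

ut_from_phylo <- function(phy) {
  n <- length(phy$tip.label)
  list(
    labels = stats::setNames(seq_len(n), phy$tip.label),
    edges = cbind(phy$edge[, 1L], phy$edge[, 2L]),
    next_id = n + phy$Nnode + 1L
  )
}

# --- rearrangements ---------------------------------------------------------

node_degrees <- function(ut) {
  tabulate(c(ut$edges[, 1L], ut$edges[, 2L]), nbins = ut$next_id - 1L)
}

# NNI neighbours: two per internal edge.
ut_nni_neighbors <- function(ut) {
  deg <- node_degrees(ut)
  adj <- ut_adjacency(ut)
  out <- list()
  for (i in seq_len(nrow(ut$edges))) {
    u <- ut$edges[i, 1L]; v <- ut$edges[i, 2L]
    if (deg[u] < 3L || deg[v] < 3L) next
    a <- setdiff(adj[[u]], v)   # two subtrees on u's side
    b <- setdiff(adj[[v]], u)   # two subtrees on v's side
    for (bj in b) {
      nb <- ut
      # swap subtree a[2] (attached to u) with subtree bj (attached to v)
      nb$edges <- swap_attachment(nb$edges, u, a[2L], v, bj)
      out[[length(out) + 1L]] <- nb
    }
  }
  out
}

swap_attachment <- function(edges, u, x, v, y) {
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    if ((e[1L] == u && e[2L] == x) || (e[1L] == x && e[2L] == u)) edges[i, ] <- c(u, y)
    else if ((e[1L] == v && e[2L] == y) || (e[1L] == y && e[2L] == v)) edges[i, ] <- c(v, x)
  }
  edges
}

# SPR neighbours, generated lazily through a callback so the search can stop
# at the first improving move. `fun(nb)` is called for every neighbour; if it
# returns non-NULL the sweep stops and that value is returned.
ut_spr_sweep <- function(ut, fun) {
  m <- nrow(ut$edges)
  deg <- node_degrees(ut)
  adj <- ut_adjacency(ut)
  for (i in seq_len(m)) {
    for (dir in 1:2) {
      u <- ut$edges[i, dir]           # remainder-side endpoint
      v <- ut$edges[i, 3L - dir]      # root of pruned subtree
      if (deg[u] != 3L) next          # pruning at a tip leaves no remainder
      nbu <- setdiff(adj[[u]], v)     # u's two other neighbours (a, b)
      # remainder edges after suppressing u: all edges not incident to u and
      # not in the pruned subtree, plus the closing edge (a, b)
      pruned_nodes <- ut_component(ut, v, exclude_edge = i)
      keep <- rep(TRUE, m)       # remainder edges
      inprune <- rep(FALSE, m)   # edges inside the pruned subtree
      keep[i] <- FALSE
      for (j in seq_len(m)) {
        if (!keep[j]) next
        e <- ut$edges[j, ]
        if (e[1L] == u || e[2L] == u) { keep[j] <- FALSE; next }
        if (pruned_nodes[e[1L]] || pruned_nodes[e[2L]]) {
          keep[j] <- FALSE
          inprune[j] <- TRUE
        }
      }
      pruned_edges <- ut$edges[inprune, , drop = FALSE]
      rem_edges <- rbind(ut$edges[keep, , drop = FALSE], nbu)
      # regraft on every remainder edge except the closing edge (original)
      n_rem <- nrow(rem_edges)
      if (n_rem < 2L) next
      for (j in seq_len(n_rem - 1L)) {
        x <- rem_edges[j, 1L]; y <- rem_edges[j, 2L]
        nb <- ut
        w <- nb$next_id
        nb$next_id <- w + 1L
        nb$edges <- rbind(rem_edges[-j, , drop = FALSE], pruned_edges,
                          c(x, w), c(w, y), c(w, v))
        res <- fun(nb)
        if (!is.null(res)) return(res)
      }
    }
  }
  NULL
}

# Logical vector marking the component containing `from` when `exclude_edge`
# is removed.
ut_component <- function(ut, from, exclude_edge) {
  maxid <- ut$next_id - 1L
  adj <- vector("list", maxid)
  for (i in seq_len(nrow(ut$edges))) {
    if (i == exclude_edge) next
    a <- ut$edges[i, 1L]; b <- ut$edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(maxid)
  stack <- from
  seen[from] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  seen
}

# All unrooted binary topologies on the given labels, by recursive edge
# insertion; (2n-5)!! trees for n labels.
ut_all_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  trees <- list(ut_init(labels[1:3]))
  if (n == 3L) return(trees)
  for (k in 4:n) {
    nxt <- list()
    for (tr in trees) {
      for (i in seq_len(nrow(tr$edges))) {
        nxt[[length(nxt) + 1L]] <- ut_insert_tip(tr, labels[k], i)
      }
    }
    trees <- nxt
  }
  trees
}
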