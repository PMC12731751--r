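library(ape)

test_that("fitch length matches hand-checked examples and brute enumeration", {
  m <- cbind(c1 = c(A = 0, B = 0, C = 1, D = 1),
             c2 = c(A = 0, B = 1, C = 0, D = 1))
  tr <- read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_length(tr, m), 3L)
  expect_equal(unname(fitch_length(tr, m, per_character = TRUE)), c(1L, 2L))
  # the 0101 character: verified against enumeration of internal labelings
  expect_equal(oracle_min_changes(tr, m[, "c2"]), 2)

  # all-constant matrix has length zero on any tree
  cm <- cbind(c1 = c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(fitch_length(tr, cm), 0L)

  # random trees and characters vs the brute-force oracle
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    phy <- rtree(n, tip.label = paste0("t", 1:n))
    m <- random_binary_matrix(n, 6)
    per <- fitch_length(phy, m, per_character = TRUE)
    for (j in seq_len(ncol(m))) {
      expect_equal(unname(per[j]), oracle_min_changes(phy, m[, j]))
    }
  }
})

test_that("fitch length is invariant to leaf order and rerooting", {
  set.seed(3)
  m <- random_binary_matrix(7, 15)
  phy <- rtree(7, tip.label = rownames(m))
  len <- fitch_length(phy, m)
  expect_equal(fitch_length(phy, m[sample(rownames(m)), ]), len)
  for (og in rownames(m)[1:3]) {
    expect_equal(fitch_length(root(phy, og, resolve.root = TRUE), m), len)
  }
  expect_equal(fitch_length(unroot(phy), m), len)
})

test_that("leaf/matrix mismatch is reported with the symmetric difference", {
  m <- random_binary_matrix(4, 3)
  phy <- read.tree(text = "((t1,t2),(t3,x));")
  expect_error(fitch_length(phy, m), "t4.*x|x.*t4")
})

test_that("exhaustive search enumerates (2n-5)!! topologies and finds the optimum", {
  m4 <- random_binary_matrix(4, 5)
  ex4 <- exhaustive_search(m4)
  expect_equal(ex4$n_topologies, 3L)

  set.seed(8)
  m6 <- random_binary_matrix(6, 8)
  ex6 <- exhaustive_search(m6)
  expect_equal(ex6$n_topologies, 105L)
  # optimum is indeed minimal: no enumerated tree scores below it
  expect_true(all(vapply(ex6$trees, fitch_length, integer(1), matrix = m6) == ex6$length))

  big <- random_binary_matrix(10, 4)
  expect_error(exhaustive_search(big), "refused")
})

test_that("a planted perfect phylogeny is the unique optimum and has CI 1", {
  taxa <- c("HTU", paste0("t", 1:6))
  m <- ladder_matrix(taxa, reps = 2)
  ex <- exhaustive_search(m)
  expect_equal(length(ex$trees), 1L)
  expect_equal(ex$length, sum(apply(m, 2, function(x) length(unique(x)) > 1)))
  hs <- heuristic_search(m, n_replicates = 3, seed = 5)
  expect_equal(hs$length, ex$length)
  expect_equal(hs$n_best, 1L)
  ci <- consistency_index(hs$trees[[1]], m)
  expect_equal(as.numeric(ci), 1)
})

test_that("heuristic search is deterministic and never beats the exact optimum", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:7, 1)
    m <- random_binary_matrix(n, 10)
    ex <- exhaustive_search(m)
    hs <- heuristic_search(m, n_replicates = 3, seed = i)
    expect_gte(hs$length, ex$length)
    expect_equal(hs$length, ex$length)  # SPR from 4 starts finds it here
  }
  m <- random_binary_matrix(7, 12)
  a <- heuristic_search(m, n_replicates = 4, seed = 99)
  b <- heuristic_search(m, n_replicates = 4, seed = 99)
  expect_identical(lapply(a$trees, write.tree), lapply(b$trees, write.tree))
  expect_error(heuristic_search(m[1:2, ]), "at least 3 taxa")
})

test_that("rooting on the outgroup preserves the ingroup and round-trips", {
  phy <- read.tree(text = "((O,A),(B,C));")
  r <- root_on_outgroup(phy, "O")
  expect_true(is.rooted(r))
  expect_setequal(r$tip.label, phy$tip.label)
  expect_equal(phangorn::RF.dist(unroot(r), unroot(phy)), 0)
  expect_error(root_on_outgroup(phy, "Z"), "not in tree")

  set.seed(6)
  for (i in 1:5) {
    t0 <- rtree(8)
    r0 <- root_on_outgroup(t0, t0$tip.label[1])
    expect_setequal(r0$tip.label, t0$tip.label)
    expect_equal(phangorn::RF.dist(unroot(r0), unroot(t0)), 0)
  }
})

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- read.tree(text = "((A,B),(C,D),E);")
  same <- strict_consensus(c(t1, t1))
  expect_equal(phangorn::RF.dist(unroot(same), unroot(t1)), 0)

  # two trees sharing no internal split give the star tree
  ta <- read.tree(text = "((A,B),(C,D),E);")
  tb <- read.tree(text = "((A,C),(B,E),D);")
  star <- strict_consensus(c(ta, tb))
  expect_equal(star$Nnode, 1L)

  # random tree sets: every output split occurs in every input
  set.seed(12)
  for (i in 1:5) {
    trees <- c(rtree(7, tip.label = paste0("t", 1:7)),
               rtree(7, tip.label = paste0("t", 1:7)),
               rtree(7, tip.label = paste0("t", 1:7)))
    cons <- strict_consensus(trees)
    cons_splits <- phylometab:::ut_splits(phylometab:::ut_from_phylo(cons))
    for (tr in trees) {
      tr_splits <- phylometab:::ut_splits(phylometab:::ut_from_phylo(tr))
      expect_true(all(cons_splits %in% tr_splits))
    }
  }
  expect_error(strict_consensus(c(ta, rtree(5))), "mismatched leaf sets")
})

test_that("consistency index reflects homoplasy and is capped at 1", {
  m <- cbind(c2 = c(A = 0, B = 1, C = 0, D = 1))
  tr <- read.tree(text = "((A,B),(C,D));")
  expect_equal(as.numeric(consistency_index(tr, m)), 0.5)

  zero <- cbind(c1 = c(A = 0, B = 0, C = 0, D = 0))
  ci0 <- consistency_index(tr, zero)
  expect_true(is.na(ci0))
  expect_false(attr(ci0, "defined"))

  set.seed(19)
  for (i in 1:10) {
    m <- random_binary_matrix(6, 8)
    phy <- rtree(6, tip.label = rownames(m))
    ci <- consistency_index(phy, m)
    if (!is.na(ci)) expect_lte(as.numeric(ci), 1)
  }
})

test_that("per-character length is positive iff a character is variable", {
  set.seed(23)
  m <- random_binary_matrix(6, 20, p = 0.3)
  phy <- rtree(6, tip.label = rownames(m))
  per <- fitch_length(phy, m, per_character = TRUE)
  variable <- apply(m, 2, function(x) length(unique(x)) > 1)
  expect_identical(unname(per >= 1L), unname(variable))
  expect_gte(sum(per), sum(variable))
})
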