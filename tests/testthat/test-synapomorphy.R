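library(ape)

# 5 ingroup taxa + hypothetical ancestor; characters 1-3 derived exactly in
# {A,B}, characters 4-5 exactly in {C,D,E}
two_clade_matrix <- function() {
  m <- matrix(0L, 6, 5,
              dimnames = list(c("HTU", "A", "B", "C", "D", "E"),
                              paste0("f", 1:5)))
  m[c("A", "B"), 1:3] <- 1L
  m[c("C", "D", "E"), 4:5] <- 1L
  m
}

two_clade_tree <- function() {
  root_on_outgroup(read.tree(text = "(HTU,((A,B),(C,(D,E))));"), "HTU")
}

test_that("strict and reconstructed modes agree on a homoplasy-free matrix", {
  m <- two_clade_matrix()
  tr <- two_clade_tree()
  for (mode in c("strict", "reconstructed")) {
    syn <- extract_synapomorphies(tr, m, mode = mode)
    by_clade <- split(syn$clades$character, syn$clades$leaves)
    expect_setequal(by_clade[["A,B"]], c("f1", "f2", "f3"))
    expect_setequal(by_clade[["C,D,E"]], c("f4", "f5"))
    expect_equal(nrow(syn$clades), 5L)
    expect_equal(nrow(syn$autapomorphies), 0L)
  }
})

test_that("a character derived in every patient annotates the ingroup root", {
  m <- two_clade_matrix()
  m <- cbind(m, all1 = c(0L, 1L, 1L, 1L, 1L, 1L))  # ancestral only in HTU
  tr <- two_clade_tree()
  syn <- extract_synapomorphies(tr, m, mode = "strict")
  row <- syn$clades[syn$clades$character == "all1", ]
  expect_equal(row$leaves, "A,B,C,D,E")
})

test_that("reconstruction places clean changes on stem edges and matches fitch", {
  m <- two_clade_matrix()
  tr <- two_clade_tree()
  rec <- reconstruct_states(tr, m, resolution = "acctran")
  # constant characters change nowhere; per-character counts equal fitch
  expect_identical(rec$n_changes, fitch_length(tr, m, per_character = TRUE))
  # character f1 changes once, on the stem of {A,B}
  ch <- rec$changes[rec$changes$character == "f1", ]
  expect_equal(nrow(ch), 1L)
  sets <- phylometab:::node_tipsets(tr)
  expect_equal(sets[[ch$child]], c("A", "B"))

  cm <- cbind(const = c(HTU = 0L, A = 0L, B = 0L, C = 0L, D = 0L, E = 0L))
  rec0 <- reconstruct_states(tr, cm)
  expect_equal(nrow(rec0$changes), 0L)

  expect_error(reconstruct_states(unroot(tr), m), "rooted")
})

test_that("reconstructed change counts equal fitch length on random homoplasious data", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:7, 1)
    m <- random_binary_matrix(n, 8)
    m <- rbind(HTU = rep(0L, ncol(m)), m)
    phy <- root_on_outgroup(rtree(n + 1, tip.label = rownames(m)), "HTU")
    for (res in c("acctran", "deltran")) {
      rec <- reconstruct_states(phy, m, resolution = res)
      expect_identical(rec$n_changes, fitch_length(phy, m, per_character = TRUE))
    }
  }
})

test_that("strict synapomorphies of non-nested clades are disjoint and have >= 2 carriers", {
  set.seed(44)
  for (i in 1:8) {
    n <- 7
    m <- random_binary_matrix(n, 25, p = 0.35)
    m <- rbind(HTU = rep(0L, ncol(m)), m)
    phy <- root_on_outgroup(rtree(n + 1, tip.label = rownames(m)), "HTU")
    syn <- extract_synapomorphies(phy, m, mode = "strict")
    if (nrow(syn$clades) == 0) next
    expect_lte(max(table(syn$clades$character)), 1L)  # <= 1 node per character
    expect_true(all(syn$clades$n_leaves >= 2L))
    for (r in seq_len(nrow(syn$clades))) {
      leaves <- strsplit(syn$clades$leaves[r], ",")[[1]]
      expect_equal(sum(m[leaves, syn$clades$character[r]]), length(leaves))
      outside <- setdiff(rownames(m), leaves)
      expect_equal(sum(m[outside, syn$clades$character[r]]), 0L)
    }
  }
})

test_that("in a homoplasy-free matrix synapomorphies plus autapomorphies cover all variable characters", {
  taxa <- c("HTU", paste0("t", 1:6))
  m <- ladder_matrix(taxa)
  m <- cbind(m, auto = c(0L, 1L, rep(0L, 5)))  # one autapomorphy on t1
  ex <- exhaustive_search(m)
  tr <- root_on_outgroup(ex$trees[[1]], "HTU")
  s1 <- extract_synapomorphies(tr, m, "strict")
  s2 <- extract_synapomorphies(tr, m, "reconstructed")
  expect_setequal(s1$clades$character, s2$clades$character)
  n_var <- sum(apply(m, 2, function(x) length(unique(x)) > 1))
  expect_equal(nrow(s1$clades) + nrow(s1$autapomorphies), n_var)
  expect_equal(s1$autapomorphies$character, "auto")
  expect_equal(s1$autapomorphies$specimen, "t1")
})

test_that("shared synapomorphies between two clades are recovered exactly", {
  # sibling clades {A,B} and {C,D}: 3 + 3 private characters, 2 shared
  m <- matrix(0L, 5, 8,
              dimnames = list(c("HTU", "A", "B", "C", "D"), paste0("f", 1:8)))
  m[c("A", "B"), 1:3] <- 1L
  m[c("C", "D"), 4:6] <- 1L
  m[c("A", "B", "C", "D"), 7:8] <- 1L
  tr <- root_on_outgroup(read.tree(text = "(HTU,((A,B),(C,D)));"), "HTU")
  shared <- shared_synapomorphies(tr, m, c("A", "B"), c("C", "D"))
  expect_setequal(shared, c("f7", "f8"))

  # disjoint derived patterns share nothing
  expect_length(shared_synapomorphies(tr, m[, 1:6], c("A", "B"), c("C", "D")), 0)

  # planted generator case: k shared + private markers
  plan <- list(
    list(label = "all", members = paste0("P0", 1:4), n_syn = 2, directions = "up"),
    list(label = "left", members = c("P01", "P02"), n_syn = 3, directions = "up"),
    list(label = "right", members = c("P03", "P04"), n_syn = 3, directions = "up")
  )
  coh <- generate_cohort(cohort_config(
    n_outgroup = 4, n_patients = 4, clade_plan = plan,
    n_noise_features = 10, noise_sd = 0, seed = 61
  ))
  rng <- compute_normal_ranges(coh$feature_table, coh$manifest)
  pm <- append_hypothetical_ancestor(polarize(coh$feature_table, rng, coh$manifest))
  ex <- exhaustive_search(pm)
  tr2 <- root_on_outgroup(ex$trees[[1]], "HTU")
  shared2 <- shared_synapomorphies(tr2, pm, c("P01", "P02"), c("P03", "P04"))
  planted_shared <- coh$truth$synapomorphies$feature_id[
    coh$truth$synapomorphies$clade == "all"]
  expect_setequal(shared2, planted_shared)
})

test_that("annotated newick carries per-node synapomorphy counts", {
  m <- two_clade_matrix()
  tr <- two_clade_tree()
  syn <- extract_synapomorphies(tr, m, "strict")
  nwk <- annotated_newick(tr, syn)
  expect_match(nwk, "\\)3")  # the {A,B} node carries 3
  expect_match(nwk, "\\)2")  # the {C,D,E} node carries 2
})
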