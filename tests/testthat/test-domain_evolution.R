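# Pair decomposition, profiles, ancestral reconstruction, Dollo placement,
# diversification classification and the gain-enrichment test

test_that("architecture decomposition collapses runs and enumerates pairs", {
  expect_setequal(decompose_architecture(c("A", "B", "B", "C")),
                  c("A->B", "A->C", "B->C"))
  expect_equal(decompose_architecture("A"), character(0))
  expect_equal(decompose_architecture(character(0)), character(0))
  expect_setequal(decompose_architecture(c("A", "B", "A")),
                  c("A->B", "A->A", "B->A"))
  # idempotent under pre-collapsed input; |pairs| <= k(k-1)/2
  set.seed(2)
  for (i in 1:20) {
    arch <- sample(LETTERS[1:5], sample(1:8, 1), replace = TRUE)
    collapsed <- arch[c(TRUE, arch[-1] != arch[-length(arch)])]
    p1 <- decompose_architecture(arch)
    expect_setequal(p1, decompose_architecture(collapsed))
    k <- length(collapsed)
    expect_lte(length(p1), k * (k - 1) / 2)
    # exhaustive i<j enumeration oracle on the collapsed sequence
    oracle <- unique(unlist(lapply(seq_len(max(k - 1, 0)), function(i)
      paste0(collapsed[i], "->", collapsed[(i + 1):k]))))
    if (k < 2) oracle <- character(0)
    expect_setequal(p1, oracle)
  }
})

test_that("pair profiles count per species, cluster and paralog", {
  dt <- data.frame(
    protein_id = c("p1", "p1", "p2", "p2", "p3", "p3", "p4", "p4"),
    domain_id = c("A", "B", "A", "B", "A", "B", "A", "B"),
    ali_start = c(1, 50, 1, 50, 1, 50, 1, 50),
    ali_end = c(40, 90, 40, 90, 40, 90, 40, 90),
    species = c("sp1", "sp1", "sp1", "sp1", "sp2", "sp2", "sp2", "sp2"))
  og <- structure(list(
    OG1 = list(sp1 = c("p1", "p2"), sp2 = "p3"),
    OG2 = list(sp1 = character(0), sp2 = "p4")), class = "ortholog_table")
  prof <- build_pair_profile(dt, og)
  expect_equal(prof$count[prof$species == "sp1" & prof$orthocluster == "OG1"],
               2L)  # two paralogs
  expect_equal(prof$count[prof$species == "sp2" & prof$orthocluster == "OG1"],
               1L)
  # same pair in two clusters -> two rows
  expect_equal(sum(prof$pair == "A->B"), 3L)
  expect_setequal(unique(prof$orthocluster), c("OG1", "OG2"))
  m <- pair_presence_matrix(prof, c("sp1", "sp2"))
  expect_equal(unname(m["A->B@OG1", ]), c(1, 1))
  expect_equal(unname(m["A->B@OG2", ]), c(0, 1))
})

test_that("pair history reconstruction calls ancestral presence at 0.9", {
  tr <- fixture_tree4()
  mat <- rbind("X->Y@OG1" = c(A = 1, B = 1, C = 1, D = 1),
               "X->Z@OG2" = c(A = 1, B = 1, C = 0, D = 0),
               "Z->W@OG3" = c(A = 0, B = 0, C = 0, D = 1))
  rates <- gainloss_rates(tr, gain = 0.05, loss = 0.05, root_p = 0.5)
  h <- reconstruct_pair_history(mat, tr, rates = rates)
  expect_gte(h$recon$posterior["X->Y@OG1", "R"], 0.99)
  expect_equal(unname(h$calls["X->Y@OG1", "R"]), 1)
  # a pair at posterior < 0.9 is not called
  expect_true(all(h$calls %in% c(0, 1)))
  expect_true(all((h$recon$posterior >= 0.9) == (h$calls == 1)))
  # leaf-specific pair: gain maximal on that terminal branch
  ev <- setNames(h$recon$events$expected_gains, h$recon$events$branch)
  # recompute for the single character
  r3 <- reconstruct_ancestral_sites(mat[3, , drop = FALSE], tr, rates)
  g3 <- setNames(r3$events$expected_gains, r3$events$branch)
  expect_true(all(g3["D"] > g3[setdiff(names(g3), "D")]))
})

test_that("simulated pair histories are recovered within tolerance", {
  tr <- fixture_tree8()
  sim <- simulate_domain_histories(tr, n_orthoclusters = 150, n_domains = 12,
                                   gain_rate = 0.25, loss_rate = 0.2,
                                   seed = 11)
  prof <- build_pair_profile(sim$domain_table, sim$orthogroups)
  mat <- pair_presence_matrix(prof, tr$tip.label)
  h <- reconstruct_pair_history(mat, tr)
  # true pair presence at root vs calls: most root pairs have high posterior
  truth_root <- unique(paste0(
    sim$pair_truth$pair[sim$pair_truth$node == "R"], "@",
    sim$pair_truth$orthocluster[sim$pair_truth$node == "R"]))
  truth_root <- intersect(truth_root, rownames(mat))
  post_root <- h$recon$posterior[truth_root, "R"]
  expect_gt(mean(post_root >= 0.5), 0.7)
})

test_that("Dollo placement equals the exhaustive single-gain oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1)N1:1,C:1)R;")
  d <- dollo_reconstruct(c(A = 1, B = 0, C = 1), tr)
  expect_equal(d$gain_node, "R")
  expect_equal(d$loss_branches, "B")
  expect_equal(d$n_losses, 1L)
  d2 <- dollo_reconstruct(c(A = 1, B = 0, C = 0), tr)
  expect_equal(d2$gain_node, "A")
  expect_equal(d2$n_losses, 0L)
  d3 <- dollo_reconstruct(c(A = 1, B = 1, C = 1), tr)
  expect_equal(d3$gain_node, "R")
  expect_equal(d3$n_losses, 0L)
  expect_equal(dollo_reconstruct(c(A = 0, B = 0, C = 0), tr)$n_losses, 0L)
  # all presence patterns on a 5-taxon tree against the enumeration oracle
  tr5 <- ape::read.tree(text = "(((A:1,B:1)N1:1,(C:1,D:1)N2:1)N3:1,E:1)R;")
  pats <- as.matrix(expand.grid(rep(list(0:1), 5)))
  colnames(pats) <- tr5$tip.label
  for (i in seq_len(nrow(pats))) {
    pres <- pats[i, ]
    got <- dollo_reconstruct(pres, tr5)
    want <- oracle_dollo(tr5, pres)
    expect_equal(got$n_losses, want$n_losses, info = paste(pres, collapse = ""))
    if (sum(pres) > 0)
      expect_equal(got$gain_node, want$gain_node,
                   info = paste(pres, collapse = ""))
  }
})

test_that("node diversification classifies gain/loss bias by the 5% rule", {
  np <- c(R = 100, N1 = 100, A = 100, B = 0)
  g <- c(N1 = 12, A = 6, B = 1)
  l <- c(N1 = 5, A = 6, B = 1)
  d <- node_diversification(np, g, l)
  expect_equal(d$class[d$node == "N1"], "gain-biased")  # 12 - 5 = 7 > 5
  expect_equal(d$class[d$node == "A"], "stasis")        # 6 - 6 = 0
  expect_equal(d$class[d$node == "B"], "undefined")     # no pairs present
  expect_equal(d$ratio[d$node == "A"], 0, tolerance = 1e-6)
})

test_that("gain enrichment matches the hypergeometric oracle", {
  # family domains absent from all gains -> p = 1
  expect_warning(
    e1 <- enrichment_test(c("A->B@OG1", "C->D@OG2"), c("E->F@OG3"), "ZZ"),
    "empty margin")
  expect_equal(e1$p, 1)
  # all focal gains in family, none elsewhere
  focal <- paste0("TF", 1:5, "->X@OG", 1:5)
  bg <- paste0("Y->Z@OG", 6:15)
  e2 <- enrichment_test(focal, bg, paste0("TF", 1:5))
  tab <- matrix(c(5, 0, 0, 10), 2)
  expect_equal(e2$p, oracle_fisher(tab), tolerance = 1e-12)
  # balanced table -> p = 1
  e3 <- enrichment_test(c("TF1->X@OG1", "Y->Z@OG2"),
                        c("TF2->X@OG3", "W->V@OG4"), c("TF1", "TF2"))
  expect_equal(e3$p, 1)
  expect_error(enrichment_test("A->B@OG1", character(0), "A"), "background")
})
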