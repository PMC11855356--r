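test_that("two-species gene-tree root time is 1 + Exp(1) on average", {
  gs <- simulate_gene_trees("(A:1,B:1);", n = 50000, seed = 101)
  root_times <- vapply(gs$trees, function(tr) {
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  # E = 1 + 1 = 2, Var = 1: 4 standard errors at n = 50,000
  expect_lt(abs(mean(root_times) - 2.0), 4 / sqrt(50000))
})

test_that("every simulated gene tree conserves lineages and coalescences", {
  sp <- "((A:1,B:1):1,C:2);"
  gs <- simulate_gene_trees(sp, n = 200, seed = 102)
  for (tr in gs$trees) {
    expect_setequal(tr$tip.label, c("A", "B", "C"))
    expect_equal(tr$Nnode, 2)                # coalescences = leaves - 1
    expect_true(all(tr$edge.length >= 0))
  }
  gs2 <- simulate_gene_trees(sp, n = 50, seed = 103,
                             samples_per_species = 2)
  for (tr in gs2$trees) {
    expect_equal(length(tr$tip.label), 6)
    expect_equal(tr$Nnode, 5)
  }
})

test_that("MSC concordance at tau = 1 matches the closed form", {
  n <- 20000
  gs <- simulate_gene_trees("((A:1,B:1):1,C:2);", n = n, seed = 104)
  ref <- topology_key(parse_newick("((A,B),C);"))
  keys <- vapply(gs$trees, topology_key, character(1))
  p <- 1 - (2 / 3) * exp(-1)
  expect_lt(abs(mean(keys == ref) - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("same seed gives bit-identical samples, different seeds differ", {
  sp <- "((A:1,B:1):1,C:2);"
  a <- simulate_gene_trees(sp, n = 20, seed = 105)
  b <- simulate_gene_trees(sp, n = 20, seed = 105)
  expect_identical(lapply(a$trees, write_newick),
                   lapply(b$trees, write_newick))
  c <- simulate_gene_trees(sp, n = 20, seed = 106)
  expect_false(identical(lapply(a$trees, write_newick),
                         lapply(c$trees, write_newick)))
})

test_that("hybrid routing frequency matches gamma", {
  # donor edge leads to a distant outgroup: a routed recipient lineage
  # cannot join its sister before the root, so the sister topology tracks
  # the routing indicator almost surely
  net <- species_network(
    "((A:1,B:1):9,C:10);",
    events = data.frame(recipient = "A", donor = "C", time = 0.5,
                        gamma = 0.3))
  n <- 5000
  gs <- simulate_gene_trees(net, n = n, seed = 107)
  sister_ab <- topology_key(parse_newick("((A,B),C);"))
  keys <- vapply(gs$trees, topology_key, character(1))
  routed <- mean(keys != sister_ab)
  # not-routed lineages fail to join B with prob e^-9; 3 binomial SE
  expect_lt(abs(routed - 0.3), 3 * sqrt(0.3 * 0.7 / n) + 2e-4)
})

test_that("gamma = 0 network is indistinguishable from the plain MSC", {
  tree_txt <- "(((A:1,B:1):1,C:2):1,D:3);"
  net <- species_network(
    tree_txt,
    events = data.frame(recipient = "B", donor = "C", time = 1.0,
                        gamma = 0))
  g_net <- simulate_gene_trees(net, n = 4000, seed = 108)
  g_msc <- simulate_gene_trees(tree_txt, n = 4000, seed = 109)
  k1 <- vapply(g_net$trees, topology_key, character(1))
  k2 <- vapply(g_msc$trees, topology_key, character(1))
  lev <- union(k1, k2)
  tab <- rbind(table(factor(k1, lev)), table(factor(k2, lev)))
  keep <- colSums(tab) >= 10
  pval <- suppressWarnings(stats::chisq.test(tab[, keep]))$p.value
  expect_gt(pval, 1e-3)
})

test_that("model validation rejects bad gamma and negative branch lengths", {
  expect_error(species_network(
    "((A:1,B:1):1,C:2);",
    events = data.frame(recipient = "A", donor = "C", time = 0.5,
                        gamma = 1.5)), "gamma")
  bad <- parse_newick("((A:1,B:-1):1,C:2);")
  expect_error(simulate_gene_trees(bad, n = 1, seed = 1), "non-negative")
  expect_error(species_network(
    "((A:1,B:1):1,C:2);",
    events = data.frame(recipient = "A", donor = "C", time = 5,
                        gamma = 0.1)), "outside.*span")
})

test_that("zero-length edges copy the parent sequence unchanged", {
  tr <- parse_newick("(A:0,B:0);")
  a <- simulate_alignment(tr, n_sites = 500, mut_rate = 0.1, seed = 110)
  expect_identical(a["A", ], a["B", ])
})

test_that("pairwise JC69 difference fractions match the closed form", {
  # total path mu * t = 0.1
  tr <- parse_newick("(A:2.5,B:2.5);")
  n <- 100000
  a <- simulate_alignment(tr, n_sites = n, mut_rate = 0.02, seed = 111)
  p_expect <- (3 / 4) * (1 - exp(-0.4 / 3))
  p_obs <- mean(a["A", ] != a["B", ])
  expect_lt(abs(p_obs - p_expect), 4 * sqrt(p_expect * (1 - p_expect) / n))
  # saturation: path length 50 -> 3/4
  tr2 <- parse_newick("(A:25,B:25);")
  a2 <- simulate_alignment(tr2, n_sites = 20000, mut_rate = 1, seed = 112)
  expect_lt(abs(mean(a2["A", ] != a2["B", ]) - 0.75), 0.01)
  expect_error(simulate_alignment(tr, n_sites = 0, mut_rate = 0.1), "n_sites")
})

test_that("the hybrid-quartet scenario behaves at the gamma extremes", {
  # gamma = 0: ABBA and BABA arise only from ILS and balance out
  sc0 <- xanthoceras_scenario(0, n_loci = 400, sites_per_locus = 500,
                              seed = 113)
  q <- quartet_assignment("P1", "H", "P2", "O")
  cc0 <- Reduce(function(a, b) {
    for (f in names(a)[1:5]) a[[f]] <- a[[f]] + b[[f]]
    a
  }, lapply(sc0$alignments, count_site_patterns, q = q))
  diff <- cc0$n_ABBA - cc0$n_BABA
  expect_lt(abs(diff), 4 * sqrt(cc0$n_ABBA + cc0$n_BABA) + 1)
  # gamma = 1: the mirror scenario, estimator near 1
  sc1 <- xanthoceras_scenario(1, n_loci = 400, sites_per_locus = 500,
                              seed = 114)
  cc1 <- Reduce(function(a, b) {
    for (f in names(a)[1:5]) a[[f]] <- a[[f]] + b[[f]]
    a
  }, lapply(sc1$alignments, count_site_patterns, q = q))
  expect_lt(abs(estimate_gamma(cc1) - 1), 0.05)
})
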