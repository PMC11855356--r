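test_that("concordance_fraction is exact on identical and deep trees", {
  ref <- parse_newick("((A,B),C);")
  gs <- replicate(20, parse_newick("((A:1,B:1):1,C:2);"), simplify = FALSE)
  expect_equal(concordance_fraction(gs, ref), 1.0)
  # tau = 50: deep coalescence suppressed, species topology near-certain
  deep <- simulate_gene_trees("((A:1,B:1):50,C:51);", n = 2000, seed = 201)
  expect_gt(concordance_fraction(deep, ref), 0.999)
})

test_that("concordance with a discordant reference matches (1/3) e^-tau", {
  n <- 20000
  gs <- simulate_gene_trees("((A:1,B:1):1,C:2);", n = n, seed = 202)
  wrong <- parse_newick("((A,C),B);")
  p <- (1 / 3) * exp(-1)
  expect_lt(abs(concordance_fraction(gs, wrong) - p),
            4 * sqrt(p * (1 - p) / n))
})

test_that("full-topology and focal-split modes rank as strict vs lax", {
  ref <- parse_newick("(((A,B),C),D);")
  gts <- list(parse_newick("(((A,B),C),D);"),
              parse_newick("(((A,B),D),C);"),   # keeps split AB, not topology
              parse_newick("(((A,C),B),D);"))
  full <- concordance_fraction(gts, ref, mode = "full")
  split <- concordance_fraction(gts, ref, mode = "split",
                                focal = c("A", "B"))
  expect_equal(full, 1 / 3)
  expect_equal(split, 2 / 3)
  expect_gte(split, full)
  expect_error(
    concordance_fraction(gts, ref, mode = "split", focal = c("A", "D")),
    "not present")
})

test_that("topology spectrum counts sum to the number of draws", {
  gs <- simulate_gene_trees("((A:0.2,B:0.2):0.2,C:0.4);", n = 500,
                            seed = 203)
  spec <- topology_spectrum(gs)
  expect_equal(sum(spec), 500)
  expect_equal(attr(spec, "total"), 500)
  ref_key <- topology_key(parse_newick("((A,B),C);"))
  # spectrum decomposition: reference fraction plus all alternatives is 1
  conc <- concordance_fraction(gs, parse_newick("((A,B),C);"))
  expect_equal(conc + sum(spec[setdiff(names(spec), ref_key)]) / 500, 1.0)
})

test_that("distance_distribution is zero on matching trees and even on binary", {
  sp <- parse_newick("(((A,B),(C,D)),E);")
  same <- replicate(10, parse_newick("(((A,B),(C,D)),E);"), simplify = FALSE)
  d0 <- distance_distribution(same, sp)
  expect_true(all(d0 == 0L))
  gs <- simulate_gene_trees("(((A:.3,B:.3):.3,(C:.6,D:.6):.3):1,E:1.9);",
                            n = 300, seed = 204)
  d <- distance_distribution(gs$trees, sp, label = "simulated")
  expect_true(all(d %% 2 == 0))
  expect_gt(max(d), 0)        # shallow branches guarantee some discordance
  expect_identical(attr(d, "label"), "simulated")
  # gene trees missing reference taxa are skipped with a warning
  broken <- c(same, list(parse_newick("((A,B),(C,E));")))
  expect_warning(d2 <- distance_distribution(broken, sp), "skipped")
  expect_equal(length(d2), 10)
})

test_that("mann_whitney_u matches hand cases and the enumeration oracle", {
  # identical multisets: U = n^2 / 2, p near 1
  res <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res$U, 8)
  expect_gt(res$p, 0.95)
  # exact case from enumeration: x = [1,2], y = [3,4] -> p = 1/3
  res2 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res2$p, 1 / 3)
  expect_identical(res2$method, "exact")
  expect_equal(res2$p, mwu_enum_oracle(c(1, 2), c(3, 4)))
  expect_error(mann_whitney_u(numeric(0), c(1)), "non-empty")
})

test_that("exact and approximate branches agree on tie-free size-7/8 samples", {
  set.seed(205)
  gaps <- vapply(1:20, function(i) {
    x <- sample(seq(1, 2000), 7)
    y <- sample(setdiff(seq(1, 2000), x), 8)
    exact <- mann_whitney_u(x, y)
    expect_identical(exact$method, "exact")
    expect_equal(exact$p, mwu_enum_oracle(x, y), tolerance = 1e-12)
    # the approximation branch on the same data
    approx_p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    abs(exact$p - approx_p)
  }, numeric(1))
  # the continuity-corrected normal approximation tracks the exact law at
  # the 0.01 scale at these sizes (worst pointwise gap just over 0.01)
  expect_lt(mean(gaps), 0.01)
  expect_lt(max(gaps), 0.015)
})

test_that("node_concordance classifies crafted fixtures correctly", {
  sp <- parse_newick("(((A,B),(C,D)),E);")
  gts <- list(parse_newick("(((A,B),(C,D)),E);"),
              parse_newick("(((A,B),C),(D,E));"),
              parse_newick("(((A,C),(B,D)),E);"))
  nc <- node_concordance(sp, gts)
  expect_equal(nrow(nc), 2)
  # per node, counts sum to the number of gene trees
  expect_true(all(nc$concordant + nc$conflicting + nc$uninformative == 3))
  ab <- nc[grep("^C;D;E$", nc$split), ]       # the AB | CDE split
  expect_equal(unname(c(ab$concordant, ab$conflicting, ab$uninformative)),
               c(2, 1, 0))
  expect_equal(ab$prop_concordant, 2 / 3)
  # identical gene trees: everything concordant
  nc2 <- node_concordance(sp, gts[1])
  expect_true(all(nc2$concordant == 1))
})

test_that("node_concordance tolerates gene trees with missing taxa", {
  sp <- parse_newick("(((A,B),(C,D)),E);")
  gts <- list(parse_newick("((A,B),(C,D));"),      # E missing
              parse_newick("((A,C),B);"))          # informative for nothing
  nc <- node_concordance(sp, gts)
  expect_true(all(nc$concordant + nc$conflicting + nc$uninformative == 2))
  # the 3-taxon tree cannot inform any 5-taxon split
  expect_true(all(nc$uninformative >= 1))
})
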