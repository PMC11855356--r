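make_counts <- function(bbaa, abba, baba, other = 0) {
  structure(list(n_BBAA = bbaa, n_ABBA = abba, n_BABA = baba,
                 n_other = other,
                 n_used = bbaa + abba + baba + other,
                 quartet = quartet_assignment("P1", "H", "P2", "O")),
            class = "site_pattern_counts")
}

test_that("single sites classify into BBAA / ABBA / BABA as defined", {
  q <- quartet_assignment("P1", "H", "P2", "O")
  a1 <- alignment(c(P1 = "G", H = "G", P2 = "T", O = "T"))
  cc <- count_site_patterns(a1, q)
  expect_equal(cc$n_BBAA, 1)
  a2 <- alignment(c(P1 = "T", H = "G", P2 = "G", O = "T"))
  expect_equal(count_site_patterns(a2, q)$n_ABBA, 1)
  a3 <- alignment(c(P1 = "G", H = "T", P2 = "G", O = "T"))
  expect_equal(count_site_patterns(a3, q)$n_BABA, 1)
  # gap anywhere skips the site entirely
  a4 <- alignment(c(P1 = "G", H = "G", P2 = "T", O = "-"))
  expect_equal(count_site_patterns(a4, q)$n_used, 0)
  expect_error(count_site_patterns(a1, quartet_assignment("P1", "H", "P2",
                                                          "missing")),
               "missing")
})

test_that("pattern counting agrees with a per-site brute-force classifier", {
  set.seed(301)
  n <- 1000
  m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 4 * n, replace = TRUE,
                     prob = c(0.23, 0.23, 0.23, 0.23, 0.04, 0.04)),
              nrow = 4, dimnames = list(c("P1", "H", "P2", "O"), NULL))
  a <- alignment(m)
  q <- quartet_assignment("P1", "H", "P2", "O")
  cc <- count_site_patterns(a, q)
  oracle <- table(factor(
    vapply(seq_len(n), function(i) {
      classify_site_oracle(a["P1", i], a["H", i], a["P2", i], a["O", i])
    }, character(1)),
    levels = c("BBAA", "ABBA", "BABA", "other", "skipped")))
  expect_equal(cc$n_BBAA, unname(oracle["BBAA"]))
  expect_equal(cc$n_ABBA, unname(oracle["ABBA"]))
  expect_equal(cc$n_BABA, unname(oracle["BABA"]))
  expect_equal(cc$n_other, unname(oracle["other"]))
  expect_equal(cc$n_used, n - unname(oracle["skipped"]))
})

test_that("gamma estimator hits the trivial and hand-evaluated cases", {
  expect_equal(estimate_gamma(make_counts(500, 100, 100, 300)), 0)
  # C = 0.8, d = 0.1, gamma = 0.16: f = (0.688, 0.212, 0.100)
  expect_equal(estimate_gamma(make_counts(688, 212, 100)), 0.16)
  # f_BBAA = f_BABA with f_ABBA larger: roles of P1 and P2 swapped
  expect_equal(estimate_gamma(make_counts(100, 500, 100, 300)), 1)
  # zero denominator -> NA sentinel
  expect_true(is.na(estimate_gamma(make_counts(100, 100, 100, 0))))
})

test_that("gamma estimator is exact on the two-topology mixture identity", {
  set.seed(302)
  for (i in 1:100) {
    C <- runif(1, 0.1, 0.9)
    d <- runif(1, 0, C * 0.9)
    g <- runif(1)
    f <- c((1 - g) * C + g * d, (1 - g) * d + g * C, d)
    scale <- 1e7
    cc <- make_counts(f[1] * scale, f[2] * scale, f[3] * scale,
                      other = scale * 0.01)
    expect_lt(abs(estimate_gamma(cc) - g), 1e-12)
  }
})

test_that("z_test behaves at the symmetric null and on strong signal", {
  null_cc <- make_counts(6000, 2000, 2000)
  res <- z_test(null_cc, B = 200, seed = 303)
  expect_equal(res$gamma, 0)
  expect_equal(res$z, 0)
  expect_equal(res$p, 0.5)
  # the gamma = 0.16 worked example scaled to 10,000 classified sites
  sig <- make_counts(6880, 2120, 1000)
  res2 <- z_test(sig, B = 1000, seed = 304)
  expect_gt(res2$z, 3)
  expect_lt(res2$p, 0.05)
  expect_equal(res2$gamma, 0.16, tolerance = 1e-12)
})

test_that("bootstrap SE is deterministic given the seed", {
  cc <- make_counts(688, 212, 100, 1000)
  a <- z_test(cc, B = 200, seed = 305)
  b <- z_test(cc, B = 200, seed = 305)
  expect_identical(a$se, b$se)
  c <- z_test(cc, B = 200, seed = 306)
  expect_false(identical(a$se, c$se))
})

test_that("triple_scan enumerates 3 * C(k,3) canonicalized assignments", {
  set.seed(307)
  mk <- function(taxa, n = 400) {
    m <- matrix(sample(c("A", "C", "G", "T"), length(taxa) * n,
                       replace = TRUE),
                nrow = length(taxa), dimnames = list(taxa, NULL))
    alignment(m)
  }
  a3 <- mk(c("x", "y", "z", "out"))
  res3 <- triple_scan(a3, outgroup = "out", B = 50, seed = 308)
  expect_equal(nrow(res3), 3)
  a5 <- mk(c("a", "b", "c", "d", "e", "out"))
  res5 <- triple_scan(a5, outgroup = "out", B = 50, seed = 309)
  expect_equal(nrow(res5), 3 * choose(5, 3))
  expect_true(all(is.na(res5$gamma) | res5$gamma >= 0))
  # each row's hybrid is distinct from its parents
  expect_true(all(res5$H != res5$P1 & res5$H != res5$P2 &
                    res5$P1 != res5$P2))
  expect_error(triple_scan(a3, outgroup = "nope"), "outgroup")
})

test_that("heatmap_matrix books passing cells and only those", {
  res <- data.frame(P1 = c("a", "b"), H = c("h", "h"), P2 = c("c", "d"),
                    gamma = c(0.2, 0.4), se = c(0.01, 0.2),
                    z = c(20, 2), p = c(1e-8, 0.3),
                    swapped = FALSE, stringsAsFactors = FALSE)
  res$passed_filter <- filter_significant(res)
  expect_equal(res$passed_filter, c(TRUE, FALSE))
  m <- heatmap_matrix(res, "h", c("a", "b", "c", "d"))
  expect_equal(sum(!is.na(m)), 1)
  expect_equal(m["a", "c"], 0.2)
  # no significant rows: all-missing matrix
  res$p <- 1
  res$passed_filter <- filter_significant(res)
  m2 <- heatmap_matrix(res, "h", c("a", "b", "c", "d"))
  expect_true(all(is.na(m2)))
  expect_warning(heatmap_matrix(res, "absent", c("a", "b")), "absent")
})

test_that("significance filter applies 0 < gamma < 1, p < 0.05, Z > 3", {
  tab <- data.frame(gamma = c(0.5, 0, 1, 0.5, 0.5, NA),
                    p = c(0.01, 0.01, 0.01, 0.1, 0.01, 0.01),
                    z = c(5, 5, 5, 5, 2, 5))
  expect_equal(filter_significant(tab),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})
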