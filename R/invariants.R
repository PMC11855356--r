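# Site-pattern invariants hybridization detection on rooted quartets
# (((P1, H), P2), O): polarized pattern counting, a moment estimator of the
# inheritance probability gamma, a bootstrap Z-test, an all-triples scan
# with the standard significance filter (0 < gamma < 1, p < 0.05, Z > 3),
# and a heatmap matrix export.

#' Quartet assignment
#'
#' @param P1,H,P2,O Distinct taxon labels: the two parents, the putative
#'   hybrid/recipient H, and the outgroup O used to polarize site patterns.
#' @return A named character vector of class \code{"quartet_assignment"}.
#' @export
quartet_assignment <- function(P1, H, P2, O) {
  q <- c(P1 = P1, H = H, P2 = P2, O = O)
  if (anyDuplicated(q)) stop("quartet taxa must be distinct")
  structure(q, class = "quartet_assignment")
}

#' Count polarized quartet site patterns
#'
#' Sites where any of the four taxa has a gap or N are skipped. At the
#' remaining (used) sites the outgroup allele is taken as ancestral; a site
#' is classified when the ingroup trio is biallelic with exactly two taxa
#' sharing the same derived state: BBAA when P1 and H share it, ABBA when H
#' and P2 share it, BABA when P1 and P2 share it. All other used sites are
#' tallied as \code{n_other}.
#'
#' @param a An alignment matrix containing all four taxa.
#' @param q A [quartet_assignment()].
#' @return A list of class \code{"site_pattern_counts"} with elements
#'   \code{n_BBAA}, \code{n_ABBA}, \code{n_BABA}, \code{n_other},
#'   \code{n_used}, and \code{quartet}.
#' @export
count_site_patterns <- function(a, q) {
  missing <- setdiff(unname(q), rownames(a))
  if (length(missing)) {
    stop("taxa missing from alignment: ", paste(missing, collapse = ", "))
  }
  s1 <- a[q[["P1"]], ]; sh <- a[q[["H"]], ]
  s2 <- a[q[["P2"]], ]; so <- a[q[["O"]], ]
  used <- !(s1 %in% c("-", "N") | sh %in% c("-", "N") |
            s2 %in% c("-", "N") | so %in% c("-", "N"))
  s1 <- s1[used]; sh <- sh[used]; s2 <- s2[used]; so <- so[used]
  d1 <- s1 != so; dh <- sh != so; d2 <- s2 != so
  two_derived <- (d1 + dh + d2) == 2L
  bbaa <- two_derived & d1 & dh & (s1 == sh)
  abba <- two_derived & dh & d2 & (sh == s2)
  baba <- two_derived & d1 & d2 & (s1 == s2)
  structure(list(n_BBAA = sum(bbaa), n_ABBA = sum(abba),
                 n_BABA = sum(baba),
                 n_other = sum(used) - sum(bbaa) - sum(abba) - sum(baba),
                 n_used = sum(used), quartet = q),
            class = "site_pattern_counts")
}

#' Pool site-pattern counts over loci
#'
#' Element-wise sum of per-locus counts, as used when loci are concatenated
#' into a super-alignment (sites treated as independent).
#'
#' @param counts_list A list of \code{"site_pattern_counts"} for the same
#'   quartet.
#' @return A single \code{"site_pattern_counts"} object.
#' @export
sum_site_patterns <- function(counts_list) {
  out <- counts_list[[1L]]
  for (cc in counts_list[-1L]) {
    for (f in c("n_BBAA", "n_ABBA", "n_BABA", "n_other", "n_used")) {
      out[[f]] <- out[[f]] + cc[[f]]
    }
  }
  out
}

#' Moment estimator of the inheritance probability gamma
#'
#' With pattern frequencies f = count / n_used,
#' \deqn{\hat\gamma = (f_{ABBA} - f_{BABA}) /
#'       (f_{BBAA} + f_{ABBA} - 2 f_{BABA}).}
#' Under a two-topology mixture with equal internal branches -- expected
#' frequencies \eqn{f_{BBAA} = (1-\gamma) C + \gamma d},
#' \eqn{f_{ABBA} = (1-\gamma) d + \gamma C}, \eqn{f_{BABA} = d} -- the
#' estimator equals \eqn{\gamma} exactly. Under the null of no
#' introgression \eqn{f_{ABBA} = f_{BABA}} in expectation and
#' \eqn{\hat\gamma = 0}.
#'
#' @param counts A \code{"site_pattern_counts"} object.
#' @return The estimate, or \code{NA_real_} when the denominator is zero
#'   (excluded downstream by the significance filter).
#' @export
estimate_gamma <- function(counts) {
  n <- counts$n_used
  if (n <= 0) return(NA_real_)
  f_bbaa <- counts$n_BBAA / n
  f_abba <- counts$n_ABBA / n
  f_baba <- counts$n_BABA / n
  den <- f_bbaa + f_abba - 2 * f_baba
  if (den == 0) return(NA_real_)
  (f_abba - f_baba) / den
}

#' Bootstrap Z-test for gamma > 0
#'
#' The standard error is the standard deviation of the gamma estimate over
#' \code{B} multinomial resamples of the classified-site counts
#' (BBAA/ABBA/BABA/other, total \code{n_used}); Z = gamma / SE and p is the
#' one-sided upper-tail standard-normal probability, matching the question
#' of whether gamma deviates upward from 0.
#'
#' @param counts A \code{"site_pattern_counts"} object with
#'   \code{n_used > 0}.
#' @param B Bootstrap replicates (>= 50; default 200).
#' @param seed Optional integer seed; same seed gives an identical SE.
#' @return A list of class \code{"invariants_result"}: \code{quartet},
#'   \code{gamma}, \code{se}, \code{z}, \code{p}, \code{counts}.
#' @export
z_test <- function(counts, B = 200, seed = NULL) {
  stopifnot(B >= 50, counts$n_used > 0)
  gam <- estimate_gamma(counts)
  probs <- c(counts$n_BBAA, counts$n_ABBA, counts$n_BABA,
             counts$n_other) / counts$n_used
  boot <- with_opt_seed(seed, {
    draws <- rmultinom(B, size = counts$n_used, prob = probs)
    apply(draws, 2L, function(d) {
      den <- d[1L] + d[2L] - 2 * d[3L]
      if (den == 0) NA_real_ else (d[2L] - d[3L]) / den
    })
  })
  se <- sd(boot, na.rm = TRUE)
  if (is.na(gam) || is.na(se)) {
    z <- NA_real_; p <- 1
  } else if (se == 0) {
    warning("bootstrap SE is zero; Z undefined")
    z <- NA_real_; p <- 1
  } else {
    z <- gam / se
    p <- pnorm(z, lower.tail = FALSE)
  }
  structure(list(quartet = counts$quartet, gamma = gam, se = se, z = z,
                 p = p, counts = counts),
            class = "invariants_result")
}

#' Scan all ingroup triples for hybridization signals
#'
#' For every unordered triple of ingroup taxa, each of the three taxa is
#' tried in the hybrid role H with the other two as parents. The parental
#' order is canonicalized so that the reported gamma is non-negative (P1
#' and P2 swapped when needed, recorded in \code{swapped}), so each
#' unordered parental pair appears once per hybrid. Results are
#' deterministic given \code{seed}.
#'
#' @param a An alignment matrix (e.g. a stripped super-alignment over
#'   concatenated loci).
#' @param outgroup Outgroup taxon label, present in \code{a}.
#' @param taxa Optional ingroup labels (default: all rows except the
#'   outgroup); at least 3.
#' @param B Bootstrap replicates for each Z-test.
#' @param seed Optional integer seed.
#' @return A data frame with one row per assignment: \code{P1}, \code{H},
#'   \code{P2}, \code{gamma}, \code{se}, \code{z}, \code{p},
#'   \code{nBBAA}, \code{nABBA}, \code{nBABA}, \code{n_used},
#'   \code{swapped}, \code{passed_filter}.
#' @export
triple_scan <- function(a, outgroup, taxa = NULL, B = 200, seed = NULL) {
  if (!outgroup %in% rownames(a)) {
    stop("outgroup '", outgroup, "' not in alignment")
  }
  if (is.null(taxa)) taxa <- setdiff(rownames(a), outgroup)
  taxa <- setdiff(taxa, outgroup)
  if (length(taxa) < 3L) stop("need at least 3 ingroup taxa")
  triples <- combn(sort(taxa), 3L, simplify = FALSE)
  rows <- list()
  idx <- 0L
  for (tri in triples) {
    for (h in tri) {
      par <- setdiff(tri, h)
      q <- quartet_assignment(par[1L], h, par[2L], outgroup)
      cc <- count_site_patterns(a, q)
      gam <- estimate_gamma(cc)
      swapped <- FALSE
      if (!is.na(gam) && gam < 0) {
        q <- quartet_assignment(par[2L], h, par[1L], outgroup)
        cc <- count_site_patterns(a, q)
        swapped <- TRUE
      }
      idx <- idx + 1L
      res <- z_test(cc, B = B,
                    seed = if (is.null(seed)) NULL else seed + idx)
      rows[[idx]] <- data.frame(
        P1 = q[["P1"]], H = q[["H"]], P2 = q[["P2"]],
        gamma = res$gamma, se = res$se, z = res$z, p = res$p,
        nBBAA = cc$n_BBAA, nABBA = cc$n_ABBA, nBABA = cc$n_BABA,
        n_used = cc$n_used, swapped = swapped,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$passed_filter <- filter_significant(out)
  out
}

#' Significance filter for invariants results
#'
#' The retained results satisfy \eqn{0 < \hat\gamma < 1}, \eqn{p < 0.05}
#' and \eqn{Z > 3}.
#'
#' @param results A data frame with columns \code{gamma}, \code{p},
#'   \code{z}.
#' @return A logical vector.
#' @export
filter_significant <- function(results) {
  with(results, !is.na(gamma) & gamma > 0 & gamma < 1 &
         !is.na(p) & p < 0.05 & !is.na(z) & z > 3)
}

#' Gamma heatmap matrix for one hybrid
#'
#' Square matrix indexed by \code{leaf_order}: cell (i, j) holds the gamma
#' estimate of the assignment (P1 = i, P2 = j, H = hybrid) when that result
#' passed the significance filter, and NA otherwise.
#'
#' @param results A \code{triple_scan()} result data frame.
#' @param hybrid Hybrid taxon label.
#' @param leaf_order Row/column order; must cover all P1/P2 labels of the
#'   passing results.
#' @return A numeric matrix with dimnames \code{leaf_order}.
#' @export
heatmap_matrix <- function(results, hybrid, leaf_order) {
  m <- matrix(NA_real_, length(leaf_order), length(leaf_order),
              dimnames = list(leaf_order, leaf_order))
  sub <- results[results$H == hybrid & results$passed_filter, , drop = FALSE]
  if (!nrow(sub)) {
    if (!hybrid %in% results$H) {
      warning("hybrid '", hybrid, "' absent from results; empty matrix")
    }
    return(m)
  }
  bad <- setdiff(c(sub$P1, sub$P2), leaf_order)
  if (length(bad)) {
    stop("leaf_order missing taxa: ", paste(bad, collapse = ", "))
  }
  for (i in seq_len(nrow(sub))) {
    m[sub$P1[i], sub$P2[i]] <- sub$gamma[i]
  }
  m
}

#' Write a matrix as TSV
#'
#' Row-major TSV with row and column names; NA cells written empty.
#'
#' @param m A matrix.
#' @param path Output file path.
#' @export
write_tsv_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, na = "",
                     col.names = NA)
  invisible(path)
}
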