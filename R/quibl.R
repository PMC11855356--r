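# Triplet internal-branch mixture analysis: for each 3-taxon subset of the
# gene trees, the internal branch lengths of each triplet topology class
# are modelled as a mixture of an exponential (pure ILS) and a shifted
# exponential (ILS on top of a waiting time contributed by introgression or
# speciation); model choice is by BIC.

#' Extract triplet internal branch lengths from gene trees
#'
#' Each gene tree is rooted with the outgroup, restricted to the triplet
#' \{A, B, C\}, and classified by which pair is sister; the internal branch
#' is the edge between the triplet's two internal nodes. Trees missing a
#' triplet taxon or the outgroup are skipped; unresolved (polytomous)
#' restrictions are tallied separately; zero-length internal branches are
#' dropped with their count recorded.
#'
#' @param gene_trees List of \code{"phylo"} trees.
#' @param triplet Character vector of three ingroup taxon labels.
#' @param outgroup Outgroup label, used only to root each gene tree.
#' @return An object of class \code{"triplet_branch_data"}: list with
#'   \code{triplet}, \code{classes} (named list of positive branch-length
#'   vectors, one per triplet topology \code{"X,Y|Z"}), \code{counts},
#'   \code{n_skipped}, \code{n_unresolved}, \code{n_zero_dropped}.
#' @export
extract_triplet_branches <- function(gene_trees, triplet, outgroup) {
  stopifnot(length(triplet) == 3L)
  triplet <- sort(triplet)
  class_name <- function(pair, third) {
    paste0(paste(sort(pair), collapse = ","), "|", third)
  }
  classes <- setNames(
    vector("list", 3L),
    vapply(seq_len(3L),
           function(i) class_name(triplet[-i], triplet[i]), character(1)))
  for (nm in names(classes)) classes[[nm]] <- numeric(0)
  n_skipped <- 0L; n_unresolved <- 0L; n_zero <- 0L
  for (tr in gene_trees) {
    if (!all(c(triplet, outgroup) %in% tr$tip.label)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rt <- tryCatch(ape::root(tr, outgroup, resolve.root = TRUE),
                   error = function(e) NULL)
    if (is.null(rt)) {
      n_skipped <- n_skipped + 1L
      next
    }
    t3 <- ape::keep.tip(rt, triplet)
    if (t3$Nnode < 2L) {
      n_unresolved <- n_unresolved + 1L
      next
    }
    # binary rooted triplet: the cherry node's parent edge is the internal
    # branch separating the sister pair from the third taxon
    root <- 4L
    inner <- setdiff(unique(t3$edge[, 1L]), root)
    cherry_tips <- t3$edge[t3$edge[, 1L] == inner, 2L]
    pair <- t3$tip.label[cherry_tips]
    third <- setdiff(triplet, pair)
    len <- t3$edge.length[t3$edge[, 2L] == inner]
    nm <- class_name(pair, third)
    if (len > 0) {
      classes[[nm]] <- c(classes[[nm]], len)
    } else {
      n_zero <- n_zero + 1L
    }
  }
  structure(list(triplet = triplet, classes = classes,
                 counts = lengths(classes), n_skipped = n_skipped,
                 n_unresolved = n_unresolved, n_zero_dropped = n_zero),
            class = "triplet_branch_data")
}

exp_loglik <- function(x, theta) sum(-log(theta) - x / theta)

#' Fit the ILS-only (single exponential) model
#'
#' Maximum likelihood for an exponential distribution: the scale estimate
#' is the sample mean. BIC uses one free parameter.
#'
#' @param lengths Positive branch lengths, n >= 2.
#' @return A list with \code{theta}, \code{loglik}, \code{bic}, \code{n}.
#' @export
fit_ils_only <- function(lengths) {
  if (length(lengths) < 2L) stop("need at least 2 branch lengths")
  if (any(lengths <= 0)) stop("branch lengths must be strictly positive")
  theta <- mean(lengths)
  ll <- exp_loglik(lengths, theta)
  list(theta = theta, loglik = ll,
       bic = -2 * ll + log(length(lengths)), n = length(lengths))
}

mixture_loglik <- function(x, pi2, theta, delta) {
  d1 <- exp(-x / theta) / theta
  d2 <- ifelse(x >= delta, exp(-(x - delta) / theta) / theta, 0)
  sum(log((1 - pi2) * d1 + pi2 * d2))
}

#' Fit the two-component exponential mixture by EM
#'
#' Model: \eqn{f(x) = \pi_1 (1/\theta) e^{-x/\theta} + \pi_2 (1/\theta)
#' e^{-(x-\delta)/\theta} \mathbf{1}[x \ge \delta]} with
#' \eqn{\pi_1 + \pi_2 = 1}. Both components share the scale \eqn{\theta};
#' the shift \eqn{\delta \ge 0} carries the introgression/speciation
#' signal. Each iteration computes responsibilities (E-step), then updates
#' \eqn{\pi_2} and \eqn{\theta} in closed form and \eqn{\delta} by a damped
#' line search over a candidate grid of the data quantiles, accepting the
#' move only when it does not decrease the observed log-likelihood (so the
#' log-likelihood is monotone non-decreasing). Iteration stops after
#' \code{numsteps} steps or when the improvement falls below
#' \code{likelihoodthresh}. The one-component fit is nested (\eqn{\delta =
#' 0}), and is returned in its place if the EM solution is ever worse.
#'
#' @param lengths Positive branch lengths, n >= 5.
#' @param numsteps Maximum EM iterations (default 50).
#' @param likelihoodthresh Stop when the log-likelihood improves by less
#'   than this (default 0.01).
#' @param gradascentscalar Damping factor in (0, 1] for the \eqn{\delta}
#'   update (default 0.5).
#' @param seed Unused by the default deterministic initialization
#'   (\eqn{\pi_2 = 0.5}, \eqn{\delta} = median, \eqn{\theta} = mean / 2);
#'   accepted for interface stability.
#' @return A list of class \code{"mixture_fit"}: \code{pi1}, \code{pi2},
#'   \code{theta}, \code{delta}, \code{loglik1}, \code{loglik2},
#'   \code{bic1}, \code{bic2}, \code{dbic} (= bic2 - bic1), \code{n},
#'   \code{iterations}, \code{converged}.
#' @export
fit_mixture_em <- function(lengths, numsteps = 50, likelihoodthresh = 0.01,
                           gradascentscalar = 0.5, seed = NULL) {
  n <- length(lengths)
  if (n < 5L) stop("need at least 5 branch lengths")
  if (any(lengths <= 0)) stop("branch lengths must be strictly positive")
  x <- as.numeric(lengths)
  one <- fit_ils_only(x)

  pi2 <- 0.5
  delta <- stats::median(x)
  theta <- mean(x) / 2
  cand <- unique(c(0, stats::quantile(x, probs = seq(0, 1, length.out = 101),
                                      names = FALSE)))
  ll <- mixture_loglik(x, pi2, theta, delta)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(numsteps)) {
    # E-step
    d1 <- exp(-x / theta) / theta
    d2 <- ifelse(x >= delta, exp(-(x - delta) / theta) / theta, 0)
    denom <- (1 - pi2) * d1 + pi2 * d2
    r2 <- ifelse(denom > 0, pi2 * d2 / denom, 0)
    # M-step: closed forms for pi2 and theta given delta
    pi2_new <- mean(r2)
    pi2_new <- min(max(pi2_new, 1e-8), 1 - 1e-8)
    theta_new <- (sum(x) - delta * sum(r2)) / n
    if (theta_new <= 0) theta_new <- theta
    # delta: damped line search over the candidate grid, accept-if-better
    ll_cand <- vapply(cand, function(d) {
      mixture_loglik(x, pi2_new, theta_new, d)
    }, numeric(1))
    delta_star <- cand[which.max(ll_cand)]
    delta_damp <- delta + gradascentscalar * (delta_star - delta)
    options <- c(delta, delta_damp, delta_star)
    ll_opts <- c(mixture_loglik(x, pi2_new, theta_new, delta),
                 mixture_loglik(x, pi2_new, theta_new, delta_damp),
                 max(ll_cand))
    best <- which.max(ll_opts)
    delta_new <- options[best]
    ll_new <- ll_opts[best]
    if (ll_new < ll) {            # full M-step rejected; keep old params
      converged <- TRUE
      break
    }
    improved <- ll_new - ll
    pi2 <- pi2_new; theta <- theta_new; delta <- delta_new; ll <- ll_new
    if (improved < likelihoodthresh) {
      converged <- TRUE
      break
    }
  }
  if (ll < one$loglik) {          # fall back to the nested null solution
    pi2 <- 1e-8; delta <- 0; theta <- one$theta
    ll <- mixture_loglik(x, pi2, theta, delta)
  }
  bic2 <- -2 * ll + 3 * log(n)
  structure(list(pi1 = 1 - pi2, pi2 = pi2, theta = theta, delta = delta,
                 loglik1 = one$loglik, loglik2 = ll,
                 bic1 = one$bic, bic2 = bic2, dbic = bic2 - one$bic,
                 n = n, iterations = it, converged = converged),
            class = "mixture_fit")
}

#' Fit mixtures for every topology class of a set of triplets
#'
#' Runs [extract_triplet_branches()] and [fit_mixture_em()] for each
#' triplet topology class with at least \code{min_n} usable branch lengths,
#' and flags each class as concordant or discordant with the species tree
#' (the class whose sister pair matches the species-tree triplet
#' restriction is concordant).
#'
#' @param gene_trees List of \code{"phylo"} gene trees.
#' @param species_tree The reference species tree (must contain all triplet
#'   taxa and the outgroup).
#' @param outgroup Outgroup label used for rooting.
#' @param triplets List of 3-taxon character vectors; default all triples
#'   of the species tree's non-outgroup tips.
#' @param min_n Minimum usable branch lengths per class (default 5).
#' @param ... Passed to [fit_mixture_em()].
#' @return A data frame with one row per (triplet, class): \code{triplet},
#'   \code{class}, \code{count}, \code{discordant}, \code{theta},
#'   \code{delta}, \code{pi1}, \code{pi2}, \code{loglik1}, \code{loglik2},
#'   \code{bic1}, \code{bic2}, \code{dbic}, \code{skipped}.
#' @export
quibl_analysis <- function(gene_trees, species_tree, outgroup,
                           triplets = NULL, min_n = 5L, ...) {
  ingroup <- setdiff(species_tree$tip.label, outgroup)
  if (is.null(triplets)) {
    triplets <- combn(sort(ingroup), 3L, simplify = FALSE)
  }
  rows <- list()
  for (tri in triplets) {
    tbd <- extract_triplet_branches(gene_trees, tri, outgroup)
    sp3 <- ape::keep.tip(species_tree, tri)
    sp_class <- if (sp3$Nnode < 2L) NA_character_ else {
      inner <- setdiff(unique(sp3$edge[, 1L]), 4L)
      pair <- sp3$tip.label[sp3$edge[sp3$edge[, 1L] == inner, 2L]]
      paste0(paste(sort(pair), collapse = ","), "|", setdiff(tri, pair))
    }
    for (cls in names(tbd$classes)) {
      lens <- tbd$classes[[cls]]
      skipped <- length(lens) < min_n
      fit <- if (skipped) NULL else fit_mixture_em(lens, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        triplet = paste(tbd$triplet, collapse = ","), class = cls,
        count = length(lens),
        discordant = if (is.na(sp_class)) NA else cls != sp_class,
        theta = if (skipped) NA_real_ else fit$theta,
        delta = if (skipped) NA_real_ else fit$delta,
        pi1 = if (skipped) NA_real_ else fit$pi1,
        pi2 = if (skipped) NA_real_ else fit$pi2,
        loglik1 = if (skipped) NA_real_ else fit$loglik1,
        loglik2 = if (skipped) NA_real_ else fit$loglik2,
        bic1 = if (skipped) NA_real_ else fit$bic1,
        bic2 = if (skipped) NA_real_ else fit$bic2,
        dbic = if (skipped) NA_real_ else fit$dbic,
        skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Call introgression from mixture fits
#'
#' Retains (triplet, class) rows whose class is discordant with the species
#' tree and whose \eqn{\Delta}BIC falls below \code{threshold} (default
#' -30, i.e. decisive support for the two-component model). Shifts on the
#' concordant class are interpreted as speciation, not introgression, and
#' are never called.
#'
#' @param fits A [quibl_analysis()] result data frame.
#' @param threshold \eqn{\Delta}BIC call threshold (default -30).
#' @return The retained rows, with \code{pi2} attached for reporting.
#' @export
call_introgression <- function(fits, threshold = -30) {
  keep <- !is.na(fits$dbic) & fits$dbic < threshold &
    !is.na(fits$discordant) & fits$discordant
  fits[keep, , drop = FALSE]
}

#' Mixing-proportion heatmap for introgression calls
#'
#' Square matrix over \code{leaf_order}; for each call on a discordant
#' class \code{"X,Y|Z"} the cells (X, Y) and (Y, X) hold the class's
#' \eqn{\pi_2} (the larger value when several calls touch the same pair),
#' mirroring the symmetric role of the two sister taxa.
#'
#' @param calls A [call_introgression()] result.
#' @param leaf_order Row/column order covering all called taxa.
#' @return A numeric matrix.
#' @export
pi2_heatmap <- function(calls, leaf_order) {
  m <- matrix(NA_real_, length(leaf_order), length(leaf_order),
              dimnames = list(leaf_order, leaf_order))
  for (i in seq_len(nrow(calls))) {
    pair <- strsplit(sub("\\|.*$", "", calls$class[i]), ",")[[1]]
    if (!all(pair %in% leaf_order)) {
      stop("leaf_order missing taxa: ",
           paste(setdiff(pair, leaf_order), collapse = ", "))
    }
    v <- calls$pi2[i]
    old <- m[pair[1L], pair[2L]]
    if (is.na(old) || v > old) {
      m[pair[1L], pair[2L]] <- v
      m[pair[2L], pair[1L]] <- v
    }
  }
  m
}
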