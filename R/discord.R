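# Gene-tree / species-tree and plastid / nuclear discordance statistics:
# topology spectra, concordance fractions, Robinson-Foulds distance
# distributions with a Mann-Whitney rank test, and per-node concordance
# mapping in the PhyParts sense.

#' Topology spectrum of a gene-tree sample
#'
#' Tallies canonical topology keys (see [topology_key()]) across gene trees,
#' optionally after restricting every tree to a common leaf set.
#'
#' @param sample A \code{"gene_tree_sample"} or list of \code{"phylo"}
#'   trees.
#' @param leaves Optional character vector: restrict each tree to these
#'   leaves before tallying.
#' @return A named integer vector of counts (names are topology keys),
#'   with attribute \code{total}.
#' @export
topology_spectrum <- function(sample, leaves = NULL) {
  trees <- if (inherits(sample, "gene_tree_sample")) sample$trees else sample
  keys <- vapply(trees, function(tr) {
    if (!is.null(leaves) && !setequal(tr$tip.label, leaves)) {
      tr <- ape::keep.tip(tr, intersect(tr$tip.label, leaves))
    }
    topology_key(tr)
  }, character(1))
  tab <- table(keys)
  out <- as.integer(tab)
  names(out) <- names(tab)
  attr(out, "total") <- length(keys)
  out
}

#' Fraction of gene trees concordant with a reference topology
#'
#' In \code{"full"} mode a gene tree counts as concordant when, restricted
#' to the reference leaf set, its topology matches the reference exactly.
#' In \code{"split"} mode it counts when it contains the focal bipartition
#' \code{focal} (a character vector giving one side of a split of the
#' reference leaf set) -- the laxer criterion appropriate when the question
#' is where a single lineage attaches rather than whether the whole
#' topology agrees.
#'
#' @param sample A \code{"gene_tree_sample"} or list of \code{"phylo"}.
#' @param reference A \code{"phylo"} reference tree (e.g. the plastid
#'   topology); its leaf set must be contained in every gene tree's.
#' @param mode \code{"full"} (exact topology) or \code{"split"} (focal
#'   bipartition containment).
#' @param focal For \code{"split"} mode: tip labels on one side of the
#'   focal split. Must be a split present in \code{reference}.
#' @return A fraction in [0, 1].
#' @export
concordance_fraction <- function(sample, reference, mode = c("full", "split"),
                                 focal = NULL) {
  mode <- match.arg(mode)
  trees <- if (inherits(sample, "gene_tree_sample")) sample$trees else sample
  ref_leaves <- reference$tip.label
  if (mode == "split") {
    if (is.null(focal)) stop("mode = 'split' requires a focal bipartition")
    ref_splits <- tree_splits(reference)
    key <- split_key(focal, ref_leaves)
    if (!(key %in% ref_splits$keys)) {
      stop("focal split not present in the reference tree")
    }
    hits <- vapply(trees, function(tr) {
      tr <- restrict_to(tr, ref_leaves)
      key %in% tree_splits(tr)$keys
    }, logical(1))
  } else {
    ref_key <- topology_key(reference)
    hits <- vapply(trees, function(tr) {
      topology_key(restrict_to(tr, ref_leaves)) == ref_key
    }, logical(1))
  }
  mean(hits)
}

restrict_to <- function(tree, leaves) {
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing)) {
    stop("gene tree missing reference taxa: ", paste(missing, collapse = ", "))
  }
  if (setequal(tree$tip.label, leaves)) tree else
    ape::keep.tip(tree, leaves)
}

# Canonical key of one side of a split, matching tree_splits().
split_key <- function(side, labels) {
  labels <- sort(labels)
  side <- sort(side)
  other <- sort(setdiff(labels, side))
  if (length(side) < 2L || length(other) < 2L) {
    stop("focal split is trivial")
  }
  keep <- if (labels[1L] %in% side) other else side
  paste(keep, collapse = "\r")
}

#' Robinson-Foulds distance distribution of gene trees to a species tree
#'
#' One RF distance per gene tree, after restricting each gene tree to the
#' species-tree leaf set. Gene trees missing species-tree taxa are skipped
#' with a warning.
#'
#' @param gene_trees List of \code{"phylo"} trees.
#' @param species_tree Reference \code{"phylo"} tree.
#' @param label Source label stored on the result (e.g. \code{"empirical"}
#'   or \code{"simulated"}).
#' @return Integer vector of RF distances with attributes \code{label} and
#'   \code{n_skipped}.
#' @export
distance_distribution <- function(gene_trees, species_tree,
                                  label = "empirical") {
  leaves <- species_tree$tip.label
  usable <- vapply(gene_trees, function(tr) all(leaves %in% tr$tip.label),
                   logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " gene tree(s) missing species-tree taxa; skipped")
  }
  d <- vapply(gene_trees[usable], function(tr) {
    rf_distance(restrict_to(tr, leaves), species_tree)
  }, numeric(1))
  structure(as.integer(d), label = label, n_skipped = sum(!usable))
}

#' Mann-Whitney U rank test
#'
#' Wrapper around [stats::wilcox.test()] exposing the U statistic
#' (number of pairs \eqn{x_i > y_j} plus half of the ties). The p-value is
#' exact (full enumeration of rank assignments) when both samples have at
#' most 8 observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}.
#' @return A list with \code{U}, \code{p}, and \code{method}.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && max(length(x), length(y)) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Per-node gene-tree concordance mapping
#'
#' For every non-trivial split of the species tree, classifies each gene
#' tree as concordant (the gene tree, restricted to the taxa it shares with
#' the species tree, contains the split), conflicting (it contains a split
#' incompatible with it -- two splits conflict iff all four pairwise
#' intersection cells are non-empty), or uninformative (the restriction
#' leaves the split trivial, or the gene tree resolves neither way). Gene
#' trees may miss taxa.
#'
#' @param species_tree A \code{"phylo"} species tree.
#' @param gene_trees List of \code{"phylo"} gene trees with leaf sets
#'   contained in (or overlapping) the species tree's.
#' @return A data frame with one row per species-tree split: columns
#'   \code{split} (semicolon-joined smaller side), \code{concordant},
#'   \code{conflicting}, \code{uninformative} (counts summing to the number
#'   of gene trees), and \code{prop_concordant} = concordant /
#'   (concordant + conflicting).
#' @export
node_concordance <- function(species_tree, gene_trees) {
  sp <- tree_splits(species_tree)
  n_splits <- length(sp$sets)
  conc <- integer(n_splits); conf <- integer(n_splits)
  unin <- integer(n_splits)
  all_leaves <- species_tree$tip.label
  for (tr in gene_trees) {
    shared <- intersect(tr$tip.label, all_leaves)
    gt <- if (setequal(tr$tip.label, shared)) tr else
      ape::keep.tip(tr, shared)
    g_sets <- tree_splits(gt)$sets
    g_sides <- lapply(g_sets, function(s) s)          # one side per split
    for (i in seq_len(n_splits)) {
      a <- intersect(sp$sets[[i]], shared)
      b <- setdiff(shared, a)
      if (length(a) < 2L || length(b) < 2L) {
        unin[i] <- unin[i] + 1L
        next
      }
      status <- "uninformative"
      for (g in g_sides) {
        c1 <- g; c2 <- setdiff(shared, g)
        if ((setequal(a, c1) && setequal(b, c2)) ||
            (setequal(a, c2) && setequal(b, c1))) {
          status <- "concordant"
          break
        }
        if (length(intersect(a, c1)) && length(intersect(a, c2)) &&
            length(intersect(b, c1)) && length(intersect(b, c2))) {
          # splits within one tree are pairwise compatible, so a conflict
          # rules out an exact match elsewhere in the same gene tree
          status <- "conflicting"
          break
        }
      }
      if (status == "concordant") conc[i] <- conc[i] + 1L
      else if (status == "conflicting") conf[i] <- conf[i] + 1L
      else unin[i] <- unin[i] + 1L
    }
  }
  split_lab <- vapply(sp$sets, function(s) paste(s, collapse = ";"),
                      character(1))
  data.frame(split = split_lab, concordant = conc, conflicting = conf,
             uninformative = unin,
             prop_concordant = ifelse(conc + conf > 0,
                                      conc / (conc + conf), NA_real_),
             stringsAsFactors = FALSE)
}
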