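#' @importFrom stats sd setNames rexp runif rmultinom pnorm rbinom
#' @importFrom utils combn
NULL

#' Parse a newick string into a rooted tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned object is
#' an ape \code{"phylo"} tree. Branch lengths are optional; when absent they
#' are recorded as absent (no \code{edge.length} component, or \code{NA} for
#' individual missing lengths), never silently set to zero.
#'
#' @param text A single newick string. A trailing semicolon is accepted but
#'   not required.
#' @return An object of class \code{"phylo"}.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty newick string")
  if (!endsWith(txt, ";")) txt <- paste0(txt, ";")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("unbalanced parentheses in newick: %d '(' vs %d ')'",
                 n_open, n_close))
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("newick parse error: unparseable input")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(tr$tip.label))) stop("empty leaf label")
  tr
}

#' Serialize a tree to newick
#'
#' @param tree A \code{"phylo"} object.
#' @param digits Significant digits for branch lengths (default 10, enough
#'   for a lossless parse/write/parse round trip at double precision scale).
#' @return A newick string terminated by a semicolon.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Read / write one-newick-per-line tree files
#'
#' @param path File path.
#' @return \code{read_tree_file()} returns a list of \code{"phylo"} objects.
#' @export
read_tree_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_newick)
}

#' @rdname read_tree_file
#' @param trees A list of \code{"phylo"} objects.
#' @export
write_tree_file <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}

# Descendant tip-label set for every node, postorder accumulation.
node_tip_sets <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  n <- length(tr$tip.label)
  sets <- vector("list", n + tr$Nnode)
  sets[seq_len(n)] <- as.list(tr$tip.label)
  e <- tr$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]
    sets[[p]] <- c(sets[[p]], sets[[e[i, 2L]]])
  }
  sets
}

# Non-trivial splits of a tree, as canonical strings and as label sets.
# Unrooted semantics: each internal edge induces a bipartition; the stored
# side is the one NOT containing the lexicographically smallest leaf, so a
# split and its complement map to the same key. Trivial splits (one side
# with < 2 leaves) are dropped; multifurcating nodes simply contribute
# fewer splits.
tree_splits <- function(tree, rooted = FALSE) {
  n <- length(tree$tip.label)
  labels <- sort(tree$tip.label)
  sets <- node_tip_sets(tree)
  root <- n + 1L
  nodes <- setdiff((n + 1L):(n + tree$Nnode), root)
  out_sets <- list()
  keys <- character(0)
  ref <- labels[1L]
  for (nd in nodes) {
    side <- sets[[nd]]
    k <- length(side)
    if (rooted) {
      if (k < 2L || k >= n) next
      side_c <- sort(side)
    } else {
      if (k < 2L || k > n - 2L) next
      side_c <- if (ref %in% side) sort(setdiff(labels, side)) else sort(side)
    }
    key <- paste(side_c, collapse = "\r")
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      out_sets <- c(out_sets, list(side_c))
    }
  }
  list(keys = keys, sets = out_sets, labels = labels)
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference between the two trees' sets of
#' non-trivial bipartitions. By default bipartitions are unrooted (root
#' placement never changes the distance); set \code{rooted = TRUE} to compare
#' rooted clades instead.
#'
#' @param t1,t2 \code{"phylo"} trees over the same leaf set (at least 4
#'   leaves).
#' @param rooted Compare rooted clades rather than unrooted bipartitions.
#' @return Non-negative integer. Even for pairs of fully resolved binary
#'   trees under the unrooted convention.
#' @export
rf_distance <- function(t1, t2, rooted = FALSE) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2)
    only2 <- setdiff(l2, l1)
    stop("leaf sets differ; only in first: {",
         paste(only1, collapse = ", "), "}; only in second: {",
         paste(only2, collapse = ", "), "}")
  }
  if (length(l1) < 4L) stop("need at least 4 leaves")
  s1 <- tree_splits(t1, rooted = rooted)$keys
  s2 <- tree_splits(t2, rooted = rooted)$keys
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Canonical topology key of a rooted tree
#'
#' A string invariant under child order and branch lengths: children of every
#' node are serialized in lexicographic order of their own keys. Two trees
#' get equal keys if and only if they have the same rooted topology, so for
#' trees rooted consistently (e.g. with a fixed outgroup) equal keys mean
#' equal unrooted topology as well.
#'
#' @param tree A \code{"phylo"} object with >= 2 leaves.
#' @return A single string.
#' @examples
#' topology_key(parse_newick("((B:1,A:2),C);")) ==
#'   topology_key(parse_newick("((A,B),C);"))
#' @export
topology_key <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 leaves")
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  keys <- character(n + tree$Nnode)
  keys[seq_len(n)] <- tree$tip.label
  rec <- function(nd) {
    ch <- kids[[as.character(nd)]]
    ck <- character(length(ch))
    for (i in seq_along(ch)) {
      c_i <- ch[i]
      if (c_i > n && !nzchar(keys[c_i])) keys[c_i] <<- rec(c_i)
      ck[i] <- keys[c_i]
    }
    paste0("(", paste(sort(ck), collapse = ","), ")")
  }
  rec(n + 1L)
}

# ---------------------------------------------------------------------------
# Alignments: character matrices, taxa in rows, sites in columns.

#' Construct an alignment
#'
#' An alignment is a character matrix over \{A, C, G, T, -, N\} with unique
#' taxon labels as row names; all rows have equal length by construction.
#'
#' @param x A character matrix with row names, or a named list/vector of
#'   equal-length sequence strings.
#' @return A character matrix of single characters (upper case) with class
#'   \code{c("alignment", "matrix")} semantics (plain matrix; validated).
#' @export
alignment <- function(x) {
  if (is.list(x) || (is.character(x) && !is.matrix(x))) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("sequences must be named")
    }
    seqs <- vapply(x, paste0, character(1), collapse = "")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("sequences have unequal lengths: ",
           paste(unique(lens), collapse = ", "))
    }
    x <- do.call(rbind, strsplit(seqs, ""))
    rownames(x) <- names(seqs)
  }
  stopifnot(is.matrix(x), is.character(x))
  if (is.null(rownames(x))) stop("alignment must have taxon row names")
  if (anyDuplicated(rownames(x))) stop("duplicate taxon labels")
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) stop("invalid characters: ", paste(bad, collapse = ", "))
  x
}

#' Read and write FASTA alignments
#'
#' @param path File path.
#' @return \code{read_fasta()} returns an alignment matrix (taxa x sites).
#' @export
read_fasta <- function(path) {
  dn <- ape::read.FASTA(path)
  m <- as.character(as.matrix(dn))
  m[] <- toupper(m)
  alignment(m)
}

#' @rdname read_fasta
#' @param a An alignment matrix.
#' @export
write_fasta <- function(a, path) {
  seqs <- apply(a, 1L, paste0, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path, sep = "\n")
  invisible(path)
}

#' Read and write relaxed PHYLIP alignments
#'
#' Relaxed PHYLIP: a header line with taxon and site counts, then one
#' \code{name<whitespace>sequence} record per taxon.
#'
#' @param path File path.
#' @return \code{read_phylip()} returns an alignment matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
  if (length(hdr) != 2L) stop("malformed PHYLIP header")
  recs <- strsplit(trimws(lines[-1L]), "[[:space:]]+")
  if (length(recs) != hdr[1L]) {
    stop("PHYLIP header announces ", hdr[1L], " taxa, found ", length(recs))
  }
  seqs <- vapply(recs, function(r) paste0(r[-1L], collapse = ""), character(1))
  names(seqs) <- vapply(recs, `[`, character(1), 1L)
  if (any(nchar(seqs) != hdr[2L])) {
    stop("sequence length differs from PHYLIP header")
  }
  alignment(seqs)
}

#' @rdname read_phylip
#' @param a An alignment matrix.
#' @export
write_phylip <- function(a, path) {
  seqs <- apply(a, 1L, paste0, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(a), ncol(a)), con)
  writeLines(paste(format(names(seqs)), seqs), con)
  invisible(path)
}

#' Strip gapped alignment columns
#'
#' Removes columns whose proportion of missing characters (\code{-} or
#' \code{N}, case-insensitive) strictly exceeds \code{threshold}; columns at
#' exactly the threshold are retained, so a 20\% stripping threshold keeps
#' columns with exactly 20\% gaps. Row order is preserved.
#'
#' @param a An alignment matrix.
#' @param threshold Maximum tolerated gap fraction per column, in [0, 1].
#'   Default 0.2.
#' @return The filtered alignment (possibly with zero columns).
#' @export
strip_gapped_columns <- function(a, threshold = 0.2) {
  stopifnot(is.matrix(a), threshold >= 0, threshold <= 1)
  if (nrow(a) == 0L || ncol(a) == 0L) stop("empty alignment")
  gap <- a == "-" | a == "N" | a == "n"
  keep <- colMeans(gap) <= threshold
  a[, keep, drop = FALSE]
}
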