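# Independent oracles and fixture builders used across the suite.

# Random rooted binary tree with exponential branch lengths.
random_tree <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::rtree(n, tip.label = sample(labels))
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 2)
  tr
}

# Brute-force RF oracle: enumerate every non-trivial unrooted bipartition
# of both trees via ape::prop.part (an implementation independent of the
# package's split machinery) and count the symmetric difference.
rf_oracle <- function(t1, t2) {
  splits_of <- function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    n <- length(labs)
    keys <- character(0)
    for (s in pp) {
      side <- sort(labs[s])
      if (length(side) < 2L || length(side) > n - 2L) next
      if (labs[order(labs)][1L] %in% side) {
        side <- sort(setdiff(labs, side))
      }
      keys <- c(keys, paste(side, collapse = "/"))
    }
    unique(keys)
  }
  s1 <- splits_of(t1)
  s2 <- splits_of(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# Exact Mann-Whitney p by full enumeration of which of the pooled ranks
# belong to x (tie-free samples only).
mwu_enum_oracle <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y)
  u_of <- function(xv, yv) sum(outer(xv, yv, ">"))
  u_obs <- u_of(x, y)
  pooled <- sort(c(x, y))
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2L, function(i) u_of(pooled[i], pooled[-i]))
  total <- ncol(idx)
  switch(alternative,
    two.sided = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))),
    greater = mean(us >= u_obs),
    less = mean(us <= u_obs))
}

# Per-site brute-force polarized pattern classifier (single site).
classify_site_oracle <- function(p1, h, p2, o) {
  states <- c(p1, h, p2, o)
  if (any(states %in% c("-", "N"))) return("skipped")
  derived <- states[1:3] != o
  if (sum(derived) != 2L) return("other")
  pair <- which(derived)
  if (states[pair[1]] != states[pair[2]]) return("other")
  c("12" = "BBAA", "23" = "ABBA", "13" = "BABA")[paste0(pair[1], pair[2])]
}

# Grid-search ML oracle for the shared-scale shifted-exponential mixture,
# over a 50 x 50 x 50 lattice of (pi2, delta, theta).
mixture_grid_oracle <- function(x, pi2_grid = seq(0.01, 0.99, length.out = 50),
                                delta_grid = seq(0, stats::quantile(x, 0.9),
                                                 length.out = 50),
                                theta_grid = seq(mean(x) / 4, 2 * mean(x),
                                                 length.out = 50)) {
  best <- list(ll = -Inf)
  for (theta in theta_grid) {
    d1 <- exp(-x / theta) / theta
    for (delta in delta_grid) {
      d2 <- ifelse(x >= delta, exp(-(x - delta) / theta) / theta, 0)
      # all pi2 values at once: n x 50 mixture density matrix
      dens <- outer(d1, 1 - pi2_grid) + outer(d2, pi2_grid)
      lls <- colSums(log(dens))
      j <- which.max(lls)
      if (lls[j] > best$ll) {
        best <- list(ll = lls[j], pi2 = pi2_grid[j], delta = delta,
                     theta = theta)
      }
    }
  }
  best
}

# Newick text of a tree with uniformly shuffled child order at every node.
shuffle_newick <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(nd) {
    if (nd <= n) return(tree$tip.label[nd])
    ch <- sample(kids[[as.character(nd)]])
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")")
  }
  paste0(rec(n + 1L), ";")
}
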