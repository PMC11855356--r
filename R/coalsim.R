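# Multispecies-coalescent gene-tree simulation on species trees and on
# networks with inheritance probabilities, plus Jukes-Cantor sequence
# evolution along the simulated gene trees.

with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Node times measured from the tips (time 0) toward the root, derived from
# branch lengths in coalescent units (time scaled so the pairwise
# coalescence rate is 1, i.e. 2N generations per unit).
node_times <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- numeric(nn)            # distance from root
  tr <- stats::reorder(tree, "postorder")
  e <- tr$edge
  len <- tr$edge.length
  if (is.null(len)) stop("species tree must have branch lengths")
  if (any(is.na(len)) || any(len < 0)) {
    stop("species tree branch lengths must be non-negative and present")
  }
  for (i in rev(seq_len(nrow(e)))) {
    depth[e[i, 2L]] <- depth[e[i, 1L]] + len[i]
  }
  max(depth[seq_len(n)]) - depth
}

#' Build a species network
#'
#' A species network is a species tree in coalescent units plus zero or more
#' hybrid (introgression-pulse) events. Each event routes, at a fixed time,
#' every gene lineage present on the recipient edge independently to the
#' donor edge with probability \code{gamma} (the inheritance probability of
#' the donor parent); with probability \code{1 - gamma} the lineage stays,
#' so the two parental probabilities sum to 1 by construction.
#'
#' Edges are identified by the set of tip labels descending from the edge's
#' child node, given as a comma-separated string (e.g. \code{"H"} for the
#' edge above tip H, \code{"A,B"} for the edge above the MRCA of A and B).
#'
#' @param tree A \code{"phylo"} species tree (or newick string) with branch
#'   lengths in coalescent units.
#' @param events A data frame with columns \code{recipient}, \code{donor},
#'   \code{time}, \code{gamma}, or NULL for a plain species tree.
#' @return An object of class \code{"species_network"}.
#' @export
species_network <- function(tree, events = NULL) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  times <- node_times(tree)
  if (!is.null(events)) {
    stopifnot(is.data.frame(events),
              all(c("recipient", "donor", "time", "gamma") %in% names(events)))
    if (any(events$gamma < 0 | events$gamma > 1)) {
      stop("inheritance probability gamma must lie in [0, 1]")
    }
    for (i in seq_len(nrow(events))) {
      for (side in c("recipient", "donor")) {
        nd <- resolve_edge(tree, events[[side]][i])
        top <- if (nd == length(tree$tip.label) + 1L) Inf else
          times[tree$edge[tree$edge[, 2L] == nd, 1L]]
        if (events$time[i] < times[nd] - 1e-9 || events$time[i] > top + 1e-9) {
          stop(sprintf("event time %g outside %s edge span [%g, %g]",
                       events$time[i], side, times[nd], top))
        }
      }
    }
  }
  structure(list(tree = tree, events = events, node_times = times),
            class = "species_network")
}

# Map a comma-separated tip-label set to the node whose descendant tips are
# exactly that set.
resolve_edge <- function(tree, clade) {
  want <- sort(trimws(strsplit(clade, ",")[[1]]))
  sets <- node_tip_sets(tree)
  for (nd in seq_along(sets)) {
    if (identical(sort(sets[[nd]]), want)) return(nd)
  }
  stop("no edge with descendant tip set {", paste(want, collapse = ", "), "}")
}

# Flattened event schedule shared by all replicates of one simulation call.
build_schedule <- function(net, samples_per_species) {
  tree <- net$tree
  times <- net$node_times
  n <- length(tree$tip.label)
  root <- n + 1L
  parent_of <- integer(n + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])

  ev_time <- numeric(0); ev_type <- integer(0); ev_a <- integer(0)
  ev_b <- integer(0); ev_g <- numeric(0)
  # tip activations (type 0)
  for (tip in seq_len(n)) {
    ev_time <- c(ev_time, times[tip]); ev_type <- c(ev_type, 0L)
    ev_a <- c(ev_a, tip); ev_b <- c(ev_b, 0L); ev_g <- c(ev_g, 0)
  }
  # hybrid routing (type 1)
  if (!is.null(net$events)) {
    for (i in seq_len(nrow(net$events))) {
      ev_time <- c(ev_time, net$events$time[i]); ev_type <- c(ev_type, 1L)
      ev_a <- c(ev_a, resolve_edge(tree, net$events$recipient[i]))
      ev_b <- c(ev_b, resolve_edge(tree, net$events$donor[i]))
      ev_g <- c(ev_g, net$events$gamma[i])
    }
  }
  # speciation nodes (type 2), root included
  for (nd in (n + 1L):(n + tree$Nnode)) {
    ev_time <- c(ev_time, times[nd]); ev_type <- c(ev_type, 2L)
    ev_a <- c(ev_a, nd); ev_b <- c(ev_b, 0L); ev_g <- c(ev_g, 0)
  }
  ord <- order(ev_time, ev_type)
  samples <- rep(samples_per_species, length.out = n)
  tip_labels <- character(0); tip_edge <- integer(0)
  for (tip in seq_len(n)) {
    k <- samples[tip]
    lab <- if (k == 1L) tree$tip.label[tip] else
      paste0(tree$tip.label[tip], "_", seq_len(k))
    tip_labels <- c(tip_labels, lab)
    tip_edge <- c(tip_edge, rep(tip, k))
  }
  list(time = ev_time[ord], type = ev_type[ord], a = ev_a[ord],
       b = ev_b[ord], g = ev_g[ord], kids = kids, root = root,
       n_species = n, tip_labels = tip_labels, tip_edge = tip_edge,
       tip_time = times[tip_edge])
}

# One MSC replicate: returns merge records (left, right, time).
sim_one <- function(sch) {
  L <- length(sch$tip_labels)
  lin <- vector("list", sch$n_species + length(sch$kids) + 1L)
  lin_time <- numeric(2L * L - 1L)
  lin_time[seq_len(L)] <- sch$tip_time
  m_left <- integer(L - 1L); m_right <- integer(L - 1L)
  m_time <- numeric(L - 1L)
  m <- 0L
  coalesce_in <- function(edge, t0, t1) {
    v <- lin[[edge]]
    k <- length(v)
    t <- t0
    while (k >= 2L) {
      t <- t + rexp(1L, k * (k - 1L) / 2)
      if (t > t1) break
      pair <- sample.int(k, 2L)
      m <<- m + 1L
      new_id <- L + m
      m_left[m] <<- v[pair[1L]]; m_right[m] <<- v[pair[2L]]
      m_time[m] <<- t
      lin_time[new_id] <<- t
      v <- c(v[-pair], new_id)
      k <- k - 1L
    }
    lin[[edge]] <<- v
  }
  t_prev <- 0
  for (i in seq_along(sch$time)) {
    t_ev <- sch$time[i]
    if (t_ev > t_prev) {
      for (e in seq_along(lin)) {
        if (length(lin[[e]]) >= 2L) coalesce_in(e, t_prev, t_ev)
      }
      t_prev <- t_ev
    }
    type <- sch$type[i]
    if (type == 0L) {                       # tip activation
      tip <- sch$a[i]
      lin[[tip]] <- c(lin[[tip]], which(sch$tip_edge == tip))
    } else if (type == 1L) {                # hybrid routing pulse
      rec <- sch$a[i]; don <- sch$b[i]; g <- sch$g[i]
      v <- lin[[rec]]
      if (length(v)) {
        go <- runif(length(v)) < g
        if (any(go)) {
          lin[[don]] <- c(lin[[don]], v[go])
          lin[[rec]] <- v[!go]
        }
      }
    } else {                                # speciation: merge child edges
      nd <- sch$a[i]
      for (ch in sch$kids[[as.character(nd)]]) {
        lin[[nd]] <- c(lin[[nd]], lin[[ch]])
        lin[[ch]] <- integer(0)
      }
    }
  }
  coalesce_in(sch$root, t_prev, Inf)        # ancestral population above root
  list(left = m_left, right = m_right, time = m_time,
       tip_time = lin_time[seq_len(L)])
}

# Convert merge records to an ape "phylo" gene tree with coalescent-unit
# branch lengths. Tips 1..L; merge j maps to phylo node L + (L - j) so the
# final (deepest) merge is the root L + 1, per ape convention.
merges_to_phylo <- function(rec, tip_labels) {
  L <- length(tip_labels)
  nmerge <- L - 1L
  node_of <- function(id) ifelse(id <= L, id, L + (L - (id - L)))
  time_of <- c(rec$tip_time, rec$time)
  edge <- matrix(0L, 2L * nmerge, 2L)
  elen <- numeric(2L * nmerge)
  r <- 0L
  for (j in seq_len(nmerge)) {
    p <- L + (L - j)
    for (child in c(rec$left[j], rec$right[j])) {
      r <- r + 1L
      edge[r, 1L] <- p
      edge[r, 2L] <- node_of(child)
      elen[r] <- rec$time[j] - time_of[child]
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = tip_labels, Nnode = nmerge),
                  class = "phylo", order = NULL)
  tr
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Within every species-tree interval containing k gene lineages the waiting
#' time to the next coalescence is exponential with rate k(k-1)/2 (time in
#' coalescent units); lineages that have not coalesced by the top of an
#' interval are handed to the parent edge, and coalescence continues in the
#' ancestral population above the root until a single lineage remains. On a
#' network, each lineage present on a recipient edge at a hybrid event time
#' independently routes to the donor edge with probability gamma.
#'
#' @param model A \code{"phylo"} species tree (coalescent-unit branch
#'   lengths), a newick string, or a [species_network()].
#' @param n Number of independent gene trees (>= 1).
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards. With the same seed the output is bit-identical.
#' @param samples_per_species Lineages sampled per species (recycled across
#'   species; default 1). With k > 1, tips are labelled
#'   \code{<species>_1 ... <species>_k}.
#' @return An object of class \code{"gene_tree_sample"}: a list with
#'   \code{trees} (list of \code{"phylo"} gene trees with coalescent-unit
#'   node times), \code{seed}, and a \code{model} description string.
#' @examples
#' sp <- parse_newick("((A:1,B:1):1,C:2);")
#' gs <- simulate_gene_trees(sp, n = 100, seed = 1)
#' length(gs$trees)
#' @export
simulate_gene_trees <- function(model, n, seed = NULL,
                                samples_per_species = 1L) {
  stopifnot(n >= 1)
  if (!inherits(model, "species_network")) model <- species_network(model)
  sch <- build_schedule(model, as.integer(samples_per_species))
  desc <- paste0(
    "MSC", if (!is.null(model$events)) " on network with pulse introgression",
    "; time from tips (0) toward root in coalescent units (2N generations);",
    " species tree: ", write_newick(model$tree))
  trees <- with_opt_seed(seed, {
    lapply(seq_len(n), function(i) {
      merges_to_phylo(sim_one(sch), sch$tip_labels)
    })
  })
  structure(list(trees = trees, seed = seed, model = desc, n = as.integer(n)),
            class = "gene_tree_sample")
}

#' @export
print.gene_tree_sample <- function(x, ...) {
  cat("gene_tree_sample:", x$n, "gene trees,",
      length(x$trees[[1]]$tip.label), "tips each\n")
  cat("model:", x$model, "\n")
  if (!is.null(x$seed)) cat("seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate a Jukes-Cantor alignment along a gene tree
#'
#' The root sequence is uniform over \{A, C, G, T\}; along an edge of length
#' t coalescent units each site changes to one of the three other states
#' with total probability \eqn{(3/4)(1 - e^{-4 \mu t / 3})}, where \eqn{\mu}
#' is the substitution rate per site per coalescent unit. Sequence evolution
#' is delegated to [phangorn::simSeq()] under the JC69 model.
#'
#' @param g A \code{"phylo"} gene tree with coalescent-unit branch lengths.
#' @param n_sites Number of sites (> 0).
#' @param mut_rate Substitutions per site per coalescent unit (> 0).
#' @param seed Optional integer seed.
#' @return An alignment matrix (taxa x sites).
#' @export
simulate_alignment <- function(g, n_sites, mut_rate, seed = NULL) {
  stopifnot(inherits(g, "phylo"), n_sites > 0, mut_rate > 0)
  with_opt_seed(seed, {
    pd <- phangorn::simSeq(g, l = as.integer(n_sites), rate = mut_rate)
    m <- toupper(as.character(pd))
    alignment(m)
  })
}

#' The symmetric hybrid-quartet introgression scenario
#'
#' Builds the rooted quartet \code{(((P1,H),P2),O)} with P1/P2 divergence at
#' depth 2.0 coalescent units and the outgroup O at depth 3.0; the hybrid
#' lineage H attaches at time 1.0 to the P1 edge with probability
#' \code{1 - gamma} and to the P2 edge with probability \code{gamma}. The
#' depths are symmetric on purpose: both parental quartet topologies share
#' the same internal branch length (1.0), which makes the moment estimator
#' of gamma from polarized site patterns exact in expectation.
#'
#' @param gamma Inheritance probability of the donor parent P2, in [0, 1].
#' @param n_loci Number of independent loci (gene trees / alignments).
#' @param sites_per_locus Sites per locus alignment.
#' @param mut_rate Substitutions per site per coalescent unit (default
#'   0.02).
#' @param seed Optional integer seed for the whole scenario.
#' @return A list with \code{network} (the \code{"species_network"}),
#'   \code{sample} (the \code{"gene_tree_sample"}), \code{alignments}
#'   (list of per-locus alignment matrices), and \code{params}.
#' @export
xanthoceras_scenario <- function(gamma, n_loci = 2000, sites_per_locus = 500,
                                 mut_rate = 0.02, seed = NULL) {
  stopifnot(gamma >= 0, gamma <= 1)
  net <- species_network(
    "(((P1:1,H:1):1,P2:2):1,O:3);",
    events = data.frame(recipient = "H", donor = "P2", time = 1.0,
                        gamma = gamma))
  with_opt_seed(seed, {
    smp <- simulate_gene_trees(net, n = n_loci)
    alns <- lapply(smp$trees, simulate_alignment,
                   n_sites = sites_per_locus, mut_rate = mut_rate)
    list(network = net, sample = smp, alignments = alns,
         params = list(gamma = gamma, n_loci = n_loci,
                       sites_per_locus = sites_per_locus,
                       mut_rate = mut_rate, seed = seed,
                       depths = c(hybrid = 1.0, parents = 2.0,
                                  outgroup = 3.0)))
  })
}
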