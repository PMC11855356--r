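# End-to-end orchestration of the synthetic study: simulate a hybrid
# quartet scenario, quantify discordance against the ILS-only expectation,
# scan site patterns for introgression, and run the triplet mixture
# analysis -- each stage a function over a flat, fully seeded config.

#' Default run configuration
#'
#' A flat key-value list; every default matches the standard setting of the
#' corresponding analysis (20\% stripping threshold; significance filter
#' 0 < gamma < 1, p < 0.05, Z > 3; \eqn{\Delta}BIC threshold -30; EM
#' defaults numsteps 50, likelihoodthresh 0.01, gradascentscalar 0.5).
#'
#' @param ... Overrides as name = value pairs.
#' @return A named list of class \code{"run_config"}.
#' @export
default_config <- function(...) {
  cfg <- list(
    gamma = 0.16, n_loci = 2000L, sites_per_locus = 500L, mut_rate = 0.02,
    seed = 1L, outgroup = "O",
    stripping_threshold = 0.2, bootstrap_B = 200L,
    sig_p = 0.05, sig_z = 3,
    dbic_threshold = -30,
    em_numsteps = 50L, em_likelihoodthresh = 0.01,
    em_gradascentscalar = 0.5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  chk <- function(ok, field, domain) {
    if (!ok) stop("config field '", field, "' outside its domain: ", domain)
  }
  chk(cfg$gamma >= 0 && cfg$gamma <= 1, "gamma", "[0, 1]")
  chk(cfg$n_loci >= 1, "n_loci", ">= 1")
  chk(cfg$sites_per_locus >= 1, "sites_per_locus", ">= 1")
  chk(cfg$mut_rate > 0, "mut_rate", "> 0")
  chk(cfg$stripping_threshold >= 0 && cfg$stripping_threshold <= 1,
      "stripping_threshold", "[0, 1]")
  chk(cfg$bootstrap_B >= 50, "bootstrap_B", ">= 50")
  chk(cfg$sig_p > 0 && cfg$sig_p < 1, "sig_p", "(0, 1)")
  chk(cfg$em_numsteps >= 1, "em_numsteps", ">= 1")
  chk(cfg$em_gradascentscalar > 0 && cfg$em_gradascentscalar <= 1,
      "em_gradascentscalar", "(0, 1]")
  chk(!is.null(cfg$seed), "seed", "explicit integer seed required")
  cfg
}

#' Read / write a run configuration file (flat JSON)
#'
#' @param path File path.
#' @return \code{read_config()} returns a \code{"run_config"} list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, cfg)
}

#' @rdname read_config
#' @param cfg A \code{"run_config"} list.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# One top-level seed fans out deterministically to per-stage seeds so each
# stage can be rerun on its own.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 1000003 * stage_index) %%
               (.Machine$integer.max - 1)) + 1L
}

log_line <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste(..., collapse = " ")))
}

#' Simulate the hybrid-quartet scenario to files
#'
#' Writes \code{gene_trees.nwk} (one newick per line), one FASTA per locus
#' under \code{loci/}, and a \code{scenario.json} sidecar (model
#' description, gamma, seed, depths). Byte-identical output for identical
#' config and seed.
#'
#' @param cfg A [default_config()] list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the scenario object.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- xanthoceras_scenario(cfg$gamma, n_loci = cfg$n_loci,
                             sites_per_locus = cfg$sites_per_locus,
                             mut_rate = cfg$mut_rate,
                             seed = derive_seed(cfg$seed, 1L))
  trees_path <- file.path(out_dir, "gene_trees.nwk")
  write_tree_file(sc$sample$trees, trees_path)
  loci_dir <- file.path(out_dir, "loci")
  dir.create(loci_dir, showWarnings = FALSE)
  loci_paths <- vapply(seq_along(sc$alignments), function(i) {
    p <- file.path(loci_dir, sprintf("locus_%04d.fasta", i))
    write_fasta(sc$alignments[[i]], p)
    p
  }, character(1))
  meta_path <- file.path(out_dir, "scenario.json")
  jsonlite::write_json(
    list(model = sc$sample$model, gamma = cfg$gamma,
         seed = derive_seed(cfg$seed, 1L),
         depths = as.list(sc$params$depths),
         n_loci = cfg$n_loci, sites_per_locus = cfg$sites_per_locus,
         mut_rate = cfg$mut_rate),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("simulate", "gamma:", cfg$gamma, "loci:", cfg$n_loci,
           "seed:", derive_seed(cfg$seed, 1L))
  invisible(list(gene_trees = trees_path, loci = loci_paths,
                 scenario_json = meta_path, scenario = sc))
}

#' Discordance stage: distance distributions, rank test, concordance
#'
#' Computes RF distance distributions of the focal ("empirical" role) and
#' ILS-only simulated gene trees to the species tree, a Mann-Whitney U test
#' between the two distributions (p >= 0.05: fail to reject the ILS-only
#' null), and the fraction of focal gene trees concordant with an
#' alternative reference topology (both full-topology and, when
#' \code{focal_split} is given, focal-split mode). Writes a TSV of
#' distances and a JSON report section.
#'
#' @param cfg A [default_config()] list.
#' @param gene_trees Focal gene trees: a path (one newick per line) or a
#'   list of \code{"phylo"}.
#' @param species_tree The species tree (\code{"phylo"} or newick string)
#'   in coalescent units; also the ILS-only simulation model.
#' @param alternative Reference topology whose concordance is reported
#'   (e.g. the plastid topology); \code{"phylo"} or newick string.
#' @param out_dir Output directory.
#' @param n_sim Number of ILS-only gene trees to simulate (default: as many
#'   as the focal set).
#' @param focal_split Optional character vector: one side of the focal
#'   bipartition for split-mode concordance.
#' @return A list (report section): \code{U}, \code{p},
#'   \code{ils_sufficient} (p >= 0.05), \code{concordance_full},
#'   \code{concordance_split}, file paths.
#' @export
cmd_discord <- function(cfg, gene_trees, species_tree, alternative,
                        out_dir, n_sim = NULL, focal_split = NULL) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(gene_trees) && length(gene_trees) == 1L) {
    if (!file.exists(gene_trees)) stop("missing input file: ", gene_trees)
    gene_trees <- read_tree_file(gene_trees)
  }
  if (is.character(species_tree)) species_tree <- parse_newick(species_tree)
  if (is.character(alternative)) alternative <- parse_newick(alternative)
  if (is.null(n_sim)) n_sim <- length(gene_trees)
  sim <- simulate_gene_trees(species_tree, n = n_sim,
                             seed = derive_seed(cfg$seed, 2L))
  d_emp <- distance_distribution(gene_trees, species_tree, "empirical")
  d_sim <- distance_distribution(sim$trees, species_tree, "simulated")
  mwu <- mann_whitney_u(as.numeric(d_emp), as.numeric(d_sim))
  conc_full <- concordance_fraction(gene_trees, alternative, mode = "full")
  conc_split <- if (is.null(focal_split)) NA_real_ else
    concordance_fraction(gene_trees, alternative, mode = "split",
                         focal = focal_split)
  dist_path <- file.path(out_dir, "rf_distances.tsv")
  utils::write.table(
    data.frame(source = c(rep("empirical", length(d_emp)),
                          rep("simulated", length(d_sim))),
               rf = c(as.integer(d_emp), as.integer(d_sim))),
    dist_path, sep = "\t", quote = FALSE, row.names = FALSE)
  section <- list(U = mwu$U, p = mwu$p, method = mwu$method,
                  ils_sufficient = mwu$p >= 0.05,
                  concordance_full = conc_full,
                  concordance_split = conc_split,
                  distances_tsv = dist_path)
  jsonlite::write_json(section, file.path(out_dir, "discord.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("discord", "U:", signif(mwu$U, 6), "p:", signif(mwu$p, 4),
           "concordance(full):", signif(conc_full, 4))
  section
}

#' Invariants stage: concatenate, strip, scan, filter, export
#'
#' Concatenates the per-locus alignments into a super-alignment, strips
#' gapped columns at the configured threshold, scans all ingroup triples
#' for hybridization signals, applies the significance filter, and writes
#' the result table plus a gamma heatmap matrix per flagged hybrid.
#'
#' @param cfg A [default_config()] list (uses \code{outgroup},
#'   \code{stripping_threshold}, \code{bootstrap_B}, \code{seed}).
#' @param alignments A list of alignment matrices, or a directory of FASTA
#'   loci.
#' @param out_dir Output directory.
#' @return A list (report section): results table path, filtered table,
#'   mean gamma of passing results per hybrid.
#' @export
cmd_hyde <- function(cfg, alignments, out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(alignments)) {
    paths <- list.files(alignments, pattern = "\\.fa(sta)?$",
                        full.names = TRUE)
    if (!length(paths)) stop("no FASTA loci found in ", alignments)
    alignments <- lapply(paths, read_fasta)
  }
  super <- do.call(cbind, alignments)
  super <- strip_gapped_columns(super, cfg$stripping_threshold)
  if (!cfg$outgroup %in% rownames(super)) {
    stop("outgroup '", cfg$outgroup, "' not found in alignment")
  }
  res <- triple_scan(super, outgroup = cfg$outgroup, B = cfg$bootstrap_B,
                     seed = derive_seed(cfg$seed, 3L))
  tab_path <- file.path(out_dir, "invariants.tsv")
  utils::write.table(res, tab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  passed <- res[res$passed_filter, , drop = FALSE]
  gamma_by_hybrid <- if (nrow(passed)) {
    tapply(passed$gamma, passed$H, mean)
  } else numeric(0)
  leaf_order <- sort(setdiff(rownames(super), cfg$outgroup))
  for (h in unique(passed$H)) {
    write_tsv_matrix(heatmap_matrix(res, h, leaf_order),
                     file.path(out_dir, paste0("gamma_heatmap_", h, ".tsv")))
  }
  log_line("hyde", "sites:", ncol(super), "tests:", nrow(res),
           "passed:", nrow(passed))
  list(results_tsv = tab_path, n_tests = nrow(res),
       n_passed = nrow(passed), passed = passed,
       gamma_by_hybrid = as.list(gamma_by_hybrid))
}

#' Triplet mixture stage: extract, fit, call, summarize
#'
#' Runs the triplet mixture analysis over all ingroup triples of the
#' species tree, applies the \eqn{\Delta}BIC call rule on discordant
#' classes, and writes the fit table plus the \eqn{\pi_2} matrix of calls.
#' Classes with fewer than 5 usable branch lengths are skipped with a note
#' in the table. The mean \eqn{\pi_2} across discordant classes is reported
#' as the introgression contribution summary.
#'
#' @param cfg A [default_config()] list.
#' @param gene_trees Path or list of \code{"phylo"} gene trees.
#' @param species_tree \code{"phylo"} or newick string.
#' @param out_dir Output directory.
#' @return A list (report section): fits table path, calls, mean
#'   discordant-class \eqn{\pi_2}.
#' @export
cmd_quibl <- function(cfg, gene_trees, species_tree, out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(gene_trees) && length(gene_trees) == 1L) {
    if (!file.exists(gene_trees)) stop("missing input file: ", gene_trees)
    gene_trees <- read_tree_file(gene_trees)
  }
  if (is.character(species_tree)) species_tree <- parse_newick(species_tree)
  fits <- quibl_analysis(gene_trees, species_tree, cfg$outgroup,
                         numsteps = cfg$em_numsteps,
                         likelihoodthresh = cfg$em_likelihoodthresh,
                         gradascentscalar = cfg$em_gradascentscalar)
  fits_path <- file.path(out_dir, "quibl_fits.tsv")
  utils::write.table(fits, fits_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  calls <- call_introgression(fits, threshold = cfg$dbic_threshold)
  disc <- fits[!is.na(fits$discordant) & fits$discordant & !fits$skipped, ]
  mean_pi2 <- if (nrow(disc)) mean(disc$pi2) else NA_real_
  if (nrow(calls)) {
    leaf <- sort(setdiff(species_tree$tip.label, cfg$outgroup))
    write_tsv_matrix(pi2_heatmap(calls, leaf),
                     file.path(out_dir, "pi2_heatmap.tsv"))
  }
  log_line("quibl", "classes:", nrow(fits), "calls:", nrow(calls),
           "mean discordant pi2:", signif(mean_pi2, 4))
  list(fits_tsv = fits_path, n_calls = nrow(calls), calls = calls,
       mean_discordant_pi2 = mean_pi2)
}

#' Run the full synthetic demonstration
#'
#' Simulates the hybrid-quartet scenario, then runs the discordance,
#' invariants, and triplet-mixture stages on the simulated data, and writes
#' a consolidated JSON run report with the headline numbers (concordance
#' fraction, U and p, the gamma table, the \eqn{\Delta}BIC table), the
#' package version, and a config echo.
#'
#' @param cfg A [default_config()] list.
#' @param out_dir Output directory.
#' @return The run report, invisibly written to \code{report.json}.
#' @export
run_demo <- function(cfg = default_config(), out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- cmd_simulate(cfg, file.path(out_dir, "simulate"))
  sp_tree <- sim$scenario$network$tree
  # alternative reference: the minor parental topology (donor side)
  alt <- parse_newick("(((P2:1,H:1):1,P1:2):1,O:3);")
  disc <- cmd_discord(cfg, sim$scenario$sample$trees, sp_tree, alt,
                      file.path(out_dir, "discord"),
                      focal_split = c("P2", "H"))
  hyde <- cmd_hyde(cfg, sim$scenario$alignments,
                   file.path(out_dir, "hyde"))
  quibl <- cmd_quibl(cfg, sim$scenario$sample$trees, sp_tree,
                     file.path(out_dir, "quibl"))
  report <- list(
    version = as.character(utils::packageVersion("phydisc")),
    config = unclass(cfg),
    simulate = list(gene_trees = sim$gene_trees, n_loci = cfg$n_loci),
    discord = disc[c("U", "p", "ils_sufficient", "concordance_full",
                     "concordance_split")],
    hyde = hyde[c("n_tests", "n_passed", "gamma_by_hybrid")],
    quibl = quibl[c("n_calls", "mean_discordant_pi2")])
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
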