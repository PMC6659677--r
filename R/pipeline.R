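# Pipeline module: end-to-end orchestration of the stages with a single
# validated configuration, per-stage outputs, and a machine-readable run
# manifest with input/output checksums.

#' Validate a pipeline configuration
#'
#' All thresholds of the pipeline live in one configuration tree (so
#' sensitivity analyses are one-line changes): `flank` (gene-window flank,
#' bp), `alpha` (gene-significance threshold), `min_pubs` (background PIN
#' publication filter), `min_score` (interaction-evidence score filter; the
#' default 3 discards score <= 2), `hub_threshold` (strict IIH
#' connection-degree threshold), `retention_threshold` (functional-block
#' retention), `fdr_alpha` (differential-expression FDR), `n_perm`
#' (permutation count), `n_density_samples`, `sims`/`sim_thresholds` (the
#' gene-test escalation schedule), and `seed`.
#'
#' @param config Named list (e.g. parsed from YAML) overriding the defaults,
#'   or a path to a YAML file.
#' @return The validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    seed = 1L,
    flank = 50000L,
    alpha = 0.05,
    min_pubs = 2L,
    min_score = 3L,
    hub_threshold = 0.15,
    retention_threshold = 0.12,
    fdr_alpha = 0.05,
    n_perm = 200L,
    n_density_samples = 200L,
    sims = c(1e3, 1e4),
    sim_thresholds = 0.1,
    scenario = list()), config)
  stop_if_not_scalar_prob(cfg$alpha, "alpha")
  stop_if_not_scalar_prob(cfg$hub_threshold, "hub_threshold")
  stop_if_not_scalar_prob(cfg$retention_threshold, "retention_threshold")
  stop_if_not_scalar_prob(cfg$fdr_alpha, "fdr_alpha")
  stop_if_not_count(cfg$flank, "flank", 0L)
  stop_if_not_count(cfg$min_pubs, "min_pubs", 1L)
  stop_if_not_count(cfg$min_score, "min_score", 1L)
  stop_if_not_count(cfg$n_perm, "n_perm", 100L)
  stop_if_not_count(cfg$n_density_samples, "n_density_samples", 100L)
  stopifnot(length(cfg$sims) == length(cfg$sim_thresholds) + 1L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline on a synthetic scenario
#'
#' Executes the stages in dependency order on generated inputs: synthetic
#' data generation, the gene-based association test, background-network
#' filtering and significant-subnetwork extraction with its permutation null,
#' evidence QC/scoring and seed-interactome expansion with hub/core detection
#' and the core-density comparison, pathway over-representation on the
#' largest-component genes with functional-block retention between the full
#' and core enrichments, and covariate-adjusted differential expression.
#' Every stage's result table is written under `out_dir` together with
#' `manifest.json` (config snapshot, seed, per-file checksums, package
#' version, wall-clock). Rerunning with the same config and seed reproduces
#' identical result tables.
#'
#' @param config A [pipeline_config()] (or list/YAML path coercible to one).
#' @param out_dir Output directory.
#' @param scenario Optional [synthetic_scenario()]; defaults to
#'   `synthetic_scenario(seed = config$seed)` with `config$scenario`
#'   overrides.
#' @return Invisibly, a list with each stage's in-memory result plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         scenario = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  if (is.null(scenario)) {
    scenario <- do.call(synthetic_scenario,
                        c(list(seed = config$seed), config$scenario))
  }

  # Stage 1: synthetic inputs.
  gw <- gen_gwas(scenario)
  pin <- gen_pin(scenario)
  pw <- gen_pathways(scenario)
  ex <- gen_expression(scenario)

  # Stage 2: gene-based association test.
  gene_res <- gene_test(gw$snps, gw$genes, ld = gw$ld,
                        flank = config$flank, seed = config$seed,
                        sims = config$sims,
                        thresholds = config$sim_thresholds)
  write_gene_results(gene_res, file.path(out_dir, "gene_results.tsv"))

  # Stage 3: background network, significant subnetwork, permutation null.
  background <- build_background(pin$edges, min_pubs = config$min_pubs)
  subnet <- significant_subnetwork(background, gene_res,
                                   alpha = config$alpha)
  comps <- network_components(subnet)
  perm <- permutation_test(background, gene_res, alpha = config$alpha,
                           n_perm = config$n_perm,
                           seed = child_seed(config$seed, 21L))
  write_edge_tsv(subnet, file.path(out_dir, "subnetwork_edges.tsv"))
  write_graphml(subnet, file.path(out_dir, "subnetwork.graphml"))
  comp_df <- comps
  comp_df$members <- vapply(comp_df$members, paste, character(1),
                            collapse = ",")
  write_tsv(comp_df, file.path(out_dir, "components.tsv"))

  # Seeds for the interactome: the largest significant component (falling
  # back to the planted module if the subnetwork came up empty).
  seeds <- if (nrow(comps)) comps$members[[1]] else scenario$planted_module

  # Stage 4: interactome (evidence QC, scoring, hubs, core, density).
  ev <- gen_evidence(scenario)
  qc <- qc_filter(harmonize(ev$records))
  pairs <- score_pairs(qc, min_score = config$min_score)
  interactome <- build_seed_interactome(ev$seeds, pairs)
  hubs <- hub_analysis(interactome, threshold = config$hub_threshold)
  core <- extract_core(interactome, attr(hubs, "iihs"))
  density <- core_density_comparison(interactome, core,
                                     n_samples = config$n_density_samples,
                                     seed = child_seed(config$seed, 22L))
  write_tsv(as.data.frame(pairs), file.path(out_dir, "scored_pairs.tsv"))
  write_tsv(as.data.frame(hubs), file.path(out_dir, "hub_report.tsv"))
  write_graphml(interactome$graph, file.path(out_dir, "interactome.graphml"))
  write_graphml(core$graph, file.path(out_dir, "core.graphml"))

  # Stage 5: pathway enrichment on the largest-component genes, plus the
  # full-vs-core functional-block retention.
  full_enr <- enrich(seeds, pw$collection, method = "bonferroni")
  core_genes <- intersect(igraph::V(core$graph)$name,
                          pw$collection$universe)
  core_enr <- if (length(core_genes)) {
    enrich(core_genes, pw$collection, method = "bonferroni")
  } else {
    full_enr[0, ]
  }
  blocks <- block_retention(full_enr, core_enr, pw$class_map,
                            threshold = config$retention_threshold)
  write_tsv(as.data.frame(full_enr), file.path(out_dir, "enrichment.tsv"))
  write_tsv(as.data.frame(blocks), file.path(out_dir,
                                             "block_retention.tsv"))

  # Stage 6: differential expression of network genes.
  de <- flag_significant(collapse_probes(de_analysis(ex$expr,
                                                     ex$covariates)),
                         fdr_alpha = config$fdr_alpha)
  write_tsv(as.data.frame(de), file.path(out_dir, "de_results.tsv"))

  # Manifest.
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "pinrisk",
    version = as.character(utils::packageVersion("pinrisk")),
    seed = config$seed,
    config = unclass(config),
    permutation = list(observed = as.list(perm$observed),
                       tail_p = as.list(perm$tail_p),
                       n_perm = perm$n_perm),
    core = list(n_nodes = core$n_nodes, n_edges = core$n_edges,
                avg_neighbors = core$avg_neighbors,
                density_percentile = density$percentile),
    outputs = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(scenario = scenario, gene_results = gene_res,
                 background = background, subnetwork = subnet,
                 components = comps, permutation = perm,
                 scored_pairs = pairs, interactome = interactome,
                 hubs = hubs, core = core, density = density,
                 enrichment = full_enr, core_enrichment = core_enr,
                 blocks = blocks, de = de, manifest = manifest))
}
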