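# Synthetic-data module: seeded planted-truth generators for every pipeline
# stage (GWAS summary statistics with LD, background PIN, interaction evidence,
# pathway collections, case-control expression). All generators are pure
# functions of (scenario, stage offset): repeated calls are bit-identical.

#' Define a synthetic study scenario
#'
#' A `synthetic_scenario` bundles every parameter of the planted-truth
#' generators: the GWAS gene universe and LD structure, the risk genes and
#' their planted effect, the background protein-interaction network (PIN) with
#' its planted connected module, the interaction-evidence generator, the
#' pathway collection with one planted enriched set, and the case-control
#' expression study. The defaults emulate the structural features of the study
#' design the pipeline targets: a GWAS cohort scored per gene over AR(1)-LD SNP
#' blocks in 50 kb-flanked windows, a scale-free publication-annotated PIN, a
#' 10 case / 11 control brain expression panel, and a 20,650-gene annotation
#' universe.
#'
#' @param seed Integer seed; identical seeds give bit-identical outputs from
#'   every generator.
#' @param n_genes Number of genes in the GWAS gene universe.
#' @param snps_per_gene Integer range `c(min, max)` of SNPs per gene window.
#' @param ld_rho AR(1) linkage-disequilibrium correlation in `[0, 1)`:
#'   `cor(z_i, z_j) = ld_rho^|i-j|`.
#' @param n_risk_genes Number of planted risk genes.
#' @param risk_effect Non-centrality (mean shift) added to every risk-gene SNP
#'   z-score; `0` gives a global null.
#' @param flank Gene-window flank in base pairs added beyond both gene ends.
#' @param pin_size Number of proteins in the background PIN.
#' @param pin_attachment Preferential-attachment edges added per new node.
#' @param planted_module_size Size of the planted connected risk-gene module in
#'   the PIN; must not exceed `n_risk_genes` or `pin_size`.
#' @param pin_multi_pub_frac Fraction of non-module edges carrying at least two
#'   supporting publications (module edges always do).
#' @param evidence_params List controlling the interaction-evidence generator:
#'   `n_seeds`, `n_hubs`, `hub_breadth` (seeds bridged per planted hub),
#'   `interactors_per_seed` range, `pubs_per_pair` range, `methods_max`, and
#'   record-level contamination rates `taxid_contamination`,
#'   `pubmed_contamination`, `method_contamination`.
#' @param pathway_params List controlling the pathway generator:
#'   `universe_size`, `n_pathways`, `size_range`, `planted_size`,
#'   `planted_overlap` (risk genes planted into the enriched set).
#' @param expression_params List controlling the expression generator:
#'   `n_genes`, `n_cases`, `n_controls`, `n_de_genes`, `de_effect`, `noise_sd`,
#'   and covariate effect sizes `sex_effect`, `age_effect`, `pmi_effect`.
#'
#' @return An object of class `synthetic_scenario` with the validated
#'   parameters plus derived fields `genes` (gene-id universe), `risk_genes`
#'   and `planted_module` (id sets, `planted_module` a subset of `risk_genes`).
#' @examples
#' sc <- synthetic_scenario(seed = 1, n_genes = 50, pin_size = 40,
#'                          n_risk_genes = 8, planted_module_size = 5)
#' sc$planted_module %in% sc$risk_genes
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_genes = 600L,
                               snps_per_gene = c(4L, 12L),
                               ld_rho = 0.8,
                               n_risk_genes = 25L,
                               risk_effect = 2.5,
                               flank = 50000L,
                               pin_size = 400L,
                               pin_attachment = 2L,
                               planted_module_size = 10L,
                               pin_multi_pub_frac = 0.8,
                               evidence_params = list(),
                               pathway_params = list(),
                               expression_params = list()) {
  n_genes <- stop_if_not_count(n_genes, "n_genes", 1L)
  stopifnot(length(snps_per_gene) == 2L, all(snps_per_gene >= 1L),
            snps_per_gene[1] <= snps_per_gene[2])
  stop_if_not_scalar_prob(ld_rho, "ld_rho", open_right = TRUE)
  n_risk_genes <- stop_if_not_count(n_risk_genes, "n_risk_genes", 0L)
  stopifnot(is.numeric(risk_effect), risk_effect >= 0)
  flank <- stop_if_not_count(flank, "flank", 0L)
  pin_size <- stop_if_not_count(pin_size, "pin_size", 2L)
  pin_attachment <- stop_if_not_count(pin_attachment, "pin_attachment", 1L)
  planted_module_size <- stop_if_not_count(planted_module_size,
                                           "planted_module_size", 0L)
  stop_if_not_scalar_prob(pin_multi_pub_frac, "pin_multi_pub_frac")
  if (n_risk_genes > n_genes) {
    stop("`n_risk_genes` cannot exceed `n_genes`", call. = FALSE)
  }
  if (planted_module_size > n_risk_genes) {
    stop("planted module must be a subset of the risk genes: ",
         "`planted_module_size` cannot exceed `n_risk_genes`", call. = FALSE)
  }
  if (planted_module_size > pin_size) {
    stop("planted module larger than the PIN: `planted_module_size` ",
         "cannot exceed `pin_size`", call. = FALSE)
  }

  ev_defaults_used <- list(
    n_seeds = !"n_seeds" %in% names(evidence_params),
    hub_breadth = !"hub_breadth" %in% names(evidence_params))
  ev <- utils::modifyList(list(
    n_seeds = 20L, n_hubs = 5L, hub_breadth = 6L,
    interactors_per_seed = c(4L, 10L),
    pubs_per_pair = c(1L, 4L), methods_max = 3L,
    taxid_contamination = 0.05, pubmed_contamination = 0.05,
    method_contamination = 0.05), evidence_params)
  pw <- utils::modifyList(list(
    universe_size = 20650L, n_pathways = 40L, size_range = c(10L, 100L),
    planted_size = 23L, planted_overlap = 6L), pathway_params)
  ex <- utils::modifyList(list(
    n_genes = 500L, n_cases = 10L, n_controls = 11L,
    n_de_genes = 50L, de_effect = -1.5, noise_sd = 0.5,
    sex_effect = 0.3, age_effect = 0.01, pmi_effect = 0.02),
    expression_params)

  if (pw$planted_overlap > pw$planted_size) {
    stop("planted pathway overlap cannot exceed the planted pathway size",
         call. = FALSE)
  }
  if (pw$universe_size < max(pw$size_range, pw$planted_size)) {
    stop("pathway universe must be at least as large as the largest pathway",
         call. = FALSE)
  }
  if (ex$n_cases < 2L || ex$n_controls < 2L) {
    stop("expression study needs at least 2 cases and 2 controls",
         call. = FALSE)
  }
  # Defaults scale down with small scenarios; explicit values must fit.
  if (ev_defaults_used[["n_seeds"]]) {
    ev$n_seeds <- min(ev$n_seeds, n_risk_genes)
  }
  if (ev_defaults_used[["hub_breadth"]]) {
    ev$hub_breadth <- min(ev$hub_breadth, max(1L, ev$n_seeds - 1L))
  }
  if (!"planted_overlap" %in% names(pathway_params)) {
    pw$planted_overlap <- min(pw$planted_overlap, n_risk_genes)
  }
  if (ev$n_seeds > n_risk_genes) {
    stop("`evidence_params$n_seeds` cannot exceed `n_risk_genes`",
         call. = FALSE)
  }
  if (ev$n_seeds > 0L && ev$hub_breadth > ev$n_seeds) {
    stop("`evidence_params$hub_breadth` cannot exceed the number of seeds",
         call. = FALSE)
  }
  if (pw$planted_overlap > n_risk_genes) {
    stop("`pathway_params$planted_overlap` cannot exceed `n_risk_genes`",
         call. = FALSE)
  }

  genes <- sprintf("G%04d", seq_len(n_genes))
  risk_genes <- with_seed(child_seed(seed, 11L),
                          sort(sample(genes, n_risk_genes)))
  planted_module <- risk_genes[seq_len(planted_module_size)]

  structure(list(
    seed = as.integer(seed),
    n_genes = n_genes, snps_per_gene = as.integer(snps_per_gene),
    ld_rho = ld_rho, flank = flank,
    genes = genes, risk_genes = risk_genes, risk_effect = risk_effect,
    pin_size = pin_size, pin_attachment = pin_attachment,
    planted_module = planted_module,
    pin_multi_pub_frac = pin_multi_pub_frac,
    evidence_params = ev, pathway_params = pw, expression_params = ex
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic scenario (seed ", x$seed, ")\n", sep = "")
  cat("  GWAS: ", x$n_genes, " genes, ", x$snps_per_gene[1], "-",
      x$snps_per_gene[2], " SNPs/gene, LD rho ", x$ld_rho,
      ", risk effect ", x$risk_effect, " on ", length(x$risk_genes),
      " genes\n", sep = "")
  cat("  PIN: ", x$pin_size, " proteins (attachment ", x$pin_attachment,
      "), planted module of ", length(x$planted_module), "\n", sep = "")
  cat("  Pathways: ", x$pathway_params$n_pathways, " sets, universe ",
      x$pathway_params$universe_size, "\n", sep = "")
  cat("  Expression: ", x$expression_params$n_cases, " cases / ",
      x$expression_params$n_controls, " controls, ",
      x$expression_params$n_genes, " genes\n", sep = "")
  invisible(x)
}

# AR(1) correlation matrix rho^|i-j|; positive definite for |rho| < 1.
ar1_matrix <- function(k, rho) {
  if (k == 1L) return(matrix(1, 1, 1))
  idx <- seq_len(k)
  rho^abs(outer(idx, idx, "-"))
}

#' Generate synthetic GWAS summary statistics with per-gene LD
#'
#' Lays the gene universe out on chromosomes 1-22 with non-overlapping flanked
#' windows, draws each gene's SNP z-scores from a multivariate normal with
#' AR(1) correlation `ld_rho^|i-j|`, adds the planted mean shift
#' `risk_effect` to every risk-gene SNP, and converts z-scores to two-sided
#' normal tail p-values.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list of class `gwas_sim`:
#'   `snps` (data frame `SNP`, `CHR`, `BP`, `P`),
#'   `genes` (BED-style data frame `chrom`, `start`, `end`, `gene_id`;
#'   0-based half-open),
#'   `ld` (named list of per-gene LD matrices with SNP-id dimnames), and
#'   `truth` (risk genes and effect).
#' @examples
#' g <- gen_gwas(synthetic_scenario(seed = 1, n_genes = 20))
#' head(g$snps)
#' @export
gen_gwas <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  rho <- scenario$ld_rho
  if (!(rho >= 0 && rho < 1)) {
    stop("requested LD correlation must lie in [0, 1): AR(1) matrices are ",
         "only positive definite for |rho| < 1", call. = FALSE)
  }
  with_seed(child_seed(scenario$seed, 101L), {
    n <- scenario$n_genes
    chrom <- paste0("chr", rep_len(1:22, n))
    # Non-overlapping windows: genes spaced far beyond 2 * flank per chromosome.
    within_idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
    spacing <- 2L * scenario$flank + 200000L
    width <- sample(10000:80000, n, replace = TRUE)
    start <- (within_idx - 1L) * spacing + 100000L
    genes_df <- data.frame(chrom = chrom, start = start, end = start + width,
                           gene_id = scenario$genes,
                           stringsAsFactors = FALSE)

    is_risk <- scenario$genes %in% scenario$risk_genes
    m <- sample(scenario$snps_per_gene[1]:scenario$snps_per_gene[2],
                n, replace = TRUE)
    snp_counter <- 0L
    ld <- vector("list", n)
    names(ld) <- scenario$genes
    snp_tabs <- vector("list", n)
    for (i in seq_len(n)) {
      k <- m[i]
      lo <- start[i] - scenario$flank
      hi <- start[i] + width[i] + scenario$flank - 1L
      pos <- sort(sample(seq(max(lo, 1L), hi), k))
      sigma <- ar1_matrix(k, rho)
      l <- chol(sigma)
      z <- drop(rnorm(k) %*% l) + if (is_risk[i]) scenario$risk_effect else 0
      ids <- sprintf("rs%07d", snp_counter + seq_len(k))
      snp_counter <- snp_counter + k
      dimnames(sigma) <- list(ids, ids)
      ld[[i]] <- sigma
      snp_tabs[[i]] <- data.frame(SNP = ids, CHR = chrom[i], BP = pos,
                                  P = 2 * stats::pnorm(-abs(z)),
                                  stringsAsFactors = FALSE)
    }
    snps <- do.call(rbind, snp_tabs)
    rownames(snps) <- NULL
    structure(list(snps = snps, genes = genes_df, ld = ld,
                   truth = list(risk_genes = scenario$risk_genes,
                                risk_effect = scenario$risk_effect)),
              class = "gwas_sim")
  })
}

#' Generate a synthetic background protein-interaction network
#'
#' Draws a preferential-attachment (scale-free) graph over the protein
#' universe, wires the planted risk-gene module into one connected subgraph,
#' and annotates every edge with a supporting-publication count. Module-internal
#' edges always carry at least two publications so the planted module survives
#' the downstream minimum-publication filter; other edges do so with
#' probability `pin_multi_pub_frac`.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list of class `pin_sim`: `edges` (data frame `prot_a`, `prot_b`,
#'   `n_pubs`; canonical order, no self-loops, no duplicates) and `truth`
#'   (planted module ids).
#' @examples
#' p <- gen_pin(synthetic_scenario(seed = 1, n_genes = 50, pin_size = 40,
#'                                 n_risk_genes = 8, planted_module_size = 5))
#' head(p$edges)
#' @export
gen_pin <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  module <- scenario$planted_module
  if (length(module) > scenario$pin_size) {
    stop("planted module larger than the PIN", call. = FALSE)
  }
  with_seed(child_seed(scenario$seed, 202L), {
    n <- scenario$pin_size
    g <- igraph::sample_pa(n, power = 1, m = scenario$pin_attachment,
                           directed = FALSE)
    # Label nodes with gene ids (extra synthetic protein ids if the PIN is
    # larger than the gene universe), forcing the planted module in.
    pool <- setdiff(scenario$genes, module)
    if (n - length(module) > length(pool)) {
      pool <- c(pool, sprintf("P%04d",
                              seq_len(n - length(module) - length(pool))))
    }
    labels <- sample(c(module, sample(pool, n - length(module))))
    igraph::V(g)$name <- labels

    # Wire the planted module into one connected subgraph: a random spanning
    # path plus extra within-module edges.
    if (length(module) >= 2L) {
      ord <- sample(module)
      extra <- t(utils::combn(module, 2L))
      extra <- extra[stats::runif(nrow(extra)) < 0.3, , drop = FALSE]
      add <- rbind(cbind(ord[-length(ord)], ord[-1L]), extra)
      g <- igraph::add_edges(g, as.vector(t(add)))
    }
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)

    el <- igraph::as_edgelist(g, names = TRUE)
    cp <- canonical_pair(el[, 1], el[, 2])
    in_module <- cp$a %in% module & cp$b %in% module
    multi <- in_module | stats::runif(length(cp$a)) < scenario$pin_multi_pub_frac
    n_pubs <- ifelse(multi, sample(2:5, length(cp$a), replace = TRUE), 1L)
    edges <- data.frame(prot_a = cp$a, prot_b = cp$b, n_pubs = n_pubs,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$prot_a, edges$prot_b), ]
    rownames(edges) <- NULL
    structure(list(edges = edges,
                   truth = list(planted_module = module)),
              class = "pin_sim")
  })
}

# Detection-method vocabulary for evidence records.
.method_vocab <- c("two hybrid", "affinity chromatography", "pull down",
                   "coimmunoprecipitation", "x-ray crystallography",
                   "fluorescence microscopy")
.db_vocab <- c("intact", "biogrid", "mint", "innatedb")

#' Generate synthetic interaction-evidence records
#'
#' Produces per-annotation interaction-evidence records (a PSI-MITAB 2.7
#' column subset) for a set of protein pairs: each pair receives one record per
#' supporting publication across one or more source databases, with configured
#' distinct-publication and distinct-method counts. A stated fraction of
#' additional records are contaminated (non-human taxid, missing or multiple
#' PubMed ids, or missing detection method) to exercise quality control;
#' contamination is injected at the record level, never the pair level.
#'
#' When `pairs` is `NULL`, a planted seed-interactome pair list is generated:
#' `n_seeds` seed proteins each with private interactors, plus `n_hubs`
#' interconnected hub proteins each bridging `hub_breadth` seeds, forming a
#' dense core recoverable by hub analysis.
#'
#' @param scenario A [synthetic_scenario()].
#' @param pairs Optional data frame with columns `a`, `b` of protein pairs to
#'   annotate; defaults to the planted seed-interactome pairs.
#' @return A list of class `evidence_sim`: `records` (data frame `id_a`,
#'   `id_b`, `method`, `pubmed`, `taxid_a`, `taxid_b`, `source_db`,
#'   `contaminated`), `pair_truth` (data frame `a`, `b`, `n_pubs`,
#'   `n_methods`), `seeds`, and `hubs` (ids; `NULL` when `pairs` supplied).
#' @examples
#' sc <- synthetic_scenario(seed = 1)
#' ev <- gen_evidence(sc, pairs = data.frame(a = "P1", b = "P2"))
#' subset(ev$records, !contaminated)
#' @export
gen_evidence <- function(scenario, pairs = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ev <- scenario$evidence_params
  seeds <- hubs <- NULL
  with_seed(child_seed(scenario$seed, 303L), {
    if (is.null(pairs)) {
      planted <- gen_seed_pairs(scenario)
      pairs <- planted$pairs
      seeds <- planted$seeds
      hubs <- planted$hubs
    }
    if (nrow(pairs) == 0L) stop("`pairs` must be non-empty", call. = FALSE)
    cp <- canonical_pair(as.character(pairs$a), as.character(pairs$b))
    np <- nrow(pairs)
    n_pubs <- sample(ev$pubs_per_pair[1]:ev$pubs_per_pair[2], np,
                     replace = TRUE)
    n_methods <- vapply(n_pubs, function(p) {
      sample.int(min(ev$methods_max, p), 1L)
    }, integer(1))

    pub_counter <- 0L
    rec <- vector("list", np)
    for (i in seq_len(np)) {
      methods <- sample(.method_vocab, n_methods[i])
      pubs <- sprintf("pubmed:%07d", pub_counter + seq_len(n_pubs[i]))
      pub_counter <- pub_counter + n_pubs[i]
      rec[[i]] <- data.frame(
        id_a = cp$a[i], id_b = cp$b[i],
        method = methods[((seq_len(n_pubs[i]) - 1L) %% n_methods[i]) + 1L],
        pubmed = pubs,
        taxid_a = "9606", taxid_b = "9606",
        source_db = sample(.db_vocab, n_pubs[i], replace = TRUE),
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rec)
    records$contaminated <- FALSE

    # Record-level contamination: extra defective records appended.
    contam <- function(n, fix) {
      if (n == 0L) return(NULL)
      idx <- sample.int(nrow(records), n, replace = TRUE)
      out <- records[idx, ]
      out$contaminated <- TRUE
      fix(out)
    }
    n_rec <- nrow(records)
    bad <- rbind(
      contam(round(ev$taxid_contamination * n_rec), function(r) {
        r$taxid_a <- sample(c("10090", "10116", "7227"), nrow(r),
                            replace = TRUE)
        r
      }),
      contam(round(ev$pubmed_contamination * n_rec), function(r) {
        half <- stats::runif(nrow(r)) < 0.5
        r$pubmed[half] <- ""
        r$pubmed[!half] <- paste(r$pubmed[!half], "pubmed:9999999", sep = "|")
        r
      }),
      contam(round(ev$method_contamination * n_rec), function(r) {
        r$method <- ""
        r
      }))
    records <- rbind(records, bad)
    rownames(records) <- NULL

    structure(list(
      records = records,
      pair_truth = data.frame(a = cp$a, b = cp$b, n_pubs = n_pubs,
                              n_methods = n_methods,
                              stringsAsFactors = FALSE),
      seeds = seeds, hubs = hubs),
      class = "evidence_sim")
  })
}

# Planted seed-interactome topology: seeds with private interactors plus
# interconnected hubs bridging many seeds (the recoverable dense core).
gen_seed_pairs <- function(scenario) {
  ev <- scenario$evidence_params
  if (ev$n_seeds < 1L) {
    stop("evidence generation needs at least one risk gene to seed the ",
         "interactome; this scenario has none", call. = FALSE)
  }
  seeds <- scenario$risk_genes[seq_len(ev$n_seeds)]
  hubs <- sprintf("HUB%02d", seq_len(ev$n_hubs))
  pairs <- list()
  ic <- 0L
  for (s in seeds) {
    k <- sample(ev$interactors_per_seed[1]:ev$interactors_per_seed[2], 1L)
    ints <- sprintf("INT%04d", ic + seq_len(k))
    ic <- ic + k
    pairs[[length(pairs) + 1L]] <- data.frame(a = s, b = ints,
                                              stringsAsFactors = FALSE)
  }
  for (h in hubs) {
    bridged <- sample(seeds, ev$hub_breadth)
    pairs[[length(pairs) + 1L]] <- data.frame(a = h, b = bridged,
                                              stringsAsFactors = FALSE)
  }
  if (length(hubs) >= 2L) {
    hh <- t(utils::combn(hubs, 2L))
    keep <- stats::runif(nrow(hh)) < 0.8
    if (any(keep)) {
      pairs[[length(pairs) + 1L]] <- data.frame(a = hh[keep, 1],
                                                b = hh[keep, 2],
                                                stringsAsFactors = FALSE)
    }
  }
  list(pairs = do.call(rbind, pairs), seeds = seeds, hubs = hubs)
}

#' Generate a synthetic pathway collection with one planted enriched set
#'
#' Builds a gene-annotation universe of `universe_size` ids containing the
#' scenario's gene universe, samples `n_pathways` gene sets uniformly from it,
#' and plants one pathway that over-samples the risk-gene set at the configured
#' overlap. A term-to-semantic-class-to-functional-block map is emitted for the
#' downstream block-retention comparison, including deliberately "negligible"
#' classes for the drop-list.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list of class `pathway_sim`: `collection` (a
#'   [gene_set_collection()]), `class_map` (data frame `term`, `class`,
#'   `block`), and `truth` (planted pathway id and its planted risk genes).
#' @examples
#' pw <- gen_pathways(synthetic_scenario(seed = 1))
#' pw$truth$planted
#' @export
gen_pathways <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  pp <- scenario$pathway_params
  with_seed(child_seed(scenario$seed, 404L), {
    n_fill <- pp$universe_size - scenario$n_genes
    if (n_fill < 0) {
      stop("pathway universe smaller than the gene universe", call. = FALSE)
    }
    universe <- c(scenario$genes, sprintf("U%05d", seq_len(n_fill)))

    planted_genes <- sample(scenario$risk_genes, pp$planted_overlap)
    planted <- c(planted_genes,
                 sample(setdiff(universe, planted_genes),
                        pp$planted_size - pp$planted_overlap))
    sets <- list(PW0001 = sample(planted))
    sizes <- sample(pp$size_range[1]:pp$size_range[2], pp$n_pathways - 1L,
                    replace = TRUE)
    for (i in seq_along(sizes)) {
      sets[[sprintf("PW%04d", i + 1L)]] <- sample(universe, sizes[i])
    }
    names_vec <- c("planted risk module pathway",
                   sprintf("random pathway %d", seq_along(sizes)))
    collection <- gene_set_collection(sets, universe,
                                      set_names = stats::setNames(names_vec,
                                                                  names(sets)))

    classes <- c("rna metabolism", "stress response", "cell death",
                 "signaling", "development", "immunity",
                 "metabolism", "general", "physiology")
    blocks <- c(`rna metabolism` = "RNA metabolism",
                `stress response` = "stress",
                `cell death` = "cell death",
                signaling = "signaling",
                development = "development",
                immunity = "immunity",
                metabolism = "housekeeping",
                general = "housekeeping",
                physiology = "housekeeping")
    cls <- sample(classes, length(sets), replace = TRUE)
    class_map <- data.frame(term = names(sets), class = cls,
                            block = unname(blocks[cls]),
                            stringsAsFactors = FALSE)

    structure(list(collection = collection, class_map = class_map,
                   truth = list(planted = "PW0001",
                                planted_genes = planted_genes)),
              class = "pathway_sim")
  })
}

#' Generate a synthetic case-control expression study
#'
#' Gene-by-sample matrix on a log-intensity-like scale: per-gene baseline plus
#' a planted case-status effect for the differentially expressed genes, plus
#' sex, age, and post-mortem-interval covariate effects, plus Gaussian noise.
#' Covariates are stored per sample; sex is balanced so the default design is
#' full rank.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list of class `expression_sim`: `expr` (numeric matrix, genes x
#'   samples), `covariates` (data frame `sample`, `status`, `sex`, `age`,
#'   `pmi`), and `truth` (planted DE gene ids and their effects).
#' @examples
#' ex <- gen_expression(synthetic_scenario(seed = 1))
#' dim(ex$expr)
#' @export
gen_expression <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  xp <- scenario$expression_params
  if (xp$n_cases < 2L || xp$n_controls < 2L) {
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  }
  with_seed(child_seed(scenario$seed, 505L), {
    n_samp <- xp$n_cases + xp$n_controls
    status <- c(rep(1L, xp$n_cases), rep(0L, xp$n_controls))
    # Balanced sex within the study so the design stays full rank.
    sex <- sample(rep_len(c("F", "M"), n_samp))
    age <- round(stats::rnorm(n_samp, 70, 8), 1)
    pmi <- round(pmax(stats::rnorm(n_samp, 24, 6), 2), 1)
    covariates <- data.frame(
      sample = sprintf("S%02d", seq_len(n_samp)),
      status = ifelse(status == 1L, "case", "control"),
      sex = sex, age = age, pmi = pmi, stringsAsFactors = FALSE)
    for (v in c("sex", "age", "pmi")) {
      if (length(unique(covariates[[v]])) < 2L) {
        warning("degenerate covariate (constant column): ", v, call. = FALSE)
      }
    }

    ng <- xp$n_genes
    gene_ids <- if (ng <= scenario$n_genes) {
      scenario$genes[seq_len(ng)]
    } else {
      c(scenario$genes, sprintf("X%04d", seq_len(ng - scenario$n_genes)))
    }
    n_de <- min(xp$n_de_genes, ng)
    de_pool <- intersect(scenario$planted_module, gene_ids)
    de_genes <- c(de_pool,
                  sample(setdiff(gene_ids, de_pool),
                         max(0L, n_de - length(de_pool))))[seq_len(n_de)]
    beta <- stats::setNames(numeric(ng), gene_ids)
    beta[de_genes] <- xp$de_effect

    base <- stats::rnorm(ng, 8, 2)
    sex_num <- as.numeric(sex == "M")
    expr <- matrix(stats::rnorm(ng * n_samp, sd = xp$noise_sd), ng, n_samp)
    expr <- expr + base +
      outer(beta, status) +
      outer(rep(xp$sex_effect, ng), sex_num) +
      outer(rep(xp$age_effect, ng), age - mean(age)) +
      outer(rep(xp$pmi_effect, ng), pmi - mean(pmi))
    dimnames(expr) <- list(gene_ids, covariates$sample)

    structure(list(expr = expr, covariates = covariates,
                   truth = list(de_genes = de_genes,
                                effects = beta[de_genes])),
              class = "expression_sim")
  })
}

#' Write every synthetic artifact of a scenario to disk
#'
#' Materializes all generator outputs in the standard plain-text formats the
#' pipeline readers consume (summary statistics TSV, gene models BED, per-gene
#' LD TSVs, PIN edge-list TSV, PSI-MITAB evidence, seed list, GMT gene sets,
#' class-map TSV, expression and covariate TSVs) plus a machine-readable
#' planted-truth manifest (`truth.json`) so recovery tests never re-derive the
#' planted truths.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gw <- gen_gwas(scenario)
  pin <- gen_pin(scenario)
  ev <- gen_evidence(scenario)
  pw <- gen_pathways(scenario)
  ex <- gen_expression(scenario)

  paths <- list(
    stats = file.path(dir, "summary_stats.tsv"),
    genes = file.path(dir, "genes.bed"),
    ld_dir = file.path(dir, "ld"),
    pin = file.path(dir, "pin_edges.tsv"),
    evidence = file.path(dir, "evidence.mitab"),
    seeds = file.path(dir, "seeds.txt"),
    gmt = file.path(dir, "pathways.gmt"),
    class_map = file.path(dir, "class_map.tsv"),
    expr = file.path(dir, "expression.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    truth = file.path(dir, "truth.json"))

  write_tsv(gw$snps, paths$stats)
  utils::write.table(gw$genes, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  dir.create(paths$ld_dir, showWarnings = FALSE)
  for (g in names(gw$ld)) write_ld_matrix(gw$ld[[g]],
                                          file.path(paths$ld_dir,
                                                    paste0(g, ".tsv")))
  write_tsv(pin$edges, paths$pin)
  write_mitab(ev$records, paths$evidence)
  writeLines(ev$seeds, paths$seeds)
  write_gmt(pw$collection, paths$gmt)
  write_tsv(pw$class_map, paths$class_map)
  expr_df <- data.frame(gene_id = rownames(ex$expr), ex$expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr_df, paths$expr)
  write_tsv(ex$covariates, paths$covariates)

  truth <- list(
    seed = scenario$seed,
    risk_genes = scenario$risk_genes,
    risk_effect = scenario$risk_effect,
    planted_module = scenario$planted_module,
    interactome_seeds = ev$seeds,
    planted_hubs = ev$hubs,
    planted_pathway = pw$truth$planted,
    planted_pathway_genes = pw$truth$planted_genes,
    de_genes = ex$truth$de_genes,
    de_effect = scenario$expression_params$de_effect)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
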