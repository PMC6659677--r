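# Interactome module (weighted protein-protein interaction network analysis):
# merge multi-database evidence records, harmonize identifiers, quality
# control, score and filter interactions, build the seed interactome, detect
# inter-interactome hubs, and extract and validate the densely connected core.

#' Harmonize interaction-record identifiers
#'
#' Maps raw interactor identifiers to canonical protein ids via a supplied
#' mapping table and drops records whose identifiers are unmapped, obsolete,
#' ambiguous (one raw id mapping to several canonical ids), or non-protein
#' (e.g. chemicals). Dropped counts per reason are recorded in the
#' `drop_counts` attribute; drops are data, not errors.
#'
#' @param records Data frame of evidence records (columns `id_a`, `id_b`, ...;
#'   see [read_mitab()]).
#' @param id_map Data frame with columns `raw`, `canonical`, and optionally
#'   `status` (`ok`, `obsolete`, `chemical`; default `ok`). A raw id appearing
#'   in several rows with distinct canonical ids is ambiguous. `NULL` applies
#'   the identity mapping.
#' @return The records with canonical `id_a`, `id_b`, with attribute
#'   `drop_counts`.
#' @export
harmonize <- function(records, id_map = NULL) {
  if (is.null(id_map)) {
    attr(records, "drop_counts") <- c(unmapped = 0L, obsolete = 0L,
                                      ambiguous = 0L, non_protein = 0L)
    return(records)
  }
  stopifnot(all(c("raw", "canonical") %in% names(id_map)))
  if (!"status" %in% names(id_map)) id_map$status <- "ok"
  amb <- unique(id_map$raw[duplicated(id_map[c("raw")]) |
                             duplicated(id_map[c("raw")], fromLast = TRUE)])
  amb <- amb[vapply(amb, function(r) {
    length(unique(id_map$canonical[id_map$raw == r])) > 1L
  }, logical(1))]
  bad_status <- stats::setNames(id_map$status, id_map$raw)
  map <- stats::setNames(id_map$canonical, id_map$raw)

  classify <- function(ids) {
    out <- rep("ok", length(ids))
    out[!(ids %in% id_map$raw)] <- "unmapped"
    known <- ids %in% id_map$raw
    st <- bad_status[ids[known]]
    out[known][st == "obsolete"] <- "obsolete"
    out[known][st == "chemical"] <- "non_protein"
    out[ids %in% amb] <- "ambiguous"
    out
  }
  ca <- classify(records$id_a)
  cb <- classify(records$id_b)
  reason <- ifelse(ca != "ok", ca, cb)
  keep <- reason == "ok"
  counts <- table(factor(reason[!keep],
                         levels = c("unmapped", "obsolete", "ambiguous",
                                    "non_protein")))
  out <- records[keep, , drop = FALSE]
  out$id_a <- unname(map[out$id_a])
  out$id_b <- unname(map[out$id_b])
  rownames(out) <- NULL
  attr(out, "drop_counts") <- stats::setNames(as.integer(counts),
                                              names(counts))
  out
}

#' Quality-control filter for evidence records
#'
#' Keeps only records where both interactor taxids are human (9606), exactly
#' one PubMed identifier is cited (no empty and no multiple `|`-separated
#' ids), and a detection method is described.
#'
#' @param records Harmonized evidence records.
#' @param taxid Required taxon id (default `"9606"`).
#' @return The surviving records, with per-reason drop counts in the
#'   `drop_counts` attribute.
#' @export
qc_filter <- function(records, taxid = "9606") {
  human <- records$taxid_a == taxid & records$taxid_b == taxid
  one_pub <- records$pubmed != "" & !grepl("|", records$pubmed, fixed = TRUE)
  has_method <- !is.na(records$method) & records$method != ""
  keep <- human & one_pub & has_method
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_counts") <- c(
    non_human_taxid = sum(!human),
    bad_pubmed = sum(human & !one_pub),
    no_method = sum(human & one_pub & !has_method))
  out
}

#' Score interaction pairs from evidence records
#'
#' Groups QC-filtered records by unordered protein pair and scores each pair
#' as `n_pubs + n_methods`, the number of distinct publications plus the
#' number of distinct detection methods reporting the interaction. Pairs with
#' score at or below `min_score - 1` (i.e. score <= 2 at the default) are
#' discarded to reduce the false-positive rate: a pair supported by a single
#' publication and a single method never survives.
#'
#' @param records QC-filtered evidence records.
#' @param min_score Minimum surviving score (default 3, i.e. discard score
#'   <= 2).
#' @return Data frame of class `scored_pairs`: `a`, `b` (canonical order),
#'   `n_pubs`, `n_methods`, `score`, sorted by pair; discarded pair count in
#'   `attr(, "n_discarded")`.
#' @export
score_pairs <- function(records, min_score = 3) {
  if (nrow(records) == 0L) {
    out <- data.frame(a = character(0), b = character(0),
                      n_pubs = integer(0), n_methods = integer(0),
                      score = integer(0), stringsAsFactors = FALSE)
    attr(out, "n_discarded") <- 0L
    class(out) <- c("scored_pairs", "data.frame")
    return(out)
  }
  key <- pair_key(records$id_a, records$id_b)
  pubs <- tapply(records$pubmed, key, function(x) length(unique(x)))
  meths <- tapply(records$method, key, function(x) length(unique(x)))
  ord <- sort(names(pubs))
  ab <- do.call(rbind, strsplit(ord, "\t", fixed = TRUE))
  out <- data.frame(a = ab[, 1], b = ab[, 2],
                    n_pubs = as.integer(pubs[ord]),
                    n_methods = as.integer(meths[ord]),
                    stringsAsFactors = FALSE)
  out$score <- out$n_pubs + out$n_methods
  n_all <- nrow(out)
  out <- out[out$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_all - nrow(out)
  class(out) <- c("scored_pairs", "data.frame")
  out
}

#' Build the seed interactome
#'
#' First-layer expansion: nodes are the seeds plus every direct interactor of
#' a seed among the surviving scored pairs; edges are all surviving pairs
#' whose two endpoints both belong to that node set (so interactor-interactor
#' edges inside the first layer are included). Seeds absent from the evidence
#' universe are reported as unmapped; seeds present but with no surviving
#' interactions are reported as disconnected. Exclusion-listed promiscuous
#' nodes (e.g. a ubiquitin-like protein that tags targets for degradation and
#' binds non-specifically) stay in the graph but are flagged and omitted from
#' hub statistics and core seeding.
#'
#' @param seeds Character vector of seed protein ids.
#' @param scored_pairs A [score_pairs()] result (or data frame with `a`, `b`).
#' @param exclusions Character vector of promiscuous node ids.
#' @return List of class `seed_interactome`: `graph` (igraph), `seeds`
#'   (mapped seeds), `unmapped_seeds`, `disconnected_seeds`,
#'   `interactor_sets` (named list: seed plus its first-layer interactors),
#'   `exclusions`.
#' @export
build_seed_interactome <- function(seeds, scored_pairs,
                                   exclusions = character(0)) {
  if (length(seeds) == 0L) stop("`seeds` must be non-empty", call. = FALSE)
  seeds <- unique(as.character(seeds))
  universe <- unique(c(scored_pairs$a, scored_pairs$b))
  unmapped <- setdiff(seeds, universe)
  mapped <- setdiff(seeds, unmapped)

  touches <- scored_pairs$a %in% mapped | scored_pairs$b %in% mapped
  first_layer <- unique(c(scored_pairs$a[touches], scored_pairs$b[touches]))
  nodes <- unique(c(mapped, first_layer))
  keep <- scored_pairs$a %in% nodes & scored_pairs$b %in% nodes
  el <- scored_pairs[keep, , drop = FALSE]
  if (nrow(el) == 0L) {
    stop("no surviving interactions among the seeds: the interactome is ",
         "empty", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(el[, c("a", "b", "score")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- igraph::set_vertex_attr(g, "is_seed",
                               value = igraph::V(g)$name %in% mapped)
  g <- igraph::set_vertex_attr(g, "excluded",
                               value = igraph::V(g)$name %in% exclusions)

  interactor_sets <- lapply(mapped, function(s) {
    nb <- unique(c(scored_pairs$b[scored_pairs$a == s],
                   scored_pairs$a[scored_pairs$b == s]))
    unique(c(s, nb))
  })
  names(interactor_sets) <- mapped
  disconnected <- mapped[vapply(interactor_sets, length,
                                integer(1)) <= 1L]

  structure(list(graph = g, seeds = mapped, unmapped_seeds = unmapped,
                 disconnected_seeds = disconnected,
                 interactor_sets = interactor_sets,
                 exclusions = exclusions),
            class = "seed_interactome")
}

#' @export
print.seed_interactome <- function(x, ...) {
  cat("Seed interactome: ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges, ", length(x$seeds), " seed(s)\n",
      sep = "")
  if (length(x$unmapped_seeds)) {
    cat("  unmapped seeds: ", paste(x$unmapped_seeds, collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$disconnected_seeds)) {
    cat("  disconnected seeds: ",
        paste(x$disconnected_seeds, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Inter-interactome hub analysis
#'
#' For every node, counts the seeds whose interactome (the seed plus its
#' first-layer interactors) contains the node (the bridged-seed count), and
#' divides by the number of seeds to get the connection degree. A node is an
#' inter-interactome hub (IIH) when its connection degree is strictly greater
#' than `threshold` (default 0.15, i.e. bridging more than 15% of the seeds'
#' interactomes). Exclusion-listed nodes are never IIHs.
#'
#' @param interactome A [build_seed_interactome()] result.
#' @param threshold Strict connection-degree threshold (default 0.15).
#' @return Data frame of class `hub_report`: `node`, `bridged_seeds`,
#'   `connection_degree`, `excluded`, `is_seed`, `iih`, sorted by bridged
#'   count descending; the IIH ids are in `attr(, "iihs")` and the threshold
#'   in `attr(, "threshold")`.
#' @export
hub_analysis <- function(interactome, threshold = 0.15) {
  stopifnot(inherits(interactome, "seed_interactome"))
  stop_if_not_scalar_prob(threshold, "threshold")
  sets <- interactome$interactor_sets
  if (length(sets) == 0L) {
    stop("no seed has an interactome", call. = FALSE)
  }
  n_seeds <- length(sets)
  nodes <- igraph::V(interactome$graph)$name
  member <- unlist(sets, use.names = FALSE)
  counts <- table(factor(member, levels = nodes))
  bridged <- as.integer(counts)
  degree <- bridged / n_seeds
  excluded <- nodes %in% interactome$exclusions
  is_seed <- nodes %in% interactome$seeds
  iih <- degree > threshold & !excluded
  out <- data.frame(node = nodes, bridged_seeds = bridged,
                    connection_degree = degree, excluded = excluded,
                    is_seed = is_seed, iih = iih, stringsAsFactors = FALSE)
  out <- out[order(-out$bridged_seeds, out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "iihs") <- out$node[out$iih]
  attr(out, "threshold") <- threshold
  attr(out, "n_seeds") <- n_seeds
  class(out) <- c("hub_report", "data.frame")
  out
}

#' Extract the network core around the inter-interactome hubs
#'
#' The core is the IIH set plus all their direct interactors in the
#' interactome, with the edges induced among those nodes. The average number
#' of neighbors is reported both raw (`2 * n_edges / n_nodes`) and with
#' exclusion-listed nodes removed first.
#'
#' @param interactome A [build_seed_interactome()] result.
#' @param iihs Character vector of IIH ids (e.g. `attr(hub_report, "iihs")`).
#' @return List of class `core_network`: `graph` (induced igraph), `iihs`,
#'   `n_nodes`, `n_edges`, `avg_neighbors`, `avg_neighbors_excl`.
#' @export
extract_core <- function(interactome, iihs) {
  stopifnot(inherits(interactome, "seed_interactome"))
  if (length(iihs) == 0L) stop("IIH set is empty", call. = FALSE)
  g <- interactome$graph
  present <- intersect(iihs, igraph::V(g)$name)
  if (length(present) == 0L) {
    stop("none of the IIHs are present in the interactome", call. = FALSE)
  }
  nb <- unique(unlist(lapply(present, function(h) {
    igraph::neighbors(g, h)$name
  })))
  nodes <- unique(c(present, nb))
  core <- igraph::induced_subgraph(g, nodes)
  n_nodes <- igraph::vcount(core)
  n_edges <- igraph::ecount(core)
  keep <- setdiff(nodes, interactome$exclusions)
  core_excl <- igraph::induced_subgraph(g, keep)
  structure(list(graph = core, iihs = present,
                 n_nodes = n_nodes, n_edges = n_edges,
                 avg_neighbors = 2 * n_edges / n_nodes,
                 avg_neighbors_excl = if (igraph::vcount(core_excl)) {
                   2 * igraph::ecount(core_excl) / igraph::vcount(core_excl)
                 } else 0),
            class = "core_network")
}

#' @export
print.core_network <- function(x, ...) {
  cat("Core network: ", x$n_nodes, " nodes (", length(x$iihs),
      " IIHs and their interactors), ", x$n_edges, " edges\n", sep = "")
  cat(sprintf("  average neighbors: %.2f (%.2f after exclusions)\n",
              x$avg_neighbors, x$avg_neighbors_excl))
  invisible(x)
}

#' Compare core density against random same-size node subsets
#'
#' Edge density of the induced subgraph, `2E / (V (V - 1))`, of the core
#' versus `n_samples` uniformly sampled node subsets of the same size from the
#' interactome. The reported percentile is the share of sampled subsets with
#' density strictly below the core's (conservative ties by default;
#' `ties = "randomized"` randomizes the rank among ties, making the percentile
#' exactly uniform when the "core" is itself a random subset).
#'
#' @param interactome A [build_seed_interactome()] result.
#' @param core A [extract_core()] result (or an igraph graph).
#' @param n_samples Number of random subsets (>= 100).
#' @param seed Integer seed.
#' @param ties `"conservative"` or `"randomized"`.
#' @return List of class `density_comparison`: `core_density`, `percentile`
#'   (0-100), `tail_p`, `null_densities`, `n_samples`, `seed`.
#' @export
core_density_comparison <- function(interactome, core, n_samples = 1000,
                                    seed = 1L,
                                    ties = c("conservative", "randomized")) {
  ties <- match.arg(ties)
  stopifnot(inherits(interactome, "seed_interactome"))
  n_samples <- stop_if_not_count(n_samples, "n_samples", 100L)
  g <- interactome$graph
  core_g <- if (inherits(core, "core_network")) core$graph else core
  k <- igraph::vcount(core_g)
  if (k > igraph::vcount(g)) {
    stop("core larger than the interactome", call. = FALSE)
  }
  if (k < 2L) stop("core must have at least 2 nodes", call. = FALSE)
  dens <- function(sub) {
    v <- igraph::vcount(sub)
    2 * igraph::ecount(sub) / (v * (v - 1))
  }
  core_density <- dens(core_g)
  nodes <- igraph::V(g)$name
  with_seed(seed, {
    null <- vapply(seq_len(n_samples), function(b) {
      dens(igraph::induced_subgraph(g, sample(nodes, k)))
    }, numeric(1))
    tail_p <- if (ties == "conservative") {
      (1 + sum(null >= core_density)) / (1 + n_samples)
    } else {
      n_gt <- sum(null > core_density)
      n_eq <- sum(null == core_density)
      (n_gt + stats::runif(1) * (n_eq + 1)) / (1 + n_samples)
    }
    structure(list(core_density = core_density,
                   percentile = 100 * sum(null < core_density) / n_samples,
                   tail_p = tail_p, null_densities = null, ties = ties,
                   n_samples = n_samples, seed = as.integer(seed)),
              class = "density_comparison")
  })
}

#' @export
print.density_comparison <- function(x, ...) {
  cat(sprintf(paste0("Core density %.4f at the %.1f percentile of %d ",
                     "random same-size subsets (tail p %.4g)\n"),
              x$core_density, x$percentile, x$n_samples, x$tail_p))
  invisible(x)
}
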