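# Network-extraction module: publication-filtered background PIN, induction of
# the subnetwork of association-significant genes, connected-component
# statistics, and a label-shuffling permutation null for the largest
# component. Graph machinery via igraph.

#' Build the background protein-interaction network
#'
#' Keeps only edges supported by at least `min_pubs` independent publications,
#' canonicalizes undirected pairs (so `(A,B)` and `(B,A)` rows merge, keeping
#' the larger publication count), removes self-loops, and drops isolated
#' nodes.
#'
#' @param edges Data frame with columns `prot_a`, `prot_b`, `n_pubs` (see
#'   [read_edge_list()]).
#' @param min_pubs Minimum supporting-publication count (default 2).
#' @return An igraph graph of class `annotated_network` with edge attribute
#'   `n_pubs` and graph attribute `min_pubs`.
#' @export
build_background <- function(edges, min_pubs = 2) {
  stopifnot(all(c("prot_a", "prot_b") %in% names(edges)))
  if (!"n_pubs" %in% names(edges)) edges$n_pubs <- 1
  if (any(edges$n_pubs < 1)) {
    stop("publication counts must be >= 1", call. = FALSE)
  }
  cp <- canonical_pair(as.character(edges$prot_a), as.character(edges$prot_b))
  df <- data.frame(a = cp$a, b = cp$b, n_pubs = edges$n_pubs,
                   stringsAsFactors = FALSE)
  df <- df[df$a != df$b, , drop = FALSE]              # no self-loops
  key <- paste(df$a, df$b, sep = "\t")
  df <- df[order(key, -df$n_pubs), , drop = FALSE]
  df <- df[!duplicated(paste(df$a, df$b, sep = "\t")), , drop = FALSE]
  df <- df[df$n_pubs >= min_pubs, , drop = FALSE]
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::set_graph_attr(g, "min_pubs", min_pubs)
  class(g) <- c("annotated_network", class(g))
  g
}

#' Annotate network nodes with gene-level p-values
#'
#' Attaches `empirical_p` (NA where unknown) and a logical `significant` flag
#' (`p < alpha`, strict; nodes without a p-value are non-significant) as node
#' attributes.
#'
#' @param network An igraph graph.
#' @param gene_p Named numeric vector of gene p-values, or a
#'   `gene_assoc_result` data frame.
#' @param alpha Significance threshold (default 0.05, strict `<`).
#' @return The annotated graph.
#' @export
annotate_network <- function(network, gene_p, alpha = 0.05) {
  p <- as_gene_p(gene_p)
  ids <- igraph::V(network)$name
  pv <- unname(p[ids])
  network <- igraph::set_vertex_attr(network, "empirical_p", value = pv)
  sig <- !is.na(pv) & pv < alpha
  igraph::set_vertex_attr(network, "significant", value = sig)
}

as_gene_p <- function(gene_p) {
  if (is.data.frame(gene_p)) {
    stats::setNames(gene_p$empirical_p, gene_p$gene_id)
  } else {
    stopifnot(is.numeric(gene_p), !is.null(names(gene_p)))
    gene_p
  }
}

#' Induce the significant-gene subnetwork
#'
#' Induced subgraph on the background nodes whose gene-level p-value is
#' strictly below `alpha`; nodes without a p-value are treated as
#' non-significant. Attributes are preserved.
#'
#' @inheritParams annotate_network
#' @return The induced igraph subgraph (possibly empty).
#' @export
significant_subnetwork <- function(network, gene_p, alpha = 0.05) {
  stop_if_not_scalar_prob(alpha, "alpha")
  g <- annotate_network(network, gene_p, alpha)
  keep <- which(igraph::V(g)$significant)
  igraph::induced_subgraph(g, keep)
}

#' Connected components of a network
#'
#' @param network An igraph graph.
#' @return Data frame of class `component_stats`, one row per connected
#'   component, sorted by `(n_nodes, n_edges)` descending: `component`,
#'   `n_nodes`, `n_edges`, `members` (list column of node ids). For every
#'   connected component `n_edges >= n_nodes - 1` holds.
#' @export
network_components <- function(network) {
  comp <- igraph::components(network)
  if (comp$no == 0L) {
    out <- data.frame(component = integer(0), n_nodes = integer(0),
                      n_edges = integer(0))
    out$members <- list()
    class(out) <- c("component_stats", "data.frame")
    return(out)
  }
  stats_list <- lapply(seq_len(comp$no), function(i) {
    ids <- igraph::V(network)$name[comp$membership == i]
    sub <- igraph::induced_subgraph(network, ids)
    list(n_nodes = length(ids), n_edges = igraph::ecount(sub), members = ids)
  })
  out <- data.frame(
    component = seq_len(comp$no),
    n_nodes = vapply(stats_list, `[[`, integer(1), "n_nodes"),
    n_edges = vapply(stats_list, function(s) as.integer(s$n_edges),
                     integer(1)))
  out$members <- lapply(stats_list, `[[`, "members")
  out <- out[order(-out$n_nodes, -out$n_edges), , drop = FALSE]
  out$component <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("component_stats", "data.frame")
  out
}

largest_component_size <- function(network, gene_p, alpha) {
  sub <- significant_subnetwork(network, gene_p, alpha)
  if (igraph::vcount(sub) == 0L) return(c(n_nodes = 0L, n_edges = 0L))
  comp <- igraph::components(sub)
  big <- which.max(comp$csize)
  ids <- which(comp$membership == big)
  sub2 <- igraph::induced_subgraph(sub, ids)
  c(n_nodes = as.integer(comp$csize[big]),
    n_edges = as.integer(igraph::ecount(sub2)))
}

#' Permutation null for the largest significant component
#'
#' Shuffles the observed gene-level p-values randomly amongst all background
#' nodes that carry a p-value, re-induces the significant subnetwork at
#' `alpha`, and records the largest component's node and edge counts per
#' permutation. The observed network is compared against this null.
#'
#' Percentiles and tail probabilities use the conservative tie rule by
#' default: null values tied with the observed count against significance
#' (`tail_p = (1 + #\{null >= obs\}) / (1 + n_perm)`). With
#' `ties = "randomized"` the rank among tied values is randomized, which makes
#' the null tail probability exactly uniform under exchangeability (the
#' standard randomized-rank construction for discrete statistics).
#'
#' @inheritParams annotate_network
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param ties `"conservative"` (default) or `"randomized"`.
#' @return List of class `permutation_null`: observed counts, null count
#'   matrices, per-metric `percentile` (share of null strictly below the
#'   observed, in percent) and `tail_p`, plus `n_perm`, `seed`, `alpha`.
#' @export
permutation_test <- function(network, gene_p, alpha = 0.05, n_perm = 1000,
                             seed = 1L, ties = c("conservative",
                                                 "randomized")) {
  ties <- match.arg(ties)
  n_perm <- stop_if_not_count(n_perm, "n_perm", 100L)
  p <- as_gene_p(gene_p)
  ids <- intersect(igraph::V(network)$name, names(p))
  pvals <- unname(p[ids])
  obs <- largest_component_size(network, p, alpha)
  null_nodes <- integer(n_perm)
  null_edges <- integer(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- stats::setNames(sample(pvals), ids)
      sz <- largest_component_size(network, perm, alpha)
      null_nodes[b] <- sz["n_nodes"]
      null_edges[b] <- sz["n_edges"]
    }
    tail_fun <- function(null, ob) {
      if (ties == "conservative") {
        (1 + sum(null >= ob)) / (1 + n_perm)
      } else {
        # Randomized rank among ties: exactly uniform under the null.
        n_gt <- sum(null > ob)
        n_eq <- sum(null == ob)
        (n_gt + stats::runif(1) * (n_eq + 1)) / (1 + n_perm)
      }
    }
    tail_nodes <- tail_fun(null_nodes, obs["n_nodes"])
    tail_edges <- tail_fun(null_edges, obs["n_edges"])
    structure(list(
      observed = obs,
      null_nodes = null_nodes, null_edges = null_edges,
      percentile = c(nodes = 100 * sum(null_nodes < obs["n_nodes"]) / n_perm,
                     edges = 100 * sum(null_edges < obs["n_edges"]) / n_perm),
      tail_p = c(nodes = tail_nodes, edges = tail_edges),
      ties = ties, n_perm = n_perm, seed = as.integer(seed), alpha = alpha),
      class = "permutation_null")
  })
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null for the largest significant component\n")
  cat("  observed: ", x$observed["n_nodes"], " nodes, ",
      x$observed["n_edges"], " edges\n", sep = "")
  cat("  n_perm = ", x$n_perm, ", alpha = ", x$alpha,
      ", ties = ", x$ties, "\n", sep = "")
  cat(sprintf("  nodes: percentile %.1f, tail p %.4g\n",
              x$percentile["nodes"], x$tail_p["nodes"]))
  cat(sprintf("  edges: percentile %.1f, tail p %.4g\n",
              x$percentile["edges"], x$tail_p["edges"]))
  invisible(x)
}

#' Write a network to GraphML or TSV edge list
#'
#' @param network An igraph graph.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- network
  class(g) <- "igraph"
  # GraphML attribute handlers reject logical/NA-heavy attributes poorly
  # across tools; coerce to character where needed.
  for (at in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, at)
    if (is.logical(v)) g <- igraph::set_vertex_attr(g, at,
                                                    value = as.character(v))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_tsv <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  df <- data.frame(prot_a = el[, 1], prot_b = el[, 2],
                   stringsAsFactors = FALSE)
  if ("n_pubs" %in% igraph::edge_attr_names(network)) {
    df$n_pubs <- igraph::E(network)$n_pubs
  }
  write_tsv(df, path)
}
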