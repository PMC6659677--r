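# Independent oracles used across tests. These deliberately avoid the code
# paths they check: components via recursive depth-first search on an
# adjacency list, hypergeometric tails via explicit binomial-coefficient
# sums.

# Brute-force connected components by depth-first search.
dfs_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (visited[v]) next
    stack <- v
    members <- character(0)
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (visited[u]) next
      visited[u] <- TRUE
      members <- c(members, u)
      stack <- c(stack, adj[[u]])
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# Upper-tail hypergeometric probability by explicit enumeration:
# P(X >= k) = sum_{j >= k} C(K, j) C(N - K, n - j) / C(N, n).
enum_hyper_tail <- function(k, n, K, N) {
  j <- max(0, k):min(K, n)
  feasible <- (n - j) <= (N - K) & (n - j) >= 0
  j <- j[feasible]
  if (!length(j)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# A random undirected simple graph as an edge data frame.
random_graph_edges <- function(n_nodes, p_edge = 0.1) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- which(runif(nrow(pairs)) < p_edge)
  list(nodes = nodes,
       edges = data.frame(prot_a = pairs[keep, 1], prot_b = pairs[keep, 2],
                          n_pubs = rep(2L, length(keep)),
                          stringsAsFactors = FALSE))
}

# A small clean evidence-record data frame.
make_records <- function(id_a, id_b, pubmed, method,
                         taxid_a = "9606", taxid_b = "9606",
                         source_db = "intact") {
  data.frame(id_a = id_a, id_b = id_b, method = method, pubmed = pubmed,
             taxid_a = taxid_a, taxid_b = taxid_b, source_db = source_db,
             stringsAsFactors = FALSE)
}
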