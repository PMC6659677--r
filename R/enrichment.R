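# Enrichment module: hypergeometric over-representation with fold enrichment
# (one-tailed Fisher on the 2x2 table gives the identical p-value), Bonferroni
# or Benjamini-Hochberg adjustment, and the functional-block retention
# comparison between full-network and core enrichments.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set id -> member gene ids).
#'   Duplicate members within a set are collapsed.
#' @param universe Character vector of universe gene ids, or a single integer
#'   universe size. All set members must belong to an id universe.
#' @param set_names Optional named character vector of display names.
#' @return List of class `gene_set_collection`: `sets`, `set_names`,
#'   `universe` (ids or `NULL`), `universe_size`.
#' @export
gene_set_collection <- function(sets, universe, set_names = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(vapply(sets, length, integer(1)) == 0L)) {
    stop("every gene set must be non-empty", call. = FALSE)
  }
  if (is.numeric(universe) && length(universe) == 1L) {
    universe_ids <- NULL
    n <- stop_if_not_count(universe, "universe", 1L)
  } else {
    universe_ids <- unique(as.character(universe))
    n <- length(universe_ids)
    missing <- setdiff(unique(unlist(sets)), universe_ids)
    if (length(missing)) {
      stop("set members outside the universe: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (any(vapply(sets, length, integer(1)) > n)) {
    stop("a gene set is larger than the universe", call. = FALSE)
  }
  if (is.null(set_names)) {
    set_names <- stats::setNames(names(sets), names(sets))
  }
  structure(list(sets = sets, set_names = set_names,
                 universe = universe_ids, universe_size = n),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection: ", length(x$sets), " set(s), universe size ",
      x$universe_size, "\n", sep = "")
  invisible(x)
}

#' Fold enrichment
#'
#' Observed over expected overlap fraction: `(k / n) / (K / N)` for an overlap
#' of `k` candidates in a reference set of size `K`, with `n` candidates drawn
#' from a universe of `N`.
#'
#' @param k Overlap count (>= 0).
#' @param n Candidate-set size (>= 1).
#' @param K Reference-set size (>= 1, <= N).
#' @param N Universe size (>= 1).
#' @return The fold enrichment (exact rational arithmetic, unrounded).
#' @examples
#' round(fold_enrichment(4, 64, 23, 20650), 2)  # 56.11
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_hyper_args(k, n, K, N)
  (k / n) / (K / N)
}

check_hyper_args <- function(k, n, K, N) {
  if (!(N >= 1 && K >= 1 && n >= 1 && k >= 0)) {
    stop("need N, K, n >= 1 and k >= 0", call. = FALSE)
  }
  if (K > N || n > N) {
    stop("reference and candidate sets cannot exceed the universe ",
         "(K <= N, n <= N)", call. = FALSE)
  }
  if (k > min(K, n)) {
    stop("overlap k cannot exceed min(K, n)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` — the chance of observing at least `k`
#' reference-set members among `n` candidates drawn without replacement from a
#' universe of `N` containing `K` reference members. Identical to the
#' one-tailed Fisher exact test on the 2x2 table.
#'
#' @inheritParams fold_enrichment
#' @return The upper-tail p-value.
#' @export
overrepresentation_p <- function(k, n, K, N) {
  check_hyper_args(k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' `bonferroni`: `min(1, m p)`; `bh`: Benjamini-Hochberg step-up with
#' monotonicity enforcement (via [stats::p.adjust()]).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, elementwise `>=` the raw values and `<= 1`.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = if (method == "bh") "BH" else "bonferroni")
}

#' Over-representation analysis of a candidate gene list
#'
#' One hypergeometric upper-tail test per gene set, with fold enrichment and
#' multiplicity adjustment across the collection. Duplicate candidates are
#' collapsed; candidates outside the universe (when universe ids are known)
#' are logged and dropped from the candidate count `n`.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param collection A [gene_set_collection()].
#' @param method Adjustment method, see [adjust_pvalues()] (default
#'   Bonferroni).
#' @param alpha Significance threshold on the adjusted p for the `enriched`
#'   flag (default 0.05, strict `<`).
#' @return Data frame of class `enrichment_result`, one row per set, sorted by
#'   adjusted p then fold (descending): `set_id`, `name`, `K`, `k`, `n`, `N`,
#'   `fold`, `p_raw`, `p_adj`, `enriched`; dropped candidates in
#'   `attr(, "dropped_candidates")`.
#' @export
enrich <- function(candidates, collection, method = c("bonferroni", "bh"),
                   alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(collection, "gene_set_collection"))
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0L) {
    stop("candidate list is empty", call. = FALSE)
  }
  dropped <- character(0)
  if (!is.null(collection$universe)) {
    dropped <- setdiff(candidates, collection$universe)
    candidates <- intersect(candidates, collection$universe)
    if (length(candidates) == 0L) {
      stop("no candidate is in the annotation universe", call. = FALSE)
    }
  }
  n <- length(candidates)
  N <- collection$universe_size
  ids <- names(collection$sets)
  K <- vapply(collection$sets, length, integer(1))
  k <- vapply(collection$sets, function(s) {
    length(intersect(s, candidates))
  }, integer(1))
  fold <- mapply(fold_enrichment, k, n, K, N)
  p_raw <- mapply(overrepresentation_p, k, n, K, N)
  p_adj <- adjust_pvalues(p_raw, method)
  out <- data.frame(set_id = ids,
                    name = unname(collection$set_names[ids]),
                    K = unname(K), k = unname(k), n = n, N = N,
                    fold = unname(fold), p_raw = unname(p_raw),
                    p_adj = unname(p_adj),
                    enriched = unname(p_adj) < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, -out$fold, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_candidates") <- dropped
  attr(out, "method") <- method
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Functional-block retention between full-network and core enrichments
#'
#' Maps enriched terms to semantic classes and functional blocks, removes
#' negligible classes (the drop list, e.g. general, metabolism, enzymes,
#' protein modification, physiology), and computes per block the percentage of
#' full-network enriched terms that re-appear among the core enriched terms.
#' A block is flagged as retained when its retention is strictly greater than
#' `100 * threshold` percent. Blocks absent from the full-network enrichment
#' are reported as undefined (`NA`), not 0; terms without a class mapping are
#' reported in `attr(, "unmapped_terms")` and excluded.
#'
#' @param full_results,core_results [enrich()] results over the same term
#'   namespace (only rows with `enriched == TRUE` are counted).
#' @param class_map Data frame with columns `term`, `class`, `block`.
#' @param threshold Retention threshold as a fraction (default 0.12, i.e.
#'   12%).
#' @param drop_classes Character vector of negligible semantic classes to
#'   remove from both lists.
#' @return Data frame of class `block_retention`: `block`, `n_full`, `n_core`,
#'   `retention` (percent, `NA` when undefined), `retained`.
#' @export
block_retention <- function(full_results, core_results, class_map,
                            threshold = 0.12,
                            drop_classes = c("general", "metabolism",
                                             "enzymes",
                                             "protein modification",
                                             "physiology")) {
  stopifnot(all(c("term", "class", "block") %in% names(class_map)))
  stop_if_not_scalar_prob(threshold, "threshold")
  terms_of <- function(res) {
    if (inherits(res, "enrichment_result") || "enriched" %in% names(res)) {
      unique(res$set_id[res$enriched])
    } else {
      unique(as.character(res))
    }
  }
  full_terms <- terms_of(full_results)
  core_terms <- terms_of(core_results)
  all_terms <- unique(c(full_terms, core_terms))
  unmapped <- setdiff(all_terms, class_map$term)
  cls <- stats::setNames(class_map$class, class_map$term)
  blk <- stats::setNames(class_map$block, class_map$term)
  usable <- function(terms) {
    terms <- setdiff(terms, unmapped)
    terms[!(cls[terms] %in% drop_classes)]
  }
  full_terms <- usable(full_terms)
  core_terms <- usable(core_terms)

  blocks <- sort(unique(blk[setdiff(class_map$term,
                                    class_map$term[class_map$class %in%
                                                     drop_classes])]))
  n_full <- vapply(blocks, function(b) sum(blk[full_terms] == b), integer(1))
  n_core <- vapply(blocks, function(b) {
    sum(blk[intersect(core_terms, full_terms)] == b)
  }, integer(1))
  retention <- ifelse(n_full > 0, 100 * n_core / n_full, NA_real_)
  out <- data.frame(block = blocks, n_full = n_full, n_core = n_core,
                    retention = retention,
                    retained = !is.na(retention) &
                      retention > 100 * threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unmapped_terms") <- unmapped
  attr(out, "threshold") <- threshold
  class(out) <- c("block_retention", "data.frame")
  out
}

#' @export
print.block_retention <- function(x, ...) {
  cat("Functional-block retention (threshold ",
      100 * attr(x, "threshold"), "%)\n", sep = "")
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}
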