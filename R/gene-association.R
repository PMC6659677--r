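# Gene-based association module: converts SNP-level p-values within flanked
# gene windows into gene-level empirical p-values against an LD-aware
# Monte-Carlo null. The observed statistic is the sum of 1-df chi-square
# quantiles of the SNP p-values; the null simulates multivariate normal
# z-scores under the gene's LD matrix.

#' Assign SNPs to flanked gene windows
#'
#' A SNP at position `pos` is assigned to every gene whose half-open window
#' `[start - flank, end + flank)` contains it (0-based, half-open coordinates
#' as in BED). SNPs falling in overlapping windows are assigned to all such
#' genes; genes with zero SNPs are reported in the `untested` attribute.
#'
#' @param snps Data frame with columns `SNP`, `CHR`, `BP`, `P` (see
#'   [read_summary_stats()]).
#' @param genes Data frame with columns `chrom`, `start`, `end`, `gene_id`
#'   (see [read_gene_models()]).
#' @param flank Window flank in base pairs beyond both gene ends
#'   (default 50,000).
#' @return Named list, one entry per tested gene, each a data frame of the
#'   assigned SNP rows; genes with no SNPs are in `attr(, "untested")`.
#'   Chromosome naming mismatch between the two inputs (no shared chromosome
#'   names) is an error listing both sets.
#' @examples
#' snps <- data.frame(SNP = "rs1", CHR = "chr1", BP = 951, P = 0.5)
#' genes <- data.frame(chrom = "chr1", start = 1000, end = 2000,
#'                     gene_id = "G1")
#' assign_snps_to_genes(snps, genes, flank = 50)
#' @export
assign_snps_to_genes <- function(snps, genes, flank = 50000) {
  stopifnot(all(c("SNP", "CHR", "BP", "P") %in% names(snps)),
            all(c("chrom", "start", "end", "gene_id") %in% names(genes)),
            flank >= 0)
  shared <- intersect(unique(snps$CHR), unique(genes$chrom))
  if (length(shared) == 0L && nrow(snps) && nrow(genes)) {
    stop("chromosome name mismatch between SNPs and gene models; ",
         "SNP chromosomes: ", paste(unique(snps$CHR), collapse = ", "),
         "; gene chromosomes: ", paste(unique(genes$chrom), collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  snps_by_chr <- split(snps, snps$CHR)
  for (i in seq_len(nrow(genes))) {
    ch <- snps_by_chr[[genes$chrom[i]]]
    if (is.null(ch)) {
      out[[i]] <- ch <- snps[0, ]
      next
    }
    lo <- genes$start[i] - flank
    hi <- genes$end[i] + flank   # exclusive
    hit <- ch$BP >= lo & ch$BP < hi
    out[[i]] <- ch[hit, , drop = FALSE]
  }
  n_hit <- vapply(out, nrow, integer(1))
  untested <- names(out)[n_hit == 0L]
  out <- out[n_hit > 0L]
  attr(out, "untested") <- untested
  out
}

#' Gene test statistic: sum of 1-df chi-square quantiles
#'
#' `T = sum_i Q(1 - p_i)` where `Q` is the quantile function of the 1-df
#' chi-square distribution, i.e. the SNP p-values mapped back to chi-square
#' scale and summed.
#'
#' @param pvals Numeric vector of SNP p-values in `(0, 1]`.
#' @return The non-negative statistic `T`.
#' @examples
#' gene_statistic(c(0.05, 0.05))  # 7.6829
#' @export
gene_statistic <- function(pvals) {
  if (length(pvals) == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(pvals <= 0 | pvals > 1)) {
    stop("SNP p-values must lie in (0, 1]; clamp zeros upstream ",
         "(see read_summary_stats)", call. = FALSE)
  }
  sum(stats::qchisq(pvals, df = 1, lower.tail = FALSE))
}

# Repair a symmetric correlation matrix to positive semi-definiteness: floor
# negative eigenvalues at zero and renormalize the diagonal to one. Sample LD
# matrices from small reference panels are routinely indefinite.
repair_psd <- function(r, tol = 1e-8) {
  r <- (r + t(r)) / 2
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= -tol && min(e$values) >= 0) return(r)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  d[d == 0] <- 1
  out <- out / outer(d, d)
  diag(out) <- 1
  dimnames(out) <- dimnames(r)
  out
}

#' Simulate null gene statistics under an LD matrix
#'
#' Draws `n` realizations of `T = sum_i z_i^2` with
#' `z ~ MVN(0, Sigma)`, where `Sigma` is the gene's LD (correlation) matrix,
#' repaired to positive semi-definiteness by flooring negative eigenvalues at
#' zero and renormalizing the diagonal.
#'
#' @param ld Square symmetric correlation matrix (unit diagonal).
#' @param n Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @return Numeric vector of `n` null statistics.
#' @export
simulate_null_statistics <- function(ld, n, seed) {
  ld <- as.matrix(ld)
  k <- nrow(ld)
  if (ncol(ld) != k) {
    stop("LD matrix must be square (dimension mismatch with SNP count)",
         call. = FALSE)
  }
  if (max(abs(ld - t(ld))) > 1e-6) {
    stop("LD matrix must be symmetric", call. = FALSE)
  }
  n <- stop_if_not_count(n, "n", 1L)
  e <- eigen(repair_psd(ld), symmetric = TRUE)
  l <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * k), n, k) %*% t(l)
    rowSums(z * z)
  })
}

#' Empirical p-value of an observed statistic against null draws
#'
#' `p = (1 + #\{draws >= T\}) / (1 + n)`: the +1 correction (permutation-test
#' convention) guarantees `p > 0` so downstream `-log(p)` stays finite.
#'
#' @param t_obs Observed statistic.
#' @param draws Numeric vector of null draws.
#' @return Empirical p-value in `(0, 1]`.
#' @export
empirical_p <- function(t_obs, draws) {
  if (length(draws) == 0L) stop("`draws` must be non-empty", call. = FALSE)
  (1 + sum(draws >= t_obs)) / (1 + length(draws))
}

#' Adaptive Monte-Carlo gene test
#'
#' Computes the gene statistic from its SNP p-values and the empirical p
#' against simulated nulls, escalating the simulation count in stages: start
#' at `sims[1]`; if the empirical p is at or below `thresholds[j]`, escalate
#' to `sims[j + 1]`. Defaults: 1,000 sims, escalating to 10,000 at p <= 0.1
#' and to 1,000,000 at p <= 0.001.
#'
#' @param pvals SNP p-values for the gene.
#' @param ld LD matrix matching `length(pvals)` (identity if `NULL`).
#' @param seed Integer seed (each stage derives its own child seed).
#' @param sims Integer vector of simulation counts per stage.
#' @param thresholds Escalation thresholds, length `length(sims) - 1`.
#' @param gene_id Optional id recorded in the result.
#' @return A one-row data frame of class `gene_assoc_result`: `gene_id`,
#'   `n_snps`, `statistic`, `n_sims`, `empirical_p`.
#' @export
adaptive_gene_test <- function(pvals, ld = NULL, seed = 1L,
                               sims = c(1e3, 1e4, 1e6),
                               thresholds = c(0.1, 0.001),
                               gene_id = NA_character_) {
  stopifnot(length(sims) >= 1L, length(thresholds) == length(sims) - 1L)
  k <- length(pvals)
  if (k == 0L) stop("gene has no SNPs", call. = FALSE)
  if (is.null(ld)) ld <- diag(k)
  if (nrow(as.matrix(ld)) != k) {
    stop("LD matrix dimension does not match the SNP count", call. = FALSE)
  }
  t_obs <- gene_statistic(pvals)
  p <- NA_real_
  n_used <- NA_integer_
  for (stage in seq_along(sims)) {
    n_used <- as.integer(sims[stage])
    draws <- simulate_null_statistics(ld, n_used,
                                      child_seed(seed, 1000L * stage))
    p <- empirical_p(t_obs, draws)
    if (stage == length(sims) || p > thresholds[stage]) break
  }
  structure(data.frame(gene_id = gene_id, n_snps = k, statistic = t_obs,
                       n_sims = n_used, empirical_p = p,
                       stringsAsFactors = FALSE),
            class = c("gene_assoc_result", "data.frame"))
}

#' Run the gene-based association test over all genes
#'
#' Assigns SNPs to flanked gene windows, then runs the adaptive Monte-Carlo
#' test per gene under its LD matrix. LD matrices are matched to each gene's
#' assigned SNPs by SNP id; genes without a supplied matrix fall back to
#' identity (independence).
#'
#' @param snps,genes,flank As in [assign_snps_to_genes()].
#' @param ld Named list of per-gene LD matrices (SNP ids as dimnames), or
#'   `NULL`.
#' @param seed Integer seed; each gene derives a child seed, so results are
#'   reproducible and independent of gene order.
#' @param sims,thresholds Escalation schedule, see [adaptive_gene_test()].
#' @return Data frame of class `gene_assoc_result`, one row per tested gene
#'   (`gene_id`, `n_snps`, `statistic`, `n_sims`, `empirical_p`); untested
#'   genes (no SNPs in window) are in `attr(, "untested")`.
#' @export
gene_test <- function(snps, genes, ld = NULL, flank = 50000, seed = 1L,
                      sims = c(1e3, 1e4, 1e6), thresholds = c(0.1, 0.001)) {
  assigned <- assign_snps_to_genes(snps, genes, flank = flank)
  res <- vector("list", length(assigned))
  gene_ids <- names(assigned)
  for (i in seq_along(assigned)) {
    gi <- gene_ids[i]
    tab <- assigned[[i]]
    ld_g <- NULL
    if (!is.null(ld) && gi %in% names(ld)) {
      full <- ld[[gi]]
      have <- intersect(tab$SNP, rownames(full))
      if (length(have) == nrow(tab)) {
        ld_g <- full[tab$SNP, tab$SNP, drop = FALSE]
      }
    }
    res[[i]] <- adaptive_gene_test(tab$P, ld = ld_g,
                                   seed = child_seed(seed, 7L * i),
                                   sims = sims, thresholds = thresholds,
                                   gene_id = gi)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "untested") <- attr(assigned, "untested")
  class(out) <- c("gene_assoc_result", "data.frame")
  out
}

#' @export
print.gene_assoc_result <- function(x, ...) {
  cat("Gene-based association results: ", nrow(x), " gene(s)\n", sep = "")
  untested <- attr(x, "untested")
  if (!is.null(untested) && length(untested)) {
    cat("  untested (no SNPs in window): ", length(untested), "\n", sep = "")
  }
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

#' Write / read per-gene association results
#'
#' Tab-delimited table with columns `gene_id`, `n_snps`, `statistic`,
#' `n_sims`, `empirical_p`.
#'
#' @param results A `gene_assoc_result` data frame.
#' @param path File path.
#' @return `write_gene_results()` returns the path invisibly;
#'   `read_gene_results()` returns the data frame.
#' @export
write_gene_results <- function(results, path) {
  write_tsv(as.data.frame(results), path)
}

#' @rdname write_gene_results
#' @export
read_gene_results <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "empirical_p")
  if (!all(need %in% names(df))) {
    stop("gene-results file must have columns gene_id and empirical_p",
         call. = FALSE)
  }
  class(df) <- c("gene_assoc_result", "data.frame")
  df
}
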