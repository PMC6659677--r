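# Expression module: case-control differential expression of network genes by
# ordinary least squares with sex, age, and post-mortem-interval adjustment,
# probe-to-gene collapsing, and Benjamini-Hochberg false-discovery-rate
# control.

# Build the design matrix: intercept, case status, sex, age, PMI.
de_design <- function(covariates) {
  need <- c("status", "sex", "age", "pmi")
  stopifnot(all(need %in% names(covariates)))
  x <- cbind(
    `(Intercept)` = 1,
    status = as.numeric(covariates$status %in% c("case", "1", 1, TRUE)),
    sex = as.numeric(factor(covariates$sex)) - 1,
    age = as.numeric(covariates$age),
    pmi = as.numeric(covariates$pmi))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    collinear <- colnames(x)[setdiff(seq_len(ncol(x)), keep)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(collinear, collapse = ", "), call. = FALSE)
  }
  x
}

#' Fit the case-status model for one gene
#'
#' Ordinary-least-squares fit of expression on case status adjusted for sex,
#' age, and post-mortem interval, with a two-sided t-test on the status
#' coefficient at the residual degrees of freedom.
#'
#' @param values Numeric expression values, one per sample.
#' @param covariates Data frame with columns `status` (`case`/`control`),
#'   `sex`, `age`, `pmi` in the same sample order.
#' @return Named list: `beta`, `se`, `p` for the status term, and `df`.
#' @export
fit_gene <- function(values, covariates) {
  stopifnot(length(values) == nrow(covariates))
  x <- de_design(covariates)
  fit <- stats::lm.fit(x, values)
  df <- length(values) - ncol(x)
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)
  sigma2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- unname(fit$coefficients["status"])
  tval <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(-abs(tval), df = df), df = df)
}

#' Differential expression across all genes/probes
#'
#' Fits the covariate-adjusted status model of [fit_gene()] to every row of
#' the expression matrix in one QR decomposition (the design is shared across
#' genes, so coefficients and residuals for all genes come from a single
#' solve).
#'
#' @param expr Numeric matrix, genes/probes by samples; values are used as-is
#'   (no normalization or log transform).
#' @param covariates Data frame matching the sample columns (`sample`,
#'   `status`, `sex`, `age`, `pmi`); reordered to the matrix columns when a
#'   `sample` column is present.
#' @return Data frame of class `de_result`, one row per input row: `probe`,
#'   `beta`, `se`, `p_raw`.
#' @export
de_analysis <- function(expr, covariates) {
  stopifnot(is.matrix(expr))
  if ("sample" %in% names(covariates)) {
    if (!all(colnames(expr) %in% covariates$sample)) {
      stop("expression columns missing from the covariate table: ",
           paste(setdiff(colnames(expr), covariates$sample), collapse = ", "),
           call. = FALSE)
    }
    covariates <- covariates[match(colnames(expr), covariates$sample), ,
                             drop = FALSE]
  }
  x <- de_design(covariates)
  qrx <- qr(x)
  yt <- t(expr)                       # samples x genes
  coefs <- qr.coef(qrx, yt)           # p x genes
  resid <- qr.resid(qrx, yt)          # samples x genes
  df <- nrow(x) - ncol(x)
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- coefs["status", ]
  tval <- beta / se
  out <- data.frame(probe = rownames(expr),
                    beta = unname(beta), se = unname(se),
                    p_raw = unname(2 * stats::pt(-abs(tval), df = df)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Collapse probe-level results to one result per gene
#'
#' Keeps, per gene, the probe with the smallest raw p-value (ties broken by
#' smallest standard error, then lexicographic probe id), matching the
#' top-associated-probe convention. The order of the input rows does not
#' affect the output.
#'
#' @param results A [de_analysis()] result.
#' @param mapping Data frame with columns `probe`, `gene`; probes without a
#'   mapping are treated as their own gene.
#' @return The collapsed `de_result` with a `gene` column.
#' @export
collapse_probes <- function(results, mapping = NULL) {
  res <- as.data.frame(results)
  if (is.null(mapping)) {
    res$gene <- res$probe
  } else {
    stopifnot(all(c("probe", "gene") %in% names(mapping)))
    m <- stats::setNames(mapping$gene, mapping$probe)
    res$gene <- ifelse(res$probe %in% names(m), m[res$probe], res$probe)
  }
  res <- res[order(res$gene, res$p_raw, res$se, res$probe), , drop = FALSE]
  out <- res[!duplicated(res$gene), , drop = FALSE]
  out <- out[c("gene", "probe", "beta", "se", "p_raw")]
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Flag significant genes after FDR correction
#'
#' Benjamini-Hochberg adjustment across the (collapsed) genes; a gene is
#' flagged when its adjusted p is strictly below `fdr_alpha`.
#'
#' @param results A (collapsed) `de_result`.
#' @param fdr_alpha FDR threshold (default 0.05, strict `<`).
#' @return The results with `p_fdr` and logical `significant` columns, sorted
#'   by raw p.
#' @export
flag_significant <- function(results, fdr_alpha = 0.05) {
  res <- as.data.frame(results)
  res$p_fdr <- adjust_pvalues(res$p_raw, "bh")
  res$significant <- res$p_fdr < fdr_alpha
  res <- res[order(res$p_raw), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  cat("Differential expression results: ", nrow(x), " row(s)", sep = "")
  if ("significant" %in% names(x)) {
    cat(", ", sum(x$significant), " significant after FDR", sep = "")
  }
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}
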