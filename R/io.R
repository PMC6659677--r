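# Readers and writers for the standard plain-text formats used across the
# pipeline: summary-statistics TSV, BED gene models, square LD matrices,
# edge-list TSV, PSI-MITAB 2.7 column subset, GMT gene sets, expression and
# covariate TSVs.

#' Read GWAS summary statistics
#'
#' Expects a tab-delimited file with a header containing at least the columns
#' `SNP`, `CHR`, `BP`, `P`. P-values of exactly zero are clamped to the
#' smallest representable positive double with a warning, so downstream
#' chi-square quantiles stay finite.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `SNP`, `CHR`, `BP`, `P`.
#' @export
read_summary_stats <- function(path) {
  df <- read_tsv(path)
  need <- c("SNP", "CHR", "BP", "P")
  if (!all(need %in% names(df))) {
    stop("summary-statistics file must have header columns ",
         paste(need, collapse = ", "), "; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  df$P <- as.numeric(df$P)
  if (any(df$P < 0 | df$P > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1] in ", path, call. = FALSE)
  }
  zero <- !is.na(df$P) & df$P == 0
  if (any(zero)) {
    warning(sum(zero), " SNP p-value(s) of exactly 0 clamped to ",
            ".Machine$double.xmin", call. = FALSE)
    df$P[zero] <- .Machine$double.xmin
  }
  df
}

#' Read gene models from a BED file
#'
#' BED is 0-based, half-open; the fourth column is taken as the gene id.
#'
#' @param path Path to the BED file (no header).
#' @return Data frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) {
    stop("BED gene-model file needs at least 4 columns ",
         "(chrom, start, end, gene id)", call. = FALSE)
  }
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "gene_id")
  if (any(df$start >= df$end)) {
    stop("gene models must satisfy start < end (0-based, half-open)",
         call. = FALSE)
  }
  df
}

#' Write / read a square LD matrix
#'
#' Square tab-delimited matrix with SNP ids as both header row and first
#' column.
#'
#' @param ld Correlation matrix with SNP-id dimnames.
#' @param path File path.
#' @return `write_ld_matrix()` returns the path invisibly; `read_ld_matrix()`
#'   returns the matrix.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(SNP = rownames(ld), ld, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("LD matrix in ", path, " is not square with matching SNP ids",
         call. = FALSE)
  }
  m
}

#' Read a protein-interaction edge list
#'
#' Tab-delimited with header; the first two columns are interactor ids and a
#' `n_pubs` column (defaulting to 1 when absent) carries the
#' supporting-publication count. Malformed rows (missing ids, non-numeric
#' counts) are reported with their line numbers.
#'
#' @param path Path to the edge-list TSV.
#' @return Data frame with columns `prot_a`, `prot_b`, `n_pubs`.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("edge list needs at least two columns", call. = FALSE)
  out <- data.frame(prot_a = as.character(df[[1]]),
                    prot_b = as.character(df[[2]]),
                    n_pubs = if ("n_pubs" %in% names(df)) {
                      suppressWarnings(as.numeric(df$n_pubs))
                    } else 1,
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$prot_a) | out$prot_a == "" |
                 is.na(out$prot_b) | out$prot_b == "" |
                 is.na(out$n_pubs) | out$n_pubs < 1)
  if (length(bad)) {
    stop("malformed edge rows at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  out
}

# PSI-MITAB 2.7 column subset used by the interactome stage:
# 1-2 interactor ids, 7 detection method, 9 publication ids, 10-11 taxids,
# 13 source database. Other columns are written as "-".
.mitab_ncol <- 15L

#' Write / read interaction-evidence records as a PSI-MITAB 2.7 subset
#'
#' Only columns 1, 2, 7, 9, 10, 11 and 13 are populated / parsed; the rest are
#' placeholder `-` fields. Taxids are written as `taxid:9606(Homo sapiens)`
#' style and parsed back to the bare numeric id; empty fields round-trip as
#' `-`.
#'
#' @param records Data frame with columns `id_a`, `id_b`, `method`, `pubmed`,
#'   `taxid_a`, `taxid_b`, `source_db` (an optional `contaminated` flag is
#'   ignored on write).
#' @param path File path.
#' @return `write_mitab()` returns the path invisibly; `read_mitab()` returns
#'   the records data frame.
#' @export
write_mitab <- function(records, path) {
  n <- nrow(records)
  m <- matrix("-", n, .mitab_ncol)
  m[, 1] <- paste0("uniprotkb:", records$id_a)
  m[, 2] <- paste0("uniprotkb:", records$id_b)
  m[, 7] <- ifelse(records$method == "", "-",
                   paste0("psi-mi:\"MI:0000\"(", records$method, ")"))
  m[, 9] <- ifelse(records$pubmed == "", "-", records$pubmed)
  m[, 10] <- ifelse(records$taxid_a == "", "-",
                    paste0("taxid:", records$taxid_a))
  m[, 11] <- ifelse(records$taxid_b == "", "-",
                    paste0("taxid:", records$taxid_b))
  m[, 13] <- paste0("psi-mi:\"MI:0000\"(", records$source_db, ")")
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}

strip_prefix <- function(x, prefix) {
  sub(paste0("^", prefix), "", x)
}

mitab_field <- function(x) ifelse(x == "-", "", x)

#' @rdname write_mitab
#' @export
read_mitab <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 13L)
  if (length(bad)) {
    stop("MITAB rows with fewer than 13 columns at line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  getf <- function(i) vapply(parts, `[[`, character(1), i)
  paren <- function(x) {
    out <- sub("^.*\\(([^)]*)\\)$", "\\1", x)
    ifelse(out == x & grepl("^psi-mi", x), "", out)
  }
  data.frame(
    id_a = strip_prefix(getf(1), "uniprotkb:"),
    id_b = strip_prefix(getf(2), "uniprotkb:"),
    method = mitab_field(paren(mitab_field(getf(7)))),
    pubmed = mitab_field(getf(9)),
    taxid_a = strip_prefix(mitab_field(getf(10)), "taxid:"),
    taxid_b = strip_prefix(mitab_field(getf(11)), "taxid:"),
    source_db = paren(getf(13)),
    stringsAsFactors = FALSE)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: id, name, then member ids, tab-separated.
#'
#' @param collection A [gene_set_collection()] (its universe is not stored in
#'   the GMT; supply it again on read).
#' @param path File path.
#' @param universe Universe of gene ids (or its size) for the read-back
#'   collection; defaults to the union of the sets read.
#' @return `write_gmt()` returns the path invisibly; `read_gmt()` returns a
#'   [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$set_names[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad)) {
    stop("GMT lines with fewer than 3 fields at line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  nms <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  gene_set_collection(sets, universe, set_names = stats::setNames(nms, ids))
}

#' Read an expression matrix and its covariate table
#'
#' The expression TSV has gene/probe ids in the first column and one column
#' per sample; values are taken as-is (no normalization or log transform is
#' applied). The covariate TSV must contain columns `sample`, `status`, `sex`,
#' `age`, `pmi`, with `status` coded `case`/`control`.
#'
#' @param path Path to the expression TSV.
#' @return `read_expression()`: numeric matrix with gene ids as row names.
#'   `read_covariates()`: data frame with the five covariate columns.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @export
read_covariates <- function(path) {
  df <- read_tsv(path)
  need <- c("sample", "status", "sex", "age", "pmi")
  if (!all(need %in% names(df))) {
    stop("covariate file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$status %in% c("case", "control"))) {
    stop("`status` must be coded case/control", call. = FALSE)
  }
  df[need]
}
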