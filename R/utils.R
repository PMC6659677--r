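# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage offset, kept within the
# 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

stop_if_not_scalar_prob <- function(x, name, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must be a single value in [0,%s), got: %s",
                 name, if (open_right) "1" else "1]", format(x)), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
  if (!ok) {
    stop(sprintf("`%s` must be a single integer >= %d, got: %s",
                 name, min, format(x)), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Canonicalize an undirected pair: element-wise sorted so (A,B) == (B,A).
canonical_pair <- function(a, b) {
  list(a = pmin(a, b), b = pmax(a, b))
}

pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p$a, p$b, sep = "\t")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
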