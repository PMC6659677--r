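# Over-representation analysis: fold enrichment, hypergeometric tail,
# adjustment, candidate handling, block retention.

test_that("fold enrichment reproduces the printed pathway-table values", {
  expect_equal(round(fold_enrichment(4, 64, 23, 20650), 2), 56.11)
  expect_equal(round(fold_enrichment(4, 64, 34, 20650), 2), 37.96)
  expect_equal(round(fold_enrichment(3, 64, 13, 20650), 2), 74.46)
  expect_equal(round(fold_enrichment(5, 64, 110, 20650), 2), 14.67)
  expect_equal(round(fold_enrichment(8, 64, 282, 20650), 2), 9.15)
})

test_that("fold enrichment boundary identities and validation", {
  expect_equal(fold_enrichment(0, 10, 5, 100), 0)
  expect_equal(fold_enrichment(7, 7, 7, 7), 1)
  expect_error(fold_enrichment(5, 4, 10, 100), "min")
  expect_error(fold_enrichment(1, 10, 200, 100), "universe")
  expect_error(fold_enrichment(0, 0, 5, 100), ">= 1")
})

test_that("hypergeometric tail matches enumeration and Fisher", {
  expect_equal(overrepresentation_p(0, 3, 3, 10), 1)
  expect_equal(overrepresentation_p(3, 3, 3, 10), 1 / 120)
  # spot-check against the enumeration oracle and fisher.test
  set.seed(9)
  for (i in 1:25) {
    N <- sample(5:25, 1); K <- sample(N, 1); n <- sample(N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(overrepresentation_p(k, n, K, N),
                 enum_hyper_tail(k, n, K, N), tolerance = 1e-12)
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2)
    if (all(tab >= 0)) {
      expect_equal(overrepresentation_p(k, n, K, N),
                   stats::fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("p_raw is strictly decreasing in the overlap count", {
  for (N in c(10, 18, 25)) {
    K <- 6; n <- 7
    # strictly decreasing over the support; below the minimum possible
    # overlap (n + K - N) the tail probability is flat at 1
    ks <- max(0, n + K - N):min(K, n)
    ps <- vapply(ks, overrepresentation_p, numeric(1), n = n, K = K, N = N)
    expect_true(all(diff(ps) < 0))
  }
})

test_that("adjustment methods behave as documented", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.004, rep(0.5, 9)), "bonferroni")[1], 0.04)
  p <- runif(50)
  bh <- adjust_pvalues(p, "bh")
  expect_true(all(bh >= p) && all(bh <= 1))
  expect_true(all(diff(bh[order(p)]) >= -1e-12))
  expect_error(adjust_pvalues(1.2), "\\[0, 1\\]")
})

test_that("enrich handles duplicates, out-of-universe candidates and sorting", {
  universe <- sprintf("g%03d", 1:100)
  coll <- gene_set_collection(list(S1 = universe[1:10], S2 = universe[41:60]),
                              universe)
  res <- enrich(c(universe[1:5], universe[1:5], "nope"), coll)
  expect_equal(attr(res, "dropped_candidates"), "nope")
  expect_equal(unique(res$n), 5)  # duplicates collapsed, outsider dropped
  expect_equal(res$k[res$set_id == "S1"], 5)
  expect_equal(res$set_id[1], "S1")
  # disjoint candidates: all folds 0, p_raw 1
  res0 <- enrich(universe[90:95],
                 gene_set_collection(list(S1 = universe[1:10]), universe))
  expect_equal(res0$fold, 0)
  expect_equal(res0$p_raw, 1)
  # the full universe as candidates gives fold 1 for every set
  res1 <- enrich(universe, coll)
  expect_equal(res1$fold, c(1, 1))
  expect_error(enrich(character(0), coll), "empty")
})

test_that("block retention drops negligible classes and flags strictly", {
  class_map <- data.frame(
    term = sprintf("T%02d", 1:12),
    class = c(rep("rna", 8), rep("stress", 2), rep("metabolism", 2)),
    block = c(rep("RNA metabolism", 8), rep("stress", 2),
              rep("housekeeping", 2)),
    stringsAsFactors = FALSE)
  full <- sprintf("T%02d", 1:12)
  # exactly 1 of 8 rna terms retained: 12.5% > 12% -> flagged
  out <- block_retention(full, "T01", class_map, threshold = 0.12)
  rna <- out[out$block == "RNA metabolism", ]
  expect_equal(rna$retention, 12.5)
  expect_true(rna$retained)
  # stress: 0 of 2 retained, defined but not flagged
  stress <- out[out$block == "stress", ]
  expect_equal(stress$retention, 0)
  expect_false(stress$retained)
  # metabolism class is dropped entirely
  expect_false("housekeeping" %in% out$block)
  # identical lists retain 100% everywhere
  out2 <- block_retention(full, full, class_map)
  expect_true(all(out2$retention == 100) && all(out2$retained))
  # empty core -> all defined blocks 0%, none flagged
  out3 <- block_retention(full, character(0), class_map)
  expect_true(all(out3$retention == 0) && !any(out3$retained))
  # unmapped terms are reported, not counted
  out4 <- block_retention(c(full, "TXX"), "TXX", class_map)
  expect_equal(attr(out4, "unmapped_terms"), "TXX")
})

test_that("blocks absent from the full enrichment are undefined, not zero", {
  class_map <- data.frame(term = c("T1", "T2"),
                          class = c("rna", "stress"),
                          block = c("RNA metabolism", "stress"),
                          stringsAsFactors = FALSE)
  out <- block_retention("T1", "T1", class_map)
  expect_true(is.na(out$retention[out$block == "stress"]))
  expect_false(out$retained[out$block == "stress"])
})

test_that("GMT round trip preserves sets and universe handling", {
  universe <- sprintf("g%03d", 1:50)
  coll <- gene_set_collection(list(A = universe[1:5], B = universe[10:20]),
                              universe,
                              set_names = c(A = "set a", B = "set b"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, universe)
  expect_equal(back$sets, coll$sets)
  expect_equal(back$set_names, coll$set_names)
  expect_equal(back$universe_size, 50)
})
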