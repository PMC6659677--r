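# Interactome stage: harmonization, QC, pair scoring, seed interactome, hub
# detection, core extraction, density comparison.

test_that("harmonization drops ambiguous, obsolete and non-protein ids", {
  rec <- make_records(c("x1", "x2", "x3", "x4", "x5"),
                      c("y1", "y1", "y1", "y1", "y1"),
                      pubmed = paste0("pm", 1:5), method = "two hybrid")
  id_map <- data.frame(
    raw = c("x1", "x2", "x3", "x4", "x4", "y1"),
    canonical = c("P1", "P2", "P3", "P4a", "P4b", "Q1"),
    status = c("ok", "obsolete", "chemical", "ok", "ok", "ok"),
    stringsAsFactors = FALSE)
  out <- harmonize(rec, id_map)
  expect_equal(out$id_a, "P1")          # x2 obsolete, x3 chemical,
  expect_equal(out$id_b, "Q1")          # x4 ambiguous, x5 unmapped
  dc <- attr(out, "drop_counts")
  expect_equal(unname(dc[c("obsolete", "non_protein", "ambiguous",
                           "unmapped")]), c(1L, 1L, 1L, 1L))
  # identity mapping leaves records unchanged
  expect_equal(harmonize(rec, NULL)$id_a, rec$id_a)
})

test_that("QC keeps only human, single-PubMed, method-described records", {
  rec <- make_records(rep("A", 5), rep("B", 5),
                      pubmed = c("pm1", "pm2", "", "pm4|pm5", "pm6"),
                      method = c("two hybrid", "pull down", "pull down",
                                 "pull down", ""),
                      taxid_a = c("9606", "10090", "9606", "9606", "9606"))
  out <- qc_filter(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$pubmed, "pm1")
  dc <- attr(out, "drop_counts")
  expect_equal(unname(dc), c(1L, 2L, 1L))
})

test_that("pair scoring counts distinct publications plus distinct methods", {
  rec <- make_records(c("A", "A", "A", "B", "B"),
                      c("B", "B", "B", "A", "C"),
                      pubmed = c("pm1", "pm2", "pm3", "pm1", "pm9"),
                      method = c("two hybrid", "pull down", "two hybrid",
                                 "two hybrid", "pull down"))
  out <- score_pairs(rec, min_score = 1)
  ab <- out[out$a == "A" & out$b == "B", ]
  expect_equal(ab$n_pubs, 3)      # pm1, pm2, pm3 (B,A row merges into A,B)
  expect_equal(ab$n_methods, 2)
  expect_equal(ab$score, 5)
  # the 1-pub 1-method pair is discarded at the default cutoff
  def <- score_pairs(rec)
  expect_false(any(def$a == "B" & def$b == "C"))
  expect_equal(attr(def, "n_discarded"), 1L)
  # 2 pubs + 1 method scores 3 and is kept
  rec2 <- make_records(c("X", "X"), c("Y", "Y"), pubmed = c("p1", "p2"),
                       method = "pull down")
  expect_equal(score_pairs(rec2)$score, 3)
})

test_that("scoring is order-independent and monotone under added evidence", {
  set.seed(77)
  ids <- sprintf("N%02d", 1:8)
  rec <- make_records(sample(ids, 60, TRUE), sample(ids, 60, TRUE),
                      pubmed = sprintf("pm%02d", sample(30, 60, TRUE)),
                      method = sample(c("m1", "m2", "m3"), 60, TRUE))
  rec <- rec[rec$id_a != rec$id_b, ]
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(score_pairs(rec), score_pairs(shuffled),
               ignore_attr = TRUE)
  # adding a record with a new publication never drops a kept pair
  before <- score_pairs(rec)
  extra <- make_records("N01", "N02", pubmed = "pm_new", method = "m_new")
  after <- score_pairs(rbind(rec, extra))
  expect_true(all(paste(before$a, before$b) %in% paste(after$a, after$b)))
  key <- paste(after$a, after$b)
  for (i in seq_len(nrow(before))) {
    j <- match(paste(before$a[i], before$b[i]), key)
    expect_gte(after$score[j], before$score[i])
  }
})

toy_interactome <- function() {
  # seeds S1..S4; H bridges S1-S3; private interactors I1..I3; S4 isolated
  pairs <- data.frame(
    a = c("S1", "S2", "S3", "H", "H", "H", "S1"),
    b = c("I1", "I2", "I3", "S1", "S2", "S3", "I2"),
    score = 3, stringsAsFactors = FALSE)
  build_seed_interactome(c("S1", "S2", "S3", "S4", "ZZ"), pairs)
}

test_that("seed interactome reports unmapped and disconnected seeds", {
  it <- toy_interactome()
  expect_setequal(it$unmapped_seeds, c("S4", "ZZ"))
  expect_setequal(it$seeds, c("S1", "S2", "S3"))
  expect_equal(length(it$disconnected_seeds), 0)
  # a shared interactor's bridged-seed count is 2
  hub <- hub_analysis(it, threshold = 0.15)
  expect_equal(hub$bridged_seeds[hub$node == "I2"], 2L)
  expect_error(build_seed_interactome(character(0), it), "non-empty")
})

test_that("hub threshold is strict: exactly 15% never, above always", {
  # 20 seeds; node bridging exactly 3 (15%) is not an IIH; 4 (20%) is
  seeds <- sprintf("S%02d", 1:20)
  mk <- function(n_bridge, node) {
    data.frame(a = node, b = seeds[seq_len(n_bridge)],
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk(3, "H3"), mk(4, "H4"),
                 data.frame(a = seeds, b = paste0("I", seq_along(seeds)),
                            stringsAsFactors = FALSE))
  pairs$score <- 3
  it <- build_seed_interactome(seeds, pairs)
  hub <- hub_analysis(it, threshold = 0.15)
  expect_false(hub$iih[hub$node == "H3"])
  expect_true(hub$iih[hub$node == "H4"])
  expect_equal(hub$connection_degree[hub$node == "H3"], 0.15)
})

test_that("excluded promiscuous nodes stay in the graph but are never IIHs", {
  seeds <- sprintf("S%02d", 1:10)
  pairs <- data.frame(a = "UBC", b = seeds, score = 3,
                      stringsAsFactors = FALSE)
  it <- build_seed_interactome(seeds, pairs, exclusions = "UBC")
  expect_true("UBC" %in% igraph::V(it$graph)$name)
  hub <- hub_analysis(it, threshold = 0.15)
  row <- hub[hub$node == "UBC", ]
  expect_equal(row$bridged_seeds, 10L)
  expect_false(row$iih)
})

test_that("hub detection is invariant to seed relabeling", {
  it <- toy_interactome()
  hub1 <- attr(hub_analysis(it), "iihs")
  pairs2 <- data.frame(
    a = c("S3", "S2", "S1", "H", "H", "H", "S3"),
    b = c("I1", "I2", "I3", "S3", "S2", "S1", "I2"),
    score = 3, stringsAsFactors = FALSE)
  it2 <- build_seed_interactome(c("S1", "S2", "S3"), pairs2)
  expect_setequal(attr(hub_analysis(it2), "iihs"), hub1)
})

test_that("core extraction matches the star-graph hand computation", {
  # star: the hub seed has 5 first-layer interactors and no other edges
  pairs <- data.frame(a = "HUB", b = c("S1", paste0("I", 1:4)), score = 3,
                      stringsAsFactors = FALSE)
  it <- build_seed_interactome("HUB", pairs)
  core <- extract_core(it, "HUB")
  expect_equal(core$n_nodes, 6)
  expect_equal(core$n_edges, 5)
  expect_equal(round(core$avg_neighbors, 2), 1.67)
  # overlapping interactors are not double counted
  pairs2 <- rbind(pairs, data.frame(a = "HUB2", b = c("S1", "I1"),
                                    score = 3))
  it2 <- build_seed_interactome(c("HUB", "HUB2"), pairs2)
  core2 <- extract_core(it2, c("HUB", "HUB2"))
  expect_equal(core2$n_nodes,
               length(unique(c("HUB", "HUB2", "S1", paste0("I", 1:4)))))
  expect_error(extract_core(it, character(0)), "empty")
})

test_that("core edges equal the brute-force induced-subgraph oracle", {
  set.seed(202)
  for (rep in 1:20) {
    gr <- random_graph_edges(sample(8:25, 1), p_edge = 0.2)
    names(gr$edges)[1:2] <- c("a", "b")
    gr$edges$score <- 3
    seeds <- sample(gr$nodes, 3)
    it <- tryCatch(build_seed_interactome(seeds, gr$edges),
                   error = function(e) NULL)
    if (is.null(it)) next
    present <- igraph::V(it$graph)$name
    iihs <- sample(present, min(2, length(present)))
    core <- extract_core(it, iihs)
    # oracle: nodes = iihs + neighbors from the raw pair list restricted to
    # the interactome; edges = pairs with both ends in that set
    nb <- unique(c(gr$edges$b[gr$edges$a %in% iihs],
                   gr$edges$a[gr$edges$b %in% iihs]))
    nodes <- intersect(unique(c(iihs, nb)), present)
    keep <- gr$edges$a %in% nodes & gr$edges$b %in% nodes &
      gr$edges$a %in% present & gr$edges$b %in% present
    expect_setequal(igraph::V(core$graph)$name, nodes)
    expect_equal(core$n_edges, sum(keep))
  }
})

test_that("the density comparison validates inputs and ranks a dense core", {
  sc <- synthetic_scenario(seed = 41)
  ev <- gen_evidence(sc)
  pairs <- score_pairs(qc_filter(ev$records))
  it <- build_seed_interactome(ev$seeds, pairs)
  hub <- hub_analysis(it)
  core <- extract_core(it, attr(hub, "iihs"))
  expect_error(core_density_comparison(it, core, n_samples = 0), "n_samples")
  dc <- core_density_comparison(it, core, n_samples = 200, seed = 1)
  expect_gte(dc$percentile, 95)
  # the core is a subgraph of the interactome containing all IIHs
  expect_true(all(core$iihs %in% igraph::V(core$graph)$name))
  expect_true(all(igraph::V(core$graph)$name %in%
                    igraph::V(it$graph)$name))
})

test_that("bridged-count double-counting identity holds on synthetic data", {
  sc <- synthetic_scenario(seed = 43)
  ev <- gen_evidence(sc)
  pairs <- score_pairs(qc_filter(ev$records))
  it <- build_seed_interactome(ev$seeds, pairs)
  hub <- hub_analysis(it)
  nodes <- igraph::V(it$graph)$name
  lhs <- sum(hub$bridged_seeds)
  rhs <- sum(vapply(it$interactor_sets, function(s) {
    length(intersect(s, nodes))
  }, integer(1)))
  expect_equal(lhs, rhs)
})

test_that("MITAB round trip preserves the QC-relevant fields", {
  sc <- synthetic_scenario(seed = 44)
  ev <- gen_evidence(sc)
  path <- withr::local_tempfile(fileext = ".mitab")
  write_mitab(ev$records, path)
  back <- read_mitab(path)
  expect_equal(back$id_a, ev$records$id_a)
  expect_equal(back$pubmed, ev$records$pubmed)
  expect_equal(back$method, ev$records$method)
  expect_equal(back$taxid_a, ev$records$taxid_a)
  # QC gives identical results before and after the round trip
  expect_equal(nrow(qc_filter(back)), nrow(qc_filter(ev$records)))
})
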