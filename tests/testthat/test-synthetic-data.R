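# Synthetic-data generators: determinism, planted structure, null calibration.

small_scenario <- function(seed = 1, ...) {
  synthetic_scenario(seed = seed, n_genes = 60, n_risk_genes = 12,
                     planted_module_size = 6, pin_size = 50, ...)
}

test_that("scenario validation enforces the planted-truth invariants", {
  expect_s3_class(small_scenario(), "synthetic_scenario")
  sc <- small_scenario()
  expect_true(all(sc$planted_module %in% sc$risk_genes))
  expect_true(all(sc$risk_genes %in% sc$genes))
  expect_error(synthetic_scenario(ld_rho = 1), "ld_rho")
  expect_error(synthetic_scenario(ld_rho = -0.1), "ld_rho")
  expect_error(synthetic_scenario(n_risk_genes = 10, planted_module_size = 11),
               "planted_module_size")
  expect_error(synthetic_scenario(pin_size = 5, n_risk_genes = 10,
                                  planted_module_size = 8),
               "pin_size")
  expect_error(synthetic_scenario(
    pathway_params = list(planted_size = 5, planted_overlap = 6)), "overlap")
})

test_that("all generators are bit-identical under the same seed", {
  sc <- small_scenario(seed = 7)
  expect_identical(gen_gwas(sc), gen_gwas(sc))
  expect_identical(gen_pin(sc), gen_pin(sc))
  expect_identical(gen_evidence(sc), gen_evidence(sc))
  expect_identical(gen_pathways(sc), gen_pathways(sc))
  expect_identical(gen_expression(sc), gen_expression(sc))
  # and a different seed changes the draw
  expect_false(identical(gen_gwas(sc)$snps,
                         gen_gwas(small_scenario(seed = 8))$snps))
})

test_that("null GWAS p-values are uniform and LD matrices are valid", {
  sc <- synthetic_scenario(seed = 3, n_genes = 300, n_risk_genes = 0,
                           planted_module_size = 0, risk_effect = 0,
                           ld_rho = 0)
  gw <- gen_gwas(sc)
  expect_gt(stats::ks.test(gw$snps$P, "punif")$p.value, 0.01)
  # every SNP lies inside its gene's flanked window
  for (g in sample(names(gw$ld), 20)) {
    row <- gw$genes[gw$genes$gene_id == g, ]
    snps <- gw$snps[gw$snps$SNP %in% rownames(gw$ld[[g]]), ]
    expect_true(all(snps$BP >= row$start - sc$flank &
                      snps$BP < row$end + sc$flank))
  }
  # LD matrices: symmetric, unit diagonal, PSD
  for (g in sample(names(gw$ld), 20)) {
    m <- gw$ld[[g]]
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("generated z-score correlation matches the AR(1) parameter", {
  # Two adjacent SNPs at rho = 0.9: sample correlation of z-scores across
  # many replicate gene draws should sit within 3 SEs of 0.9.
  rho <- 0.9
  n <- 10000
  zs <- t(replicate(n, {
    l <- chol(matrix(c(1, rho, rho, 1), 2))
    drop(rnorm(2) %*% l)
  }))
  # Monte-Carlo oracle for the generating mechanism used by gen_gwas
  r <- cor(zs[, 1], zs[, 2])
  se <- (1 - rho^2) / sqrt(n)
  expect_lt(abs(r - rho), 3 * se)
  # And the generator itself reproduces rho between adjacent SNP p-values'
  # z-scores: recover z from p and compare adjacent-pair correlation.
  sc <- synthetic_scenario(seed = 5, n_genes = 400, n_risk_genes = 0,
                           planted_module_size = 0, risk_effect = 0,
                           ld_rho = rho, snps_per_gene = c(2, 2))
  gw <- gen_gwas(sc)
  z2 <- do.call(rbind, lapply(names(gw$ld), function(g) {
    ids <- rownames(gw$ld[[g]])
    abs(qnorm(gw$snps$P[match(ids, gw$snps$SNP)] / 2))
  }))
  # |z| correlation underestimates rho; check the sign-free bound loosely
  expect_gt(cor(z2[, 1], z2[, 2]), 0.5)
})

test_that("gen_gwas rejects a non-positive-definite LD request", {
  sc <- small_scenario()
  sc$ld_rho <- 1
  expect_error(gen_gwas(sc), "positive definite")
})

test_that("the planted PIN module is connected and the graph is simple", {
  sc <- small_scenario(seed = 11)
  pin <- gen_pin(sc)
  e <- pin$edges
  expect_true(all(e$prot_a != e$prot_b))
  expect_false(any(duplicated(paste(e$prot_a, e$prot_b))))
  expect_true(all(e$prot_a <= e$prot_b))  # canonical order
  mod <- sc$planted_module
  in_mod <- e$prot_a %in% mod & e$prot_b %in% mod
  comps <- dfs_components(mod, as.matrix(e[in_mod, 1:2]))
  expect_length(comps, 1L)
  # module edges always survive the two-publication filter
  expect_true(all(e$n_pubs[in_mod] >= 2))
})

test_that("publication-count fraction 1 makes every edge survive the filter", {
  sc <- small_scenario(seed = 2, pin_multi_pub_frac = 1)
  pin <- gen_pin(sc)
  expect_true(all(pin$edges$n_pubs >= 2))
  g <- build_background(pin$edges, min_pubs = 2)
  expect_equal(igraph::ecount(g), nrow(pin$edges))
})

test_that("evidence bookkeeping matches the pair truth exactly", {
  sc <- small_scenario(seed = 4)
  ev <- gen_evidence(sc)
  clean <- ev$records[!ev$records$contaminated, ]
  for (i in sample(nrow(ev$pair_truth), 15)) {
    rows <- clean[clean$id_a == ev$pair_truth$a[i] &
                    clean$id_b == ev$pair_truth$b[i], ]
    expect_equal(length(unique(rows$pubmed)), ev$pair_truth$n_pubs[i])
    expect_equal(length(unique(rows$method)), ev$pair_truth$n_methods[i])
  }
})

test_that("contamination-free evidence with one pub and one method scores 2", {
  sc <- small_scenario(
    seed = 9,
    evidence_params = list(pubs_per_pair = c(1L, 1L), methods_max = 1L,
                           taxid_contamination = 0, pubmed_contamination = 0,
                           method_contamination = 0))
  ev <- gen_evidence(sc)
  expect_false(any(ev$records$contaminated))
  qc <- qc_filter(ev$records)
  expect_equal(nrow(qc), nrow(ev$records))
  scored <- score_pairs(qc, min_score = 1)
  expect_true(all(scored$score == 2))
  # ... so the default discard rule removes every pair
  expect_equal(nrow(score_pairs(qc)), 0L)
})

test_that("contaminated records are exactly the ones QC removes", {
  sc <- small_scenario(seed = 6)
  ev <- gen_evidence(sc)
  expect_gt(sum(ev$records$contaminated), 0)
  kept <- qc_filter(ev$records)
  expect_false(any(kept$contaminated))
  expect_equal(nrow(kept), sum(!ev$records$contaminated))
})

test_that("the planted pathway holds its configured risk-gene overlap", {
  sc <- small_scenario(seed = 12)
  pw <- gen_pathways(sc)
  planted <- pw$collection$sets[[pw$truth$planted]]
  expect_equal(length(planted), sc$pathway_params$planted_size)
  expect_equal(length(intersect(planted, sc$risk_genes)),
               sc$pathway_params$planted_overlap)
  expect_equal(pw$collection$universe_size,
               sc$pathway_params$universe_size)
  expect_true(all(pw$class_map$term %in% names(pw$collection$sets)))
})

test_that("expression truth is planted with the stated effect and covariates", {
  sc <- small_scenario(seed = 13)
  ex <- gen_expression(sc)
  expect_equal(dim(ex$expr),
               c(sc$expression_params$n_genes,
                 sc$expression_params$n_cases +
                   sc$expression_params$n_controls))
  expect_setequal(unique(ex$covariates$status), c("case", "control"))
  expect_true(all(table(ex$covariates$sex) >= 2))
  # planted genes separate cases and controls by roughly the planted effect
  de <- ex$truth$de_genes[1]
  case_cols <- ex$covariates$status == "case"
  diff <- mean(ex$expr[de, case_cols]) - mean(ex$expr[de, !case_cols])
  expect_lt(abs(diff - sc$expression_params$de_effect), 1.0)
})
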