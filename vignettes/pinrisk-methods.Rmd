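---
title: "Methods: from GWAS summary statistics to a characterized risk-gene network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GWAS summary statistics to a characterized risk-gene network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pinrisk)
```

pinrisk turns SNP-level genome-wide association summary statistics into a
characterized protein-interaction risk-gene network in five statistical
stages, each of which can be run, inspected, and validated on its own. This
vignette states the model behind each stage, the numerical choices made in
the implementation, and what the built-in synthetic scenarios do and do not
emulate.

## 1. Gene-based association test

### Model

For a gene with $k$ SNPs inside its window, the gene statistic is the sum of
1-df chi-square transforms of the SNP p-values:

$$T \;=\; \sum_{i=1}^{k} \chi^2_1\!\left(p_i\right)
      \;=\; \sum_{i=1}^{k} F^{-1}_{\chi^2_1}(1 - p_i).$$

Under the null, SNP z-scores within a gene are correlated through linkage
disequilibrium (LD). The null distribution of $T$ is therefore taken as the
distribution of $\sum_i z_i^2$ with
$\mathbf{z} \sim \mathcal{N}(\mathbf{0}, \Sigma)$, where $\Sigma$ is the
SNP-SNP LD correlation matrix. The gene-level p-value is the Monte-Carlo
tail estimate with the standard add-one correction,

$$\hat p \;=\; \frac{1 + \#\{T^{(b)} \ge T\}}{1 + B},$$

which is never exactly zero and is conservative by construction.

SNPs are assigned to genes by a flanked, half-open window
$[\mathrm{start} - f,\; \mathrm{end} + f)$ with $f = 50$ kb by default, so a
SNP falling between two nearby genes counts toward both — multiplicity is
deliberate, matching how gene-based tests treat shared regulatory regions.

### Numerical choices

- **Simulation, not integration.** The distribution of a correlated
  chi-square sum has no closed form for general $\Sigma$; Monte-Carlo
  sampling via the symmetric eigen square root of $\Sigma$ is exact up to
  sampling error and costs $O(k^2 B)$.
- **Adaptive escalation.** Each gene starts at $10^3$ simulations; genes
  with $\hat p \le 0.1$ escalate to $10^4$, and genes with
  $\hat p \le 0.001$ to $10^6$ (`sims` and `thresholds` arguments). This
  concentrates compute on the genes where tail resolution matters.
- **PSD repair.** Empirical LD matrices can be indefinite after pairwise
  estimation; eigenvalues are floored at a small positive value and the
  matrix is rescaled back to unit diagonal before factorization.
- **p = 0 inputs.** File readers clamp zero p-values to the smallest
  positive double with a warning; the statistic itself refuses
  non-positive p-values so silent infinities cannot propagate.

```{r gene-test}
sc <- synthetic_scenario(seed = 1, n_genes = 40, n_risk_genes = 6,
                         planted_module_size = 4, pin_size = 40)
gw <- gen_gwas(sc)
res <- gene_test(gw$snps, gw$genes, gw$ld, seed = 1,
                 sims = c(1e3, 1e4), thresholds = 0.1)
head(res[order(res$empirical_p), ], 3)
```

## 2. Significant subnetwork and permutation null

The background protein-interaction network (PIN) keeps only edges supported
by at least two publications (`min_pubs = 2`), a reproducibility filter that
removes most single-report false positives at the cost of recall. Genes with
gene-level $p < 0.05$ (strict inequality) induce the significant
subnetwork; its connected components are the candidate risk modules.

Whether the largest component is bigger than chance is judged by a
label-shuffle permutation null: gene p-values are permuted across the
background nodes, the largest significant component is re-extracted, and
the observed size is ranked against `n_perm` replicates.

**Tie handling.** Component sizes are small integers, so ties between the
observed and null sizes are common. Two policies are implemented:

- `ties = "conservative"` (default): $\hat p = (1 + \#\{S^{(b)} \ge
  S\})/(1 + B)$. Every tie counts against the observed value, so reported
  significance is never overstated. Under a true null this makes the tail
  p-value stochastically **larger** than uniform — a deliberate bias toward
  caution.
- `ties = "randomized"`: ties are broken by a uniform random rank. This is
  exactly uniform under the null and is what the calibration tests use;
  it is the right choice when the tail p feeds downstream calibration
  checks rather than a significance claim.

```{r network}
net <- build_background(gen_pin(sc)$edges)
sub <- significant_subnetwork(net, res)
network_components(sub)[, c("n_nodes", "n_edges")]
```

## 3. Evidence-scored interactome

Interaction records pass three QC gates patterned on curated-database
practice: both interactors human (taxid 9606), exactly one PubMed
identifier per record (multi-publication rows are curation artifacts), and
a non-empty detection method. Each protein pair is then scored as

$$\mathrm{score} = \#\text{distinct publications} +
                   \#\text{distinct methods},$$

and pairs with score $\le 2$ — exactly one publication reported by exactly
one method — are discarded (`min_score = 3`). The score is monotone:
adding evidence can only keep or promote a pair, never demote it.

The seed interactome is the seeds plus their first-layer interactors with
all induced edges. A node is an **inter-interactome hub (IIH)** when its
connection degree — the fraction of seeds whose first-layer interactome
contains it — strictly exceeds 0.15. The boundary is exclusive by
definition: bridging exactly 15% of seeds never qualifies. Known
promiscuous binders (e.g. ubiquitin-C) can be passed as `exclusions`; they
stay in the graph but are barred from IIH status. The **core network** is
the IIHs plus their direct interactors with induced edges, and its density
$2E/(V(V-1))$ is ranked against random same-size node subsets of the
interactome.

## 4. Pathway over-representation and block retention

For a candidate set of $n$ genes from a universe of $N$, overlap $k$ with a
pathway of size $K$ is scored by the hypergeometric upper tail
(equivalently, one-tailed Fisher):

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

with fold enrichment $(k/n)/(K/N)$ reported alongside. Bonferroni is the
default adjustment (conservative, appropriate for the small number of
curated pathways tested); Benjamini–Hochberg is available.

```{r fold}
round(fold_enrichment(4, 64, 23, 20650), 2)
```

Enriched terms are grouped into semantic classes and classes into
functional blocks. A block is **retained** in the core network when
strictly more than 12% of its full-network terms re-appear among the
core-network enrichments. Catch-all classes (`general`, `metabolism`,
`enzymes`, `protein modification`, `physiology`) are dropped before
retention is computed, since they are uninformative about the specific
biology of the core.

## 5. Differential expression

Per-gene expression is modeled by ordinary least squares with diagnosis
plus sex, age, and post-mortem interval as covariates:

$$y_g = \beta_0 + \beta_1\,\mathrm{status} + \beta_2\,\mathrm{sex}
       + \beta_3\,\mathrm{age} + \beta_4\,\mathrm{PMI} + \varepsilon.$$

The status coefficient is tested two-sided with the usual $t$ statistic on
residual degrees of freedom. All genes share one design matrix, so the
implementation QR-factorizes it once and sweeps the whole expression matrix
through it. Multiple probes per gene are collapsed to the probe with the
smallest raw p-value (ties: smaller standard error, then probe identifier),
and significance is declared at Benjamini–Hochberg FDR strictly below 0.05.

## The synthetic scenarios

`synthetic_scenario()` plants a known truth through every stage so that
recovery is checkable: risk genes with shifted z-scores under AR(1) LD
($\Sigma_{ij} = \rho^{|i-j|}$, $\rho = 0.8$), a connected module of risk
genes wired into a preferential-attachment PIN, a seed interactome with
planted hubs plus typed contamination for QC to remove, one enriched
pathway overlapping the risk genes, and a differential-expression signal
with realistic covariate effects. Defaults (600 genes, 25 risk genes,
module of 10, 20 seeds, universe of 20,650) were fixed from power
considerations before the validation suite was run, and every generator is
a pure function of `seed`.

What the scenarios **emulate**: LD-correlated test statistics, multi-SNP
genes, scale-free background topology, evidence redundancy and typed
contamination, pathway overlap structure, covariate confounding.

What they **do not** emulate: real LD block structure (AR(1) is a
stylization), population stratification, linkage between neighboring genes'
windows, database-specific identifier chaos beyond the modeled drop
reasons, probe-level microarray noise models, or any real genotype or
expression dataset. Results on synthetic scenarios validate the machinery,
not any biological claim.

## Limitations

- The gene test assumes the supplied LD matrix is the null covariance of
  the z-scores; mis-specified LD (e.g. from a mismatched reference panel)
  biases gene p-values in either direction.
- The permutation null shuffles p-values across nodes, which preserves the
  network but ignores gene length and degree confounding; on real data a
  degree-matched null would be stricter.
- Evidence scoring treats publications and methods as exchangeable units
  of support; it does not weight by method reliability.
- Hypergeometric enrichment assumes genes are sampled exchangeably from
  the universe, ignoring gene-set overlap and gene length bias.
- OLS differential expression with few samples has limited power; the
  package reports honest p-values rather than moderated (shrunken)
  variance estimates.
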