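---
title: "Methods: co-expression networks and eQTL-bridged GWAS enrichment in coexr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks and eQTL-bridged GWAS enrichment in coexr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

coexr implements the transcriptome-organization analysis used for
case-control bulk RNA-seq of post-mortem brain tissue: normalization and
covariate handling, per-gene negative-binomial differential expression,
weighted gene co-expression network analysis (WGCNA), module-trait
correlation, and enrichment of a module's eQTL SNPs among nominally
significant GWAS variants. Every stage is exercised against a synthetic
cohort generator with planted ground truth, so the pipeline's operating
characteristics (calibration, power, recovery) are measurable without any
external data. This vignette documents the models, the tunable parameters,
the numerical choices, and what the simulation does and does not establish
about real data.

## The synthetic cohort model

The generator (`simulate_cohort()`) draws a cohort of 65 cases and 73
controls by default, the configuration of the motivating brain bank cohort,
and produces counts from a log-linear negative-binomial factor model. For
gene $g$ in sample $s$:

$$\log_2 \mu_{gs} = b_g + \lambda_g f_{m(g)}(s) + \beta_{g,\mathrm{batch}(s)}
 + \gamma_g (\mathrm{RIN}_s - \overline{\mathrm{RIN}})
 + \Delta_g \, \mathrm{case}_s,$$

with counts $y_{gs} \sim \mathrm{NB}(\mu_{gs} \cdot L_s/10^6, \alpha)$,
where $L_s$ is a log-normal library size and $\alpha$ the dispersion in the
parameterization $\mathrm{Var} = \mu + \alpha\mu^2$. The pieces are:

* **Baseline abundance** $b_g \sim N(5, 1.5^2)$ on the log2 scale relative
  to a $10^6$ library; configurable (`baseline_log2_mean/sd`) so tests can
  plant genes at a prescribed mean count.
* **Modules.** Genes are partitioned into `n_modules` blocks; each block
  loads on an independent standard-normal factor per sample. Loadings are
  positive, centred at `loading_sd` with 10% spread. The default
  `loading_sd = 0.8` was calibrated so the realized within-module absolute
  correlation is about 0.6 after counting noise — the naive Gaussian value
  (0.6) undershoots because NB sampling adds residual variance on the log
  scale. Positive loadings keep the eigengene orientation (non-negative
  mean member correlation) aligned with the latent factor, so the sign of a
  planted module-trait coupling is recoverable; a module with mixed-sign
  loadings would carry the same unsigned network structure but an
  arbitrary trait-correlation sign.
* **Covariate effects.** Batch shifts $\beta \sim N(0, 0.3^2)$ per gene and
  batch, and per-gene RIN slopes $\gamma \sim N(0, 0.1^2)$ per RIN unit —
  modest technical structure of the kind the residualization and DE design
  are meant to absorb.
* **Traits.** Each trait's latent value is
  $z_t = \sum_m \rho_{mt} f_m + (1 - \sum_m \rho_{mt}^2)^{1/2}\,\epsilon$,
  so the correlation between any module factor and the trait equals the
  configured target in expectation, and several modules can couple to the
  same trait. With a single coupled module this reduces to the familiar
  $z = \rho f + \sqrt{1-\rho^2}\,\epsilon$ construction. Observed scales
  (consumption in g/day, AUDIT score, drinking years) are strictly
  monotone (exponential) transforms of the latent, which leaves Spearman
  correlations untouched; AUDIT is rounded to integer scores, adding mild
  ties. Diagnosis is the thresholded latent, with exactly 65 cases — this
  attenuates the point-biserial correlation by the usual factor
  $\phi(c)/\sqrt{p(1-p)} \approx 0.8$, which is why the default diagnosis
  couplings mirror observed (already attenuated) magnitudes, about
  $-0.28$ and $+0.18$ for the two coupled default modules.
* **Differential expression** is planted in `n_de_genes` genes chosen
  outside the modules (so DE recovery and module recovery can be scored
  independently), at $\pm$`de_log2fc` log2 units, case over control.

The genetics generator (`simulate_genetics()`) gives each gene a Poisson
number of eQTL SNPs (p-values below the `eqtl_p_cap = 5e-8` significance
bound), adds background SNPs with GWAS statistics only, and draws GWAS
p-values Uniform(0,1) except for the eQTL SNPs of one designated module,
which follow $\mathrm{Beta}(a, 1)$ with `enrichment_beta` $= a \le 1$, so
$P(p \le t) = t^a$; $a = 1$ is the exact null and $a = 0.3$ plants strong
polygenic enrichment.

One integer seed fans out to fixed per-stage substreams
(`substream_seeds()`), so identical configurations reproduce bit-identical
cohorts and adding draws to one stage never perturbs another.

**What the generator does not emulate:** linkage disequilibrium among SNPs
(each SNP is independent), cell-type composition shifts, RNA-degradation
gradients beyond a linear RIN slope, gene-gene correlation outside the
planted low-rank blocks, gene length or GC effects, and outlier samples.
Passing recovery tests therefore demonstrate that the algorithms are
implemented correctly and are well-calibrated under the assumed model —
not that the pipeline is robust to every pathology of real post-mortem
tissue data.

## Preprocessing

CPM uses the unfiltered column totals as library sizes, so the filter
cannot feed back into its own normalizer. The low-expression rule keeps
genes with CPM $\ge 1$ in $\ge 50\%$ of samples, both bounds inclusive
(`filter_config()`), the standard "at least 1 CPM in at least half the
cohort" convention. Network input is $\log_2(\mathrm{CPM} + 1)$
residualized by OLS against batch, RIN and age (the network covariate
trio); the DE model instead keeps the raw counts and adjusts inside the
GLM with the fuller design (diagnosis, sex, age, PMI, RIN, batch).

`variance_partition()` is a fixed-effects simplification of mixed-model
variance partitioning: each covariate's marginal (added-last) sum of
squares is computed against the full design, and the attributed fractions
apportion the explained variance proportionally to those marginal sums of
squares. Marginal contributions overlap under collinearity, so the
proportional apportioning is what guarantees the per-gene identity
(fractions + residual = 1) exactly; for orthogonal designs it reduces to
the plain marginal $R^2$. At this cohort scale a mixed model adds
machinery without changing which covariates stand out.

`covariate_group_test()` is the pooled-variance two-sample t-test
($df = n_1 + n_2 - 2$), also callable from printed summary statistics
(`pooled_t_summary()`). Pooled rather than Welch was chosen because it
reproduces the published PMI comparison for the reference cohort's printed
summaries (p = 0.0049; Welch gives 0.0053) — a flag about that table's
likely provenance, not a general endorsement of the equal-variance
assumption.

## Differential expression

Per gene, a negative-binomial log-link GLM is fitted by IRLS at fixed
dispersion with the log library size as offset; the Wald statistic is the
diagnosis coefficient over its standard error, with a two-sided normal
p-value and $\log_2\mathrm{FC} = \hat\beta/\ln 2$ reported case over
control. Numerical settings: initialization from an OLS fit to
$\log(y + 0.5)$, at most 100 iterations, relative deviance tolerance
$10^{-8}$, linear predictor capped at 30 to prevent overflow;
non-converged genes are flagged and their p set to missing.

Dispersions come from a method-of-moments estimator on design-adjusted,
library-size-normalized counts, $\hat\alpha = \max(0,
(s^2 - \bar m)/\bar m^2)$ with the design regressed out by OLS, optionally
(default) blended half-and-half with a lowess mean-dispersion trend across
genes. The shrinkage stabilizes the noisy per-gene moment estimates at
desk-scale gene counts; the outlier filtering and independent filtering of
full-featured DE packages are deliberately not replicated — the target is
simulation calibration (type-I error within binomial noise of nominal at
n = 138, power $\ge 0.8$ for planted log2FC = 1 at $\alpha = 0.1$, mean
100), which the simplified estimator meets. FDR control is
Benjamini-Hochberg throughout.

## Co-expression network

The network follows the canonical WGCNA recipe, re-implemented: Pearson
correlation on the residualized log-CPM matrix; unsigned soft-threshold
adjacency $a_{ij} = |r_{ij}|^\beta$ (signed variant available); power
chosen as the smallest $\beta \in 1..20$ whose scale-free fit index — the
$R^2$ of the log-log regression of connectivity-bin frequency on bin mean
connectivity, counted only when the slope is negative — reaches 0.90, else
the argmax with a warning; topological overlap
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$;
average-linkage clustering on $1-\mathrm{TOM}$.

Two places where the design was genuinely open:

* **Cut height.** The published parameterization (minimum module size 100,
  cutting height 0.99, deepSplit) refers to the dynamic tree-cutting
  algorithm, whose "tree" variant interprets its 0.99 default as a
  fraction of the dendrogram's joining-height range — not an absolute
  dissimilarity. `detect_modules()` adopts that reading: the cut sits at
  the 5th percentile of joining heights plus `cut_height` times the range
  above it. An absolute cut at 0.99 would be scale-dependent: TOM values
  shrink roughly geometrically with $\beta$, so the same 0.99 that works
  at $\beta = 6$ leaves every gene unassigned at $\beta = 14$. The
  relative reading keeps the canonical 0.99 meaningful across powers.
* **Assignment completeness.** A static cut plus minimum-size filter
  reliably finds module cores but strands weak-loading members on
  branches that join above the cut. The dynamic hybrid algorithm handles
  this with a PAM-like assignment stage; coexr provides a light
  counterpart, `assign_by_kme()`: after detection, an unassigned gene is
  attached to the module whose eigengene it correlates with most strongly
  if that absolute correlation reaches `kme_rescue = 0.3` (roughly 3.5
  null standard errors at n = 138, so noise genes essentially never
  attach). Without the rescue, 20-30% of planted-module genes stay grey
  at scan-selected powers and recovery ARI drops from ~1.0 to ~0.6. Set
  `kme_rescue = NA` to disable.

Module eigengenes are the first principal component of the per-gene
standardized member submatrix, unit variance, oriented to non-negative
mean member correlation. Modules whose eigengenes correlate above 0.75
are merged iteratively (at most 10 rounds, average-linkage grouping on
$1 - \mathrm{cor}$). Labels are size-ranked `M1, M2, ...` with ties broken
by lowest gene index; color names are presentation only. Intramodular
connectivity (kME) is the gene-eigengene correlation, and a module's hubs
are its top own-module kME members.

## Module-trait correlation

Spearman rank correlation (Pearson on average ranks, pairwise-complete,
$n \ge 4$) between each eigengene and each alcohol-related trait, with the
two-sided t-approximation p-value
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, $df = n - 2$ — this reproduces the
reference analysis' printed p-values at the printed rho precision
(e.g. $\rho = -0.28$, $n = 138 \Rightarrow p = 8.8\times10^{-4}$, printed
$9.0\times10^{-4}$). Binary diagnosis enters as 0/1 (control = 0), the
rank-biserial special case of Spearman. The Bonferroni flag defaults to
$\alpha / (\text{modules} \times \text{traits})$; the additive
modules-plus-traits divisor seen in the motivating analysis (0.05/31 for
27 modules and 4 traits) can be requested explicitly via `bonferroni_k` —
the arithmetic idiosyncrasy is reproducible but not silently the default.

## eQTL-bridged GWAS enrichment

Gene-SNP pairs with eQTL $p < 5\times10^{-8}$ define each gene's SNP set.
For a module, the 2x2 table splits the SNP universe (union of all mapped
genes' SNPs, intersected with the GWAS table) by module membership — a SNP
counts as a module SNP if *any* of its mapped target genes is in the
module — and by GWAS $p \le 0.05$ (inclusive). Directional Fisher exact
tests use hypergeometric tails: right = over-enrichment
($P(A \ge a)$), left = under-enrichment ($P(A \le a)$); the two-sided p
sums outcomes no more likely than the observed.

The permutation null resamples **gene sets**, not SNPs: each of
`n_permutations` (default 100,000) draws takes a uniform random set of
mapped genes of the module's size, translates it to its SNPs, and scores
the same tailed Fisher p. Resampling genes preserves each gene's eQTL SNP
count and the shared-SNP structure that SNP-level shuffling would destroy;
the published analysis does not state its permutation unit, so this choice
is documented rather than asserted. The empirical p uses the +1
correction, $(1 + \#\{p^{perm} \le p^{obs}\})/(1 + B)$, and is therefore
never zero. Known limitation: no LD pruning — SNPs are treated as
exchangeable tokens, so enrichment driven by a single long haplotype would
be overstated.

A note on calibration checks: the permutation p is uniform under the
exchangeable null to within binomial noise, but the *exact* Fisher p is
conservative by construction (its null CDF steps below uniform by the
point mass $P(A = a)$). Distribution-agreement comparisons between the two
are therefore run on tables dense enough (module of ~100 genes, ~6 eQTL
SNPs per gene) that the point mass is small; at coarser tables the
systematic discreteness, not any implementation defect, dominates the
distance.

## Problem sizes and runtime

The shipped test and acceptance configurations run at desk scale, chosen
as the package's own testing conditions: cohorts of 138 samples; 2000
genes for DE calibration; 300 genes in 5 modules of 60 for network
recovery; 500 mapped genes, ~3 eQTL SNPs per gene and 2000 permutations
per replicate for the enrichment suites (25-200 replicates). All sizes are
configurable; the full published scale (18,463 genes, 100,000
permutations) is a matter of runtime, not algorithm.

## Known limitations

* The Wald test relies on the normal approximation; at very small counts
  or extreme dispersions a likelihood-ratio test would be more accurate.
* The scale-free fit index on strongly modular toy data is an imperfect
  selection criterion — it keeps rising with $\beta$ — which is precisely
  why the detection stage must not depend on the absolute TOM scale (see
  the cut-height discussion above).
* Variance partitioning ignores random effects; batches with very few
  samples will have unstable attributed fractions.
* Missing trait values are propagated (pairwise-complete correlations),
  never imputed.
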