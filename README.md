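# coexr

Whole-transcriptome organization analysis for case-control bulk RNA-seq,
built for cohorts like post-mortem prefrontal cortex in alcohol dependence:
who drives expression differences, which co-expressed gene modules track
alcohol-related traits, and whether a module's regulatory variants carry
genetic association signal.

The pipeline chains five analyses behind one configuration:

1. **Preprocessing** — counts-per-million (CPM) normalization, the
   "≥ 1 CPM in ≥ 50% of samples" low-expression filter, log2-CPM,
   OLS residualization of technical covariates (batch, RIN, age), a
   fixed-effects variance partition, and cohort covariate comparisons
   (pooled two-sample t-tests, also from printed summary statistics).
2. **Differential expression** — per-gene negative-binomial Wald tests
   (log-link GLM by IRLS at fixed method-of-moments dispersion, library
   size offset, design `~ diagnosis + sex + age + pmi + rin + batch`),
   Benjamini–Hochberg FDR and tiered summaries.
3. **Co-expression** — WGCNA-style network construction from scratch:
   soft-threshold power chosen by the scale-free fit index
   (R² ≥ 0.90), unsigned adjacency `|r|^β`, topological overlap
   TOM_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij), average-linkage
   module detection (minimum size 100, cut height 0.99 interpreted on the
   joining-height range), kME-based assignment of stragglers, eigengene
   merging at correlation > 0.75, and intramodular connectivity / hubs.
4. **Module–trait correlation** — Spearman correlation of eigengenes with
   diagnosis, alcohol consumption (g/day), AUDIT score and drinking years;
   two-sided t-approximation p-values and a Bonferroni threshold.
5. **eQTL-bridged GWAS enrichment** — each module's significant eQTL SNPs
   (p < 5×10⁻⁸) tested for over-/under-representation among nominally
   significant GWAS SNPs (p ≤ 0.05) by directional Fisher exact tests,
   with an empirical p from gene-set permutations (default 100,000).

A first-class synthetic-data module generates NB-count cohorts with
planted co-expression modules, planted differential expression,
module-coupled traits and planted eQTL→GWAS enrichment, plus ground-truth
labels — so calibration, power and recovery of every stage are measurable
offline.

## Worked example

```r
library(coexr)

cfg <- pipeline_config(list(
  seed = 1, out_dir = "run1",
  simulate   = list(n_genes = 300, n_modules = 3, module_sizes = rep(60, 3),
                    n_de_genes = 30),
  genetics   = list(enriched_module = "M2", enrichment_beta = 0.3,
                    n_background_snps = 300),
  network    = list(min_module_size = 30),
  enrichment = list(n_permutations = 2000)))
manifest <- run_pipeline(cfg)
str(manifest$metrics)
#> $ de_power_q05             : num 1
#> $ de_type1_at_005          : num 0.0111
#> $ selected_power           : int 12
#> $ n_modules                : int 3
#> $ module_ari               : num 1
#> $ n_module_trait_bonferroni: int 2
#> $ top_enriched_module      : chr "M1"
#> $ top_enrichment_perm_p    : num 5e-04
```

All three planted modules are recovered exactly (adjusted Rand index 1
against the planted labels; the detected labels are size-ranked, so planted
"M2" resurfaces as detected "M1"), all 30 planted DE genes pass q < 0.05
while the null genes reject at ~1%, and the planted-enrichment module tops
the report at the smallest possible permutation p (0.0005 at 2000
permutations):

```r
read.delim(file.path(cfg$out_dir, "enrichment_report.tsv"))
#>   module  a   b  c   d odds_ratio fisher_left fisher_right perm_p
#> 1     M1 62 118 27 693     13.486    1.000000     2.04e-27 0.0005
#> 2     M2  7 180 82 631      0.299    0.000512     1.00e+00 0.9980
#> 3     M3  6 163 83 648      0.287    0.000718     1.00e+00 0.9985
```

Here `a` counts the module's eQTL SNPs that are nominally GWAS-significant
and `b` those that are not; `c`/`d` are the same split for all other mapped
SNPs; `fisher_right` is the over-enrichment tail and `perm_p` the
gene-set-permutation empirical p.

Cohort-table comparisons work straight from printed summaries — e.g. the
post-mortem interval difference between 65 cases and 73 controls:

```r
r <- pooled_t_summary(33.66, 15.59, 65, 26.63, 13.25, 73)
#> t = 2.863, df = 136, p = 0.0049
```

A thin CLI wraps the same stages
(`inst/scripts/coexr run-all --config cfg.yaml --seed 1 --out run1`).

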