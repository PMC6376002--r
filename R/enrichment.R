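#' eQTL-bridged GWAS enrichment configuration
#'
#' @param eqtl_p_threshold eQTL significance bound; gene-SNP pairs with
#'   p below it define the SNP sets (default 5e-8).
#' @param gwas_p_threshold nominal GWAS significance (default 0.05,
#'   inclusive).
#' @param n_permutations random gene sets drawn for the empirical null
#'   (default 100000).
#' @param tail `"right"` (over-enrichment), `"left"` (under-enrichment) or
#'   `"both"`.
#' @param seed integer seed for the permutation stream.
#' @export
enrichment_config <- function(eqtl_p_threshold = 5e-8, gwas_p_threshold = 0.05,
                              n_permutations = 100000,
                              tail = c("right", "left", "both"), seed = 1L) {
  tail <- match.arg(tail)
  if (eqtl_p_threshold <= 0 || eqtl_p_threshold >= 1)
    stop("eqtl_p_threshold must lie in (0, 1)")
  if (gwas_p_threshold <= 0 || gwas_p_threshold >= 1)
    stop("gwas_p_threshold must lie in (0, 1)")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(eqtl_p_threshold = eqtl_p_threshold,
                 gwas_p_threshold = gwas_p_threshold,
                 n_permutations = as.integer(n_permutations), tail = tail,
                 seed = as.integer(seed)),
            class = "enrichment_config")
}

#' Map genes to their significant eQTL SNPs
#'
#' Retains gene-SNP pairs with eQTL p strictly below the threshold and drops
#' genes left with no SNPs.
#'
#' @param eqtl data.frame with columns snp_id, gene_id, p_value.
#' @param cfg an [enrichment_config()].
#' @return named list gene -> character vector of SNP ids.
#' @export
build_gene_snp_map <- function(eqtl, cfg = enrichment_config()) {
  stopifnot(all(c("snp_id", "gene_id", "p_value") %in% names(eqtl)))
  if (any(eqtl$p_value < 0 | eqtl$p_value > 1)) stop("eQTL p-values out of [0, 1]")
  keep <- eqtl$p_value < cfg$eqtl_p_threshold
  lapply(split(eqtl$snp_id[keep], eqtl$gene_id[keep]), unique)
}

#' Build the module-vs-GWAS 2x2 contingency table
#'
#' The SNP universe is the union of all mapped genes' SNPs intersected with
#' the GWAS table. A SNP counts as a module SNP when at least one of its
#' mapped target genes belongs to the module (any-target rule); each SNP is
#' counted once. Cells: a = module SNPs with GWAS p <= threshold, b = module
#' SNPs above, c/d likewise for non-module SNPs.
#'
#' @param map gene -> SNP sets from [build_gene_snp_map()].
#' @param module_genes character vector of module member genes.
#' @param gwas data.frame with columns snp_id, p_value.
#' @param cfg an [enrichment_config()].
#' @return named integer vector (a, b, c, d) of class `contingency_2x2`.
#' @export
build_contingency <- function(map, module_genes, gwas, cfg = enrichment_config()) {
  mapped <- names(map)
  inter <- intersect(module_genes, mapped)
  universe <- intersect(unique(unlist(map, use.names = FALSE)), gwas$snp_id)
  if (length(universe) == 0)
    stop("empty SNP universe (mapped genes: ", length(mapped),
         ", GWAS SNPs: ", nrow(gwas), ")")
  if (length(inter) == 0)
    stop("no module genes with significant eQTLs (module: ",
         length(module_genes), ", mapped: ", length(mapped), ")")
  sig <- stats::setNames(gwas$p_value <= cfg$gwas_p_threshold, gwas$snp_id)[universe]
  mod_snps <- intersect(unique(unlist(map[inter], use.names = FALSE)), universe)
  is_mod <- universe %in% mod_snps
  a <- sum(sig & is_mod); b <- sum(!sig & is_mod)
  c_ <- sum(sig & !is_mod); d <- sum(!sig & !is_mod)
  structure(c(a = a, b = b, c = c_, d = d), class = "contingency_2x2")
}

## Vectorized hypergeometric tail probabilities for tables that share the
## column margin: a = module significant, m = module total, k = significant
## total, n_tot = universe. Used by both fisher_exact and the permutations.
hyper_tail_p <- function(a, m, n2, k, tail) {
  switch(tail,
         right = stats::phyper(a - 1, m, n2, k, lower.tail = FALSE),
         left = stats::phyper(a, m, n2, k),
         stop("tail must be 'right' or 'left'"))
}

#' Fisher exact test for a 2x2 table
#'
#' Hypergeometric tail probabilities at fixed margins: right tail
#' `P(A >= a)` (over-enrichment), left tail `P(A <= a)`
#' (under-enrichment); the two-sided p sums the probabilities of all
#' outcomes no more likely than the observed one. Degenerate margins (a
#' zero row or column) return p = 1 with attribute `degenerate = TRUE`.
#'
#' @param tbl length-4 vector (a, b, c, d) or 2x2 matrix.
#' @param tail `"right"`, `"left"` or `"both"`.
#' @return the p-value.
#' @export
fisher_exact <- function(tbl, tail = c("right", "left", "both")) {
  tail <- match.arg(tail)
  x <- as.integer(tbl)
  if (length(x) != 4 || any(x < 0)) stop("need a 2x2 table of non-negative counts")
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  m <- a + b; n2 <- c_ + d; k <- a + c_
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0)
    return(structure(1, degenerate = TRUE))
  if (tail != "both") return(unname(hyper_tail_p(a, m, n2, k, tail)))
  support <- max(0, k - n2):min(k, m)
  dens <- stats::dhyper(support, m, n2, k)
  ## relative tolerance as in the classical implementation, so ties in the
  ## point probabilities are included
  sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
}

#' Odds ratio of a 2x2 table
#'
#' `(a d) / (b c)`; returns `NA` with attribute `undefined = TRUE` when the
#' denominator is zero.
#'
#' @param tbl length-4 vector (a, b, c, d).
#' @export
odds_ratio <- function(tbl) {
  x <- as.numeric(tbl)
  if (x[2] * x[3] == 0) return(structure(NA_real_, undefined = TRUE))
  (x[1] * x[4]) / (x[2] * x[3])
}

#' Permutation test of eQTL-GWAS enrichment for one module
#'
#' The observed statistic is the tailed Fisher p of the observed table. The
#' null resamples gene sets: `n_permutations` random sets of the same size
#' as the module's mapped genes are drawn uniformly without replacement from
#' all mapped genes, each set is translated to its SNPs (preserving each
#' gene's eQTL SNP structure) and scored with the same tailed Fisher p. The
#' empirical p-value is `(1 + #{permuted p <= observed p}) / (1 +
#' n_permutations)`, so it is never zero.
#'
#' @param map gene -> SNP sets from [build_gene_snp_map()].
#' @param module_genes module member genes.
#' @param gwas GWAS table (snp_id, p_value).
#' @param cfg an [enrichment_config()].
#' @param module optional module label for reporting.
#' @param gwas_name optional GWAS dataset label for reporting.
#' @return list of class `enrichment_result`: module, gwas_name, table,
#'   odds_ratio, fisher_p_left, fisher_p_right, fisher_p_observed,
#'   permutation_p, n_permutations, tail, seed.
#' @export
permutation_enrichment <- function(map, module_genes, gwas,
                                   cfg = enrichment_config(),
                                   module = "module", gwas_name = "gwas") {
  tbl <- build_contingency(map, module_genes, gwas, cfg)
  mapped <- names(map)
  inter <- intersect(module_genes, mapped)
  size <- length(inter)
  if (size > length(mapped))
    stop("module size exceeds the mapped-gene count")

  universe <- intersect(unique(unlist(map, use.names = FALSE)), gwas$snp_id)
  sig <- stats::setNames(gwas$p_value <= cfg$gwas_p_threshold, gwas$snp_id)[universe]
  n_tot <- length(universe)
  k_sig <- sum(sig)
  ## integer-index SNP sets for fast unions inside the permutation loop
  sets <- lapply(map, function(s) match(intersect(s, universe), universe))

  obs_p <- if (cfg$tail == "both") fisher_exact(tbl, "both")
           else unname(hyper_tail_p(tbl[1], tbl[1] + tbl[2],
                                    n_tot - tbl[1] - tbl[2], k_sig, cfg$tail))

  set.seed(cfg$seed)
  B <- cfg$n_permutations
  a_perm <- m_perm <- integer(B)
  for (i in seq_len(B)) {
    snps <- unique(unlist(sets[sample.int(length(sets), size)], use.names = FALSE))
    m_perm[i] <- length(snps)
    a_perm[i] <- sum(sig[snps])
  }
  perm_p <- if (cfg$tail == "both") {
    vapply(seq_len(B), function(i) {
      fisher_exact(c(a_perm[i], m_perm[i] - a_perm[i],
                     k_sig - a_perm[i],
                     n_tot - m_perm[i] - k_sig + a_perm[i]), "both")
    }, numeric(1))
  } else {
    hyper_tail_p(a_perm, m_perm, n_tot - m_perm, k_sig, cfg$tail)
  }
  empirical <- (1 + sum(perm_p <= obs_p)) / (1 + B)

  structure(list(module = module, gwas_name = gwas_name, table = tbl,
                 odds_ratio = odds_ratio(tbl),
                 fisher_p_left = fisher_exact(tbl, "left"),
                 fisher_p_right = fisher_exact(tbl, "right"),
                 fisher_p_observed = obs_p, permutation_p = empirical,
                 n_permutations = B, tail = cfg$tail, seed = cfg$seed),
            class = "enrichment_result")
}

#' Tabulate enrichment results across modules and GWAS datasets
#'
#' @param results list of `enrichment_result` objects.
#' @return data.frame sorted by permutation p ascending: module, gwas_name,
#'   a, b, c, d, odds_ratio, fisher_left, fisher_right, perm_p, n_perm,
#'   seed.
#' @export
enrichment_report <- function(results) {
  if (length(results) == 0) stop("need at least one enrichment result")
  rows <- lapply(results, function(r) {
    data.frame(module = r$module, gwas_name = r$gwas_name,
               a = r$table[1], b = r$table[2], c = r$table[3], d = r$table[4],
               odds_ratio = as.numeric(r$odds_ratio),
               fisher_left = as.numeric(r$fisher_p_left),
               fisher_right = as.numeric(r$fisher_p_right),
               perm_p = r$permutation_p, n_perm = r$n_permutations,
               seed = r$seed, row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$perm_p), , drop = FALSE]
}
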