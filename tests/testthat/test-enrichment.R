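toy_eqtl <- function() {
  data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    gene_id = c("gA", "gA", "gB", "gC", "gD"),
    p_value = c(1e-9, 0.5, 4e-8, 0.2, 1e-10),
    stringsAsFactors = FALSE)
}

test_that("gene-SNP map keeps only significant eQTL pairs", {
  map <- build_gene_snp_map(toy_eqtl())
  expect_identical(sort(names(map)), c("gA", "gB", "gD"))
  expect_identical(map$gA, "rs1")
  expect_identical(map$gB, "rs3")
  ## all-nonsignificant table gives an empty map
  e <- toy_eqtl(); e$p_value <- 0.5
  expect_length(build_gene_snp_map(e), 0)
  ## raising the threshold never shrinks a gene's set
  map_hi <- build_gene_snp_map(toy_eqtl(), enrichment_config(eqtl_p_threshold = 0.3))
  for (g in names(map)) expect_true(all(map[[g]] %in% map_hi[[g]]))
})

test_that("contingency table matches exhaustive hand enumeration", {
  ## 6 SNPs: rs1-rs3 map to module genes (rs1, rs2 GWAS-significant),
  ## rs4-rs6 map only to non-module genes (rs4 significant)
  map <- list(gA = c("rs1", "rs2"), gB = "rs3",
              gC = c("rs4", "rs5"), gD = "rs6")
  gwas <- data.frame(snp_id = paste0("rs", 1:6),
                     p_value = c(0.01, 0.05, 0.5, 0.001, 0.9, 0.4))
  tbl <- build_contingency(map, c("gA", "gB"), gwas)
  expect_equal(unclass(tbl), c(a = 2L, b = 1L, c = 1L, d = 2L), ignore_attr = TRUE)
  ## module covering all mapped genes empties the non-module cells
  tbl2 <- build_contingency(map, c("gA", "gB", "gC", "gD"), gwas)
  expect_equal(unname(tbl2[3] + tbl2[4]), 0)
  ## no significant GWAS SNP empties the significant column
  gwas0 <- gwas; gwas0$p_value <- 0.9
  tbl3 <- build_contingency(map, c("gA", "gB"), gwas0)
  expect_equal(unname(tbl3[1] + tbl3[3]), 0)
  ## a SNP shared by module and non-module genes counts as module (any-target)
  map_shared <- list(gA = "rs1", gC = "rs1")
  tbl4 <- build_contingency(map_shared, "gA",
                            data.frame(snp_id = "rs1", p_value = 0.01))
  expect_equal(unname(tbl4[1]), 1)
  expect_error(build_contingency(map, "gZ", gwas), "no module genes")
})

test_that("Fisher tails match the enumeration oracle and fisher.test", {
  set.seed(30)
  for (rep in 1:200) {
    tbl <- as.integer(sample(0:30, 4, replace = TRUE))
    for (tail in c("right", "left", "both")) {
      expect_equal(as.numeric(fisher_exact(tbl, tail)),
                   fisher_oracle(tbl[1], tbl[2], tbl[3], tbl[4], tail),
                   tolerance = 1e-10)
    }
    ## cross-check against the standard implementation where defined
    if (all(tbl > 0)) {
      m <- matrix(tbl, 2, byrow = TRUE)
      expect_equal(fisher_exact(tbl, "right"),
                   fisher.test(m, alternative = "greater")$p.value,
                   tolerance = 1e-9)
      expect_equal(fisher_exact(tbl, "left"),
                   fisher.test(m, alternative = "less")$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("Fisher degenerate margins return 1 and tails are complementary", {
  expect_equal(as.numeric(fisher_exact(c(0, 0, 3, 5), "right")), 1)
  expect_true(attr(fisher_exact(c(2, 3, 0, 0), "both"), "degenerate"))
  set.seed(31)
  for (rep in 1:50) {
    tbl <- as.integer(sample(1:20, 4, replace = TRUE))
    a <- tbl[1]; m <- tbl[1] + tbl[2]; n2 <- tbl[3] + tbl[4]; k <- tbl[1] + tbl[3]
    lhs <- fisher_exact(tbl, "left") + fisher_exact(tbl, "right") -
      dhyper(a, m, n2, k)
    expect_equal(lhs, 1, tolerance = 1e-12)
  }
})

test_that("odds ratio handles zero denominators", {
  expect_equal(odds_ratio(c(4, 2, 1, 3)), 6)
  or <- odds_ratio(c(4, 0, 1, 3))
  expect_true(is.na(or) && attr(or, "undefined"))
})

test_that("permutation p is 1 when the module is the whole mapped set, and seeded", {
  sim <- simulate_cohort(sim_cohort_config(n_genes = 100, n_modules = 1,
                                           module_sizes = 40, n_de_genes = 0,
                                           seed = 9))
  gen <- simulate_genetics(rownames(sim$counts), sim$truth,
                           sim_genetics_config(n_background_snps = 50, seed = 10))
  map <- build_gene_snp_map(gen$eqtl)
  cfg <- enrichment_config(n_permutations = 200, seed = 12)
  r_all <- permutation_enrichment(map, names(map), gen$gwas, cfg)
  expect_equal(r_all$permutation_p, 1)
  ## determinism under a fixed seed
  mod <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene %in% "M1"]
  r1 <- permutation_enrichment(map, mod, gen$gwas, cfg)
  r2 <- permutation_enrichment(map, mod, gen$gwas, cfg)
  expect_identical(r1$permutation_p, r2$permutation_p)
  expect_gte(r1$permutation_p, 1 / 201)
})

test_that("planted depletion is caught by the left tail", {
  hits <- vapply(1:15, function(s) {
    sim <- simulate_cohort(sim_cohort_config(n_genes = 500, n_modules = 5,
                                             module_sizes = rep(50, 5),
                                             n_de_genes = 0, seed = 7000 + s))
    gen <- simulate_genetics(rownames(sim$counts), sim$truth,
                             sim_genetics_config(mean_eqtls_per_gene = 3,
                                                 n_background_snps = 0,
                                                 seed = 7100 + s))
    ## enrich everything except module M1: GWAS signal everywhere else
    mod <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene %in% "M1"]
    out <- gen$eqtl$gene_id %in% setdiff(names(build_gene_snp_map(gen$eqtl)), mod)
    snps_out <- gen$eqtl$snp_id[out]
    set.seed(7200 + s)
    idx <- match(snps_out, gen$gwas$snp_id)
    gen$gwas$p_value[idx] <- runif(length(idx))^(1 / 0.3)
    map <- build_gene_snp_map(gen$eqtl)
    r <- permutation_enrichment(map, mod, gen$gwas,
                                enrichment_config(n_permutations = 1000,
                                                  tail = "left", seed = 7300 + s))
    r$permutation_p <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("enrichment report ranks modules by permutation p", {
  sim <- simulate_cohort(sim_cohort_config(n_genes = 300, n_modules = 3,
                                           module_sizes = rep(60, 3),
                                           n_de_genes = 0, seed = 14))
  gen <- simulate_genetics(rownames(sim$counts), sim$truth,
                           sim_genetics_config(mean_eqtls_per_gene = 3,
                                               enriched_module = "M2",
                                               enrichment_beta = 0.3, seed = 15))
  map <- build_gene_snp_map(gen$eqtl)
  results <- lapply(c("M1", "M2", "M3"), function(m) {
    mod <- names(sim$truth$module_of_gene)[sim$truth$module_of_gene %in% m]
    permutation_enrichment(map, mod, gen$gwas,
                           enrichment_config(n_permutations = 500, seed = 16),
                           module = m, gwas_name = "sim_gwas")
  })
  rep_tbl <- enrichment_report(results)
  expect_identical(rep_tbl$module[1], "M2")
  expect_true(!is.unsorted(rep_tbl$perm_p))
  expect_identical(names(rep_tbl),
                   c("module", "gwas_name", "a", "b", "c", "d", "odds_ratio",
                     "fisher_left", "fisher_right", "perm_p", "n_perm", "seed"))
})
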