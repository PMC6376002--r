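#' Configuration for the synthetic case-control cohort
#'
#' The generator emulates a post-mortem prefrontal-cortex RNA-seq cohort of
#' 65 alcohol-dependent cases and 73 controls: negative-binomial counts on a
#' log-linear scale with planted low-rank co-expression modules, sequencing
#' batch and RIN effects, planted differentially expressed genes, and
#' alcohol-related traits (DSM-IV diagnosis, consumption in g/day, AUDIT
#' score, drinking years) coupled to module factors at configurable Spearman
#' targets. Defaults give a desk-scale cohort (2000 genes) whose per-gene
#' abundances, dispersions and covariate effect sizes are realistic for bulk
#' brain RNA-seq.
#'
#' @param n_cases,n_controls cohort arm sizes (defaults 65 and 73).
#' @param n_genes total number of genes simulated.
#' @param n_modules number of planted co-expression modules.
#' @param module_sizes integer vector of genes per module (sums to at most
#'   `n_genes`).
#' @param loading_sd factor-loading scale on the log2 scale; the default 0.8
#'   yields within-module absolute correlations near 0.6 at the default
#'   dispersion and abundance (counting noise adds to the residual variance,
#'   so the loading must exceed the naive Gaussian calibration).
#' @param trait_module_rho numeric matrix (`n_modules` rows, 4 columns named
#'   `diagnosis`, `alcohol_consumption`, `audit`, `drinking_years`) of target
#'   correlations between each module's latent factor and each trait. The
#'   default couples module M1 negatively (-0.28, -0.22, -0.25, 0) and module
#'   M2 positively (0.18, 0.14, 0.12, 0), with a third module tied to
#'   drinking years (-0.24), matching the magnitudes reported for
#'   alcohol-dependence module-trait correlations in post-mortem cohorts.
#' @param n_de_genes number of planted differentially expressed genes
#'   (drawn from genes outside modules so DE and module recovery can be
#'   scored independently).
#' @param de_log2fc absolute log2 fold change (case over control) planted in
#'   DE genes; signs alternate at random.
#' @param nb_dispersion negative-binomial dispersion alpha (>0), so
#'   var = mu + alpha * mu^2.
#' @param batch_count number of sequencing batches.
#' @param batch_log2_shift_sd per-gene, per-batch log2 shift SD.
#' @param rin_slope_sd per-gene log2 slope SD per RIN unit.
#' @param libsize_log_mean,libsize_log_sd log-normal library size parameters.
#' @param baseline_log2_mean,baseline_log2_sd distribution of baseline
#'   abundance on the log2-CPM scale.
#' @param seed integer seed; one seed fans out to per-stage substreams.
#' @return a validated `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(n_cases = 65, n_controls = 73, n_genes = 2000,
                              n_modules = 5, module_sizes = rep(60L, n_modules),
                              loading_sd = 0.8, trait_module_rho = NULL,
                              n_de_genes = 100, de_log2fc = 1,
                              nb_dispersion = 0.1, batch_count = 2,
                              batch_log2_shift_sd = 0.3, rin_slope_sd = 0.1,
                              libsize_log_mean = log(1e6), libsize_log_sd = 0.2,
                              baseline_log2_mean = 5, baseline_log2_sd = 1.5,
                              seed = 1L) {
  if (n_modules == 0) module_sizes <- integer(0)
  if (is.null(trait_module_rho)) trait_module_rho <- default_trait_couplings(n_modules)
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes), loading_sd = loading_sd,
              trait_module_rho = trait_module_rho, n_de_genes = as.integer(n_de_genes),
              de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
              batch_count = as.integer(batch_count),
              batch_log2_shift_sd = batch_log2_shift_sd, rin_slope_sd = rin_slope_sd,
              libsize_log_mean = libsize_log_mean, libsize_log_sd = libsize_log_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd, seed = as.integer(seed))
  if (any(c(cfg$n_cases, cfg$n_controls, cfg$n_genes, cfg$n_de_genes,
            cfg$batch_count) < 0))
    stop("configuration error: counts must be non-negative")
  if (length(cfg$module_sizes) != cfg$n_modules)
    stop("configuration error: module_sizes length must equal n_modules")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("configuration error: module sizes exceed n_genes")
  if (cfg$nb_dispersion <= 0)
    stop("configuration error: nb_dispersion must be > 0")
  if (cfg$n_modules > 0) {
    if (!is.matrix(cfg$trait_module_rho) ||
        nrow(cfg$trait_module_rho) != cfg$n_modules)
      stop("configuration error: trait_module_rho must have n_modules rows")
    if (any(abs(cfg$trait_module_rho) > 1))
      stop("configuration error: trait_module_rho entries must lie in [-1, 1]")
    if (any(colSums(cfg$trait_module_rho^2) > 1))
      stop("configuration error: per-trait squared couplings must sum to <= 1")
  }
  class(cfg) <- "sim_cohort_config"
  cfg
}

sim_trait_names <- c("diagnosis", "alcohol_consumption", "audit", "drinking_years")

default_trait_couplings <- function(n_modules) {
  m <- matrix(0, nrow = max(n_modules, 0), ncol = 4,
              dimnames = list(NULL, sim_trait_names))
  if (n_modules >= 1) m[1, ] <- c(-0.28, -0.22, -0.25, 0)
  if (n_modules >= 2) m[2, ] <- c(0.18, 0.14, 0.12, 0)
  if (n_modules >= 3) m[3, ] <- c(0, 0, 0, -0.24)
  m
}

#' Simulate a case-control RNA-seq cohort with planted structure
#'
#' Counts follow a log-linear negative-binomial factor model: for gene g in
#' sample s, `log2 mu = baseline_g + lambda_g * f_m(s) + batch shift +
#' rin slope * (RIN_s - mean RIN) + log2FC * case_s`, scaled by a log-normal
#' library size, with NB sampling at the configured dispersion. Module
#' factors are standard normal across samples; each trait's latent value is
#' the coupling-weighted sum of module factors plus independent noise so its
#' correlation with each factor matches the configured target in expectation.
#' Case status is obtained by thresholding its latent at the configured case
#' fraction (exactly `n_cases` cases).
#'
#' @param config a [sim_cohort_config()].
#' @return a list with elements `counts` (integer gene x sample matrix),
#'   `samples` (data.frame of phenotypes/covariates) and `truth`
#'   (planted module labels, DE effects, trait couplings).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_cohort_config"))
  cfg <- config
  n <- cfg$n_cases + cfg$n_controls
  seeds <- substream_seeds(cfg$seed, 4L)

  ## --- sample-level covariates and traits -------------------------------
  set.seed(seeds[1])
  sample_ids <- sprintf("s%03d", seq_len(n))
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  factors <- matrix(stats::rnorm(n * max(cfg$n_modules, 1)), nrow = n)
  if (cfg$n_modules == 0) factors <- factors[, 0, drop = FALSE]
  colnames(factors) <- if (cfg$n_modules > 0) paste0("M", seq_len(cfg$n_modules))

  trait_z <- sapply(sim_trait_names, function(tr) {
    rho <- if (cfg$n_modules > 0) cfg$trait_module_rho[, tr] else numeric(0)
    sig <- sqrt(max(0, 1 - sum(rho^2)))
    drop(factors %*% rho) + sig * stats::rnorm(n)
  })

  ## diagnosis: threshold the latent so exactly n_cases samples are cases
  case <- rank(-trait_z[, "diagnosis"], ties.method = "first") <= cfg$n_cases
  diagnosis <- factor(ifelse(case, "case", "control"),
                      levels = c("control", "case"))

  sex <- ifelse(stats::runif(n) < ifelse(case, 0.78, 0.82), "M", "F")
  age <- stats::rnorm(n, mean = ifelse(case, 55.65, 54.96),
                      sd = ifelse(case, 11.81, 12.11))
  pmi <- pmax(1, stats::rnorm(n, mean = ifelse(case, 33.66, 26.63),
                              sd = ifelse(case, 15.59, 13.25)))
  rin <- pmin(10, pmax(5.5, stats::rnorm(n, mean = ifelse(case, 6.84, 7.0),
                                         sd = ifelse(case, 0.96, 1.01))))
  brain_ph <- stats::rnorm(n, mean = ifelse(case, 6.54, 6.58),
                           sd = ifelse(case, 0.23, 0.29))
  batch <- factor(paste0("b", sample.int(cfg$batch_count, n, replace = TRUE)))

  samples <- data.frame(
    sample_id = sample_ids, diagnosis = diagnosis, sex = factor(sex),
    age = round(age, 2), pmi = round(pmi, 2), rin = round(rin, 2),
    brain_ph = round(brain_ph, 2), batch = batch,
    ## strictly monotone maps latent -> observed scale, so Spearman targets
    ## survive the change of scale exactly (AUDIT rounding adds mild ties)
    alcohol_consumption = round(60 * exp(0.6 * trait_z[, "alcohol_consumption"]), 1),
    audit = pmin(40L, pmax(0L, as.integer(round(15 + 7 * trait_z[, "audit"])))),
    drinking_years = round(20 * exp(0.4 * trait_z[, "drinking_years"]), 1),
    stringsAsFactors = FALSE)

  ## --- gene-level parameters --------------------------------------------
  set.seed(seeds[2])
  module_of_gene <- rep(NA_character_, cfg$n_genes)
  idx <- 0L
  for (m in seq_len(cfg$n_modules)) {
    module_of_gene[idx + seq_len(cfg$module_sizes[m])] <- paste0("M", m)
    idx <- idx + cfg$module_sizes[m]
  }
  names(module_of_gene) <- gene_ids

  loadings <- numeric(cfg$n_genes)
  in_mod <- !is.na(module_of_gene)
  ## positive loadings centred at loading_sd with 10% spread: keeps
  ## within-module correlations near the nominal target, and keeps the
  ## eigengene orientation (positive mean member correlation) aligned with
  ## the latent factor so trait-coupling signs are recoverable
  loadings[in_mod] <-
    abs(stats::rnorm(sum(in_mod), mean = cfg$loading_sd, sd = 0.1 * cfg$loading_sd))

  free <- which(!in_mod)
  if (cfg$n_de_genes > length(free))
    stop("configuration error: n_de_genes exceeds the number of non-module genes")
  de_idx <- sort(sample(free, cfg$n_de_genes))
  de_lfc <- sample(c(-1, 1), cfg$n_de_genes, replace = TRUE) * cfg$de_log2fc
  names(de_lfc) <- gene_ids[de_idx]

  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  batch_shift <- matrix(stats::rnorm(cfg$n_genes * cfg$batch_count,
                                     sd = cfg$batch_log2_shift_sd),
                        nrow = cfg$n_genes)
  rin_slope <- stats::rnorm(cfg$n_genes, sd = cfg$rin_slope_sd)

  ## --- assemble log2 means and sample counts ----------------------------
  set.seed(seeds[3])
  libsize <- stats::rlnorm(n, cfg$libsize_log_mean, cfg$libsize_log_sd)

  log2mu <- matrix(baseline, nrow = cfg$n_genes, ncol = n)
  if (cfg$n_modules > 0) {
    lam <- matrix(0, nrow = cfg$n_genes, ncol = cfg$n_modules)
    for (m in seq_len(cfg$n_modules))
      lam[which(module_of_gene == paste0("M", m)), m] <- 1
    log2mu <- log2mu + (lam * loadings) %*% t(factors)
  }
  log2mu <- log2mu + batch_shift[, as.integer(batch), drop = FALSE]
  log2mu <- log2mu + outer(rin_slope, rin - mean(rin))
  log2mu[de_idx, ] <- log2mu[de_idx, ] + outer(de_lfc, as.numeric(case))

  mu <- 2^log2mu * rep(libsize / 1e6, each = cfg$n_genes)

  set.seed(seeds[4])
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = cfg$n_genes,
                   dimnames = list(gene_ids, sample_ids))
  storage.mode(counts) <- "integer"

  truth <- list(module_of_gene = module_of_gene, de_genes = de_lfc,
                trait_couplings = cfg$trait_module_rho,
                module_factors = factors, enriched_module = NA_character_)
  list(counts = counts, samples = samples, truth = truth)
}

#' Configuration for synthetic eQTL and GWAS summary tables
#'
#' @param mean_eqtls_per_gene Poisson mean number of significant eQTL SNPs
#'   per gene.
#' @param n_background_snps SNPs with GWAS statistics but no significant eQTL.
#' @param enriched_module module label whose eQTL SNPs carry enriched GWAS
#'   signal, or `NA` for none.
#' @param enrichment_beta shape a of the Beta(a, 1) distribution for GWAS
#'   p-values of enriched-module eQTL SNPs; 1 is the null (uniform), smaller
#'   is stronger enrichment.
#' @param eqtl_p_cap upper bound for significant eQTL p-values
#'   (default 5e-8, the genome-wide eQTL significance threshold).
#' @param seed integer seed.
#' @export
sim_genetics_config <- function(mean_eqtls_per_gene = 3, n_background_snps = 1000,
                                enriched_module = NA_character_,
                                enrichment_beta = 1, eqtl_p_cap = 5e-8,
                                seed = 1L) {
  cfg <- list(mean_eqtls_per_gene = mean_eqtls_per_gene,
              n_background_snps = as.integer(n_background_snps),
              enriched_module = enriched_module,
              enrichment_beta = enrichment_beta, eqtl_p_cap = eqtl_p_cap,
              seed = as.integer(seed))
  if (cfg$mean_eqtls_per_gene < 0)
    stop("configuration error: mean_eqtls_per_gene must be >= 0")
  if (cfg$enrichment_beta <= 0 || cfg$enrichment_beta > 1)
    stop("configuration error: enrichment_beta must lie in (0, 1]")
  if (cfg$eqtl_p_cap <= 0)
    stop("configuration error: eqtl_p_cap must be > 0")
  class(cfg) <- "sim_genetics_config"
  cfg
}

#' Simulate eQTL and GWAS summary statistics with optional planted enrichment
#'
#' Each gene receives a Poisson number of eQTL SNPs with p-values below
#' `eqtl_p_cap`; background SNPs carry GWAS statistics only. GWAS p-values
#' are Uniform(0, 1) everywhere except the eQTL SNPs of the enriched module,
#' which follow Beta(`enrichment_beta`, 1), so
#' `P(p <= t) = t^enrichment_beta`.
#'
#' @param gene_ids character vector of genes in the expression universe.
#' @param truth a `truth` list from [simulate_cohort()] (for module labels).
#' @param config a [sim_genetics_config()].
#' @return list with `eqtl` (snp_id, gene_id, p_value), `gwas`
#'   (snp_id, p_value) and the updated `truth` with `enriched_module` set.
#' @export
simulate_genetics <- function(gene_ids, truth, config) {
  stopifnot(inherits(config, "sim_genetics_config"))
  if (length(gene_ids) == 0) stop("gene_ids must be nonempty")
  cfg <- config
  seeds <- substream_seeds(cfg$seed, 2L)

  set.seed(seeds[1])
  n_snps <- stats::rpois(length(gene_ids), cfg$mean_eqtls_per_gene)
  gene_rep <- rep(gene_ids, n_snps)
  total <- sum(n_snps)
  snp_ids <- sprintf("rs%06d", seq_len(total))
  eqtl <- data.frame(snp_id = snp_ids, gene_id = gene_rep,
                     p_value = stats::runif(total, 0, cfg$eqtl_p_cap),
                     stringsAsFactors = FALSE)

  set.seed(seeds[2])
  bg_ids <- if (cfg$n_background_snps > 0)
    sprintf("bg%06d", seq_len(cfg$n_background_snps)) else character(0)
  all_ids <- c(snp_ids, bg_ids)
  p <- stats::runif(length(all_ids))
  if (!is.na(cfg$enriched_module)) {
    enriched_genes <- names(truth$module_of_gene)[
      !is.na(truth$module_of_gene) & truth$module_of_gene == cfg$enriched_module]
    hit <- eqtl$snp_id[eqtl$gene_id %in% enriched_genes]
    ## Beta(a, 1) via inverse CDF: U^(1/a)
    p[match(hit, all_ids)] <- stats::runif(length(hit))^(1 / cfg$enrichment_beta)
  }
  gwas <- data.frame(snp_id = all_ids, p_value = p, stringsAsFactors = FALSE)
  truth$enriched_module <- cfg$enriched_module
  list(eqtl = eqtl, gwas = gwas, truth = truth)
}
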