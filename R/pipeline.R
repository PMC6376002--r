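#' Assemble (or load) a pipeline configuration
#'
#' Nested sections mirror the stage configurations: `simulate` (cohort),
#' `genetics`, `filter`, `de`, `network`, `module_trait`, `enrichment`,
#' plus `seed`, `out_dir`, `stages` (enable flags) and optional input file
#' paths (`counts`, `samples`, `gwas`, `eqtl`) used when simulation is
#' disabled. Unknown keys are rejected.
#'
#' @param config a named list, or a path to a YAML file holding one.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "stages", "simulate", "genetics", "filter",
             "de", "network", "module_trait", "enrichment", "inputs")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  seed <- config$seed %||% 1L
  stages_default <- list(simulate = TRUE, filter = TRUE, varpart = TRUE,
                         de = TRUE, network = TRUE, module_trait = TRUE,
                         enrichment = TRUE)
  stages <- utils::modifyList(stages_default, config$stages %||% list())

  cohort_args <- config$simulate %||% list()
  if (is.null(cohort_args$seed)) cohort_args$seed <- seed
  genetics_args <- config$genetics %||% list()
  if (is.null(genetics_args$seed)) genetics_args$seed <- seed + 1L
  enrich_args <- config$enrichment %||% list()
  if (is.null(enrich_args$seed)) enrich_args$seed <- seed + 2L

  structure(list(
    seed = as.integer(seed),
    out_dir = config$out_dir %||% tempfile("coexr_run_"),
    stages = stages,
    inputs = config$inputs %||% list(),
    simulate = do.call(sim_cohort_config, cohort_args),
    genetics = do.call(sim_genetics_config, genetics_args),
    filter = do.call(filter_config, config$filter %||% list()),
    de = do.call(de_config, config$de %||% list()),
    network = do.call(network_config, config$network %||% list()),
    module_trait = config$module_trait %||% list(),
    enrichment = do.call(enrichment_config, enrich_args)),
    class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes simulate (or load inputs) -> low-expression filter ->
#' log2-CPM + covariate residualization -> variance partition -> NB Wald
#' differential expression -> co-expression network (soft-threshold scan,
#' TOM, module detection, merging, eigengenes, kME) -> module-trait
#' correlation -> eQTL-bridged GWAS enrichment, writing every intermediate
#' table to `out_dir` and returning a run manifest. When planted truth is
#' available (simulation runs), recovery metrics (module adjusted Rand
#' index, DE power and type-I error, enrichment permutation p for the
#' planted module) are added to the manifest.
#'
#' The covariates regressed out before network construction default to
#' batch, RIN and age; the DE design keeps its own covariate list.
#'
#' @param config a [pipeline_config()] (or list / YAML path accepted by it).
#' @param network_covariates covariates residualized before the network.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         network_covariates = c("batch", "rin", "age")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  tick <- function(stage, start) timing[[stage]] <<- round(proc.time()[["elapsed"]] - start, 3)
  stage_wrap <- function(stage, fn) {
    start <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    tick(stage, start)
    out
  }

  truth <- NULL
  if (isTRUE(config$stages$simulate)) {
    sim <- stage_wrap("simulate", function() simulate_cohort(config$simulate))
    counts <- sim$counts; samples <- sim$samples; truth <- sim$truth
    gen <- stage_wrap("simulate_genetics", function()
      simulate_genetics(rownames(counts), truth, config$genetics))
    eqtl <- gen$eqtl; gwas <- gen$gwas; truth <- gen$truth
    write_counts(counts, file.path(config$out_dir, "counts.tsv"))
    write_sample_table(samples, file.path(config$out_dir, "samples.tsv"))
    write_eqtl(eqtl, file.path(config$out_dir, "eqtl.tsv"))
    write_gwas(gwas, file.path(config$out_dir, "gwas.tsv"))
    jsonlite::write_json(
      list(module_of_gene = as.list(truth$module_of_gene[!is.na(truth$module_of_gene)]),
           de_genes = as.list(truth$de_genes),
           enriched_module = truth$enriched_module),
      file.path(config$out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    counts <- stage_wrap("read_counts", function() read_counts(config$inputs$counts))
    samples <- stage_wrap("read_samples", function() read_sample_table(config$inputs$samples))
    eqtl <- if (!is.null(config$inputs$eqtl)) read_eqtl(config$inputs$eqtl)
    gwas <- if (!is.null(config$inputs$gwas)) read_gwas(config$inputs$gwas)
  }

  metrics <- list()

  ## ---- filter ----------------------------------------------------------
  if (isTRUE(config$stages$filter)) {
    filt <- stage_wrap("filter", function() filter_low_expression(counts, config$filter))
    write_table_tsv(filt$report, file.path(config$out_dir, "filter_report.tsv"))
    counts <- filt$counts
    metrics$n_genes_retained <- filt$n_retained
  }

  ## ---- expression for network / varpart --------------------------------
  lexpr <- log_cpm(counts)
  rexpr <- stage_wrap("residualize", function()
    residualize(lexpr, samples, network_covariates))

  if (isTRUE(config$stages$varpart)) {
    vp <- stage_wrap("varpart", function()
      variance_partition(lexpr, samples, network_covariates))
    write_table_tsv(vp, file.path(config$out_dir, "variance_partition.tsv"))
  }

  ## ---- differential expression -----------------------------------------
  de_res <- NULL
  if (isTRUE(config$stages$de)) {
    de_res <- stage_wrap("de", function() {
      disp <- estimate_dispersions(counts, samples, config$de)
      nb_wald_test(counts, samples, disp, config$de)
    })
    write_table_tsv(de_res, file.path(config$out_dir, "de_results.tsv"))
    metrics$de_tier_counts <- as.list(de_summary(de_res, config$de$fdr_tiers)$tier_counts)
    if (!is.null(truth)) {
      planted <- de_res$gene_id %in% names(truth$de_genes)
      if (any(planted))
        metrics$de_power_q05 <- mean(de_res$q_value[planted] < 0.05, na.rm = TRUE)
      null_genes <- !planted & is.na(truth$module_of_gene[de_res$gene_id])
      if (any(null_genes))
        metrics$de_type1_at_005 <- mean(de_res$p_value[null_genes] <= 0.05, na.rm = TRUE)
    }
  }

  ## ---- co-expression network -------------------------------------------
  assignment <- NULL; eig <- NULL
  if (isTRUE(config$stages$network)) {
    net <- stage_wrap("network", function() {
      corr <- correlation_matrix(rexpr)
      scan <- scan_soft_threshold(corr, config$network)
      adj <- adjacency(corr, attr(scan, "selected_power"), config$network$signed)
      tm <- tom(adj)
      pre <- detect_modules(tm, config$network)
      pre <- assign_by_kme(rexpr, pre, config$network)
      merged <- merge_modules(rexpr, pre, config$network)
      list(scan = scan, pre = pre, assignment = merged)
    })
    assignment <- net$assignment
    write_table_tsv(as.data.frame(net$scan),
                    file.path(config$out_dir, "soft_threshold_scan.tsv"))
    metrics$selected_power <- attr(net$scan, "selected_power")
    n_mods <- length(setdiff(unique(assignment), config$network$unassigned_label))
    metrics$n_modules <- n_mods
    if (n_mods > 0) {
      eig <- module_eigengenes(rexpr, assignment, config$network)
      kme <- intramodular_connectivity(rexpr, eig, assignment)
      own <- vapply(seq_along(assignment), function(i) {
        m <- assignment[i]
        if (m %in% rownames(eig)) kme$kme[names(assignment)[i], m] else NA_real_
      }, numeric(1))
      write_table_tsv(data.frame(gene_id = names(assignment),
                                 module_label = unname(assignment),
                                 own_module_kME = own),
                      file.path(config$out_dir, "module_assignment.tsv"))
      write_table_tsv(data.frame(module = rownames(eig), eig, check.names = FALSE),
                      file.path(config$out_dir, "eigengenes.tsv"))
      if (!is.null(truth)) {
        keep <- !is.na(truth$module_of_gene)
        metrics$module_ari <- mclust::adjustedRandIndex(
          truth$module_of_gene[keep], assignment[names(which(keep))])
      }
    }
  }

  ## ---- module-trait correlation ----------------------------------------
  if (isTRUE(config$stages$module_trait) && !is.null(eig)) {
    mt_args <- config$module_trait
    mt <- stage_wrap("module_trait", function()
      do.call(module_trait_matrix, c(list(eigengenes = eig, samples = samples), mt_args)))
    write_table_tsv(mt, file.path(config$out_dir, "module_trait.tsv"))
    metrics$n_module_trait_bonferroni <- sum(mt$passes_bonferroni)
  }

  ## ---- eQTL-bridged GWAS enrichment ------------------------------------
  if (isTRUE(config$stages$enrichment) && !is.null(assignment) &&
      !is.null(eqtl) && !is.null(gwas)) {
    enr <- stage_wrap("enrichment", function() {
      map <- build_gene_snp_map(eqtl, config$enrichment)
      mods <- setdiff(unique(assignment), config$network$unassigned_label)
      results <- list()
      for (m in mods) {
        genes_m <- names(assignment)[assignment == m]
        r <- tryCatch(permutation_enrichment(map, genes_m, gwas,
                                             config$enrichment, module = m),
                      error = function(e) NULL)
        if (!is.null(r)) results[[m]] <- r
      }
      results
    })
    if (length(enr)) {
      rep_tbl <- enrichment_report(enr)
      write_table_tsv(rep_tbl, file.path(config$out_dir, "enrichment_report.tsv"))
      metrics$top_enriched_module <- rep_tbl$module[1]
      metrics$top_enrichment_perm_p <- rep_tbl$perm_p[1]
    }
  }

  manifest <- list(tool = "coexr", version = as.character(utils::packageVersion("coexr")),
                   seed = config$seed, stage_seconds = timing,
                   total_seconds = round(proc.time()[["elapsed"]] - t0, 3),
                   metrics = metrics)
  tmp <- file.path(config$out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
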