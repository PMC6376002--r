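#' Counts per million
#'
#' CPM = count / library size x 1e6, where the library size is the sample's
#' column sum of the (unfiltered) count matrix, so each sample's CPM column
#' sums to one million.
#'
#' @param counts gene x sample count matrix.
#' @return an expression matrix with `scale_tag = "cpm"`.
#' @export
compute_cpm <- function(counts) {
  validate_counts(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  expression_matrix(sweep(counts, 2, libsize, "/") * 1e6, "cpm")
}

#' Low-expression filter configuration
#'
#' Genes are kept when their CPM is at least `min_cpm` in at least
#' `min_fraction` of the samples (both bounds inclusive).
#'
#' @param min_cpm minimum CPM (default 1).
#' @param min_fraction minimum fraction of samples (default 0.5).
#' @export
filter_config <- function(min_cpm = 1, min_fraction = 0.5) {
  if (min_cpm <= 0) stop("min_cpm must be > 0")
  if (min_fraction <= 0 || min_fraction > 1) stop("min_fraction must be in (0, 1]")
  structure(list(min_cpm = min_cpm, min_fraction = min_fraction),
            class = "filter_config")
}

#' Remove low-expression genes
#'
#' Library sizes are computed on the unfiltered matrix, so the filtering
#' decision does not feed back into its own normalizer. Gene order is
#' preserved.
#'
#' @param counts gene x sample count matrix.
#' @param cfg a [filter_config()].
#' @return list with `counts` (the retained submatrix), `n_retained`, and
#'   `report` (per-gene data.frame: gene_id, n_samples_ge_min_cpm, retained).
#' @export
filter_low_expression <- function(counts, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  cpm <- compute_cpm(counts)
  n_ok <- rowSums(cpm >= cfg$min_cpm)
  keep <- n_ok >= cfg$min_fraction * ncol(counts)
  if (!any(keep)) warning("all genes removed by the low-expression filter")
  report <- data.frame(gene_id = rownames(counts),
                       n_samples_ge_min_cpm = as.integer(n_ok),
                       retained = keep, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(counts = counts[keep, , drop = FALSE],
       n_retained = sum(keep), report = report)
}

#' Log2 counts per million
#'
#' `log2(CPM + prior_count)`; the prior damps the variance of low counts.
#'
#' @param counts gene x sample count matrix.
#' @param prior_count positive pseudo-CPM added before the log (default 1).
#' @return expression matrix with `scale_tag = "log2cpm"`.
#' @export
log_cpm <- function(counts, prior_count = 1) {
  if (prior_count <= 0) stop("prior_count must be > 0")
  expression_matrix(log2(compute_cpm(counts) + prior_count), "log2cpm")
}

## Build (and rank-check) the covariate design used by residualize and
## variance_partition; categoricals are one-hot with the reference dropped.
## Constant covariates carry no information and reduce to the intercept, so
## they are dropped (they'd otherwise be trivially collinear); genuine
## collinearity among varying covariates is an error.
covariate_design <- function(samples, covariates) {
  miss <- setdiff(covariates, names(samples))
  if (length(miss)) stop("covariate(s) not in sample table: ",
                         paste(miss, collapse = ", "))
  sub <- samples[, covariates, drop = FALSE]
  if (anyNA(sub)) {
    bad <- covariates[vapply(sub, anyNA, logical(1))]
    stop("missing values in covariate(s): ", paste(bad, collapse = ", "))
  }
  sub[] <- lapply(sub, function(x) if (is.character(x)) factor(x) else
    if (is.factor(x)) droplevels(x) else x)
  const <- vapply(sub, function(x) length(unique(x)) <= 1L, logical(1))
  used <- covariates[!const]
  mm <- if (length(used) == 0)
    matrix(1, nrow = nrow(sub), dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(~., data = sub[, used, drop = FALSE])
  qx <- qr(mm)
  if (qx$rank < ncol(mm)) {
    dropped <- colnames(mm)[qx$pivot[(qx$rank + 1):ncol(mm)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  attr(mm, "covariates_used") <- used
  mm
}

#' Residualize expression on covariates
#'
#' Per gene, ordinary least-squares residuals against intercept plus the
#' named covariates (categoricals one-hot, reference level dropped).
#' Residuals are centered per gene and orthogonal to every design column.
#'
#' @param expr gene x sample expression matrix.
#' @param samples sample table (rows aligned to `colnames(expr)` by
#'   `sample_id`).
#' @param covariates character vector of covariate names.
#' @return expression matrix with `scale_tag = "residualized"`.
#' @export
residualize <- function(expr, samples, covariates) {
  samples <- align_samples(expr, samples)
  mm <- covariate_design(samples, covariates)
  qx <- qr(mm)
  res <- t(qr.resid(qx, t(expr)))
  dimnames(res) <- dimnames(expr)
  expression_matrix(res, "residualized")
}

#' Fixed-effects variance partition
#'
#' Per gene, each covariate's attributed fraction is derived from its
#' marginal (added-last) sum of squares: the increase in residual sum of
#' squares when the covariate's columns are dropped from the full design.
#' Because marginal sums of squares overlap under collinearity, the
#' attributed fractions are normalized to apportion exactly the explained
#' variance, so per gene all fractions plus the residual fraction sum to 1.
#'
#' @inheritParams residualize
#' @return data.frame with one row per gene: a fraction column per covariate
#'   plus `residual`.
#' @export
variance_partition <- function(expr, samples, covariates) {
  samples <- align_samples(expr, samples)
  mm <- covariate_design(samples, covariates)
  used <- attr(mm, "covariates_used")
  assign_map <- attr(mm, "assign") %||% 0L
  Y <- t(expr)                                  # samples x genes
  qx_full <- qr(mm)
  rss_full <- colSums(qr.resid(qx_full, Y)^2)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  tss[tss == 0] <- NA_real_

  marg <- sapply(seq_along(covariates), function(i) {
    j <- match(covariates[i], used)
    if (is.na(j)) return(rep(0, ncol(Y)))       # constant covariate: no signal
    keep <- assign_map != j
    rss_red <- colSums(qr.resid(qr(mm[, keep, drop = FALSE]), Y)^2)
    pmax(0, rss_red - rss_full)
  })
  if (is.null(dim(marg))) marg <- matrix(marg, nrow = 1)
  colnames(marg) <- covariates

  explained <- pmax(0, tss - rss_full)
  denom <- rowSums(marg)
  scalefac <- ifelse(denom > 0, explained / tss / denom, 0)
  fracs <- marg * scalefac
  residual <- ifelse(is.na(tss), NA_real_, rss_full / tss)
  ## guarantee the exact-sum identity
  residual <- 1 - rowSums(fracs)
  out <- data.frame(gene_id = rownames(expr), fracs, residual = residual,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' The classical equal-variance two-sample t-test computed from group means,
#' standard deviations and sizes, with `df = n1 + n2 - 2` and a two-sided
#' p-value.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list of class `group_test`: statistic, df, p_value, group_means,
#'   group_sds, group_ns.
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean1 - mean2) / se
  structure(list(statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 group_means = c(mean1, mean2), group_sds = c(sd1, sd2),
                 group_ns = c(n1, n2)),
            class = "group_test")
}

#' Compare a numeric covariate between two groups
#'
#' Pooled-variance two-sample t-test of `covariate` between the two levels of
#' `group` (e.g. PMI between cases and controls).
#'
#' @param samples sample table.
#' @param covariate name of a numeric column.
#' @param group name of a two-level column.
#' @return a `group_test` (see [pooled_t_summary()]).
#' @export
covariate_group_test <- function(samples, covariate, group = "diagnosis") {
  x <- samples[[covariate]]
  g <- samples[[group]]
  if (is.null(x) || is.null(g)) stop("covariate or group column not found")
  if (!is.numeric(x)) stop("covariate must be numeric")
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(factor(g[keep]))
  if (nlevels(g) != 2) stop("group must have exactly 2 levels")
  xs <- split(x, g)
  if (any(lengths(xs) < 2)) stop("each group needs at least 2 observations")
  pooled_t_summary(mean(xs[[1]]), stats::sd(xs[[1]]), length(xs[[1]]),
                   mean(xs[[2]]), stats::sd(xs[[2]]), length(xs[[2]]))
}
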