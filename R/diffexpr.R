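#' Differential expression configuration
#'
#' The default design mirrors the covariates of the case-control analysis:
#' `~ diagnosis + sex + age + pmi + rin + batch`, with the diagnosis
#' coefficient as the contrast of interest and FDR summary tiers at 5%, 10%
#' and 25%.
#'
#' @param design_covariates ordered covariate names (first is conventionally
#'   the contrast).
#' @param coefficient_of_interest one of `design_covariates`.
#' @param fdr_tiers q-value thresholds for the summary.
#' @export
de_config <- function(design_covariates = c("diagnosis", "sex", "age", "pmi",
                                            "rin", "batch"),
                      coefficient_of_interest = "diagnosis",
                      fdr_tiers = c(0.05, 0.10, 0.25)) {
  if (!coefficient_of_interest %in% design_covariates)
    stop("coefficient_of_interest must be one of design_covariates")
  structure(list(design_covariates = design_covariates,
                 coefficient_of_interest = coefficient_of_interest,
                 fdr_tiers = fdr_tiers),
            class = "de_config")
}

## Design matrix for the DE model; rows aligned to counts columns.
de_design <- function(counts, samples, cfg) {
  samples <- align_samples(counts, samples)
  mm <- covariate_design(samples, cfg$design_covariates)
  used <- attr(mm, "covariates_used")
  if (!cfg$coefficient_of_interest %in% used)
    stop("coefficient of interest '", cfg$coefficient_of_interest,
         "' is constant across samples")
  j <- match(cfg$coefficient_of_interest, used)
  coef_cols <- which((attr(mm, "assign") %||% 0L) == j)
  list(mm = mm, coef_col = coef_cols[1], samples = samples)
}

#' Method-of-moments negative-binomial dispersion estimates
#'
#' Counts are scaled to a common library size, the design is regressed out
#' by OLS on the normalized scale, and the NB moment identity
#' `var = mu + alpha * mu^2` is inverted:
#' `alpha_hat = max(0, (s^2 - mean) / mean^2)`. With `shrink = TRUE`
#' (default) per-gene estimates are blended half-and-half with a lowess
#' mean-dispersion trend across genes, which stabilizes the per-gene noise
#' at desk-scale cohorts.
#'
#' @param counts gene x sample count matrix (low-expression filtered).
#' @param samples sample table.
#' @param cfg a [de_config()].
#' @param shrink blend towards the fitted mean-dispersion trend.
#' @return named per-gene dispersion vector (never negative).
#' @export
estimate_dispersions <- function(counts, samples, cfg = de_config(),
                                 shrink = TRUE) {
  validate_counts(counts)
  d <- de_design(counts, samples, cfg)
  libsize <- colSums(counts)
  yn <- sweep(counts, 2, mean(libsize) / libsize, "*")   # normalized counts
  m <- rowMeans(yn)
  if (any(m == 0))
    stop("all-zero gene(s) reached dispersion estimation (filter first): ",
         paste(utils::head(rownames(counts)[m == 0], 5), collapse = ", "))
  qx <- qr(d$mm)
  rss <- colSums(qr.resid(qx, t(yn))^2)
  s2 <- rss / (ncol(counts) - ncol(d$mm))
  alpha <- pmax(0, (s2 - m) / m^2)
  if (shrink && length(alpha) >= 20) {
    trend <- stats::lowess(log(m), alpha, f = 2 / 3)
    fit <- stats::approx(trend$x, trend$y, xout = log(m), rule = 2)$y
    alpha <- pmax(0, 0.5 * alpha + 0.5 * fit)
  }
  names(alpha) <- rownames(counts)
  alpha
}

## NB deviance at fixed dispersion alpha (alpha = 0 reduces to Poisson).
nb_deviance <- function(y, mu, alpha) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (alpha > 0) {
    2 * sum(t1 - (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu)))
  } else {
    2 * sum(t1 - (y - mu))
  }
}

## One-gene NB log-link GLM by IRLS at fixed dispersion.
## Returns coefficients, SEs, convergence flag.
nb_irls <- function(y, X, offset, alpha, max_iter = 100, tol = 1e-8) {
  beta <- qr.coef(qr(X), log(y + 0.5) - offset)
  beta[is.na(beta)] <- 0
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(drop(X %*% beta) + offset, 30)
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) break
    beta <- beta_new
    dev <- nb_deviance(y, pmax(exp(pmin(drop(X %*% beta) + offset, 30)), 1e-10), alpha)
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- pmin(drop(X %*% beta) + offset, 30)
  mu <- pmax(exp(eta), 1e-10)
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(chol2inv(chol(xtwx)))), error = function(e) rep(NA_real_, ncol(X)))
  list(beta = beta, se = se, converged = converged)
}

#' Per-gene negative-binomial Wald test
#'
#' Fits, for every gene, a negative-binomial log-link GLM at fixed
#' dispersion by iteratively reweighted least squares, with the log library
#' size as offset, and reports the Wald test of the coefficient of interest:
#' statistic = coefficient / SE, two-sided normal p-value,
#' log2 fold change = coefficient / ln 2 (case over control for the default
#' design). Genes whose IRLS fails to converge within 100 iterations are
#' flagged and their p-value set to `NA`.
#'
#' @param counts gene x sample count matrix.
#' @param samples sample table.
#' @param dispersions per-gene dispersion vector (>= 0), e.g. from
#'   [estimate_dispersions()].
#' @param cfg a [de_config()].
#' @return data.frame of class `de_result`: gene_id, base_mean,
#'   log2_fold_change, standard_error (log2 scale), wald_statistic, p_value,
#'   q_value (Benjamini-Hochberg), dispersion, converged.
#' @export
nb_wald_test <- function(counts, samples, dispersions, cfg = de_config()) {
  validate_counts(counts)
  if (length(dispersions) != nrow(counts))
    stop("dispersions must have one entry per gene")
  if (any(dispersions < 0)) stop("dispersions must be >= 0")
  d <- de_design(counts, samples, cfg)
  X <- d$mm
  offset <- log(colSums(counts))
  libsize <- colSums(counts)
  base_mean <- rowMeans(sweep(counts, 2, mean(libsize) / libsize, "*"))

  n_genes <- nrow(counts)
  lfc <- se2 <- wald <- p <- rep(NA_real_, n_genes)
  conv <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    fit <- nb_irls(counts[g, ], X, offset, dispersions[g])
    conv[g] <- fit$converged
    b <- fit$beta[d$coef_col]
    s <- fit$se[d$coef_col]
    lfc[g] <- b / log(2)
    se2[g] <- s / log(2)
    if (fit$converged && is.finite(s) && s > 0) {
      wald[g] <- b / s
      p[g] <- 2 * stats::pnorm(-abs(wald[g]))
    }
  }
  out <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2_fold_change = lfc, standard_error = se2,
                    wald_statistic = wald, p_value = p,
                    q_value = bh_fdr(p), dispersion = as.numeric(dispersions),
                    converged = conv, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (`stats::p.adjust` with `method = "BH"`);
#' `NA` p-values propagate as `NA` and do not enter the adjustment.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, order-preserving in p-rank.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Summarize a DE result by FDR tier
#'
#' @param result a `de_result` from [nb_wald_test()].
#' @param tiers q-value thresholds (default 0.05, 0.10, 0.25).
#' @param top_n rows of the top-gene table (sorted by p ascending).
#' @return list with `tier_counts` (genes with q < tier) and `top_genes`.
#' @export
de_summary <- function(result, tiers = c(0.05, 0.10, 0.25), top_n = 10) {
  if (nrow(result) == 0) stop("empty DE result")
  counts <- vapply(tiers, function(t) sum(result$q_value < t, na.rm = TRUE), numeric(1))
  names(counts) <- paste0("q<", tiers)
  ord <- order(result$p_value)
  list(tier_counts = counts,
       top_genes = result[utils::head(ord, top_n), , drop = FALSE])
}
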