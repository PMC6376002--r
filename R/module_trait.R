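#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged), computed on
#' pairwise-complete observations; at least 4 complete pairs are required.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho` and `n` (pairs used).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs (got ", n, ")")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance; correlation undefined")
  list(rho = stats::cor(rx, ry), n = n)
}

#' t-approximation p-value for a correlation
#'
#' Two-sided p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom. A boundary correlation (|rho| = 1) returns
#' p = 0 with the attribute `boundary = TRUE`.
#'
#' @param rho correlation in \[-1, 1\].
#' @param n number of pairs (>= 4).
#' @return the p-value (numeric scalar).
#' @export
correlation_pvalue <- function(rho, n) {
  if (n < 4) stop("need n >= 4")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (abs(rho) == 1) return(structure(0, boundary = TRUE))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Module-trait correlation matrix
#'
#' Spearman correlation of every module eigengene with every trait, with
#' t-approximation p-values and a Bonferroni pass flag. The binary diagnosis
#' is encoded 0/1 (control = 0); traits that are entirely missing are
#' excluded with a warning. Missing values are handled pairwise-complete.
#'
#' @param eigengenes module x sample eigengene matrix.
#' @param samples sample table (matched to eigengene columns by sample_id).
#' @param traits trait column names (default: diagnosis,
#'   alcohol_consumption, audit, drinking_years).
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param bonferroni_k Bonferroni divisor; default is modules x traits.
#'   (An additive modules + traits divisor can be supplied explicitly.)
#' @return data.frame: module, trait, rho, n_used, p_value,
#'   passes_bonferroni, threshold_used.
#' @export
module_trait_matrix <- function(eigengenes, samples,
                                traits = c("diagnosis", "alcohol_consumption",
                                           "audit", "drinking_years"),
                                alpha = 0.05, bonferroni_k = NULL) {
  idx <- match(colnames(eigengenes), samples$sample_id)
  if (anyNA(idx)) stop("sample table is missing samples present in eigengenes")
  samples <- samples[idx, , drop = FALSE]
  miss <- setdiff(traits, names(samples))
  if (length(miss)) stop("trait(s) not in sample table: ", paste(miss, collapse = ", "))
  empty <- traits[vapply(traits, function(tr) all(is.na(samples[[tr]])), logical(1))]
  if (length(empty)) {
    warning("trait(s) entirely missing, excluded: ", paste(empty, collapse = ", "))
    traits <- setdiff(traits, empty)
  }
  k <- bonferroni_k %||% (nrow(eigengenes) * length(traits))
  thr <- bonferroni_threshold(alpha, k)
  rows <- list()
  for (m in rownames(eigengenes)) {
    for (tr in traits) {
      y <- samples[[tr]]
      if (!is.numeric(y)) {
        f <- if (all(y %in% c("control", "case")))
          factor(y, levels = c("control", "case")) else factor(y)
        y <- as.numeric(f) - 1
      }
      s <- spearman_cor(eigengenes[m, ], y)
      p <- correlation_pvalue(s$rho, s$n)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, rho = s$rho, n_used = s$n, p_value = p,
        passes_bonferroni = p < thr, threshold_used = thr,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bonferroni threshold
#'
#' `alpha / k` for `k` tests. The pipeline default takes
#' `k = modules x traits`; an additive `modules + traits` divisor can be
#' passed for comparison with published analyses that used it.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param k number of tests (>= 1).
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (k < 1) stop("k must be >= 1")
  alpha / k
}
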