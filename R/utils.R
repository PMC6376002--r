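#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Fan a single user-facing seed out into independent per-stage substreams so
## that adding draws to one stage never perturbs another.
substream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Validate a gene-by-sample count matrix
#'
#' Checks the container contract used throughout the pipeline: a numeric
#' matrix with unique gene row names and unique sample column names, all
#' entries finite, non-negative and integral.
#'
#' @param counts matrix of counts (genes in rows, samples in columns).
#' @return the matrix, invisibly, after validation.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts))) stop("counts contain non-finite values")
  if (any(counts < 0)) stop("counts contain negative values")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts contain non-integer values")
  invisible(counts)
}

## Light constructor for expression matrices: a plain matrix plus a tag
## recording which scale the values are on (cpm, log2cpm, residualized).
expression_matrix <- function(values, scale_tag) {
  stopifnot(is.matrix(values), scale_tag %in% c("cpm", "log2cpm", "residualized"))
  attr(values, "scale_tag") <- scale_tag
  values
}

#' @export
scale_tag <- function(x) attr(x, "scale_tag")

validate_sample_table <- function(samples, require_traits = FALSE) {
  req <- c("sample_id", "diagnosis", "sex", "age", "pmi", "rin", "brain_ph", "batch")
  if (require_traits) req <- c(req, "alcohol_consumption", "audit", "drinking_years")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample table is missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  if (!all(samples$diagnosis %in% c("case", "control")))
    stop("diagnosis must be 'case' or 'control'")
  low <- samples$rin < 5.5 & !is.na(samples$rin)
  if (any(low))
    warning(sum(low), " sample(s) have RIN < 5.5; degraded RNA samples are usually excluded upstream")
  invisible(samples)
}

## Align a sample table to count-matrix columns (order and identity).
align_samples <- function(counts, samples) {
  if (!all(colnames(counts) %in% samples$sample_id))
    stop("sample table is missing samples present in counts")
  samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
}
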