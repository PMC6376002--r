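## All pipeline tables are TSV: UTF-8, tab-separated, '.' decimal, no
## thousands separators. read.delim is gzip-transparent, so .tsv.gz works.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a count matrix TSV
#'
#' Expected layout: first column `gene_id`, remaining columns one per
#' sample, integer cells.
#'
#' @param path TSV file (optionally gzipped).
#' @return validated gene x sample integer matrix.
#' @export
read_counts <- function(path) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "gene_id") stop("first column must be 'gene_id'")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer or invalid count at gene ", df$gene_id[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  validate_counts(m)
  m
}

#' Write a count matrix TSV
#'
#' @param counts gene x sample matrix.
#' @param path output file.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table TSV
#'
#' Header: sample_id, diagnosis, sex, age, pmi, rin, brain_ph, batch,
#' alcohol_consumption, audit, drinking_years; empty cells become missing
#' values. Samples with RIN < 5.5 trigger a warning (degraded RNA).
#'
#' @param path TSV file.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_checked(path)
  validate_sample_table(df, require_traits = TRUE)
  df$diagnosis <- factor(df$diagnosis, levels = c("control", "case"))
  df$sex <- factor(df$sex)
  df$batch <- factor(df$batch)
  for (col in c("age", "pmi", "rin", "brain_ph", "alcohol_consumption",
                "audit", "drinking_years"))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write a sample table TSV
#'
#' @param samples sample table data.frame.
#' @param path output file.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Columns `snp_id` and `p` (or `p_value`); extra columns are ignored.
#'
#' @param path TSV file.
#' @return data.frame (snp_id, p_value).
#' @export
read_gwas <- function(path) {
  df <- read_tsv_checked(path)
  pcol <- intersect(c("p", "p_value"), names(df))[1]
  if (!"snp_id" %in% names(df) || is.na(pcol))
    stop("GWAS file needs columns 'snp_id' and 'p' (or 'p_value')")
  out <- data.frame(snp_id = as.character(df$snp_id),
                    p_value = as.numeric(df[[pcol]]), stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp_id)) stop("duplicate snp_id in GWAS table")
  if (any(is.na(out$p_value) | out$p_value < 0 | out$p_value > 1))
    stop("GWAS p-values must lie in [0, 1]")
  out
}

#' @rdname read_gwas
#' @param gwas GWAS table.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(data.frame(snp_id = gwas$snp_id, p = gwas$p_value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an eQTL table
#'
#' Columns `snp_id`, `gene_id` and `p` (or `p_value`); (snp, gene) pairs
#' must be unique.
#'
#' @param path TSV file.
#' @return data.frame (snp_id, gene_id, p_value).
#' @export
read_eqtl <- function(path) {
  df <- read_tsv_checked(path)
  pcol <- intersect(c("p", "p_value"), names(df))[1]
  if (!all(c("snp_id", "gene_id") %in% names(df)) || is.na(pcol))
    stop("eQTL file needs columns 'snp_id', 'gene_id' and 'p' (or 'p_value')")
  out <- data.frame(snp_id = as.character(df$snp_id),
                    gene_id = as.character(df$gene_id),
                    p_value = as.numeric(df[[pcol]]), stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("snp_id", "gene_id")]))
    stop("duplicate (snp_id, gene_id) pair in eQTL table")
  if (any(is.na(out$p_value) | out$p_value < 0 | out$p_value > 1))
    stop("eQTL p-values must lie in [0, 1]")
  out
}

#' @rdname read_eqtl
#' @param eqtl eQTL table.
#' @export
write_eqtl <- function(eqtl, path) {
  utils::write.table(data.frame(snp_id = eqtl$snp_id, gene_id = eqtl$gene_id,
                                p = eqtl$p_value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## generic TSV writer for result tables (module assignment, eigengenes, ...)
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
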