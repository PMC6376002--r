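#' Weighted co-expression network configuration
#'
#' Defaults follow the canonical WGCNA recipe for bulk brain RNA-seq:
#' candidate soft powers 1..20 selected at scale-free fit R^2 >= 0.90,
#' unsigned adjacency, minimum module size 100 (scale down for toy data),
#' dendrogram cut height 0.99, and eigengene merging at correlation > 0.75.
#'
#' @param candidate_powers integer soft-threshold powers to scan.
#' @param scale_free_target_r2 fit index needed to accept a power.
#' @param signed use signed adjacency `((1 + r) / 2)^beta` instead of
#'   unsigned `|r|^beta`.
#' @param n_degree_bins equal-width connectivity bins for the scale-free fit.
#' @param min_module_size smallest branch kept as a module.
#' @param cut_height static dendrogram cut height on the 1 - TOM scale.
#' @param merge_correlation eigengene correlation above which modules merge.
#' @param unassigned_label label for genes in no module (default "grey").
#' @param deep_split refine detected branches recursively where a branch
#'   splits into >= 2 sub-branches each of at least `min_module_size` genes.
#' @param kme_rescue minimum absolute module-membership correlation (kME) at
#'   which an unassigned gene is attached to its best-matching module by
#'   [assign_by_kme()]; set to `NA` to disable the rescue pass.
#' @export
network_config <- function(candidate_powers = 1:20, scale_free_target_r2 = 0.90,
                           signed = FALSE, n_degree_bins = 10,
                           min_module_size = 100, cut_height = 0.99,
                           merge_correlation = 0.75, unassigned_label = "grey",
                           deep_split = FALSE, kme_rescue = 0.3) {
  if (any(candidate_powers < 1)) stop("candidate powers must be >= 1")
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must lie in (0, 1]")
  if (merge_correlation <= 0 || merge_correlation >= 1)
    stop("merge_correlation must lie in (0, 1)")
  structure(list(candidate_powers = as.integer(candidate_powers),
                 scale_free_target_r2 = scale_free_target_r2, signed = signed,
                 n_degree_bins = as.integer(n_degree_bins),
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, merge_correlation = merge_correlation,
                 unassigned_label = unassigned_label, deep_split = deep_split,
                 kme_rescue = kme_rescue),
            class = "network_config")
}

#' Gene-gene Pearson correlation matrix
#'
#' @param expr gene x sample expression matrix (>= 3 samples); genes with
#'   zero variance are an error (they have no defined correlation).
#' @return symmetric gene x gene correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  if (ncol(expr) < 3) stop("need at least 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  C <- stats::cor(t(expr))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

#' Soft-threshold adjacency
#'
#' Unsigned: `a_ij = |r_ij|^beta`; signed: `a_ij = ((1 + r_ij) / 2)^beta`.
#' The diagonal is set to 1.
#'
#' @param corr gene x gene correlation matrix.
#' @param power soft-threshold exponent (>= 1).
#' @param signed signed network flag.
#' @export
adjacency <- function(corr, power, signed = FALSE) {
  if (power < 1) stop("power must be >= 1")
  a <- if (signed) ((1 + corr) / 2)^power else abs(corr)^power
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  a
}

## Scale-free fit index for a connectivity vector: R^2 of the log10-log10
## regression of bin frequency on bin mean connectivity, reported only when
## the slope is negative (else 0).
scale_free_fit <- function(k, n_bins) {
  if (max(k) - min(k) < 1e-12) {
    warning("degenerate connectivity (all equal); scale-free fit undefined")
    return(0)
  }
  bins <- cut(k, breaks = seq(min(k), max(k), length.out = n_bins + 1),
              include.lowest = TRUE)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(ok) < 3) {
    warning("fewer than 3 non-empty connectivity bins; scale-free fit set to 0")
    return(0)
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] < 0) r2 else 0
}

#' Scan soft-threshold powers for scale-free topology
#'
#' For each candidate power the adjacency is built, whole-network
#' connectivity `k_i = sum_j != i a_ij` computed, binned into equal-width
#' bins, and the scale-free fit index taken as the R^2 of the log-log
#' regression of bin frequency on bin mean connectivity (negative-slope
#' convention). The selected power is the smallest one whose fit reaches the
#' target, or the argmax with a warning if none does.
#'
#' @param corr gene x gene correlation matrix.
#' @param cfg a [network_config()].
#' @return data.frame (power, fit_r2, mean_k) with attribute
#'   `selected_power`.
#' @export
scan_soft_threshold <- function(corr, cfg = network_config()) {
  res <- lapply(cfg$candidate_powers, function(b) {
    a <- adjacency(corr, b, cfg$signed)
    k <- rowSums(a) - 1
    data.frame(power = b, fit_r2 = scale_free_fit(k, cfg$n_degree_bins),
               mean_k = mean(k))
  })
  scan <- do.call(rbind, res)
  hit <- which(scan$fit_r2 >= cfg$scale_free_target_r2)
  if (length(hit)) {
    sel <- scan$power[hit[1]]
  } else {
    sel <- scan$power[which.max(scan$fit_r2)]
    warning("no power reached the scale-free target R^2 = ",
            cfg$scale_free_target_r2, "; using argmax power ", sel)
  }
  attr(scan, "selected_power") <- sel
  class(scan) <- c("soft_threshold_scan", "data.frame")
  scan
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over shared neighbours and
#' `k_i = sum_u != i a_iu`; the diagonal is 1.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @return symmetric TOM in \[0, 1\].
#' @export
tom <- function(adj) {
  A <- adj
  diag(A) <- 0
  L <- A %*% A
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  T <- (L + A) / denom
  T <- pmin(pmax((T + t(T)) / 2, 0), 1)
  diag(T) <- 1
  T
}

## Recursive branch refinement used by deep_split: split a branch in two
## when both halves of its subtree meet the minimum size.
refine_branch <- function(d, members, min_size) {
  if (length(members) < 2 * min_size) return(list(members))
  h <- stats::hclust(stats::as.dist(d[members, members, drop = FALSE]), "average")
  parts <- stats::cutree(h, k = 2)
  g1 <- members[parts == 1]
  g2 <- members[parts == 2]
  if (length(g1) >= min_size && length(g2) >= min_size)
    c(refine_branch(d, g1, min_size), refine_branch(d, g2, min_size))
  else list(members)
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static cut at
#' `cut_height`, and a minimum-size filter: branches with at least
#' `min_module_size` genes become modules (labelled `M1`, `M2`, ... by
#' descending size; ties broken by lowest gene index); smaller branches get
#' the unassigned label. As in the tree variant of the dynamic tree-cut
#' algorithm, `cut_height` is interpreted as a fraction of the dendrogram's
#' joining-height range (above its 5th percentile), which keeps the
#' canonical 0.99 cut meaningful across soft-threshold powers. With
#' `deep_split`, detected branches are refined recursively wherever they
#' split into two sub-branches that both meet the minimum size.
#'
#' @param tom_mat TOM from [tom()].
#' @param cfg a [network_config()].
#' @return named character vector gene -> module label.
#' @export
detect_modules <- function(tom_mat, cfg = network_config()) {
  genes <- rownames(tom_mat) %||% paste0("g", seq_len(nrow(tom_mat)))
  if (cfg$min_module_size > nrow(tom_mat)) {
    warning("min_module_size exceeds the number of genes; nothing assigned")
    return(stats::setNames(rep(cfg$unassigned_label, nrow(tom_mat)), genes))
  }
  d <- 1 - tom_mat
  h <- stats::hclust(stats::as.dist(d), method = "average")
  lo <- stats::quantile(h$height, 0.05, names = FALSE)
  cut_at <- lo + cfg$cut_height * (max(h$height) - lo)
  cl <- stats::cutree(h, h = cut_at)
  branches <- split(seq_along(cl), cl)
  branches <- branches[lengths(branches) >= cfg$min_module_size]
  if (cfg$deep_split && length(branches)) {
    branches <- unlist(lapply(branches, refine_branch, d = d,
                              min_size = cfg$min_module_size),
                       recursive = FALSE)
  }
  labels <- rep(cfg$unassigned_label, length(cl))
  if (length(branches)) {
    ord <- order(-lengths(branches), vapply(branches, min, numeric(1)))
    for (i in seq_along(ord))
      labels[branches[[ord[i]]]] <- paste0("M", i)
  }
  stats::setNames(labels, genes)
}

#' Attach unassigned genes to modules by module membership (kME)
#'
#' A light counterpart of the dynamic hybrid tree-cut's assignment stage:
#' after branch detection, each unassigned gene is attached to the module
#' whose eigengene it correlates with most strongly, provided the absolute
#' correlation reaches `cfg$kme_rescue`; genes below the threshold stay
#' unassigned. No-op when there are no modules or the rescue threshold is
#' `NA`.
#'
#' @param expr gene x sample expression matrix.
#' @param assignment gene -> module labels from [detect_modules()].
#' @param cfg a [network_config()].
#' @return updated assignment vector.
#' @export
assign_by_kme <- function(expr, assignment, cfg = network_config()) {
  if (is.na(cfg$kme_rescue)) return(assignment)
  mods <- setdiff(unique(assignment), cfg$unassigned_label)
  grey <- which(assignment == cfg$unassigned_label)
  if (length(mods) == 0 || length(grey) == 0) return(assignment)
  eig <- module_eigengenes(expr, assignment, cfg)
  kme <- abs(stats::cor(t(expr[grey, , drop = FALSE]), t(eig)))
  best <- max.col(kme, ties.method = "first")
  best_kme <- kme[cbind(seq_along(grey), best)]
  hit <- best_kme >= cfg$kme_rescue
  assignment[grey[hit]] <- rownames(eig)[best[hit]]
  assignment
}

#' Module eigengene
#'
#' First principal component across samples of the per-gene standardized
#' member submatrix, scaled to unit variance and oriented so the mean
#' correlation with the member genes is non-negative.
#'
#' @param expr gene x sample expression matrix.
#' @param assignment gene -> module labels from [detect_modules()].
#' @param module module label.
#' @return named eigengene vector over samples (variance 1).
#' @export
module_eigengene <- function(expr, assignment, module) {
  members <- names(assignment)[assignment == module]
  if (length(members) == 0) stop("module '", module, "' is empty")
  Z <- scale(t(expr[members, , drop = FALSE]))    # samples x genes
  e <- if (length(members) == 1) Z[, 1] else svd(Z, nu = 1, nv = 0)$u[, 1]
  e <- e / stats::sd(e)
  if (mean(stats::cor(e, Z)) < 0) e <- -e
  stats::setNames(as.numeric(e), colnames(expr))
}

#' All module eigengenes
#'
#' @inheritParams module_eigengene
#' @param cfg a [network_config()] (for the unassigned label, which is
#'   skipped).
#' @return module x sample eigengene matrix.
#' @export
module_eigengenes <- function(expr, assignment, cfg = network_config()) {
  mods <- setdiff(unique(assignment), cfg$unassigned_label)
  mods <- mods[order(suppressWarnings(as.integer(sub("^M", "", mods))), mods,
                     na.last = TRUE)]
  if (length(mods) == 0) stop("no modules to summarize")
  E <- t(vapply(mods, function(m) module_eigengene(expr, assignment, m),
                numeric(ncol(expr))))
  rownames(E) <- mods
  E
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively computes eigengenes, clusters them by average linkage on
#' `1 - cor`, merges every group linked below `1 - merge_correlation`,
#' and stops when no eigengene pair correlates above `merge_correlation`
#' (at most 10 iterations). Labels are re-assigned by descending module
#' size after merging.
#'
#' @inheritParams module_eigengene
#' @param cfg a [network_config()].
#' @return updated gene -> module assignment.
#' @export
merge_modules <- function(expr, assignment, cfg = network_config()) {
  for (it in 1:10) {
    mods <- setdiff(unique(assignment), cfg$unassigned_label)
    if (length(mods) < 2) break
    E <- module_eigengenes(expr, assignment, cfg)
    C <- stats::cor(t(E))
    if (max(C[upper.tri(C)]) <= cfg$merge_correlation) break
    h <- stats::hclust(stats::as.dist(1 - C), method = "average")
    grp <- stats::cutree(h, h = 1 - cfg$merge_correlation)
    new_lab <- stats::setNames(paste0("tmp", grp), rownames(E))
    assigned <- assignment != cfg$unassigned_label
    assignment[assigned] <- new_lab[assignment[assigned]]
    ## rename by descending size, ties by first gene index
    tab <- table(assignment[assigned])
    first_idx <- vapply(names(tab), function(l) min(which(assignment == l)), numeric(1))
    ord <- names(tab)[order(-as.integer(tab), first_idx)]
    remap <- stats::setNames(paste0("M", seq_along(ord)), ord)
    assignment[assigned] <- remap[assignment[assigned]]
  }
  assignment
}

#' Intramodular connectivity (kME) and hub genes
#'
#' kME is the Pearson correlation of each gene's profile with each module
#' eigengene; a module's hubs are its member genes with the largest
#' own-module kME.
#'
#' @inheritParams module_eigengene
#' @param eigengenes module x sample matrix from [module_eigengenes()].
#' @param n_hubs hub genes reported per module.
#' @return list with `kme` (gene x module matrix) and `hubs`
#'   (per-module character vectors).
#' @export
intramodular_connectivity <- function(expr, eigengenes, assignment,
                                      n_hubs = 10) {
  kme <- stats::cor(t(expr), t(eigengenes))
  hubs <- lapply(rownames(eigengenes), function(m) {
    members <- names(assignment)[assignment == m]
    members[order(-kme[members, m])][seq_len(min(n_hubs, length(members)))]
  })
  names(hubs) <- rownames(eigengenes)
  list(kme = kme, hubs = hubs)
}
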