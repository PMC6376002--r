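test_that("correlation matrix matches the direct sum formula", {
  set.seed(1)
  expr <- matrix(rnorm(4 * 12), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:12)))
  C <- correlation_matrix(expr)
  ## direct formula oracle
  for (i in 1:4) for (j in 1:4) {
    x <- expr[i, ]; y <- expr[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(C[i, j], r, tolerance = 1e-12)
  }
  ## duplicated gene and negated gene
  expr2 <- rbind(expr, g5 = expr[1, ], g6 = -expr[1, ])
  C2 <- correlation_matrix(expr2)
  expect_equal(unname(C2["g1", "g5"]), 1)
  expect_equal(unname(C2["g1", "g6"]), -1)
  ## zero-variance gene is an error naming the gene
  expr3 <- rbind(expr, flat = rep(2, 12))
  expect_error(correlation_matrix(expr3), "flat")
  expect_error(correlation_matrix(expr[, 1:2]), "3 samples")
})

test_that("adjacency follows the soft-threshold power laws", {
  r <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), nrow = 3)
  expect_equal(adjacency(r, 2)[1, 2], 0.25)
  expect_equal(adjacency(r, 7)[1, 3], 1)      # |r| = 1 for any power
  expect_equal(adjacency(r, 3)[2, 3], 0)      # r = 0 unsigned
  expect_equal(adjacency(r, 2, signed = TRUE)[1, 3], 0)  # signed: (1-1)/2
  expect_equal(adjacency(r, 1, signed = TRUE)[2, 3], 0.5)
  expect_error(adjacency(r, 0), "power")
})

test_that("TOM matches the brute-force triple-loop oracle", {
  ## 2-gene closed form: TOM_12 = a_12
  a2 <- matrix(c(1, 0.4, 0.4, 1), nrow = 2)
  expect_equal(tom(a2)[1, 2], 0.4, tolerance = 1e-12)
  ## complete graph saturates at 1
  ac <- matrix(1, 5, 5)
  expect_true(all(abs(tom(ac) - 1) < 1e-12))
  ## random 5-gene networks vs explicit oracle
  set.seed(2)
  for (rep in 1:25) {
    r <- matrix(runif(25, -1, 1), 5, 5)
    r <- (r + t(r)) / 2
    a <- adjacency(r, 2)
    expect_equal(unname(tom(a)), unname(tom_oracle(a)), tolerance = 1e-12)
  }
})

test_that("TOM stays within [0, 1] and symmetric on random admissible adjacencies", {
  set.seed(3)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    r <- matrix(runif(n * n, -1, 1), n, n)
    r <- (r + t(r)) / 2; diag(r) <- 1
    t_m <- tom(adjacency(r, sample(1:6, 1)))
    expect_true(all(t_m >= 0 & t_m <= 1))
    expect_lt(max(abs(t_m - t(t_m))), 1e-10)
  }
})

test_that("scale-free fit index matches an independent binned regression", {
  sim <- network_cohort(seed = 41, n_modules = 3, module_size = 40)
  corr <- correlation_matrix(sim$resid)
  cfg <- network_config(candidate_powers = c(2, 4, 6), n_degree_bins = 10)
  scan <- suppressWarnings(scan_soft_threshold(corr, cfg))
  ## oracle: re-derive the fit index by hand for each power
  for (i in seq_len(nrow(scan))) {
    a <- abs(corr)^scan$power[i]; diag(a) <- 1
    k <- rowSums(a) - 1
    br <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- as.vector(table(bin))
    mk <- tapply(k, bin, mean)
    ok <- freq > 0 & !is.na(mk) & mk > 0
    fit <- lm(log10(freq[ok]) ~ log10(mk[ok]))
    r2 <- if (coef(fit)[2] < 0) summary(fit)$r.squared else 0
    expect_equal(scan$fit_r2[i], unname(r2), tolerance = 1e-10)
  }
})

test_that("degenerate equal-connectivity input yields zero fit with a warning", {
  r <- matrix(1, 10, 10)
  w <- capture_warnings(scan <- scan_soft_threshold(r, network_config(candidate_powers = 2)))
  expect_match(w, "degenerate|no power", all = TRUE)
  expect_equal(scan$fit_r2[1], 0)
})

test_that("module detection recovers planted blocks and is deterministic", {
  ## two planted blocks of 50 genes with high within-block TOM
  set.seed(5)
  n <- 100
  f1 <- rnorm(40); f2 <- rnorm(40)
  expr <- rbind(
    t(sapply(1:50, function(i) f1 + rnorm(40, sd = 0.4))),
    t(sapply(1:50, function(i) f2 + rnorm(40, sd = 0.4))))
  rownames(expr) <- paste0("g", 1:n); colnames(expr) <- paste0("s", 1:40)
  tm <- tom(adjacency(correlation_matrix(expr), 6))
  cfg <- network_config(min_module_size = 30)
  asg <- detect_modules(tm, cfg)
  expect_setequal(unique(asg), c("M1", "M2"))
  expect_equal(length(unique(asg[1:50])), 1)
  expect_equal(length(unique(asg[51:100])), 1)
  ## deterministic across runs
  expect_identical(asg, detect_modules(tm, cfg))
  ## min size larger than gene count: everything unassigned with warning
  expect_warning(asg2 <- detect_modules(tm, network_config(min_module_size = 500)),
                 "min_module_size")
  expect_true(all(asg2 == "grey"))
})

test_that("identical genes collapse into a single module", {
  tm <- tom(matrix(1, 12, 12))
  rownames(tm) <- colnames(tm) <- paste0("g", 1:12)
  asg <- detect_modules(tm, network_config(min_module_size = 5))
  expect_equal(unname(table(asg)["M1"]), 12L, ignore_attr = TRUE)
})

test_that("eigengenes recover planted factors and are unit variance", {
  set.seed(6)
  nsamp <- 138
  f <- rnorm(nsamp)
  lambda <- runif(40, 0.5, 1.5)
  expr <- outer(lambda, f) + matrix(rnorm(40 * nsamp, sd = 0.05), nrow = 40)
  rownames(expr) <- paste0("g", 1:40); colnames(expr) <- paste0("s", 1:nsamp)
  asg <- setNames(rep("M1", 40), rownames(expr))
  e <- module_eigengene(expr, asg, "M1")
  expect_gte(abs(cor(e, f)), 0.99)
  expect_equal(var(e), 1, tolerance = 1e-9)
  ## orientation: positively correlated with its members on average
  expect_gt(mean(cor(e, t(expr))), 0)
  ## single-gene module equals the gene's z-scores
  asg1 <- setNames(c("M1", rep("grey", 39)), rownames(expr))
  e1 <- module_eigengene(expr, asg1, "M1")
  z <- as.numeric(scale(expr[1, ]))
  expect_equal(unname(e1), z, tolerance = 1e-9)
  expect_error(module_eigengene(expr, asg, "M9"), "empty")
})

test_that("modules from a shared factor merge; independent ones do not", {
  set.seed(7)
  nsamp <- 100
  f_shared <- rnorm(nsamp); f_other <- rnorm(nsamp)
  expr <- rbind(outer(runif(30, 0.8, 1.2), f_shared),
                outer(runif(30, 0.8, 1.2), f_shared),
                outer(runif(30, 0.8, 1.2), f_other)) +
    matrix(rnorm(90 * nsamp, sd = 0.3), nrow = 90)
  rownames(expr) <- paste0("g", 1:90); colnames(expr) <- paste0("s", 1:nsamp)
  asg <- setNames(rep(c("M1", "M2", "M3"), each = 30), rownames(expr))
  cfg <- network_config(min_module_size = 20)
  merged <- merge_modules(expr, asg, cfg)
  ## the two same-factor modules collapse, the independent one survives
  expect_equal(length(setdiff(unique(merged), "grey")), 2)
  expect_equal(length(unique(merged[1:60])), 1)
  expect_equal(length(unique(merged[61:90])), 1)
  ## post-condition: no remaining eigengene pair above the merge threshold
  E <- module_eigengenes(expr, merged, cfg)
  C <- cor(t(E))
  expect_lte(max(C[upper.tri(C)]), cfg$merge_correlation + 0.05)
})

test_that("kME table bounds, hub ordering, and rescue of unassigned genes", {
  set.seed(8)
  nsamp <- 120
  f <- rnorm(nsamp)
  lambda <- seq(1.5, 0.6, length.out = 30)
  expr <- outer(lambda, f) + matrix(rnorm(30 * nsamp, sd = 0.2), nrow = 30)
  noise <- matrix(rnorm(10 * nsamp), nrow = 10)
  expr <- rbind(expr, noise)
  rownames(expr) <- paste0("g", 1:40); colnames(expr) <- paste0("s", 1:nsamp)
  ## leave two true members unassigned, then rescue them
  asg <- setNames(c(rep("M1", 28), "grey", "grey", rep("grey", 10)),
                  rownames(expr))
  cfg <- network_config(min_module_size = 10, kme_rescue = 0.3)
  resc <- assign_by_kme(expr, asg, cfg)
  expect_identical(unname(resc[29:30]), c("M1", "M1"))
  expect_true(all(resc[31:40] == "grey"))
  eig <- module_eigengenes(expr, resc, cfg)
  kme <- intramodular_connectivity(expr, eig, resc, n_hubs = 5)
  expect_true(all(abs(kme$kme) <= 1))
  ## strongest-loading genes are the hubs
  expect_true(all(kme$hubs$M1 %in% paste0("g", 1:10)))
  ## a gene equal to the eigengene pattern has kME 1
  expr2 <- rbind(expr, g41 = eig["M1", ] * 2 + 3)
  resc2 <- c(resc, g41 = "M1")
  kme2 <- intramodular_connectivity(expr2, eig, resc2)
  expect_equal(unname(kme2$kme["g41", "M1"]), 1, tolerance = 1e-9)
})

test_that("permuting gene order permutes the module partition consistently", {
  sim <- network_cohort(seed = 12, n_modules = 3, module_size = 40)
  corr <- correlation_matrix(sim$resid)
  tm <- tom(adjacency(corr, 6))
  cfg <- network_config(min_module_size = 20)
  asg <- detect_modules(tm, cfg)
  set.seed(13)
  perm <- sample(nrow(tm))
  asg_p <- detect_modules(tm[perm, perm], cfg)
  ## same partition up to relabeling
  expect_equal(mclust::adjustedRandIndex(asg[perm], asg_p), 1)
})
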