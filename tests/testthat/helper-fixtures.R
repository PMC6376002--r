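## Small fixture builders shared across test files.

toy_counts <- function(mat, genes = sprintf("g%d", seq_len(nrow(mat))),
                       samples = sprintf("s%d", seq_len(ncol(mat)))) {
  m <- as.matrix(mat)
  dimnames(m) <- list(genes, samples)
  storage.mode(m) <- "integer"
  m
}

toy_samples <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    diagnosis = factor(rep(c("control", "case"), length.out = n),
                       levels = c("control", "case")),
    sex = factor(sample(c("M", "F"), n, replace = TRUE)),
    age = round(rnorm(n, 55, 10), 1),
    pmi = round(runif(n, 10, 50), 1),
    rin = round(runif(n, 5.5, 9.5), 1),
    brain_ph = round(rnorm(n, 6.5, 0.2), 2),
    batch = factor(sample(c("b1", "b2"), n, replace = TRUE)),
    alcohol_consumption = round(runif(n, 0, 200), 1),
    audit = sample(0:40, n, replace = TRUE),
    drinking_years = round(runif(n, 0, 40), 1),
    stringsAsFactors = FALSE)
}

## quick cohort for network tests: 5 modules x 60 genes, 138 samples
network_cohort <- function(seed = 11, n_modules = 5, module_size = 60,
                           n_extra = 0) {
  cfg <- sim_cohort_config(n_genes = n_modules * module_size + n_extra,
                           n_modules = n_modules,
                           module_sizes = rep(module_size, n_modules),
                           n_de_genes = 0, seed = seed)
  sim <- simulate_cohort(cfg)
  sim$resid <- residualize(log_cpm(sim$counts), sim$samples,
                           c("batch", "rin", "age"))
  sim
}

## independent brute-force TOM oracle (explicit triple loop)
tom_oracle <- function(adj) {
  n <- nrow(adj)
  A <- adj; diag(A) <- 0
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    out[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  out
}

## independent Fisher oracle: enumerate the hypergeometric support with
## log-factorial weights (no dhyper/phyper)
fisher_oracle <- function(a, b, c_, d, tail) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  logw <- lchoose(m, support) + lchoose(n2, k - support)
  w <- exp(logw - max(logw))
  prob <- w / sum(w)
  obs <- which(support == a)
  switch(tail,
         right = sum(prob[support >= a]),
         left = sum(prob[support <= a]),
         both = sum(prob[prob <= prob[obs] * (1 + 1e-7)]))
}
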