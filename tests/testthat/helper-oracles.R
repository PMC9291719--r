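# Independent oracles used to validate the package's implementations.
# These are deliberately naive (enumeration / O(n^2) brute force) and never
# share code with the implementation under test.

# Exact Shapley values by enumeration over all 2^M subsets, with
# weighted-background imputation of absent features.
brute_shapley <- function(predict_fn, x, centroids, weights) {
  M <- length(x)
  w <- weights / sum(weights)
  value_of <- function(members) {
    z <- integer(M)
    z[members] <- 1L
    v <- 0
    for (b in seq_len(nrow(centroids))) {
      row <- ifelse(z == 1L, x, centroids[b, ])
      Xb <- matrix(row, 1, dimnames = list(NULL, names(x)))
      v <- v + w[b] * as.numeric(predict_fn(Xb))
    }
    v
  }
  # cache all subset values keyed by bitmask
  vals <- numeric(2^M)
  for (mask in 0:(2^M - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(M) - 1)) > 0)
    vals[mask + 1] <- value_of(members)
  }
  phi <- numeric(M)
  for (i in seq_len(M)) {
    bit <- 2^(i - 1)
    for (mask in 0:(2^M - 1)) {
      if (bitwAnd(mask, bit) > 0) next
      s <- sum(bitwAnd(mask, 2^(seq_len(M) - 1)) > 0)
      wgt <- factorial(s) * factorial(M - s - 1) / factorial(M)
      phi[i] <- phi[i] + wgt * (vals[mask + bit + 1] - vals[mask + 1])
    }
  }
  names(phi) <- names(x)
  phi
}

# O(n^2) Dunn index by explicit double loops.
brute_dunn <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  inter <- Inf
  diam <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- d(i, j)
      if (labels[i] == labels[j]) diam <- max(diam, dij)
      else inter <- min(inter, dij)
    }
  }
  if (diam == 0) Inf else inter / diam
}

# Adjusted Rand index for comparing two partitions.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# A small random smooth model for SHAP oracle tests: linear + pairwise
# interaction + a bounded nonlinearity, with coefficients drawn per seed.
random_model_fn <- function(M, seed) {
  set.seed(seed)
  a <- rnorm(M)
  B <- matrix(rnorm(M * M, sd = 0.3), M, M)
  c0 <- rnorm(1)
  function(X) {
    X <- as.matrix(X)
    as.numeric(c0 + X %*% a + rowSums((X %*% B) * X) + tanh(rowSums(X)))
  }
}

# Small genotype fixture: flat data frame of SNPs with constant MAF.
flat_snp_spec <- function(m, maf = 0.3, chrom = "1") {
  data.frame(snp_id = sprintf("s%03d", seq_len(m)), chrom = chrom,
             pos = seq_len(m) * 1000L, maf = maf,
             stringsAsFactors = FALSE)
}

# A cohort + genotypes + feature-set map with one planted causal feature set.
# The causal SNPs are chosen from the connected gene exclusive to one FS, so
# only that FS carries signal. Returns everything needed by search tests.
planted_fs_fixture <- function(n_samples = 2000, n_fs = 10, beta = 1.0,
                               n_causal = 3, seed = 1) {
  ann <- simulate_annotations(n_druggable = 1,
                              connected_per_druggable = n_fs,
                              snps_per_gene = 6, pass_fraction = 1,
                              seed = seed)
  G <- simulate_genotypes(n_samples, ann, seed = seed + 1)
  fsm <- build_fs_from_annotation(ann, G)
  target <- names(fsm)[ceiling(length(fsm) / 2)]
  exclusive <- setdiff(fsm[[target]],
                       unique(unlist(fsm[setdiff(names(fsm), target)])))
  causal <- utils::head(exclusive, n_causal)
  b <- stats::setNames(rep(beta, length(causal)), causal)
  maf <- ann$snps$maf[match(causal, ann$snps$snp_id)]
  # prevalence ~0.45 so controls always outnumber cases for down-sampling
  model <- generative_model(
    causal_sets = list(b),
    baseline_log_odds = stats::qlogis(0.45) - sum(b * 2 * maf),
    covariate_effects = list(age = 0, sex = 0),
    seed = seed + 2)
  cohort <- simulate_phenotype(G, model)
  list(annotation = ann, G = G, fs_map = fsm, target = target,
       model = model, cohort = cohort, causal = b)
}

# Fast operator pool for search tests (logistic regression only).
fast_pool <- function(problem = "classification") {
  operator_pool(problem, transformers = c("identity", "standardize"),
                estimators = "linear")
}
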