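# Model explanation: well-predicted case selection, permutation importance,
# Dunn index, k selection, kernel SHAP against brute-force Shapley, SHAP
# clustering, rankings, force-matrix export.

test_that("well-predicted case selection covers both modes and ties", {
  # classification: correctly classified cases only
  pred <- c(0.9, 0.4, 0.6, 0.2, 0.8)
  truth <- c(1, 1, 1, 0, 0)
  expect_identical(select_well_predicted(pred, truth, "classification"),
                   c(1L, 3L))
  # a perfect classifier returns every case
  expect_identical(select_well_predicted(truth, truth, "classification"),
                   which(truth == 1))
  # regression: bottom quartile of |observed - predicted| among cases
  set.seed(12)
  n <- 1000
  obs <- rnorm(2 * n)
  prd <- obs + rnorm(2 * n)
  cases <- rep(c(TRUE, FALSE), each = n)
  idx <- select_well_predicted(prd, obs, "regression", cases = cases)
  expect_length(idx, 250)
  expect_true(all(cases[idx]))
  # sorted-order oracle: exactly the 250 smallest errors among cases
  err <- abs(obs - prd)[cases]
  expect_setequal(idx, which(cases)[order(err)[1:250]])
  # ties at the cutoff are all included
  prd2 <- obs
  prd2[1:8] <- obs[1:8] + rep(c(0, 1), c(4, 4))
  idx2 <- select_well_predicted(prd2[1:8], obs[1:8], "regression",
                                cases = rep(TRUE, 8))
  expect_identical(idx2, 1:4)
  expect_error(select_well_predicted(prd, obs, "regression"), "cases")
  expect_error(select_well_predicted(c(0.1), c(1), "classification"),
               "no well-predicted")
})

test_that("permutation importance isolates the informative feature", {
  set.seed(13)
  n <- 400
  X <- cbind(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- as.integer(X[, "signal"] > 0)
  model <- function(Z) as.numeric(Z[, "signal"] > 0)  # deterministic
  imp <- permutation_importance(model, X, y, "accuracy", n_repeats = 20,
                                seed = 14)
  expect_s3_class(imp, "importance_table")
  expect_equal(imp$feature[1], "signal")
  # analytic drop: baseline 1.0, shuffled accuracy ~0.5 on balanced labels
  se <- sqrt(0.25 / n) / sqrt(20)
  expect_lt(abs(imp$importance[imp$feature == "signal"] - 0.5), 3 * se + 0.02)
  # unused features have importance ~ 0
  for (f in c("noise1", "noise2"))
    expect_lt(abs(imp$importance[imp$feature == f]), 1e-12)
  # invariance to feature column order
  imp2 <- permutation_importance(function(Z) as.numeric(Z[, "signal"] > 0),
                                 X[, c(3, 1, 2)], y, "accuracy",
                                 n_repeats = 20, seed = 14)
  expect_equal(imp2$importance[imp2$feature == "signal"],
               imp$importance[imp$feature == "signal"], tolerance = 0.03)
})

test_that("Dunn index matches hand computation and brute force", {
  # min inter-cluster distance 10 ((0,0)-(10,0)), max diameter 1
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labels <- c(1, 1, 2, 2)
  expect_equal(dunn_index(pts, labels), 10 / 1, tolerance = 1e-12)
  expect_equal(dunn_index(pts, labels), brute_dunn(pts, labels))
  # degenerate: all diameters zero -> +Inf with a warning
  ident <- rbind(c(0, 0), c(0, 0), c(5, 5))
  expect_warning(d <- dunn_index(ident, c(1, 1, 2)), "Inf")
  expect_identical(d, Inf)
  # identical points in one cluster, far from the other: large finite value
  pts2 <- rbind(c(0, 0), c(0, 0), c(9, 0), c(9, 1))
  expect_gt(dunn_index(pts2, c(1, 1, 2, 2)), 5)
  expect_error(dunn_index(pts, rep(1, 4)), "two clusters")
  # brute-force oracle on random instances
  for (s in 1:50) {
    set.seed(s)
    n <- sample(10:100, 1)
    k <- sample(2:5, 1)
    P <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(k, n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- 1:2
    expect_equal(dunn_index(P, lab), brute_dunn(P, lab), tolerance = 1e-10)
  }
})

test_that("Dunn-guided k selection recovers planted blob counts", {
  set.seed(15)
  blobs <- rbind(matrix(rnorm(60, 0), ncol = 2),
                 matrix(rnorm(60, 8), ncol = 2),
                 matrix(rnorm(60, c(0, 16)), ncol = 2))
  sel <- select_k_by_dunn(blobs, 2:6, seed = 16)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$report), 5)
  expect_equal(sel$assignment$k, 3)
  # singleton range returns that k
  sel1 <- select_k_by_dunn(blobs, 4, seed = 16)
  expect_equal(sel1$k, 4)
  expect_error(select_k_by_dunn(blobs, integer(0)), "empty")
  expect_error(select_k_by_dunn(blobs, c(1, 3)), "k_range")
})

test_that("k-means background conserves weights and snaps to the support", {
  set.seed(17)
  X <- matrix(sample(c(0, 1, 2), 200, replace = TRUE), 50, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  bg <- kmeans_background(X, k = 5, seed = 18)
  expect_equal(sum(bg$weights), 50)
  expect_equal(bg$k, 5)
  for (j in 1:4)
    expect_true(all(bg$centroids[, j] %in% X[, j]))
  expect_error(kmeans_background(X, k = 50), "smaller")
  # with k = number of distinct rows, centroids are data rows with
  # multiplicity weights
  Xd <- rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 0))
  colnames(Xd) <- c("a", "b")
  bgd <- kmeans_background(Xd, k = 3, seed = 19)
  expect_equal(sum(bgd$weights), 4)
  rows <- apply(bgd$centroids, 1, paste, collapse = ",")
  expect_setequal(rows, c("0,0", "1,1", "2,0"))
  expect_equal(sort(bgd$weights), c(1, 1, 2))
})

test_that("full-coalition kernel SHAP equals brute-force Shapley", {
  for (s in 1:10) {
    set.seed(s)
    M <- sample(2:8, 1)
    f <- random_model_fn(M, seed = 100 + s)
    x <- setNames(rnorm(M), paste0("f", seq_len(M)))
    k <- sample(2:5, 1)
    centroids <- matrix(rnorm(k * M), k, M,
                        dimnames = list(NULL, names(x)))
    w <- sample(1:5, k, replace = TRUE)
    bg <- structure(list(centroids = centroids, weights = w, k = k),
                    class = "shap_background")
    ks <- kernel_shap(f, x, bg, n_coalitions = "all")
    phi <- brute_shapley(f, x, centroids, w)
    expect_lt(max(abs(ks$shap - phi)), 1e-6)
    # local accuracy
    fx <- as.numeric(f(matrix(x, 1, dimnames = list(NULL, names(x)))))
    expect_lt(abs(ks$base_value + sum(ks$shap) - fx), 1e-6)
  }
})

test_that("kernel SHAP closed forms: linear and constant models", {
  a <- c(2, -1, 0.5, 3)
  f <- function(X) as.matrix(X) %*% a
  x <- setNames(c(1, 0, 2, -1), paste0("g", 1:4))
  b <- matrix(c(0.5, 1, 0, 0.25), 1, dimnames = list(NULL, names(x)))
  ks <- kernel_shap(function(X) as.numeric(f(X)), x, b)
  expect_equal(unname(ks$shap), a * (x - b[1, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(ks$base_value, as.numeric(f(b)), tolerance = 1e-10)
  # constant model: zero attributions, base equals the constant
  kc <- kernel_shap(function(X) rep(7, nrow(X)), x, b)
  expect_equal(unname(kc$shap), rep(0, 4), tolerance = 1e-10)
  expect_equal(kc$base_value, 7)
  expect_error(kernel_shap(function(X) 1, numeric(0), b), "no features")
})

test_that("sampled-coalition mode keeps local accuracy and approximates the
           exact values", {
  set.seed(21)
  M <- 10
  f <- random_model_fn(M, seed = 22)
  x <- setNames(rnorm(M), paste0("f", 1:M))
  centroids <- matrix(rnorm(3 * M), 3, M, dimnames = list(NULL, names(x)))
  bg <- structure(list(centroids = centroids, weights = c(1, 1, 1), k = 3),
                  class = "shap_background")
  exact <- kernel_shap(f, x, bg, "all")
  sampled <- kernel_shap(f, x, bg, n_coalitions = 300, seed = 23)
  fx <- as.numeric(f(matrix(x, 1, dimnames = list(NULL, names(x)))))
  expect_lt(abs(sampled$base_value + sum(sampled$shap) - fx), 1e-3)
  expect_lt(max(abs(sampled$shap - exact$shap)), 0.5)
  expect_gt(cor(sampled$shap, exact$shap), 0.95)
})

test_that("shap_matrix satisfies row-wise local accuracy", {
  set.seed(24)
  f <- function(X) as.numeric(plogis(as.matrix(X) %*% c(1, -2, 0.5)))
  cases <- matrix(sample(0:2, 30, TRUE), 10, 3,
                  dimnames = list(paste0("c", 1:10), paste0("s", 1:3)))
  bgX <- matrix(sample(0:2, 15, TRUE), 5, 3,
                dimnames = list(NULL, paste0("s", 1:3)))
  S <- shap_matrix(f, cases, bgX)
  expect_equal(dim(S$values), c(10, 3))
  outs <- S$base_value + rowSums(S$values)
  expect_lt(max(abs(outs - f(cases))), 1e-6)
  # constant model gives the zero matrix
  S0 <- shap_matrix(function(X) rep(2, nrow(X)), cases, bgX)
  expect_lt(max(abs(S0$values)), 1e-10)
  expect_equal(S0$base_value, 2)
})

test_that("SHAP clustering recovers planted structure and honors override", {
  set.seed(25)
  vals <- rbind(matrix(rnorm(40 * 3, mean = 0, sd = 0.2), 40, 3),
                sweep(matrix(rnorm(40 * 3, sd = 0.2), 40, 3), 2, c(3, -3, 0),
                      "+"))
  S <- structure(list(values = vals, base_value = 0.5,
                      case_ids = as.character(1:80),
                      feature_ids = paste0("s", 1:3)),
                 class = "shap_matrix")
  truth <- rep(1:2, each = 40)
  cl <- cluster_cases_by_shap(S, k_range = 2:5, seed = 26)
  expect_gte(adjusted_rand_index(cl$labels, truth), 0.9)
  cl4 <- cluster_cases_by_shap(S, seed = 26, k_override = 4)
  expect_equal(cl4$k, 4)
  expect_length(unique(cl4$labels), 4)
  # permuting case order permutes labels identically
  perm <- sample(80)
  Sp <- S; Sp$values <- vals[perm, ]; Sp$case_ids <- S$case_ids[perm]
  clp <- cluster_cases_by_shap(Sp, seed = 26, k_override = 2)
  cl2 <- cluster_cases_by_shap(S, seed = 26, k_override = 2)
  expect_gte(adjusted_rand_index(clp$labels, cl2$labels[perm]), 0.999)
  expect_error(cluster_cases_by_shap(S, seed = 1, k_override = 100),
               "k_override")
})

test_that("per-cluster rankings follow mean absolute SHAP with id ties", {
  vals <- rbind(c(0.5, 0, 0), c(0.3, 0, 0), c(0.2, 0.1, 0))
  S <- structure(list(values = vals, base_value = 0,
                      case_ids = paste0("c", 1:3),
                      feature_ids = c("b", "a", "c")),
                 class = "shap_matrix")
  cl <- structure(list(labels = c(1, 1, 2), k = 2, dunn = 1, seed = 1),
                  class = "cluster_assignment")
  rk <- rank_features_per_cluster(S, cl)
  expect_named(rk, c("cluster1", "cluster2"))
  expect_equal(rk$cluster1$feature[1], "b")
  # recompute oracle
  expect_equal(rk$cluster1$mean_abs_shap,
               sort(colMeans(abs(vals[1:2, ])), decreasing = TRUE),
               ignore_attr = TRUE)
  # zero-valued features tie and order alphabetically
  expect_equal(rk$cluster1$feature[2:3], c("a", "c"))
  rk5 <- rank_features_per_cluster(S, cl, top_m = 1)
  expect_setequal(attr(rk5, "top_union"), "b")
  expect_error(rank_features_per_cluster(S, c(1, 1)), "cover")
})

test_that("force-matrix export round-trips and seriates identical rows
           adjacently", {
  set.seed(27)
  vals <- matrix(rnorm(12), 4, 3,
                 dimnames = list(paste0("c", 1:4), paste0("s", 1:3)))
  vals[3, ] <- vals[1, ]  # duplicate rows must end up adjacent
  S <- structure(list(values = vals, base_value = 0.4,
                      case_ids = rownames(vals), feature_ids = colnames(vals)),
                 class = "shap_matrix")
  fm <- export_force_matrix(S)
  # reconstruct the matrix exactly
  back <- matrix(fm$shap, 4, 3, byrow = TRUE,
                 dimnames = list(unique(fm$case), unique(fm$feature)))
  expect_equal(back, vals)
  expect_equal(unique(fm$base_value), 0.4)
  expect_equal(fm$model_output, unname(rep(0.4 + rowSums(vals), each = 3)))
  ord <- fm$case_order[seq(1, 12, by = 3)]
  expect_equal(abs(ord[1] - ord[3]), 1)  # identical rows adjacent
  # caller-provided order is respected
  fm2 <- export_force_matrix(S, order = "given", case_order = c(4, 3, 2, 1))
  expect_equal(fm2$case_order[seq(1, 12, by = 3)], c(4, 3, 2, 1))
  # file export writes a readable TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  export_force_matrix(S, path = path)
  expect_equal(nrow(read.delim(path)), 12)
})
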