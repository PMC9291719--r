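# Kernel SHAP: model-agnostic Shapley-value estimation by weighted least
# squares over feature coalitions, with a weighted k-means background for
# imputing absent features. With all coalitions enumerated the solution is
# the exact Shapley value; sampled-coalition mode uses paired sampling with
# the local-accuracy sum constraint imposed by elimination.

#' Weighted k-means background for the kernel explainer
#'
#' Summarizes the training data into `k` weighted centroids used to impute
#' "absent" features in coalitions. Each centroid coordinate is snapped to
#' the nearest observed value of that feature in the training data, keeping
#' dosage-like features on their support.
#'
#' @param X_train training feature matrix.
#' @param k number of clusters (`k < nrow(X_train)`).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return an object of class `shap_background` with `centroids` (k x
#'   features), `weights` (cluster sizes, summing to `nrow(X_train)`) and
#'   `k`.
#' @export
kmeans_background <- function(X_train, k, seed = 1, nstart = 10) {
  X_train <- as.matrix(X_train)
  if (k >= nrow(X_train))
    stop("background size k must be smaller than the training set",
         call. = FALSE)
  km <- with_seed(seed, stats::kmeans(X_train, centers = k, nstart = nstart))
  centroids <- km$centers
  for (j in seq_len(ncol(centroids))) {
    obs <- sort(unique(X_train[, j]))
    centroids[, j] <- vapply(centroids[, j], function(v)
      obs[which.min(abs(obs - v))], numeric(1))
  }
  colnames(centroids) <- colnames(X_train)
  structure(list(centroids = centroids, weights = as.numeric(km$size), k = k),
            class = "shap_background")
}

#' @export
print.shap_background <- function(x, ...) {
  cat("SHAP background:", x$k, "weighted centroids over",
      ncol(x$centroids), "features (", sum(x$weights), "training rows )\n")
  invisible(x)
}

as_background <- function(background) {
  if (inherits(background, "shap_background")) return(background)
  B <- as.matrix(background)
  if (!nrow(B)) stop("background is empty", call. = FALSE)
  structure(list(centroids = B, weights = rep(1, nrow(B)), k = nrow(B)),
            class = "shap_background")
}

# all coalition indicator rows of size 1..M-1 (excludes empty and full)
all_coalitions <- function(M) {
  if (M > 20) stop("full enumeration limited to M <= 20 features", call. = FALSE)
  Z <- as.matrix(expand.grid(rep(list(0:1), M)))[, M:1, drop = FALSE]
  s <- rowSums(Z)
  unname(Z[s > 0 & s < M, , drop = FALSE])
}

kernel_weight <- function(M, s) (M - 1) / (choose(M, s) * s * (M - s))

# model value of coalitions: weighted-background imputation of absent features
coalition_values <- function(predict_fn, x, Z, bg) {
  w <- bg$weights / sum(bg$weights)
  v <- numeric(nrow(Z))
  for (b in seq_len(nrow(bg$centroids))) {
    Xb <- Z * matrix(x, nrow(Z), length(x), byrow = TRUE) +
      (1 - Z) * matrix(bg$centroids[b, ], nrow(Z), length(x), byrow = TRUE)
    colnames(Xb) <- colnames(bg$centroids)
    v <- v + w[b] * as.numeric(predict_fn(Xb))
  }
  v
}

#' Kernel SHAP values for one instance
#'
#' Solves the weighted least-squares system of the kernel method: coalitions
#' `z` are weighted by `(M-1) / (choose(M,|z|) |z| (M-|z|))`, absent features
#' are imputed from the weighted background, and the additive attributions
#' are constrained to sum to `f(x) - base_value` (local accuracy, imposed by
#' elimination). With `n_coalitions = "all"` every non-trivial coalition is
#' enumerated and the solution equals the exact Shapley value. Otherwise
#' coalitions are drawn in complementary pairs with size probabilities
#' proportional to the aggregated kernel mass.
#'
#' @param predict_fn function mapping a feature matrix to model outputs
#'   (probabilities for classifiers, predictions for regressors).
#' @param x a single instance (named numeric vector).
#' @param background a `shap_background` or a background matrix.
#' @param n_coalitions `"all"` or a number of sampled coalitions.
#' @param seed RNG seed (used in sampled mode).
#' @return list with `shap` (named attribution vector) and `base_value` (the
#'   weighted-background expected model output).
#' @export
kernel_shap <- function(predict_fn, x, background, n_coalitions = "all",
                        seed = 1) {
  bg <- as_background(background)
  x <- unlist(x)
  M <- length(x)
  if (M == 0) stop("instance has no features", call. = FALSE)
  base <- sum(bg$weights / sum(bg$weights) *
                as.numeric(predict_fn(bg$centroids)))
  fx <- as.numeric(predict_fn(matrix(x, 1, dimnames = list(NULL, names(x)))))
  if (M == 1) {
    phi <- fx - base
    names(phi) <- names(x)
    return(list(shap = phi, base_value = base))
  }
  full <- identical(n_coalitions, "all") || (is.numeric(n_coalitions) &&
                                               n_coalitions >= 2^M - 2)
  Z <- if (full) all_coalitions(M) else
    sample_coalitions(M, n_coalitions, seed)
  kw <- kernel_weight(M, rowSums(Z))
  v <- coalition_values(predict_fn, x, Z, bg)
  # eliminate phi_M via the sum constraint phi_1 + ... + phi_M = fx - base
  d <- fx - base
  A <- Z[, -M, drop = FALSE] - Z[, M]
  t <- v - base - Z[, M] * d
  AtW <- t(A * kw)
  lhs <- AtW %*% A
  rhs <- AtW %*% t
  phi_head <- tryCatch(as.numeric(solve(lhs, rhs)),
                       error = function(e) as.numeric(MASS::ginv(lhs) %*% rhs))
  phi <- c(phi_head, d - sum(phi_head))
  names(phi) <- names(x)
  list(shap = phi, base_value = base)
}

# paired coalition sampling: sizes drawn with probability proportional to the
# kernel mass per size; each sampled subset enters with its complement
sample_coalitions <- function(M, n_coalitions, seed) {
  with_seed(seed, {
    sizes <- 1:(M - 1)
    size_mass <- (M - 1) / (sizes * (M - sizes))
    size_prob <- size_mass / sum(size_mass)
    n_pairs <- max(ceiling(n_coalitions / 2), M)  # enough rows for full rank
    seen <- new.env(parent = emptyenv())
    rows <- list()
    add <- function(z) {
      key <- paste(z, collapse = "")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        rows[[length(rows) + 1L]] <<- z
      }
    }
    # always include all singleton and leave-one-out coalitions (largest
    # kernel weights; guarantees identifiability of every feature)
    for (i in seq_len(M)) {
      z <- integer(M); z[i] <- 1L; add(z); add(1L - z)
    }
    for (p in seq_len(n_pairs)) {
      s <- sample(sizes, 1L, prob = size_prob)
      z <- integer(M)
      z[sample.int(M, s)] <- 1L
      add(z); add(1L - z)
    }
    do.call(rbind, rows)
  })
}

#' SHAP matrix for a set of cases
#'
#' Runs [kernel_shap()] for each case against a shared background; all rows
#' share one base value (the expected model output over the background).
#'
#' @param predict_fn model prediction function.
#' @param cases feature matrix of the cases to explain (rows = cases).
#' @param background `shap_background` or background matrix.
#' @param n_coalitions `"all"` or a count, passed to [kernel_shap()].
#' @param seed base seed; per-case seeds are derived from it.
#' @return an object of class `shap_matrix`: `values` (cases x features),
#'   `base_value`, `case_ids`, `feature_ids`.
#' @export
shap_matrix <- function(predict_fn, cases, background, n_coalitions = "all",
                        seed = 1) {
  cases <- as.matrix(cases)
  if (!nrow(cases)) stop("no cases to explain", call. = FALSE)
  bg <- as_background(background)
  vals <- matrix(NA_real_, nrow(cases), ncol(cases))
  base <- NA_real_
  for (i in seq_len(nrow(cases))) {
    ks <- kernel_shap(predict_fn, cases[i, ], bg, n_coalitions,
                      seed = derive_seed(seed, i))
    vals[i, ] <- ks$shap
    base <- ks$base_value
  }
  dimnames(vals) <- dimnames(cases)
  structure(list(values = vals, base_value = base,
                 case_ids = rownames(cases) %||% as.character(seq_len(nrow(cases))),
                 feature_ids = colnames(cases) %||% as.character(seq_len(ncol(cases)))),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat("SHAP matrix:", nrow(x$values), "cases x", ncol(x$values),
      "features; base value", signif(x$base_value, 4), "\n")
  invisible(x)
}

#' @export
plot.shap_matrix <- function(x, ...) {
  graphics::image(t(x$values), xlab = "feature", ylab = "case",
                  main = "SHAP attributions", ...)
  invisible(x)
}
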