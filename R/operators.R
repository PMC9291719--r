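# Operator pool for the reduced pipeline search: a small library of
# transformers and estimators with tiny hyperparameter grids. Estimator fits
# delegate to glm / glmnet / ranger / xgboost; the search layer treats every
# operator through the same fit/apply/predict surface.

#' Define the operator pool for the pipeline search
#'
#' The reduced search engine explores pipelines of the form
#' (FSS ->) Transformer -> Estimator. This function declares which operators
#' and hyperparameter values the search may draw from.
#'
#' Transformers: `identity`, `standardize` (train-set centering/scaling),
#' `variance_threshold` (drop near-constant features; hyperparameter
#' `threshold`), `select_percentile` (keep the top fraction of features by
#' univariate association with the outcome; hyperparameter `percentile`).
#'
#' Estimators (classification / regression): `linear` (logistic regression /
#' OLS), `ridge` (glmnet, alpha = 0; hyperparameter `lambda`),
#' `random_forest` (ranger; hyperparameter `num_trees`), `gbt` (xgboost;
#' hyperparameters `nrounds`, `max_depth`). Classifiers output case
#' probabilities; regressors output predictions.
#'
#' @param problem `"classification"` or `"regression"`.
#' @param transformers,estimators character vectors selecting a subset of the
#'   pool (useful for fast test configurations).
#' @param grids optional named list overriding hyperparameter grids, e.g.
#'   `list(ridge = list(lambda = c(0.1, 1)))`.
#' @return an object of class `operator_pool`.
#' @export
operator_pool <- function(problem = c("classification", "regression"),
                          transformers = c("identity", "standardize",
                                           "variance_threshold",
                                           "select_percentile"),
                          estimators = c("linear", "ridge", "random_forest",
                                         "gbt"),
                          grids = list()) {
  problem <- match.arg(problem)
  default_grids <- list(
    identity = list(),
    standardize = list(),
    variance_threshold = list(threshold = c(0, 0.05, 0.1)),
    select_percentile = list(percentile = c(25, 50, 75, 100)),
    linear = list(),
    ridge = list(lambda = c(0.01, 0.1, 1)),
    random_forest = list(num_trees = c(50, 100)),
    gbt = list(nrounds = c(30), max_depth = c(2, 3))
  )
  for (nm in names(grids)) default_grids[[nm]] <- grids[[nm]]
  structure(list(problem = problem,
                 transformers = transformers,
                 estimators = estimators,
                 grids = default_grids),
            class = "operator_pool")
}

#' @export
print.operator_pool <- function(x, ...) {
  cat("Operator pool (", x$problem, "): transformers {",
      paste(x$transformers, collapse = ", "), "} x estimators {",
      paste(x$estimators, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# sample one hyperparameter setting for an operator
sample_params <- function(pool, name) {
  grid <- pool$grids[[name]]
  if (!length(grid)) return(list())
  lapply(grid, function(v) v[[sample.int(length(v), 1L)]])
}

# Transformers ----------------------------------------------------------------

fit_transformer <- function(name, params, X, y, problem) {
  state <- switch(name,
    identity = list(),
    standardize = {
      mu <- colMeans(X)
      sdv <- apply(X, 2, stats::sd)
      sdv[sdv == 0] <- 1
      list(mu = mu, sd = sdv)
    },
    variance_threshold = {
      v <- apply(X, 2, stats::var)
      keep <- which(v > params$threshold)
      if (!length(keep)) keep <- which.max(v)  # never emit zero features
      list(keep = keep)
    },
    select_percentile = {
      score <- apply(X, 2, function(col) {
        if (stats::sd(col) == 0) return(0)
        abs(suppressWarnings(stats::cor(col, y)))
      })
      score[is.na(score)] <- 0
      k <- max(1L, ceiling(params$percentile / 100 * ncol(X)))
      list(keep = order(score, decreasing = TRUE)[seq_len(k)])
    },
    stop("unknown transformer: ", name)
  )
  structure(list(name = name, params = params, state = state),
            class = "fs_transformer")
}

apply_transformer <- function(tr, X) {
  switch(tr$name,
    identity = X,
    standardize = sweep(sweep(X, 2, tr$state$mu), 2, tr$state$sd, "/"),
    variance_threshold = X[, tr$state$keep, drop = FALSE],
    select_percentile = X[, sort(tr$state$keep), drop = FALSE]
  )
}

# Estimators ------------------------------------------------------------------

fit_estimator <- function(name, params, X, y, problem) {
  classif <- problem == "classification"
  fit <- switch(name,
    linear = {
      Xi <- cbind(1, X)
      if (classif) {
        f <- suppressWarnings(stats::glm.fit(Xi, y, family = stats::binomial()))
      } else {
        f <- stats::lm.fit(Xi, y)
      }
      co <- f$coefficients
      co[is.na(co)] <- 0
      list(coef = co)
    },
    ridge = {
      Xg <- if (ncol(X) < 2) cbind(X, 0) else X  # glmnet needs >= 2 columns
      glmnet::glmnet(Xg, y, family = if (classif) "binomial" else "gaussian",
                     alpha = 0, lambda = params$lambda)
    },
    random_forest = {
      yy <- if (classif) factor(y, levels = c(0, 1)) else y
      ranger::ranger(x = X, y = yy, num.trees = params$num_trees,
                     probability = classif, num.threads = 1,
                     seed = sample.int(.Machine$integer.max, 1L))
    },
    gbt = {
      yy <- if (classif) factor(y, levels = c(0, 1)) else y
      xgboost::xgboost(X, yy, nrounds = params$nrounds,
                       max_depth = params$max_depth, nthread = 1,
                       verbosity = 0)
    },
    stop("unknown estimator: ", name)
  )
  structure(list(name = name, params = params, fit = fit, problem = problem),
            class = "fs_estimator")
}

predict_estimator <- function(est, X) {
  classif <- est$problem == "classification"
  switch(est$name,
    linear = {
      eta <- as.numeric(cbind(1, X) %*% est$fit$coef)
      if (classif) stats::plogis(eta) else eta
    },
    ridge = {
      Xg <- if (ncol(X) < 2) cbind(X, 0) else X
      as.numeric(stats::predict(est$fit, Xg,
                                type = if (classif) "response" else "link"))
    },
    random_forest = {
      p <- stats::predict(est$fit, data = X, num.threads = 1)$predictions
      if (classif) p[, "1"] else p
    },
    gbt = {
      p <- stats::predict(est$fit, X, type = "response")
      if (is.matrix(p)) p <- p[, ncol(p)]
      as.numeric(p)
    }
  )
}

# Pipelines -------------------------------------------------------------------

# spec: list(fs = chr or NA, trans = list(name, params),
#            est = list(name, params))
fit_pipeline <- function(spec, X, y, problem, fs_map = NULL) {
  feats <- colnames(X)
  if (!is.null(spec$fs) && !is.na(spec$fs)) {
    members <- fs_map[[spec$fs]]
    if (is.null(members)) stop("unknown feature set: ", spec$fs, call. = FALSE)
    feats <- intersect(colnames(X), members)
    if (!length(feats)) stop("feature set has no columns in data", call. = FALSE)
    X <- X[, feats, drop = FALSE]
  }
  tr <- fit_transformer(spec$trans$name, spec$trans$params, X, y, problem)
  Xt <- apply_transformer(tr, X)
  est <- fit_estimator(spec$est$name, spec$est$params, Xt, y, problem)
  structure(list(spec = spec, problem = problem, features = feats,
                 transformer = tr, estimator = est),
            class = "fs_pipeline")
}

#' Predict from a fitted pipeline
#'
#' @param object an `fs_pipeline` (as stored in a search result).
#' @param newdata samples x SNPs dosage matrix containing the pipeline's
#'   features.
#' @param ... unused.
#' @return numeric predictions: case probabilities for classification
#'   pipelines, values for regression pipelines.
#' @export
predict.fs_pipeline <- function(object, newdata, ...) {
  X <- newdata[, object$features, drop = FALSE]
  Xt <- apply_transformer(object$transformer, X)
  predict_estimator(object$estimator, Xt)
}

#' @export
print.fs_pipeline <- function(x, ...) {
  fs <- x$spec$fs
  cat("Pipeline:",
      if (!is.null(fs) && !is.na(fs)) paste0("FSS[", fs, "] -> ") else "",
      x$spec$trans$name, " -> ", x$spec$est$name,
      " (", x$problem, ")\n", sep = "")
  invisible(x)
}

spec_key <- function(spec) {
  paste(spec$fs %||% "-", spec$trans$name,
        paste(unlist(spec$trans$params), collapse = ","),
        spec$est$name, paste(unlist(spec$est$params), collapse = ","),
        sep = "|")
}
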