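# Leakage-free covariate residual adjustment ("resAdj"): ordinary
# least-squares coefficients fitted on training rows only, applied as
# residuals to any row set. Adjusting the outcome turns classification into
# regression downstream.

#' Fit a leakage-free covariate adjuster
#'
#' For each column of `x`, fits OLS coefficients on covariates using
#' *training rows only*. [apply_adjuster()] then returns residuals
#' (column minus covariate prediction) for any row set, so holdout rows never
#' influence the fit. Rank-deficient covariate matrices are handled via the
#' Moore-Penrose pseudoinverse with a warning.
#'
#' @param x numeric vector or matrix to adjust (e.g. the outcome, or the
#'   dosage matrix).
#' @param covariates numeric matrix or data frame of covariates, rows aligned
#'   with `x`.
#' @param train_idx integer indices of the training rows used for fitting.
#' @return an object of class `fs_adjuster` holding the per-column
#'   coefficients (intercept first) and the covariate column names.
#' @export
fit_adjuster <- function(x, covariates, train_idx) {
  X <- as.matrix(x)
  Cv <- as.matrix(covariates)
  stopifnot(nrow(X) == nrow(Cv))
  if (anyNA(Cv[train_idx, ]))
    stop("covariates must be complete on training rows", call. = FALSE)
  B <- cbind(`(Intercept)` = 1, Cv[train_idx, , drop = FALSE])
  Y <- X[train_idx, , drop = FALSE]
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    warning("rank-deficient covariates; using pseudoinverse", call. = FALSE)
    coef <- MASS::ginv(B) %*% Y
  } else {
    coef <- qr.coef(qrB, Y)
  }
  dimnames(coef) <- list(colnames(B), colnames(X))
  structure(list(coef = coef, covariate_names = colnames(Cv)),
            class = "fs_adjuster")
}

#' Apply a fitted adjuster to any row set
#'
#' @param adjuster an `fs_adjuster` from [fit_adjuster()].
#' @param x vector/matrix of the columns to adjust (any rows).
#' @param covariates covariate matrix for the same rows.
#' @return residuals with the same shape as `x` (matrix, or vector if `x` was
#'   a vector).
#' @export
apply_adjuster <- function(adjuster, x, covariates) {
  stopifnot(inherits(adjuster, "fs_adjuster"))
  X <- as.matrix(x)
  B <- cbind(1, as.matrix(covariates))
  res <- X - B %*% adjuster$coef
  if (is.null(dim(x))) as.numeric(res) else res
}

#' @export
print.fs_adjuster <- function(x, ...) {
  cat("Covariate adjuster:", ncol(x$coef), "adjusted column(s) on",
      length(x$covariate_names), "covariate(s)\n")
  invisible(x)
}
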