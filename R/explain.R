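# Feature assessments around a fitted pipeline: permutation importance,
# Dunn-index guided k-means clustering of per-case SHAP vectors, per-cluster
# feature rankings, and a long-format export of the force-plot matrix.

#' Select well-predicted cases
#'
#' Classification mode: cases (truth = 1) whose predicted probability exceeds
#' 0.5. Regression mode: cases within the bottom quartile of the absolute
#' difference between observed and predicted outcomes, among cases only;
#' the quartile cutoff is the 25\% order statistic and ties at the cutoff are
#' all included (so the count can exceed `ceiling(n/4)`).
#'
#' @param predictions numeric predictions aligned with `truth`.
#' @param truth observed outcomes (binary for classification; the
#'   covariate-adjusted outcome for regression).
#' @param mode `"classification"` or `"regression"`.
#' @param cases for regression mode: logical vector or integer indices
#'   flagging which samples are cases (required, since the adjusted outcome
#'   is no longer binary).
#' @return integer indices of the selected cases.
#' @export
select_well_predicted <- function(predictions,
                                  truth,
                                  mode = c("classification", "regression"),
                                  cases = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(predictions) == length(truth))
  if (mode == "classification") {
    idx <- which(truth == 1 & predictions > 0.5)
  } else {
    if (is.null(cases))
      stop("regression mode needs a `cases` indicator", call. = FALSE)
    case_idx <- if (is.logical(cases)) which(cases) else as.integer(cases)
    err <- abs(truth[case_idx] - predictions[case_idx])
    cutoff <- stats::quantile(err, 0.25, type = 1, names = FALSE)
    idx <- case_idx[err <= cutoff]
  }
  if (!length(idx)) stop("no well-predicted cases found", call. = FALSE)
  idx
}

#' Permutation feature importance
#'
#' For each feature, the mean drop in the holdout score when that feature's
#' column is shuffled (within the evaluation set), over `n_repeats` seeded
#' shuffles — how much the model relies on the feature.
#'
#' @param object fitted model: an `fs_run`, `fs_pipeline`, or a prediction
#'   function.
#' @param x evaluation feature matrix (held-out data).
#' @param y evaluation outcome.
#' @param metric `"accuracy"` or `"coefficient_of_determination"`.
#' @param n_repeats shuffles per feature.
#' @param seed RNG seed.
#' @return an object of class `importance_table`: data frame with `feature`,
#'   `importance` (mean score drop), `sd`, sorted by decreasing importance;
#'   the baseline score is in `attr(, "baseline")`.
#' @export
permutation_importance <- function(object, x, y,
                                   metric = c("accuracy",
                                              "coefficient_of_determination"),
                                   n_repeats = 10, seed = 1) {
  metric <- match.arg(metric)
  if (nrow(x) < 2) stop("need at least two evaluation rows", call. = FALSE)
  baseline <- evaluate_holdout(object, x, y, metric)
  res <- with_seed(seed, {
    t(vapply(seq_len(ncol(x)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[, j] <- sample(xp[, j])
        baseline - evaluate_holdout(object, xp, y, metric)
      }, numeric(1))
      c(mean(drops), stats::sd(drops))
    }, numeric(2)))
  })
  out <- data.frame(feature = colnames(x), importance = res[, 1],
                    sd = res[, 2], stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "metric") <- metric
  attr(out, "n_repeats") <- n_repeats
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Dunn cluster-validity index
#'
#' Minimum inter-cluster distance (over all cluster pairs, minimum pointwise
#' Euclidean distance) divided by the maximum intra-cluster diameter. Higher
#' values indicate compact, well-separated clusters. If every cluster has
#' zero diameter the index is `+Inf` (flagged with a warning).
#'
#' @param points numeric matrix (rows = points).
#' @param labels cluster labels, one per row; at least 2 non-empty clusters.
#' @return a single number in `(0, Inf]`.
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("need at least two clusters", call. = FALSE)
  D <- as.matrix(stats::dist(points))
  diam <- max(vapply(ks, function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2) 0 else max(D[idx, idx])
  }, numeric(1)))
  inter <- min(vapply(seq_along(ks)[-1], function(i) {
    min(vapply(seq_len(i - 1), function(j) {
      min(D[labels == ks[i], labels == ks[j], drop = FALSE])
    }, numeric(1)))
  }, numeric(1)))
  if (diam == 0) {
    warning("all intra-cluster diameters are zero; Dunn index is +Inf",
            call. = FALSE)
    return(Inf)
  }
  inter / diam
}

#' Select the number of k-means clusters by the Dunn index
#'
#' Runs k-means (multiple restarts, seeded) for each `k` in `k_range` and
#' returns the `k` maximizing the Dunn index; ties go to the smallest `k`.
#' The full Dunn-versus-k report is returned so the choice can be inspected,
#' mirroring how background sizes and case-cluster counts were chosen by
#' examining Dunn indices over k = 30..100.
#'
#' @param points numeric matrix to cluster.
#' @param k_range candidate cluster counts, within `[2, n - 1]`.
#' @param seed RNG seed.
#' @param nstart k-means restarts per k.
#' @return list with `k`, `assignment` (class `cluster_assignment`: `labels`
#'   in `1..k`, `k`, `dunn`, `seed`) and `report` (data frame of k vs Dunn).
#' @export
select_k_by_dunn <- function(points, k_range, seed = 1, nstart = 10) {
  points <- as.matrix(points)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k range", call. = FALSE)
  if (any(k_range < 2) || any(k_range > nrow(points) - 1))
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  fits <- lapply(k_range, function(k) {
    km <- with_seed(derive_seed(seed, k),
                    stats::kmeans(points, centers = k, nstart = nstart))
    d <- suppressWarnings(dunn_index(points, km$cluster))
    list(k = k, labels = km$cluster, dunn = d)
  })
  dunns <- vapply(fits, `[[`, numeric(1), "dunn")
  best <- fits[[which.max(dunns)]]  # first maximum = smallest k on ties
  assignment <- structure(list(labels = best$labels, k = best$k,
                               dunn = best$dunn, seed = seed),
                          class = "cluster_assignment")
  list(k = best$k, assignment = assignment,
       report = data.frame(k = k_range, dunn = dunns))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment: k =", x$k, ", Dunn =", signif(x$dunn, 4),
      "; sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Cluster explained cases by their SHAP vectors
#'
#' k-means on the rows of a SHAP matrix, with `k` chosen by Dunn-index
#' maximization over `k_range` — unless `k_override` is given, replicating an
#' analyst's manual choice after inspecting the force plot and the Dunn
#' report (the study fixed 4 clusters for the classification arm and 6 for
#' the covariate-adjusted arm this way).
#'
#' @param S a `shap_matrix`.
#' @param k_range candidate k values for the Dunn criterion.
#' @param seed RNG seed.
#' @param k_override optional fixed number of clusters, within `[2, n - 1]`.
#' @param nstart k-means restarts.
#' @return a `cluster_assignment`, with the Dunn-versus-k report in
#'   `attr(, "report")` (when the criterion was used).
#' @export
cluster_cases_by_shap <- function(S, k_range = 2:8, seed = 1,
                                  k_override = NULL, nstart = 10) {
  stopifnot(inherits(S, "shap_matrix"))
  X <- S$values
  if (nrow(X) < 2) stop("need at least two cases to cluster", call. = FALSE)
  if (!is.null(k_override)) {
    if (k_override < 2 || k_override > nrow(X) - 1)
      stop("k_override must lie within [2, n - 1]", call. = FALSE)
    km <- with_seed(derive_seed(seed, k_override),
                    stats::kmeans(X, centers = k_override, nstart = nstart))
    return(structure(list(labels = km$cluster, k = k_override,
                          dunn = suppressWarnings(dunn_index(X, km$cluster)),
                          seed = seed),
                     class = "cluster_assignment"))
  }
  sel <- select_k_by_dunn(X, k_range, seed = seed, nstart = nstart)
  out <- sel$assignment
  attr(out, "report") <- sel$report
  out
}

#' Rank features within each SHAP cluster
#'
#' Within each cluster, features are ranked by the mean absolute SHAP value
#' across the cluster's cases (their average impact on model output),
#' descending; ties break by feature id.
#'
#' @param S a `shap_matrix`.
#' @param clusters a `cluster_assignment` covering the rows of `S`.
#' @param top_m optional: also return the union of the top `m` features per
#'   cluster (as used for cross-cluster ranking displays).
#' @return named list (one element per cluster) of data frames `feature`,
#'   `mean_abs_shap`; when `top_m` is given the union of per-cluster top
#'   features is in `attr(, "top_union")`.
#' @export
rank_features_per_cluster <- function(S, clusters, top_m = NULL) {
  stopifnot(inherits(S, "shap_matrix"))
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels
            else clusters
  if (length(labels) != nrow(S$values))
    stop("cluster labels must cover all explained cases", call. = FALSE)
  ks <- sort(unique(labels))
  out <- lapply(ks, function(k) {
    idx <- which(labels == k)
    if (!length(idx)) stop("empty cluster: ", k, call. = FALSE)
    m <- colMeans(abs(S$values[idx, , drop = FALSE]))
    df <- data.frame(feature = S$feature_ids, mean_abs_shap = as.numeric(m),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$mean_abs_shap, df$feature), ]
    rownames(df) <- NULL
    df
  })
  names(out) <- paste0("cluster", ks)
  if (!is.null(top_m)) {
    attr(out, "top_union") <- sort(unique(unlist(
      lapply(out, function(df) utils::head(df$feature, top_m)))))
  }
  out
}

#' Export a force-plot matrix in long format
#'
#' Produces the tabular data behind a stacked ("multisample") force plot: one
#' row per (case, feature) with the SHAP value, base value and model output,
#' plus a case-ordering column — nearest-neighbour seriation over SHAP rows
#' (greedy chain from the first case; identical rows end up adjacent) or a
#' caller-provided order. Suitable for external plotting.
#'
#' @param S a `shap_matrix`.
#' @param order `"seriation"` or `"given"`.
#' @param case_order integer ordering of cases when `order = "given"`.
#' @param path optional TSV output path.
#' @return data frame `case`, `feature`, `shap`, `base_value`,
#'   `model_output`, `case_order` (invisibly if `path` is given).
#' @export
export_force_matrix <- function(S, order = c("seriation", "given"),
                                case_order = NULL, path = NULL) {
  stopifnot(inherits(S, "shap_matrix"))
  order <- match.arg(order)
  n <- nrow(S$values)
  ord <- if (order == "given") {
    if (is.null(case_order) || length(case_order) != n)
      stop("case_order must order all cases", call. = FALSE)
    as.integer(case_order)
  } else {
    seriate_rows(S$values)
  }
  pos <- match(seq_len(n), ord)
  model_output <- S$base_value + rowSums(S$values)
  out <- data.frame(
    case = rep(S$case_ids, each = ncol(S$values)),
    feature = rep(S$feature_ids, times = n),
    shap = as.numeric(t(S$values)),
    base_value = S$base_value,
    model_output = rep(model_output, each = ncol(S$values)),
    case_order = rep(pos, each = ncol(S$values)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# greedy nearest-neighbour chain over rows, deterministic (starts at row 1,
# ties broken by row index)
seriate_rows <- function(X) {
  n <- nrow(X)
  if (n == 1) return(1L)
  D <- as.matrix(stats::dist(X))
  visited <- logical(n)
  ord <- integer(n)
  cur <- 1L
  for (i in seq_len(n)) {
    ord[i] <- cur
    visited[cur] <- TRUE
    if (i == n) break
    cand <- which(!visited)
    cur <- cand[which.min(D[cur, cand])]
  }
  ord
}
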