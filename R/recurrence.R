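# Feature-set recurrence: the consistency statistic (how often independent
# search runs select the same feature set) and its permutation null, built by
# permuting the phenotype of the full cohort and repeating the whole stage.

#' Summarize feature-set recurrence across search runs
#'
#' Tallies, over the successful runs of a stage, how many selected each
#' feature set; records the maximum count (the recurrence statistic), the
#' feature set(s) attaining it, and the best holdout score.
#'
#' @param results an `fs_stage`, or a list of per-run records each with
#'   `selected_fs` and (optionally) `holdout1_score`/`holdout2_score` and
#'   `error`.
#' @return an object of class `fs_recurrence` with fields `fs_counts`,
#'   `max_count`, `argmax_fs` (all tied maximizers), `n_runs`, `n_successful`
#'   and `best_holdout_score`.
#' @export
summarize_recurrence <- function(results) {
  stage <- NULL
  if (inherits(results, "fs_stage")) {
    stage <- results$stage
    results <- results$runs
  }
  if (!length(results)) stop("no runs to summarize", call. = FALSE)
  ok <- vapply(results, function(r) is.null(r$error) &&
                 !is.na(r$selected_fs %||% NA_character_), logical(1))
  if (!any(ok)) stop("all runs failed", call. = FALSE)
  sel <- vapply(results[ok], function(r) r$selected_fs, character(1))
  counts <- sort(table(sel), decreasing = TRUE)
  score_of <- function(r) {
    h <- if (!is.null(stage) && stage == 2) r$holdout2_score else r$holdout1_score
    h %||% NA_real_
  }
  scores <- vapply(results[ok], score_of, numeric(1))
  best <- if (all(is.na(scores))) NA_real_ else max(scores, na.rm = TRUE)
  structure(list(fs_counts = counts,
                 max_count = as.integer(counts[1]),
                 argmax_fs = names(counts)[counts == counts[1]],
                 n_runs = length(results),
                 n_successful = sum(ok),
                 best_holdout_score = best),
            class = "fs_recurrence")
}

#' @export
print.fs_recurrence <- function(x, ...) {
  cat("Feature-set recurrence over", x$n_successful, "successful of",
      x$n_runs, "runs\n")
  cat("  most recurrent FS:", paste(x$argmax_fs, collapse = ", "),
      "selected in", x$max_count, "runs\n")
  if (!is.na(x$best_holdout_score))
    cat("  best holdout score:", signif(x$best_holdout_score, 4), "\n")
  invisible(x)
}

#' @export
plot.fs_recurrence <- function(x, ...) {
  graphics::barplot(x$fs_counts, las = 2, ylab = "runs selecting FS",
                    main = "Feature-set recurrence", ...)
  invisible(x)
}

#' Permute the phenotype column of a cohort
#'
#' Uniformly permutes the binary phenotype over all samples (before any
#' down-sampling), leaving genotypes and covariates untouched; case and
#' control totals are preserved. The identity permutation is disallowed by
#' construction: if the draw reproduces the original assignment exactly it is
#' redrawn.
#'
#' @param cohort cohort table with binary `phenotype`.
#' @param seed RNG seed.
#' @return the cohort with permuted `phenotype`.
#' @export
permute_target <- function(cohort, seed = 1) {
  y <- cohort$phenotype
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary", call. = FALSE)
  perm <- with_seed(seed, {
    p <- sample(y)
    tries <- 0L
    while (identical(p, y) && stats::var(y) > 0 && tries < 100L) {
      p <- sample(y)
      tries <- tries + 1L
    }
    p
  })
  cohort$phenotype <- perm
  cohort
}

#' Permutation null for the recurrence statistic
#'
#' For each permutation: permute the phenotype of the full cohort, re-run the
#' entire stage (`n_runs` searches with fresh down-sampling and splits), and
#' record the maximum feature-set recurrence and the best holdout score. The
#' stage configuration must be identical to the observed analysis; this is
#' enforced by comparing configuration hashes when `observed_hash` is given.
#'
#' @param G genotype dosage matrix.
#' @param cohort cohort table.
#' @param stage_config the same `config` list passed to [run_stage()] for the
#'   observed arm.
#' @param n_permutations number of phenotype permutations (study setting:
#'   20).
#' @param base_seed base seed; per-permutation seeds are derived by the
#'   documented counter scheme.
#' @param observed_hash optional `config_hash` of the observed `fs_stage`;
#'   a mismatch aborts.
#' @return an object of class `fs_null`: data frame with one row per
#'   permutation (`perm`, `max_count`, `best_score`), plus the number of runs
#'   per permutation and the configuration hash.
#' @export
permutation_null <- function(G, cohort, stage_config, n_permutations = 20,
                             base_seed = 1, observed_hash = NULL) {
  stopifnot(n_permutations >= 1)
  cfg <- normalize_stage_config(stage_config)
  hash <- stage_config_hash(cfg)
  if (!is.null(observed_hash) && !identical(unname(hash), unname(observed_hash)))
    stop("configuration mismatch between observed and null arms",
         call. = FALSE)
  rows <- lapply(seq_len(n_permutations), function(p) {
    permuted <- permute_target(cohort, seed = derive_seed(base_seed, 0L, p))
    cfg_p <- cfg
    cfg_p$permutation <- p
    stage <- run_stage(G, permuted, cfg_p,
                       seeds = derive_seed(base_seed, p, seq_len(cfg$n_runs)))
    s <- summarize_recurrence(stage)
    data.frame(perm = p, max_count = s$max_count,
               best_score = s$best_holdout_score)
  })
  structure(list(values = do.call(rbind, rows),
                 n_permutations = n_permutations,
                 n_runs = cfg$n_runs, base_seed = base_seed,
                 config_hash = hash),
            class = "fs_null")
}

#' @export
print.fs_null <- function(x, ...) {
  cat("Permutation null:", x$n_permutations, "permutations x", x$n_runs,
      "runs\n")
  cat("  max recurrence per permutation:",
      paste(x$values$max_count, collapse = " "), "\n")
  cat("  best holdout score range:",
      paste(signif(range(x$values$best_score, na.rm = TRUE), 4),
            collapse = " - "), "\n")
  invisible(x)
}

#' Compare an observed recurrence summary to its permutation null
#'
#' Reports, for both the recurrence statistic and the best holdout score,
#' the number of null permutations reaching the observed value and the
#' conservative add-one empirical p upper bound
#' `p <= (1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' @param observed an `fs_recurrence` from the unpermuted analysis.
#' @param null an `fs_null` built under the identical configuration.
#' @return an object of class `fs_perm_report`.
#' @export
compare_to_null <- function(observed, null) {
  stopifnot(inherits(observed, "fs_recurrence"), inherits(null, "fs_null"))
  if (observed$n_runs != null$n_runs)
    stop("observed and null arms used different numbers of runs",
         call. = FALSE)
  n <- null$n_permutations
  exc_count <- sum(null$values$max_count >= observed$max_count)
  exc_score <- sum(null$values$best_score >= observed$best_holdout_score,
                   na.rm = TRUE)
  structure(list(observed_max_count = observed$max_count,
                 observed_best_score = observed$best_holdout_score,
                 null_max_counts = null$values$max_count,
                 null_best_scores = null$values$best_score,
                 exceedance_count = exc_count,
                 exceedance_score = exc_score,
                 p_upper_count = (1 + exc_count) / (1 + n),
                 p_upper_score = (1 + exc_score) / (1 + n),
                 n_permutations = n),
            class = "fs_perm_report")
}

#' @export
print.fs_perm_report <- function(x, ...) {
  cat("Recurrence permutation test (", x$n_permutations, " permutations)\n",
      sep = "")
  cat("  max recurrence: observed ", x$observed_max_count, ", null max ",
      max(x$null_max_counts), ", exceedance ", x$exceedance_count,
      ", p <= ", signif(x$p_upper_count, 4), "\n", sep = "")
  cat("  best holdout score: observed ", signif(x$observed_best_score, 4),
      ", exceedance ", x$exceedance_score, ", p <= ",
      signif(x$p_upper_score, 4), "\n", sep = "")
  invisible(x)
}
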