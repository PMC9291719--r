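# End-to-end orchestration of the two-stage procedure: simulate (or load)
# inputs, build feature sets, stage-1 search, recurrence summary, optional
# permutation test, stage-2 search on the winning feature set, and SHAP-based
# dissection of the well-predicted cases. Every artifact carries the
# configuration hash and base seed for provenance.

#' Assemble an analysis configuration
#'
#' Collects the tunable parameters of the full workflow into a single hashed
#' configuration object. All randomness downstream is derived from
#' `base_seed` via [derive_seed()].
#'
#' @param n_samples,n_snps_per_gene,n_druggable,connected_per_druggable
#'   synthetic cohort dimensions (used when no input paths are given).
#' @param model a [generative_model()] for the synthetic phenotype, or `NULL`
#'   for a pure-noise endpoint.
#' @param n_runs search runs per stage.
#' @param budget a [search_budget()].
#' @param pool an [operator_pool()] or `NULL` for defaults.
#' @param fractions train/test1/test2 split fractions.
#' @param resadj apply leakage-free covariate residual adjustment.
#' @param r2_max LD-pruning threshold.
#' @param n_permutations permutations for the recurrence null (0 = skip).
#' @param k_background_range,k_cluster_range Dunn-criterion ranges for the
#'   explainer background and the SHAP case clustering.
#' @param n_coalitions kernel SHAP coalition budget (`"all"` or a count).
#' @param base_seed integer base seed.
#' @return an object of class `analysis_config` (a list with a `config_hash`
#'   field).
#' @export
analysis_config <- function(n_samples = 2000, n_snps_per_gene = 8,
                            n_druggable = 1, connected_per_druggable = 5,
                            model = NULL, n_runs = 10,
                            budget = search_budget(10, 5), pool = NULL,
                            fractions = c(0.75, 0.13, 0.12), resadj = FALSE,
                            r2_max = 0.8, n_permutations = 0,
                            k_background_range = 3:6, k_cluster_range = 2:6,
                            n_coalitions = "all", base_seed = 1) {
  cfg <- list(n_samples = n_samples, n_snps_per_gene = n_snps_per_gene,
              n_druggable = n_druggable,
              connected_per_druggable = connected_per_druggable,
              model = if (!is.null(model)) unclass(model),
              n_runs = n_runs, budget = unclass(budget),
              pool = if (!is.null(pool)) unclass(pool),
              fractions = fractions, resadj = resadj, r2_max = r2_max,
              n_permutations = n_permutations,
              k_background_range = k_background_range,
              k_cluster_range = k_cluster_range,
              n_coalitions = n_coalitions, base_seed = base_seed)
  cfg$config_hash <- config_hash(cfg)
  cfg$model <- model
  cfg$budget <- budget
  cfg$pool <- pool
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration [", substr(x$config_hash, 1, 8), "...]\n",
      sep = "")
  cat("  n =", x$n_samples, "samples;", x$n_runs, "runs/stage;",
      x$n_permutations, "permutations; resadj =", x$resadj, "\n")
  invisible(x)
}

#' Run the full two-stage workflow
#'
#' Executes: synthetic cohort generation, feature-set construction, stage-1
#' template search with FSS, recurrence summary, optional permutation null,
#' stage-2 search restricted to the winning feature set, and SHAP analysis of
#' the well-predicted cases of the best stage-2 run. Artifacts (feature-set
#' file, per-run JSON-lines ledger, recurrence/permutation reports, SHAP
#' exports) are written under `out_dir`; summary outputs are byte-identical
#' across reruns with the same configuration.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (`annotation`, `G`,
#'   `cohort`, `fs_map`, `stage1`, `recurrence`, `null`, `report`, `stage2`,
#'   `shap`, `clusters`, `rankings`) and the artifact paths.
#' @export
run_workflow <- function(config, out_dir = tempfile("fsrecur_")) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$base_seed
  ledger <- file.path(out_dir, "runs.jsonl")
  if (file.exists(ledger)) unlink(ledger)

  annotation <- simulate_annotations(
    n_druggable = config$n_druggable,
    connected_per_druggable = config$connected_per_druggable,
    snps_per_gene = config$n_snps_per_gene, seed = derive_seed(seed, 101))
  G <- simulate_genotypes(config$n_samples, annotation,
                          seed = derive_seed(seed, 102))
  model <- config$model %||%
    generative_model(covariate_effects = list(age = 0, sex = 0),
                     seed = derive_seed(seed, 103))
  cohort <- simulate_phenotype(G, model)
  fs_map <- build_fs_from_annotation(annotation, G, r2_max = config$r2_max)
  write_fs_file(fs_map, file.path(out_dir, "feature_sets.tsv"))

  stage1_cfg <- list(n_runs = config$n_runs, stage = 1, fs_map = fs_map,
                     budget = config$budget, pool = config$pool,
                     fractions = config$fractions, resadj = config$resadj,
                     base_seed = seed, ledger = ledger)
  stage1 <- run_stage(G, cohort, stage1_cfg)
  recurrence <- summarize_recurrence(stage1)

  null <- NULL; report <- NULL
  if (config$n_permutations > 0) {
    null <- permutation_null(G, cohort, stage1_cfg,
                             n_permutations = config$n_permutations,
                             base_seed = derive_seed(seed, 104),
                             observed_hash = stage1$config_hash)
    report <- compare_to_null(recurrence, null)
  }

  winner <- recurrence$argmax_fs[1]
  stage2_cfg <- list(n_runs = config$n_runs, stage = 2, fs_map = fs_map,
                     stage1_fs = winner, budget = config$budget,
                     pool = config$pool, fractions = config$fractions,
                     resadj = config$resadj, base_seed = derive_seed(seed, 2),
                     ledger = ledger)
  stage2 <- run_stage(G, cohort, stage2_cfg)

  # SHAP dissection of the best stage-2 run's well-predicted holdout cases
  ok2 <- Filter(function(r) is.null(r$error), stage2$runs)
  shap <- NULL; clusters <- NULL; rankings <- NULL
  if (length(ok2)) {
    h2 <- vapply(ok2, function(r) r$holdout2_score, numeric(1))
    best <- ok2[[which.max(h2)]]
    cols <- best$pipeline$features
    Xall <- unclass(G)
    test2 <- best$splits$test2_idx
    pred <- predict(best$pipeline, Xall[test2, , drop = FALSE])
    y2 <- cohort$phenotype[test2]
    wp <- tryCatch(
      if (config$resadj)
        select_well_predicted(pred, y2, "regression", cases = y2 == 1)
      else select_well_predicted(pred, y2, "classification"),
      error = function(e) integer(0))
    if (length(wp) >= 3) {
      bg_k <- min(max(config$k_background_range), length(best$splits$train_idx) - 1)
      bg <- kmeans_background(Xall[best$splits$train_idx, cols, drop = FALSE],
                              k = bg_k, seed = derive_seed(seed, 105))
      predict_fn <- function(X) predict(best$pipeline, X)
      shap <- shap_matrix(predict_fn, Xall[test2[wp], cols, drop = FALSE],
                          bg, n_coalitions = config$n_coalitions,
                          seed = derive_seed(seed, 106))
      if (nrow(shap$values) > max(config$k_cluster_range)) {
        clusters <- cluster_cases_by_shap(shap, config$k_cluster_range,
                                          seed = derive_seed(seed, 107))
        rankings <- rank_features_per_cluster(shap, clusters, top_m = 5)
        utils::write.table(
          data.frame(case = shap$case_ids, cluster = clusters$labels),
          file.path(out_dir, "shap_clusters.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      export_force_matrix(shap, path = file.path(out_dir, "force_matrix.tsv"))
    }
  }

  summary_obj <- list(
    config_hash = config$config_hash, base_seed = seed,
    stage1 = list(
      n_runs = recurrence$n_runs, n_successful = recurrence$n_successful,
      max_count = recurrence$max_count, argmax_fs = recurrence$argmax_fs,
      best_holdout_score = recurrence$best_holdout_score),
    permutation = if (!is.null(report)) list(
      null_max_counts = report$null_max_counts,
      exceedance_count = report$exceedance_count,
      p_upper_count = report$p_upper_count,
      p_upper_score = report$p_upper_score),
    stage2 = list(
      winner_fs = winner,
      best_holdout_score = if (length(ok2))
        max(vapply(ok2, function(r) r$holdout2_score, numeric(1)))
        else NA_real_),
    shap = if (!is.null(clusters)) list(
      n_explained = nrow(shap$values), k = clusters$k,
      cluster_sizes = as.integer(table(clusters$labels))))
  jsonlite::write_json(summary_obj, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(out_dir = out_dir, annotation = annotation, G = G,
                 cohort = cohort, fs_map = fs_map, stage1 = stage1,
                 recurrence = recurrence, null = null, report = report,
                 stage2 = stage2, shap = shap, clusters = clusters,
                 rankings = rankings))
}

#' Read a run ledger
#'
#' @param path JSON-lines ledger written during [run_stage()] /
#'   [run_workflow()].
#' @return data frame, one row per search run.
#' @export
read_run_ledger <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[vapply(rec, is.null, logical(1))] <- NA
    as.data.frame(rec, stringsAsFactors = FALSE)
  }))
}

# Genotype / cohort delimited I/O ---------------------------------------------

#' Write and read a genotype dosage matrix as delimited text
#'
#' Tab-delimited: header row of SNP ids, first column `sample_id`.
#'
#' @param G dosage matrix.
#' @param path file path.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(sample_id = rownames(G), unclass(G)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  rownames(G) <- df$sample_id
  class(G) <- c("genotype_matrix", class(G))
  G
}

#' Write and read a cohort table as delimited text
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
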