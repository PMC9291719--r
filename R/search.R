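# One stage of the two-stage procedure: balanced control down-sampling,
# 75/13/12 splits, template-constrained evolutionary pipeline search with
# feature-set selection (FSS), optional leakage-free covariate residual
# adjustment, and holdout scoring.

#' Down-sample controls to balance a cohort
#'
#' Returns all case indices plus a uniform random sample of controls of equal
#' size, reproducibly per seed.
#'
#' @param cohort cohort table with a binary `phenotype` column.
#' @param seed RNG seed.
#' @return sorted integer row indices of the balanced sample set.
#' @export
downsample_controls <- function(cohort, seed = 1) {
  cases <- which(cohort$phenotype == 1)
  controls <- which(cohort$phenotype == 0)
  if (length(controls) < length(cases))
    stop("fewer controls than cases; cannot down-sample to balance",
         call. = FALSE)
  picked <- with_seed(seed, sample(controls, length(cases)))
  sort(c(cases, picked))
}

#' Random train/holdout splits of a balanced index set
#'
#' Partitions the balanced sample set into training, stage-1 holdout
#' (`test1`) and stage-2 holdout (`test2`) parts. Holdout sizes are
#' `floor(fraction * n)`; the remainder goes to the training part.
#'
#' @param balanced_idx integer indices (e.g. from [downsample_controls()]).
#' @param fractions length-3 fractions `(train, test1, test2)` summing to 1;
#'   `(0.75, 0.25, 0)` gives a two-way split.
#' @param seed RNG seed.
#' @return an object of class `fs_splits` with disjoint `train_idx`,
#'   `test1_idx`, `test2_idx` whose union is `balanced_idx`.
#' @export
make_splits <- function(balanced_idx, fractions = c(0.75, 0.13, 0.12),
                        seed = 1) {
  if (length(fractions) == 2) fractions <- c(fractions, 0)
  stopifnot(length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  n <- length(balanced_idx)
  n1 <- floor(fractions[2] * n)
  n2 <- floor(fractions[3] * n)
  perm <- with_seed(seed, sample(balanced_idx))
  structure(list(train_idx = sort(perm[seq_len(n - n1 - n2)]),
                 test1_idx = sort(perm[n - n1 - n2 + seq_len(n1)]),
                 test2_idx = if (n2 > 0) sort(perm[n - n2 + seq_len(n2)])
                             else integer(0),
                 fractions = fractions, seed = seed),
            class = "fs_splits")
}

#' @export
print.fs_splits <- function(x, ...) {
  cat("Splits: train", length(x$train_idx), "/ test1", length(x$test1_idx),
      "/ test2", length(x$test2_idx), "\n")
  invisible(x)
}

#' Search budget for the evolutionary pipeline search
#'
#' @param population individuals per generation (study setting: 100).
#' @param generations number of generations (study setting: 100).
#' @param wall_clock_limit optional limit in seconds; the search stops at the
#'   earliest of the generation budget or the limit.
#' @return an object of class `search_budget`.
#' @export
search_budget <- function(population = 100, generations = 100,
                          wall_clock_limit = NULL) {
  stopifnot(population >= 1, generations >= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 wall_clock_limit = wall_clock_limit),
            class = "search_budget")
}

random_spec <- function(pool, fs_names) {
  tname <- pool$transformers[sample.int(length(pool$transformers), 1L)]
  ename <- pool$estimators[sample.int(length(pool$estimators), 1L)]
  list(fs = if (!is.null(fs_names)) fs_names[sample.int(length(fs_names), 1L)]
            else NA_character_,
       trans = list(name = tname, params = sample_params(pool, tname)),
       est = list(name = ename, params = sample_params(pool, ename)))
}

# mutation: resample one template slot (FS choice, operator name, or one hp)
mutate_spec <- function(spec, pool, fs_names) {
  slots <- c(if (!is.null(fs_names)) "fs", "trans", "est")
  slot <- slots[sample.int(length(slots), 1L)]
  if (slot == "fs") {
    spec$fs <- fs_names[sample.int(length(fs_names), 1L)]
  } else {
    cur <- spec[[slot]]
    choices <- if (slot == "trans") pool$transformers else pool$estimators
    if (length(cur$params) && stats::runif(1) < 0.5) {
      hp <- names(cur$params)[sample.int(length(cur$params), 1L)]
      grid <- pool$grids[[cur$name]][[hp]]
      cur$params[[hp]] <- grid[[sample.int(length(grid), 1L)]]
    } else {
      nm <- choices[sample.int(length(choices), 1L)]
      cur <- list(name = nm, params = sample_params(pool, nm))
    }
    spec[[slot]] <- cur
  }
  spec
}

# crossover: each template slot taken from either parent
cross_specs <- function(a, b) {
  list(fs = if (stats::runif(1) < 0.5) a$fs else b$fs,
       trans = if (stats::runif(1) < 0.5) a$trans else b$trans,
       est = if (stats::runif(1) < 0.5) a$est else b$est)
}

score_predictions <- function(pred, y, metric) {
  if (metric == "accuracy") {
    mean((pred > 0.5) == y)
  } else {
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((y - pred)^2) / sst
  }
}

cv_score <- function(spec, X, y, problem, fs_map, fold_id, metric) {
  scores <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    fit <- fit_pipeline(spec, X[tr, , drop = FALSE], y[tr], problem, fs_map)
    score_predictions(predict(fit, X[!tr, , drop = FALSE]), y[!tr], metric)
  }, numeric(1))
  mean(scores)
}

#' Template-constrained evolutionary pipeline search
#'
#' A reduced automated-ML search: pipelines follow a fixed template
#' ((FSS ->) Transformer -> Estimator); the population evolves by tournament
#' selection (size 2), slot-swap crossover and single-slot mutation, with
#' elitism of one. Each individual is scored by k-fold cross-validation on
#' the training data (accuracy for classification, coefficient of
#' determination for regression); the best-CV individual is refit on the full
#' training data and returned together with its selected feature set. The
#' search is deterministic per seed; CV scores are cached per pipeline
#' configuration. Ties in best CV score are broken by earliest creation
#' order.
#'
#' @param x training dosage matrix (samples x SNPs, named columns).
#' @param y training outcome (binary for classification, numeric for
#'   regression).
#' @param fs_map an `fs_map` of candidate feature sets, or `NULL` to search
#'   without the FSS step (the template then has no FSS slot).
#' @param budget a [search_budget()].
#' @param pool an [operator_pool()]; its `problem` field sets the task type.
#' @param cv_folds number of CV folds (study setting: 5).
#' @param seed RNG seed.
#' @param mutation_rate probability a crossover child is additionally
#'   mutated.
#' @param crossover_rate probability an offspring is produced by crossover
#'   (otherwise a mutated copy of one parent).
#' @return an object of class `fs_run`: `selected_fs`, `cv_score`, `metric`,
#'   the fitted `pipeline`, its `spec`, per-generation best-CV `history`, and
#'   the evaluation count.
#' @export
run_pipeline_search <- function(x, y, fs_map = NULL,
                                budget = search_budget(20, 10),
                                pool = operator_pool("classification"),
                                cv_folds = 5, seed = 1,
                                mutation_rate = 0.5, crossover_rate = 0.5) {
  assert_dosage_matrix(x)
  if (!is.null(fs_map) && !length(fs_map))
    stop("fs_map must be non-empty when the template includes FSS",
         call. = FALSE)
  if (!length(pool$transformers) || !length(pool$estimators))
    stop("empty operator pool", call. = FALSE)
  problem <- pool$problem
  metric <- if (problem == "classification") "accuracy"
            else "coefficient_of_determination"
  fs_names <- if (!is.null(fs_map)) names(fs_map) else NULL
  n <- nrow(x)
  t0 <- Sys.time()

  with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(cv_folds), n))
    cache <- new.env(parent = emptyenv())
    n_evals <- 0L
    created <- 0L
    evaluate <- function(spec) {
      key <- spec_key(spec)
      if (!is.null(cache[[key]])) return(cache[[key]])
      s <- tryCatch(
        cv_score(spec, x, y, problem, fs_map, fold_id,
                 if (metric == "accuracy") "accuracy" else "r2"),
        error = function(e) NA_real_)
      n_evals <<- n_evals + 1L
      cache[[key]] <- s
      s
    }
    new_ind <- function(spec) {
      created <<- created + 1L
      list(spec = spec, score = evaluate(spec), order = created)
    }
    pop <- lapply(seq_len(budget$population),
                  function(i) new_ind(random_spec(pool, fs_names)))
    better <- function(a, b) {
      # NA-safe: a beats b?
      if (is.na(a$score)) return(FALSE)
      if (is.na(b$score)) return(TRUE)
      a$score > b$score || (a$score == b$score && a$order < b$order)
    }
    best_of <- function(inds) Reduce(function(a, b) if (better(b, a)) b else a,
                                     inds)
    history <- numeric(0)
    for (g in seq_len(budget$generations)) {
      if (!is.null(budget$wall_clock_limit) &&
          as.numeric(Sys.time() - t0, units = "secs") >
            budget$wall_clock_limit) break
      elite <- best_of(pop)
      offspring <- lapply(seq_len(budget$population - 1L), function(i) {
        tourn <- function() {
          pick <- pop[sample.int(length(pop), 2L)]
          if (better(pick[[1]], pick[[2]])) pick[[1]] else pick[[2]]
        }
        p1 <- tourn(); p2 <- tourn()
        child <- if (stats::runif(1) < crossover_rate)
          cross_specs(p1$spec, p2$spec) else p1$spec
        if (stats::runif(1) < mutation_rate)
          child <- mutate_spec(child, pool, fs_names)
        new_ind(child)
      })
      pop <- c(list(elite), offspring)
      history <- c(history, best_of(pop)$score)
    }
    best <- best_of(pop)
    if (is.na(best$score))
      stop("no pipeline configuration could be evaluated", call. = FALSE)
    fitted <- fit_pipeline(best$spec, x, y, problem, fs_map)
    structure(list(seed = seed, selected_fs = best$spec$fs,
                   cv_score = best$score, metric = metric,
                   pipeline = fitted, spec = best$spec,
                   history = history, n_evals = n_evals),
              class = "fs_run")
  })
}

#' @export
print.fs_run <- function(x, ...) {
  cat("Pipeline search result (seed ", x$seed, ")\n", sep = "")
  if (!is.na(x$selected_fs)) cat("  selected FS:", x$selected_fs, "\n")
  cat("  CV ", x$metric, ": ", signif(x$cv_score, 4),
      "  [", x$n_evals, " evaluations]\n", sep = "")
  invisible(x)
}

#' @export
predict.fs_run <- function(object, newdata, ...) {
  predict(object$pipeline, newdata, ...)
}

#' Score a fitted pipeline on holdout data
#'
#' @param object an `fs_run`, `fs_pipeline`, or a prediction function
#'   `f(X) -> numeric`.
#' @param x holdout dosage matrix.
#' @param y holdout outcome.
#' @param metric `"accuracy"` (fraction correct at the 0.5 probability
#'   threshold) or `"coefficient_of_determination"` (1 - SSres/SStot).
#' @return a single number.
#' @export
evaluate_holdout <- function(object, x, y,
                             metric = c("accuracy",
                                        "coefficient_of_determination")) {
  metric <- match.arg(metric)
  pred <- if (is.function(object)) object(x) else predict(object, x)
  score_predictions(pred, y,
                    if (metric == "accuracy") "accuracy" else "r2")
}

#' Run one stage of the two-stage search procedure
#'
#' For each run: fresh control down-sampling, fresh train/test1/test2 splits,
#' optional leakage-free residual adjustment (outcome on age + sex + PC1..10,
#' features on array + PC1..10, fitted on the training part only), the
#' evolutionary pipeline search on the training part, and holdout scoring on
#' test1 (stage 1) or test2 (stage 2). Stage 2 restricts the feature matrix
#' to the SNPs of the stage-1-winning feature set and drops the FSS step.
#' Per-run failures are caught and recorded, mirroring how long search runs
#' can fail in practice.
#'
#' @param G genotype dosage matrix for the full cohort.
#' @param cohort cohort table aligned with `G` (columns `phenotype`, `age`,
#'   `sex`, `pc1..pc10`, `array`).
#' @param config list of stage settings: `n_runs`, `stage` (1 or 2),
#'   `fs_map` (stage 1), `stage1_fs` (stage 2: winning FS name), `budget`,
#'   `pool`, `fractions`, `resadj` flag, `cv_folds`, and optionally `ledger`
#'   (path to a JSON-lines run ledger appended to as runs finish).
#' @param seeds integer vector of distinct per-run seeds (default: derived
#'   from `config$base_seed` by the documented counter scheme).
#' @return an object of class `fs_stage`: the list of per-run results plus
#'   the configuration and its hash.
#' @export
run_stage <- function(G, cohort, config, seeds = NULL) {
  assert_dosage_matrix(unclass(G))
  stopifnot(nrow(G) == nrow(cohort))
  cfg <- normalize_stage_config(config)
  if (is.null(seeds)) seeds <- derive_seed(cfg$base_seed, cfg$stage,
                                           seq_len(cfg$n_runs))
  if (anyDuplicated(seeds)) stop("per-run seeds must be distinct", call. = FALSE)
  hash <- stage_config_hash(cfg)
  metric <- if (cfg$resadj) "coefficient_of_determination" else "accuracy"
  pc_cols <- paste0("pc", 1:10)

  runs <- lapply(seq_along(seeds), function(r) {
    s <- seeds[r]
    res <- tryCatch({
      bal <- downsample_controls(cohort, seed = derive_seed(s, 1))
      spl <- make_splits(bal, cfg$fractions, seed = derive_seed(s, 2))
      cols <- if (cfg$stage == 2) {
        members <- if (!is.null(cfg$fs_map)) cfg$fs_map[[cfg$stage1_fs]]
                   else cfg$stage1_fs_snps
        intersect(colnames(G), members %||% cfg$stage1_fs_snps)
      } else colnames(G)
      X <- unclass(G)[, cols, drop = FALSE]
      y <- cohort$phenotype
      if (cfg$resadj) {
        cov_y <- as.matrix(cohort[, c("age", "sex", pc_cols)])
        cov_x <- as.matrix(cohort[, c("array", pc_cols)])
        adj_y <- fit_adjuster(y, cov_y, spl$train_idx)
        adj_x <- fit_adjuster(X, cov_x, spl$train_idx)
        y <- apply_adjuster(adj_y, y, cov_y)
        X <- apply_adjuster(adj_x, X, cov_x)
      }
      fsm <- if (cfg$stage == 1) cfg$fs_map else NULL
      run <- run_pipeline_search(X[spl$train_idx, , drop = FALSE],
                                 y[spl$train_idx], fs_map = fsm,
                                 budget = cfg$budget, pool = cfg$pool,
                                 cv_folds = cfg$cv_folds,
                                 seed = derive_seed(s, 3))
      h1 <- if (length(spl$test1_idx))
        evaluate_holdout(run, X[spl$test1_idx, , drop = FALSE],
                         y[spl$test1_idx], metric) else NA_real_
      h2 <- if (length(spl$test2_idx))
        evaluate_holdout(run, X[spl$test2_idx, , drop = FALSE],
                         y[spl$test2_idx], metric) else NA_real_
      list(run_id = r, seed = s, selected_fs = run$selected_fs,
           cv_score = run$cv_score, holdout1_score = h1, holdout2_score = h2,
           metric = metric, spec = run$spec, pipeline = run$pipeline,
           splits = spl, error = NULL)
    }, error = function(e) {
      list(run_id = r, seed = s, selected_fs = NA_character_,
           cv_score = NA_real_, holdout1_score = NA_real_,
           holdout2_score = NA_real_, metric = metric, spec = NULL,
           pipeline = NULL, splits = NULL, error = conditionMessage(e))
    })
    if (!is.null(cfg$ledger))
      ledger_append(cfg$ledger, list(
        config_hash = hash, seed = s, stage = cfg$stage,
        permutation = cfg$permutation %||% NA,
        run_id = r, selected_fs = res$selected_fs,
        cv_score = res$cv_score, holdout1_score = res$holdout1_score,
        holdout2_score = res$holdout2_score,
        outcome = if (is.null(res$error)) "ok" else res$error))
    res
  })
  structure(list(runs = runs, config = cfg, config_hash = hash,
                 stage = cfg$stage, metric = metric, seeds = seeds),
            class = "fs_stage")
}

# merge user settings over stage defaults and validate
normalize_stage_config <- function(config) {
  cfg <- list(n_runs = 50, stage = 1, fs_map = NULL, stage1_fs = NULL,
              stage1_fs_snps = NULL, budget = search_budget(20, 10),
              pool = NULL, fractions = c(0.75, 0.13, 0.12), resadj = FALSE,
              cv_folds = 5, base_seed = 1, ledger = NULL, permutation = NULL)
  cfg[names(config)] <- config
  if (cfg$stage == 2 && is.null(cfg$stage1_fs) && is.null(cfg$stage1_fs_snps))
    stop("stage 2 requested without a stage-1 winner", call. = FALSE)
  problem <- if (cfg$resadj) "regression" else "classification"
  if (is.null(cfg$pool)) cfg$pool <- operator_pool(problem)
  if (cfg$pool$problem != problem)
    stop("operator pool problem type does not match resadj setting",
         call. = FALSE)
  cfg
}

# hash of the scientifically relevant stage settings (drops ledger paths and
# fitted objects so the observed and null arms compare on substance)
stage_config_hash <- function(cfg) {
  config_hash(list(n_runs = cfg$n_runs, stage = cfg$stage,
                   fs = if (!is.null(cfg$fs_map)) lapply(cfg$fs_map, identity),
                   stage1_fs = cfg$stage1_fs,
                   budget = unclass(cfg$budget),
                   pool = unclass(cfg$pool),
                   fractions = cfg$fractions, resadj = cfg$resadj,
                   cv_folds = cfg$cv_folds))
}

#' @export
print.fs_stage <- function(x, ...) {
  ok <- sum(vapply(x$runs, function(r) is.null(r$error), logical(1)))
  cat("Stage", x$stage, "search:", length(x$runs), "runs (", ok,
      "successful ), metric", x$metric, "\n")
  invisible(x)
}

#' @export
summary.fs_stage <- function(object, ...) {
  h <- vapply(object$runs, function(r)
    if (object$stage == 1) r$holdout1_score else r$holdout2_score, numeric(1))
  out <- list(stage = object$stage, n_runs = length(object$runs),
              n_failed = sum(!vapply(object$runs,
                                     function(r) is.null(r$error), logical(1))),
              holdout_range = range(h, na.rm = TRUE),
              recurrence = summarize_recurrence(object))
  class(out) <- "summary.fs_stage"
  out
}

#' @export
print.summary.fs_stage <- function(x, ...) {
  cat("Stage", x$stage, ":", x$n_runs, "runs,", x$n_failed, "failed\n")
  cat("  holdout score range:", paste(signif(x$holdout_range, 4),
                                      collapse = " - "), "\n")
  print(x$recurrence)
  invisible(x)
}

ledger_append <- function(path, record) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, null = "null",
                           na = "null", digits = NA)
  cat(as.character(line), "\n", sep = "", file = path, append = TRUE)
}

#' Polygenic risk score baseline
#'
#' Computes each sample's PRS as the weighted sum of dosages over the scored
#' SNPs, fits a univariate logistic regression of the phenotype on the PRS on
#' the training rows, and reports holdout accuracy at the 0.5 probability
#' threshold.
#'
#' @param G genotype dosage matrix.
#' @param effects named numeric vector of per-SNP weights (reference alleles
#'   assumed already matched to the dosage orientation).
#' @param cohort cohort table with `phenotype`.
#' @param splits an `fs_splits`; accuracy is computed on `test1_idx`.
#' @return list with the fitted `model`, the `prs` vector, and
#'   `holdout_accuracy`.
#' @export
prs_baseline <- function(G, effects, cohort, splits) {
  missing <- setdiff(names(effects), colnames(G))
  if (length(missing))
    stop("weighted SNPs absent from genotype matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  prs <- as.numeric(unclass(G)[, names(effects), drop = FALSE] %*% effects)
  df <- data.frame(y = cohort$phenotype, prs = prs)
  fit <- suppressWarnings(
    stats::glm(y ~ prs, family = stats::binomial(), data = df,
               subset = splits$train_idx))
  p <- stats::predict(fit, newdata = df[splits$test1_idx, , drop = FALSE],
                      type = "response")
  list(model = fit, prs = prs,
       holdout_accuracy = mean((p > 0.5) == df$y[splits$test1_idx]))
}
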