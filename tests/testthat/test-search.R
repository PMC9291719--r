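# Search engine: down-sampling, splits, leakage-free adjustment, the
# evolutionary pipeline search with FSS, holdout scoring, stages, PRS.

test_that("control down-sampling balances and keeps all cases", {
  cohort <- data.frame(phenotype = c(rep(1, 100), rep(0, 1000)))
  idx <- downsample_controls(cohort, seed = 1)
  expect_length(idx, 200)
  expect_true(all(which(cohort$phenotype == 1) %in% idx))
  idx2 <- downsample_controls(cohort, seed = 2)
  expect_false(identical(idx, idx2))
  expect_identical(intersect(idx, 1:100), intersect(idx2, 1:100))
  # equal cases and controls: identity
  small <- data.frame(phenotype = rep(c(1, 0), each = 10))
  expect_identical(downsample_controls(small, 1), 1:20)
  many_cases <- data.frame(phenotype = rep(c(1, 0), c(10, 5)))
  expect_error(downsample_controls(many_cases, 1), "fewer controls")
})

test_that("splits honor the floor-to-holdout rounding rule and disjointness", {
  s <- make_splits(1:100, c(0.75, 0.13, 0.12), seed = 3)
  expect_length(s$train_idx, 75)
  expect_length(s$test1_idx, 13)
  expect_length(s$test2_idx, 12)
  expect_length(intersect(s$train_idx, s$test1_idx), 0)
  expect_length(intersect(s$train_idx, s$test2_idx), 0)
  expect_length(intersect(s$test1_idx, s$test2_idx), 0)
  expect_setequal(c(s$train_idx, s$test1_idx, s$test2_idx), 1:100)
  # two-way baseline mode
  s2 <- make_splits(1:101, c(0.75, 0.25, 0), seed = 4)
  expect_length(s2$test1_idx, 25)   # floor(25.25)
  expect_length(s2$test2_idx, 0)
  expect_length(s2$train_idx, 76)   # remainder goes to train
  expect_error(make_splits(1:10, c(0.7, 0.2, 0.2)), "sum to 1")
})

test_that("adjuster is fitted on training rows only (leakage-freedom)", {
  set.seed(5)
  n <- 200
  cov <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  x <- 2 + 0.5 * cov[, 1] - 1 * cov[, 2] + rnorm(n)
  train <- 1:120
  adj <- fit_adjuster(x, cov, train)
  # perturbing holdout rows must not change the fit
  x2 <- x; x2[121:200] <- 999
  cov2 <- cov; cov2[121:200, ] <- -999
  adj2 <- fit_adjuster(x2, cov2, train)
  expect_identical(adj$coef, adj2$coef)
  # training residuals orthogonal to covariates
  res <- apply_adjuster(adj, x, cov)[train]
  expect_lt(abs(cor(res, cov[train, 1])), 1e-8)
  expect_lt(abs(cor(res, cov[train, 2])), 1e-8)
})

test_that("adjuster reproduces closed-form special cases", {
  set.seed(6)
  n <- 100
  cov <- matrix(rnorm(n), ncol = 1)
  # column orthogonal to the covariate: residuals are the centered column
  x <- rnorm(n)
  x_orth <- as.numeric(residuals(lm(x ~ cov)))  # independent construction
  adj <- fit_adjuster(x_orth + 5, cov, seq_len(n))
  expect_equal(apply_adjuster(adj, x_orth + 5, cov), x_orth,
               tolerance = 1e-10)
  # column exactly linear in the covariate: residuals vanish
  y <- 3 - 2 * cov[, 1]
  adj2 <- fit_adjuster(y, cov, seq_len(n))
  expect_lt(max(abs(apply_adjuster(adj2, y, cov))), 1e-8)
  # rank-deficient covariates fall back to the pseudoinverse with a warning
  covdup <- cbind(cov, cov)
  expect_warning(adj3 <- fit_adjuster(y, covdup, seq_len(n)), "rank")
  expect_lt(max(abs(apply_adjuster(adj3, y, covdup))), 1e-6)
})

test_that("holdout metrics behave on degenerate predictors", {
  y <- rep(c(0, 1), each = 25)
  expect_equal(evaluate_holdout(function(X) rep(0.5, nrow(X)),
                                matrix(0, 50, 1), y, "accuracy"), 0.5)
  expect_equal(evaluate_holdout(function(X) y, matrix(0, 50, 1), y,
                                "accuracy"), 1.0)
  yr <- rnorm(50)
  expect_equal(evaluate_holdout(function(X) rep(mean(yr), 50),
                                matrix(0, 50, 1), yr,
                                "coefficient_of_determination"), 0)
})

test_that("a singleton pool with one FS returns that configuration", {
  fix <- planted_fs_fixture(n_samples = 300, n_fs = 2, seed = 71)
  one_fs <- fix$fs_map[1]
  class(one_fs) <- "fs_map"
  pool <- operator_pool("classification", transformers = "identity",
                        estimators = "linear")
  run <- run_pipeline_search(unclass(fix$G), fix$cohort$phenotype,
                             fs_map = one_fs, budget = search_budget(4, 2),
                             pool = pool, seed = 72)
  expect_equal(run$selected_fs, names(one_fs))
  expect_equal(run$spec$trans$name, "identity")
  expect_equal(run$spec$est$name, "linear")
  expect_error(run_pipeline_search(unclass(fix$G), fix$cohort$phenotype,
                                   fs_map = structure(list(), class = "fs_map"),
                                   pool = pool), "non-empty")
})

test_that("search recovers a planted causal feature set across seeds", {
  fix <- planted_fs_fixture(n_samples = 2000, n_fs = 10, beta = 3.0,
                            n_causal = 1, seed = 81)
  expect_gt(bayes_accuracy(fix$model, fix$G), 0.6)
  hits <- vapply(1:10, function(s) {
    run <- run_pipeline_search(unclass(fix$G)[1:1500, ],
                               fix$cohort$phenotype[1:1500],
                               fs_map = fix$fs_map,
                               budget = search_budget(20, 6),
                               pool = fast_pool(), seed = derive_seed(80, s))
    run$selected_fs == fix$target
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("search is deterministic per seed", {
  fix <- planted_fs_fixture(n_samples = 400, n_fs = 4, seed = 91)
  args <- list(unclass(fix$G), fix$cohort$phenotype, fs_map = fix$fs_map,
               budget = search_budget(6, 3), pool = fast_pool(), seed = 92)
  r1 <- do.call(run_pipeline_search, args)
  r2 <- do.call(run_pipeline_search, args)
  expect_identical(r1$selected_fs, r2$selected_fs)
  expect_identical(r1$cv_score, r2$cv_score)
  expect_identical(r1$spec, r2$spec)
})

test_that("pure-noise phenotype yields chance-level holdout accuracy", {
  fix <- planted_fs_fixture(n_samples = 400, n_fs = 5, beta = 0,
                            n_causal = 0, seed = 103)
  accs <- vapply(1:20, function(s) {
    bal <- downsample_controls(fix$cohort, seed = derive_seed(100, s, 1))
    spl <- make_splits(bal, c(0.75, 0.25, 0), seed = derive_seed(100, s, 2))
    run <- run_pipeline_search(unclass(fix$G)[spl$train_idx, ],
                               fix$cohort$phenotype[spl$train_idx],
                               fs_map = fix$fs_map,
                               budget = search_budget(5, 2),
                               pool = fast_pool(),
                               seed = derive_seed(100, s, 3))
    evaluate_holdout(run, unclass(fix$G)[spl$test1_idx, ],
                     fix$cohort$phenotype[spl$test1_idx])
  }, numeric(1))
  n_hold <- 400 * 0.25
  se <- sqrt(0.25 / n_hold) / sqrt(20)
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("every operator in the default pool fits and predicts", {
  set.seed(111)
  n <- 120
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.3) > 0)
  pool <- operator_pool("classification")
  for (est in pool$estimators) {
    for (tr in pool$transformers) {
      spec <- list(fs = NA_character_,
                   trans = list(name = tr,
                                params = lapply(pool$grids[[tr]], `[[`, 1)),
                   est = list(name = est,
                              params = lapply(pool$grids[[est]], `[[`, 1)))
      fit <- fsrecur:::fit_pipeline(spec, X, y, "classification")
      p <- predict(fit, X)
      expect_length(p, n)
      expect_true(all(p >= 0 & p <= 1))
      expect_gt(mean((p > 0.5) == y), 0.7)
    }
  }
  # regression counterparts
  yr <- X[, 1] + rnorm(n, sd = 0.2)
  poolr <- operator_pool("regression")
  for (est in poolr$estimators) {
    spec <- list(fs = NA_character_,
                 trans = list(name = "identity", params = list()),
                 est = list(name = est,
                            params = lapply(poolr$grids[[est]], `[[`, 1)))
    fit <- fsrecur:::fit_pipeline(spec, X, yr, "regression")
    expect_gt(evaluate_holdout(fit, X, yr, "coefficient_of_determination"),
              0.5)
  }
})

test_that("run_stage produces distinct down-samplings and honors stage 2", {
  fix <- planted_fs_fixture(n_samples = 500, n_fs = 3, seed = 121)
  cfg <- list(n_runs = 2, stage = 1, fs_map = fix$fs_map,
              budget = search_budget(4, 2), pool = fast_pool(),
              base_seed = 122)
  st <- run_stage(fix$G, fix$cohort, cfg)
  expect_s3_class(st, "fs_stage")
  expect_length(st$runs, 2)
  expect_false(identical(st$runs[[1]]$splits$train_idx,
                         st$runs[[2]]$splits$train_idx))
  expect_true(all(vapply(st$runs, function(r)
    length(intersect(r$splits$test1_idx, r$splits$test2_idx)) == 0,
    logical(1))))
  expect_equal(st$metric, "accuracy")
  # stage 2 restricts features to the winning FS and drops FSS
  winner <- summarize_recurrence(st)$argmax_fs[1]
  cfg2 <- modifyList(cfg, list(stage = 2, stage1_fs = winner))
  st2 <- run_stage(fix$G, fix$cohort, cfg2)
  feats <- st2$runs[[1]]$pipeline$features
  expect_true(all(feats %in% fix$fs_map[[winner]]))
  expect_true(is.na(st2$runs[[1]]$selected_fs))
  expect_false(is.na(st2$runs[[1]]$holdout2_score))
  expect_error(run_stage(fix$G, fix$cohort, modifyList(cfg, list(stage = 2))),
               "stage-1 winner")
})

test_that("resAdj stages regress residualized outcomes", {
  fix <- planted_fs_fixture(n_samples = 500, n_fs = 3, seed = 131)
  cfg <- list(n_runs = 1, stage = 1, fs_map = fix$fs_map,
              budget = search_budget(4, 2), pool = fast_pool("regression"),
              resadj = TRUE, base_seed = 132)
  st <- run_stage(fix$G, fix$cohort, cfg)
  expect_equal(st$metric, "coefficient_of_determination")
  expect_equal(st$runs[[1]]$metric, "coefficient_of_determination")
  # mismatched pool problem type is rejected
  bad <- modifyList(cfg, list(pool = fast_pool("classification")))
  expect_error(run_stage(fix$G, fix$cohort, bad), "does not match")
})

test_that("PRS baseline recovers chance on zero weights and signal on beta", {
  fix <- planted_fs_fixture(n_samples = 2000, n_fs = 4, beta = 1.2,
                            seed = 141)
  bal <- downsample_controls(fix$cohort, seed = 142)
  spl <- make_splits(bal, c(0.75, 0.25, 0), seed = 143)
  zero <- setNames(rep(0, 3), names(fix$causal))
  r0 <- prs_baseline(fix$G, zero, fix$cohort, spl)
  expect_lt(abs(r0$holdout_accuracy - 0.5), 0.08)
  r1 <- prs_baseline(fix$G, fix$causal, fix$cohort, spl)
  expect_gt(r1$holdout_accuracy, 0.58)
  # flipping weights and dosages leaves the PRS model invariant
  Gf <- 2 - unclass(fix$G)
  class(Gf) <- class(fix$G)
  r2 <- prs_baseline(Gf, -fix$causal, fix$cohort, spl)
  expect_equal(r2$holdout_accuracy, r1$holdout_accuracy, tolerance = 1e-12)
  expect_error(prs_baseline(fix$G, c(nosuch = 1), fix$cohort, spl), "absent")
})
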