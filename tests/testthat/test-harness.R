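# Cross-environment CV harness: fold plans, pooled metrics, leakage,
# learner registry.

test_that("environment folds partition exactly", {
  envs <- sprintf("E%02d", 1:14)
  f <- make_env_folds(envs, 7, seed = 3)
  expect_length(f$folds, 7)
  expect_true(all(lengths(f$folds) == 2))
  expect_setequal(unlist(f$folds), envs)
  expect_identical(f, make_env_folds(envs, 7, seed = 3))
  f2 <- make_env_folds(c("a", "b"), 2, seed = 1)
  expect_true(all(lengths(f2$folds) == 1))
  expect_error(make_env_folds(envs[1:13], 7), "equal folds")
})

test_that("random fold plans are valid and non-degenerate over seeds", {
  envs <- sprintf("E%02d", 1:14)
  first_partner <- vapply(1:200, function(s) {
    f <- make_env_folds(envs, 7, seed = s)
    expect_setequal(unlist(f$folds), envs)
    hit <- vapply(f$folds, function(x) "E01" %in% x, NA)
    setdiff(f$folds[[which(hit)]], "E01")
  }, "")
  # E01's partner varies across seeds (the partition is genuinely random)
  expect_gt(length(unique(first_partner)), 5)
})

test_that("pooled metrics match their defining formulas", {
  obs <- c(3, 5, 2, 8, 6)
  m <- pooled_metrics(obs, obs)
  expect_equal(m$PCC, 1); expect_equal(m$R2, 1); expect_equal(m$MSE, 0)
  m2 <- pooled_metrics(rep(mean(obs), 5), obs)
  expect_equal(m2$R2, 0)
  set.seed(12)
  pred <- rnorm(40); o <- rnorm(40)
  m3 <- pooled_metrics(pred, o)
  expect_equal(m3$PCC, cor(pred, o))
  expect_equal(m3$R2, 1 - sum((o - pred)^2) / sum((o - mean(o))^2))
  expect_equal(m3$MSE, mean((o - pred)^2))
  expect_equal(m3$R2, 1 - m3$MSE * 40 / sum((o - mean(o))^2))
  expect_error(pooled_metrics(rnorm(3), rep(1, 3)), "constant")
})

test_that("R2 equals squared PCC for OLS predictions", {
  set.seed(4)
  x <- rnorm(60); o <- 2 * x + rnorm(60)
  pred <- fitted(lm(o ~ x))
  m <- pooled_metrics(pred, o)
  expect_equal(m$R2, m$PCC^2, tolerance = 1e-10)
})

test_that("every sample is predicted exactly once and baselines fail", {
  sim <- small_sim(seed = 14, n_lines = 6, n_reps = 2)
  idx <- derive_daily_indices(sim$weather)
  fx <- build_window_features(idx)
  folds <- make_env_folds(unique(sim$phenotypes$env_id), 7, seed = 2)
  cv <- cross_env_evaluate(model_spec("Mean"), fx, sim$phenotypes, "BW",
                           folds)
  expect_equal(cv$n_pooled, 6 * 14)
  key <- paste(cv$predictions$genotype_id, cv$predictions$env_id)
  expect_equal(anyDuplicated(key), 0)
  # the training-mean baseline ignores real environment signal
  expect_lte(cv$R2, 0.05)
})

test_that("held-out phenotypes cannot leak into predictions", {
  sim <- small_sim(seed = 15, n_lines = 5, n_reps = 1)
  idx <- derive_daily_indices(sim$weather)
  fx <- build_window_features(idx, factors = c("radn", "tmax", "pcp"))
  envs <- unique(sim$phenotypes$env_id)
  folds <- make_env_folds(envs, 7, seed = 5)
  spec <- model_spec("RandomForest", list(n_estimators = 50, mtry = 30),
                     seed = 9)
  cv1 <- cross_env_evaluate(spec, fx, sim$phenotypes, "BW", folds)
  # permute phenotype values inside the environments of one fold
  ph2 <- sim$phenotypes
  held <- folds$folds[[3]]
  i <- which(ph2$env_id %in% held)
  set.seed(1); ph2$BW[i] <- sample(ph2$BW[i])
  cv2 <- cross_env_evaluate(spec, fx, ph2, "BW", folds)
  p1 <- cv1$predictions[cv1$predictions$fold == 3, ]
  p2 <- cv2$predictions[cv2$predictions$fold == 3, ]
  expect_equal(setNames(p1$pred, p1$genotype_id)[order(p1$genotype_id)],
               setNames(p2$pred, p2$genotype_id)[order(p2$genotype_id)])
})

test_that("deterministic learners reproduce metrics under a fixed seed", {
  sim <- small_sim(seed = 16, n_lines = 5, n_reps = 1)
  idx <- derive_daily_indices(sim$weather)
  fx <- build_window_features(idx, factors = c("radn", "rhmean"))
  folds <- make_env_folds(unique(sim$phenotypes$env_id), 7, seed = 1)
  spec <- model_spec("RandomForest", list(n_estimators = 60), seed = 4)
  a <- cross_env_evaluate(spec, fx, sim$phenotypes, "BW", folds)
  b <- cross_env_evaluate(spec, fx, sim$phenotypes, "BW", folds)
  expect_identical(a$PCC, b$PCC)
  expect_identical(a$MSE, b$MSE)
})

test_that("identical feature sets give zero deltas; empty sets error", {
  sim <- small_sim(seed = 17, n_lines = 5, n_reps = 1)
  idx <- derive_daily_indices(sim$weather)
  fx <- build_window_features(idx, factors = c("radn", "rhmean"))
  folds <- make_env_folds(unique(sim$phenotypes$env_id), 7, seed = 1)
  spec <- model_spec("RandomForest", list(n_estimators = 40), seed = 4)
  cmp <- compare_feature_sets(spec, fx, fx, sim$phenotypes, "BW", folds)
  expect_equal(cmp$delta_R2, 0)
  expect_equal(cmp$delta_PCC, 0)
  expect_equal(cmp$selection_ratio, 1)
  expect_error(
    compare_feature_sets(spec, fx, fx[, 0], sim$phenotypes, "BW", folds),
    "empty")
  expect_error(
    compare_feature_sets(spec, fx[, 1:10], fx, sim$phenotypes, "BW",
                         folds),
    "subset")
})

test_that("the evidence-maximisation ridge recovers a linear signal", {
  set.seed(33)
  n <- 80; p <- 10
  x <- matrix(rnorm(n * p), n, p)
  beta <- c(2, -1.5, rep(0, p - 2))
  y <- 1 + x %*% beta + rnorm(n, sd = 0.3)
  spec <- model_spec("BayesianRidge")
  fit <- spec$learner$fit(x, as.vector(y), spec)
  pred <- spec$learner$predict(fit, x)
  expect_gt(cor(pred, y), 0.97)
  expect_equal(fit$coef[1:2], beta[1:2], tolerance = 0.15)
  # shrinkage keeps null coefficients near zero
  expect_lt(max(abs(fit$coef[3:p])), 0.25)
})

test_that("the core learner registry is present", {
  av <- available_models()
  expect_true(all(c("RandomForest", "BayesianRidge", "Mean") %in% av))
  expect_error(model_spec("NeuralNet"), "unknown")
})
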