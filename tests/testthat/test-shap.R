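# TreeSHAP attributions, profile smoothing, and key-window selection.

fit_small <- function(seed = 1, factors = c("radn", "rhmean", "wsmean"),
                      n_lines = 8, trees = 100, mtry = 60, ...) {
  sim <- small_sim(seed = seed, n_lines = n_lines, n_reps = 1, ...)
  idx <- derive_daily_indices(sim$weather)
  fx <- build_window_features(idx, factors = factors)
  pcs <- genotype_pcs(sim$genotypes)
  fit <- fit_rf_for_trait(fx, sim$phenotypes, "BW", pcs = pcs,
                          n_estimators = trees, seed = seed, mtry = mtry)
  list(sim = sim, fx = fx, pcs = pcs, fit = fit)
}

test_that("TreeSHAP satisfies local accuracy against the forest", {
  s <- fit_small(seed = 41)
  sh <- rf_shap_values(s$fit)
  pred <- predict(s$fit$forest, data = s$fit$x,
                  num.threads = 1)$predictions
  # exported trees route samples exactly as the forest does
  expect_equal(sh$pred, pred, tolerance = 1e-10)
  # base value + attributions reproduce every prediction
  expect_equal(unname(sh$base + rowSums(sh$shap)), pred,
               tolerance = 1e-8)
  expect_equal(sh$base, mean(pred), tolerance = 0.05)
})

test_that("identical seeds give identical forests and attributions", {
  a <- fit_small(seed = 42, trees = 40)
  b <- fit_small(seed = 42, trees = 40)
  expect_identical(predict(a$fit$forest, data = a$fit$x,
                           num.threads = 1)$predictions,
                   predict(b$fit$forest, data = b$fit$x,
                           num.threads = 1)$predictions)
  expect_equal(rf_shap_values(a$fit)$shap, rf_shap_values(b$fit)$shap,
               tolerance = 1e-12)
})

test_that("a single informative feature dominates importance and SHAP", {
  set.seed(51)
  n <- 150; p <- 30
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- window_key("tmax", seq_len(p), seq_len(p) + 4)
  y <- 3 * x[, 7] + rnorm(n, sd = 0.2)
  rf <- ranger::ranger(x = x, y = y, num.trees = 100, seed = 1,
                       num.threads = 1, importance = "impurity")
  fit <- structure(list(forest = rf, x = x, y = y, trait = "BW",
                        env_cols = colnames(x),
                        cache = new.env(parent = emptyenv())),
                   class = "rf_trait_fit")
  imp <- rf$variable.importance
  expect_equal(which.max(imp), 7L, ignore_attr = TRUE)
  sh <- rf_shap_values(fit)
  expect_equal(which.max(colMeans(abs(sh$shap))), 7L, ignore_attr = TRUE)
  # impurity importance is normalised to sum to one in the profiles
  prof <- attribution_profiles(fit, span = 1)
  expect_equal(sum(prof$importance), 1, tolerance = 1e-10)
})

test_that("profiles align to the window grid and order by start day", {
  s <- fit_small(seed = 43)
  prof <- attribution_profiles(s$fit)
  expect_equal(nrow(prof), ncol(s$fx))
  expect_true(all(prof$importance >= 0))
  expect_true(all(is.finite(prof$mean_abs_shap)))
  for (f in unique(prof$factor)) {
    expect_equal(prof$start[prof$factor == f], 1:146)
  }
  # PC covariates are profiled separately, never as windows
  expect_false(any(grepl("^PC", prof$key)))
  expect_true(all(grepl("^PC", attr(prof, "pc_profile")$key)))
})

test_that("smoothing is a centered moving average with edge shrinkage", {
  expect_equal(smooth_profile(rep(4, 10), 5), rep(4, 10))
  imp <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(smooth_profile(imp, 5),
               c(0, 0, 0.2, 0.2, 0.2, 0.2, 0.2, 0, 0))
  set.seed(3)
  x <- rnorm(40)
  sm <- smooth_profile(x, 5)
  for (i in seq_along(x)) {
    expect_equal(sm[i], mean(x[max(1, i - 2):min(40, i + 2)]))
  }
  expect_error(smooth_profile(x, 4), "odd")
})

test_that("one dominant window yields exactly one merged entry", {
  prof <- data.frame(factor = rep("tmax", 20), start = 1:20, end = 5:24,
                     key = window_key("tmax", 1:20, 5:24),
                     importance = 0, mean_abs_shap = 0, shap_signed = 0)
  prof$importance[10] <- 1; prof$mean_abs_shap[10] <- 1
  prof$importance_smooth <- prof$importance
  prof$shap_smooth <- prof$mean_abs_shap
  prof <- structure(prof, class = c("window_profiles", "data.frame"),
                    trait = "BW", span = 1)
  kw <- select_key_windows(prof, tau = 0.10)
  expect_equal(nrow(kw), 1)
  expect_equal(kw$start_day, 10)
  expect_equal(kw$end_day, 14)
})

test_that("overlapping significant windows merge into one period", {
  starts <- 1:30
  prof <- data.frame(factor = "tmax", start = starts, end = starts + 4,
                     key = window_key("tmax", starts, starts + 4),
                     importance = 0, mean_abs_shap = 0, shap_signed = 0)
  hot <- starts %in% 11:15                  # windows starting 11..15
  prof$importance[hot] <- 1; prof$mean_abs_shap[hot] <- 1
  prof$importance_smooth <- prof$importance
  prof$shap_smooth <- prof$mean_abs_shap
  prof <- structure(prof, class = c("window_profiles", "data.frame"),
                    trait = "BW", span = 1)
  kw <- select_key_windows(prof, tau = 0.10)
  expect_equal(nrow(kw), 1)
  # interval union of [11,15]..[15,19]
  expect_equal(kw$start_day, 11)
  expect_equal(kw$end_day, 19)
  expect_equal(kw$n_windows, 5)
  # disjoint significant runs stay separate
  prof$importance[c(1, 2, 25)] <- 1; prof$mean_abs_shap[c(1, 2, 25)] <- 1
  prof$importance_smooth <- prof$importance
  prof$shap_smooth <- prof$mean_abs_shap
  kw2 <- select_key_windows(prof, tau = 0.10)
  expect_equal(nrow(kw2), 3)
})

test_that("all-zero profiles give an empty set with a warning", {
  prof <- data.frame(factor = "tmax", start = 1:5, end = 5:9,
                     key = window_key("tmax", 1:5, 5:9),
                     importance = 0, mean_abs_shap = 0, shap_signed = 0,
                     importance_smooth = 0, shap_smooth = 0)
  prof <- structure(prof, class = c("window_profiles", "data.frame"),
                    trait = "BW", span = 1)
  expect_warning(kw <- select_key_windows(prof), "empty")
  expect_equal(nrow(kw), 0)
})

test_that("selection is invariant to a factor's units", {
  s <- fit_small(seed = 44, trees = 60)
  kw1 <- suppressWarnings(
    select_key_windows(attribution_profiles(s$fit)))
  fx2 <- s$fx
  radn_cols <- grepl("^radn_", colnames(fx2))
  fx2[, radn_cols] <- fx2[, radn_cols] * 1000   # kJ instead of MJ
  fit2 <- fit_rf_for_trait(fx2, s$sim$phenotypes, "BW", pcs = s$pcs,
                           n_estimators = 60, seed = 44, mtry = 60)
  kw2 <- suppressWarnings(
    select_key_windows(attribution_profiles(fit2)))
  expect_equal(kw1[c("factor", "start_day", "end_day")],
               kw2[c("factor", "start_day", "end_day")])
})

test_that("dependence export pairs values with attributions per sample", {
  s <- fit_small(seed = 45, trees = 40)
  key <- colnames(s$fx)[10]
  dep <- shap_dependence_export(s$fit, key)
  expect_equal(nrow(dep), nrow(s$fit$x))
  expect_equal(dep$value, unname(s$fit$x[, key]))
  expect_error(shap_dependence_export(s$fit, "tmax_999_1003"), "unknown")
  # a constant feature is never split on, so its attributions are zero
  set.seed(9)
  x <- cbind(matrix(rnorm(200), 100, 2), 1)
  colnames(x) <- window_key("radn", 1:3, 5:7)
  y <- x[, 1] + rnorm(100, 0.1)
  rf <- ranger::ranger(x = x, y = y, num.trees = 50, seed = 2,
                       num.threads = 1, importance = "impurity")
  fit <- structure(list(forest = rf, x = x, y = y, trait = "BW",
                        env_cols = colnames(x),
                        cache = new.env(parent = emptyenv())),
                   class = "rf_trait_fit")
  sh <- rf_shap_values(fit)
  expect_equal(max(abs(sh$shap[, 3])), 0)
})

test_that("key windows expand back to the covered feature columns", {
  s <- fit_small(seed = 46, trees = 40)
  kw <- data.frame(trait = "BW", factor = "radn", start_day = 100L,
                   end_day = 112L)
  sel <- key_window_features(kw, s$fx)
  meta <- parse_window_key(colnames(sel))
  expect_true(all(meta$factor == "radn" & meta$start >= 100 &
                    meta$end <= 112))
  expect_equal(ncol(sel), 9)  # starts 100..108
  expect_error(key_window_features(
    data.frame(trait = "BW", factor = "pcp", start_day = 1L,
               end_day = 3L), s$fx), "no feature columns")
})
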