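# Random-forest key-window identification: impurity importance and
# TreeSHAP attribution profiles over the dense 5-day window grid,
# smoothing, thresholding, and merging into key-window sets.

#' Fit a regression forest for one trait
#'
#' Trains a random forest (default 500 trees, squared-error split
#' criterion, `mtry = floor(p/3)`) on genotype-by-environment samples whose
#' features are the dense window grid plus optional genotype principal
#' components. The fit is fully seeded and caches everything the
#' attribution functions need.
#'
#' @param env_features environments x window-features matrix from
#'   [build_window_features()].
#' @param phenotypes replicated phenotype table.
#' @param trait trait column.
#' @param pcs optional [genotype_pcs()]; PC columns are model covariates
#'   but never eligible as environmental key windows.
#' @param n_estimators number of trees (default 500).
#' @param seed integer seed; identical seeds give identical forests.
#' @param mtry,min_node_size forest controls; defaults `floor(p/3)` and 5.
#' @param rep_average average replicates per sample (default TRUE).
#' @return list of class `rf_trait_fit` with the fitted forest, the
#'   training matrix, the response, `training_r2`, and the set of
#'   environmental (non-PC) columns.
#' @export
fit_rf_for_trait <- function(env_features, phenotypes, trait, pcs = NULL,
                             n_estimators = 500, seed = 1, mtry = NULL,
                             min_node_size = 5, rep_average = TRUE) {
  samples <- harness_samples(phenotypes, trait, rep_average)
  x <- sample_feature_matrix(env_features, pcs, samples)
  if (!is.numeric(x)) stop("non-numeric feature matrix")
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(x) / 3))
  rf <- ranger::ranger(x = x, y = samples$y, num.trees = n_estimators,
                       mtry = mtry, min.node.size = min_node_size,
                       splitrule = "variance", importance = "impurity",
                       seed = seed, num.threads = 1)
  pred <- predict(rf, data = x, num.threads = 1)$predictions
  r2 <- 1 - sum((samples$y - pred)^2) / sum((samples$y - mean(samples$y))^2)
  structure(list(forest = rf, x = x, y = samples$y, samples = samples,
                 trait = trait, training_r2 = r2,
                 env_cols = colnames(env_features),
                 cache = new.env(parent = emptyenv())),
            class = "rf_trait_fit")
}

#' @export
print.rf_trait_fit <- function(x, ...) {
  cat(sprintf("regression forest: %s, %d samples x %d features, %d trees, training R2 %.3f\n",
              x$trait, nrow(x$x), ncol(x$x), x$forest$num.trees,
              x$training_r2))
  invisible(x)
}

# Internal: export ranger trees to the flat structure the C++ code reads,
# with node covers recomputed by routing the training data.
export_forest <- function(fit) {
  rf <- fit$forest
  x <- fit$x
  lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    if (any(ti$leftChild < ti$nodeID, na.rm = TRUE)) {
      stop("unexpected tree node ordering")  # children must follow parents
    }
    tree <- list(
      left = as.integer(ifelse(is.na(ti$leftChild), -1L, ti$leftChild)),
      right = as.integer(ifelse(is.na(ti$rightChild), -1L,
                                ti$rightChild)),
      feature = as.integer(ifelse(ti$terminal, -1L, ti$splitvarID)),
      threshold = as.double(ifelse(ti$terminal, 0, ti$splitval)),
      value = as.double(ifelse(ti$terminal, ti$prediction, 0))
    )
    tree$cover <- tree_cover_cpp(c(tree, list(cover = numeric(1))), x)
    tree
  })
}

#' TreeSHAP attributions for a fitted forest
#'
#' Exact path-dependent TreeSHAP over all trees, evaluated on the training
#' samples (or any matrix with the same columns). Satisfies local
#' accuracy: `base + rowSums(shap)` equals the forest prediction for every
#' sample. Results for the training matrix are cached inside the fit.
#'
#' @param fit an [fit_rf_for_trait()] object.
#' @param x optional matrix of samples to explain (default: training
#'   matrix).
#' @return list with `shap` (samples x features), `base` (scalar expected
#'   value), `pred` (forest predictions).
#' @export
rf_shap_values <- function(fit, x = NULL) {
  stopifnot(inherits(fit, "rf_trait_fit"))
  use_cache <- is.null(x)
  if (use_cache && !is.null(fit$cache$shap)) return(fit$cache$shap)
  if (is.null(x)) x <- fit$x
  if (!identical(colnames(x), colnames(fit$x))) {
    stop("feature columns do not match the fitted forest")
  }
  trees <- fit$cache$trees
  if (is.null(trees)) {
    trees <- export_forest(fit)
    fit$cache$trees <- trees
  }
  phi <- forest_shap_cpp(trees, x)
  dimnames(phi) <- dimnames(x)
  out <- list(shap = phi, base = attr(phi, "base"),
              pred = forest_predict_cpp(trees, x))
  if (use_cache) fit$cache$shap <- out
  out
}

#' Importance and SHAP profiles over the window grid
#'
#' Two complementary per-feature summaries of the fitted forest: impurity
#' feature importance (normalised to sum to 1 over all features) and mean
#' absolute SHAP attribution over all samples. Environmental window
#' features are grouped by factor and ordered by window start, then
#' smoothed with a centered moving average ([smooth_profile()]); genotype
#' PC covariates are profiled separately and are never eligible as key
#' windows.
#'
#' @param fit an [fit_rf_for_trait()] object.
#' @param span moving-average span in windows (odd, default 5).
#' @return data.frame of class `window_profiles` with columns `factor`,
#'   `start`, `end`, `key`, `importance`, `mean_abs_shap`,
#'   `importance_smooth`, `shap_smooth`; PC summaries in
#'   `attr(, "pc_profile")`, signed mean attributions in `shap_signed`.
#' @export
attribution_profiles <- function(fit, span = 5) {
  stopifnot(inherits(fit, "rf_trait_fit"))
  imp <- fit$forest$variable.importance
  if (is.null(imp)) stop("forest was fitted without impurity importance")
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  sh <- rf_shap_values(fit)
  mean_abs <- colMeans(abs(sh$shap))
  mean_signed <- colMeans(sh$shap)

  env_keys <- intersect(colnames(fit$x), fit$env_cols)
  meta <- parse_window_key(env_keys)
  prof <- data.frame(factor = meta$factor, start = meta$start,
                     end = meta$end, key = env_keys,
                     importance = unname(imp[env_keys]),
                     mean_abs_shap = unname(mean_abs[env_keys]),
                     shap_signed = unname(mean_signed[env_keys]),
                     stringsAsFactors = FALSE)
  prof <- prof[order(match(prof$factor, SCAN_FACTORS), prof$start), ]
  prof$importance_smooth <- NA_real_
  prof$shap_smooth <- NA_real_
  for (f in unique(prof$factor)) {
    i <- which(prof$factor == f)
    prof$importance_smooth[i] <- smooth_profile(prof$importance[i], span)
    prof$shap_smooth[i] <- smooth_profile(prof$mean_abs_shap[i], span)
  }
  rownames(prof) <- NULL
  pc_keys <- setdiff(colnames(fit$x), env_keys)
  pc_prof <- data.frame(key = pc_keys, importance = unname(imp[pc_keys]),
                        mean_abs_shap = unname(mean_abs[pc_keys]),
                        stringsAsFactors = FALSE)
  structure(prof, class = c("window_profiles", "data.frame"),
            trait = fit$trait, span = span, pc_profile = pc_prof)
}

#' Centered moving average with edge shrinkage
#'
#' Smooths an ordered per-window profile with a centered moving average of
#' odd span; at the edges the average is taken over the available
#' neighbours only (never zero-padded), so a constant profile is returned
#' unchanged.
#'
#' @param values numeric vector ordered by window start.
#' @param span odd window count (default 5).
#' @return numeric vector, same length.
#' @export
smooth_profile <- function(values, span = 5) {
  if (span < 1 || span %% 2 == 0) stop("span must be odd and >= 1")
  n <- length(values)
  half <- (span - 1) / 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(values[lo:hi])
  }, 0)
}

#' Select key environmental windows
#'
#' A 5-day window is significant when its smoothed importance reaches
#' `tau` times the maximum smoothed importance over all environmental
#' windows and (by default) its smoothed mean absolute SHAP reaches `tau`
#' times the corresponding SHAP maximum; both thresholds are global across
#' factors. Overlapping or adjacent significant windows of the same factor
#' merge into one period (minimum start, maximum end), ranked by peak
#' smoothed SHAP.
#'
#' @param profiles an [attribution_profiles()] table.
#' @param tau fraction of each profile's maximum (default 0.10).
#' @param combine `"and"` (default: both criteria), `"or"`, or a single
#'   criterion `"importance"` / `"shap"`.
#' @return data.frame of class `key_windows` with columns `trait`,
#'   `factor`, `start_day`, `end_day`, `peak_importance`,
#'   `peak_mean_abs_shap`, `n_windows`.
#' @export
select_key_windows <- function(profiles, tau = 0.10,
                               combine = c("and", "or", "importance",
                                           "shap")) {
  combine <- match.arg(combine)
  stopifnot(inherits(profiles, "window_profiles"))
  trait <- attr(profiles, "trait")
  max_imp <- max(profiles$importance_smooth)
  max_shap <- max(profiles$shap_smooth)
  empty <- function() {
    warning("no window passes the selection threshold; empty key-window set")
    structure(data.frame(trait = character(), factor = character(),
                         start_day = integer(), end_day = integer(),
                         peak_importance = numeric(),
                         peak_mean_abs_shap = numeric(),
                         n_windows = integer(), stringsAsFactors = FALSE),
              class = c("key_windows", "data.frame"))
  }
  if (max_imp <= 0 && max_shap <= 0) return(empty())
  hit_imp <- profiles$importance_smooth >= tau * max_imp
  hit_shap <- profiles$shap_smooth >= tau * max_shap
  sig <- switch(combine,
                and = hit_imp & hit_shap,
                or = hit_imp | hit_shap,
                importance = hit_imp,
                shap = hit_shap)
  if (!any(sig)) return(empty())
  s <- profiles[sig, , drop = FALSE]
  rows <- list()
  for (f in unique(s$factor)) {
    sf <- s[s$factor == f, , drop = FALSE]
    sf <- sf[order(sf$start), ]
    grp <- cumsum(c(1, as.integer(sf$start[-1] > head(sf$end, -1) + 1)))
    for (g in split(seq_len(nrow(sf)), grp)) {
      rows[[length(rows) + 1]] <- data.frame(
        trait = trait, factor = f,
        start_day = min(sf$start[g]), end_day = max(sf$end[g]),
        peak_importance = max(sf$importance_smooth[g]),
        peak_mean_abs_shap = max(sf$shap_smooth[g]),
        n_windows = length(g), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_mean_abs_shap), ]
  rownames(out) <- NULL
  structure(out, class = c("key_windows", "data.frame"), tau = tau,
            combine = combine,
            n_selected_features = sum(sig),
            n_env_features = nrow(profiles))
}

#' @export
print.key_windows <- function(x, ...) {
  cat(sprintf("key environmental windows (%s): %d period(s), %d factor(s)\n",
              x$trait[1], nrow(x), length(unique(x$factor))))
  cat(sprintf("  %d of %d window features selected (%.2f%%)\n",
              attr(x, "n_selected_features"), attr(x, "n_env_features"),
              100 * attr(x, "n_selected_features") /
                max(1, attr(x, "n_env_features"))))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Export SHAP dependence pairs for one feature
#'
#' Per-sample (feature value, attribution) pairs for dependence plotting,
#' e.g. attributions as a function of `tmax_111_115`.
#'
#' @param fit an [fit_rf_for_trait()] object.
#' @param feature_key a column of the fitted feature matrix.
#' @return data.frame with `sample`, `value`, `shap`.
#' @export
shap_dependence_export <- function(fit, feature_key) {
  stopifnot(inherits(fit, "rf_trait_fit"))
  if (!feature_key %in% colnames(fit$x)) {
    stop("unknown feature key '", feature_key, "'")
  }
  sh <- rf_shap_values(fit)
  data.frame(sample = rownames(fit$x), value = fit$x[, feature_key],
             shap = sh$shap[, feature_key], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Key windows as a feature subset
#'
#' Expands merged key-window periods back to the stride-1 window columns
#' they cover, for use as the selected feature set in
#' [compare_feature_sets()].
#'
#' @param key_windows a [select_key_windows()] result.
#' @param env_features the full environments x window-features matrix.
#' @return environments x selected-features matrix.
#' @export
key_window_features <- function(key_windows, env_features) {
  meta <- parse_window_key(colnames(env_features))
  keep <- rep(FALSE, ncol(env_features))
  for (i in seq_len(nrow(key_windows))) {
    keep <- keep | (meta$factor == key_windows$factor[i] &
                      meta$start >= key_windows$start_day[i] &
                      meta$end <= key_windows$end_day[i])
  }
  if (!any(keep)) stop("key windows cover no feature columns")
  env_features[, keep, drop = FALSE]
}
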