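# Leave-environments-out cross-validation harness with pooled-prediction
# metrics, and the before/after feature-selection comparison.

#' Random partition of environments into folds
#'
#' Environments are shuffled with the given seed and split into
#' `n_folds` equal groups (the default design holds out 2 of 14
#' environments per fold). Every environment is held out exactly once.
#'
#' @param env_ids environment labels; length must be divisible by
#'   `n_folds`.
#' @param n_folds number of folds (default 7).
#' @param seed integer seed.
#' @return list of class `env_folds`: `folds` (list of held-out id
#'   vectors), `seed`.
#' @export
make_env_folds <- function(env_ids, n_folds = 7, seed = 1) {
  env_ids <- as.character(env_ids)
  if (length(env_ids) %% n_folds != 0) {
    stop(length(env_ids), " environments cannot be split into ",
         n_folds, " equal folds; choose a divisor of the environment count")
  }
  per <- length(env_ids) / n_folds
  shuffled <- with_seed(seed, sample(env_ids))
  folds <- split(shuffled, rep(seq_len(n_folds), each = per))
  names(folds) <- NULL
  structure(list(folds = folds, seed = as.integer(seed)),
            class = "env_folds")
}

#' Pooled prediction metrics
#'
#' Metrics on predictions pooled over all held-out folds: Pearson
#' correlation (PCC), coefficient of determination
#' `R2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)` about the
#' pooled observed mean, and mean squared error.
#'
#' @param pred,obs numeric vectors of equal nonzero length.
#' @return list with `PCC`, `R2`, `MSE`, `n_pooled`; `PCC` is `NA` when
#'   the predictions are constant.
#' @export
pooled_metrics <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) > 0)
  if (sd(obs) == 0) {
    stop("constant observed values: PCC and R2 are undefined")
  }
  res <- obs - pred
  pcc <- if (sd(pred) == 0) NA_real_ else cor(pred, obs)
  list(PCC = pcc,
       R2 = 1 - sum(res^2) / sum((obs - mean(obs))^2),
       MSE = mean(res^2),
       n_pooled = length(obs))
}

# Internal: rep-averaged (or rep-level) samples for one trait.
harness_samples <- function(phenotypes, trait, rep_average = TRUE) {
  if (!trait %in% names(phenotypes)) stop("no trait column '", trait, "'")
  if (rep_average) {
    key <- interaction(phenotypes$genotype_id, phenotypes$env_id,
                       drop = TRUE)
    y <- tapply(phenotypes[[trait]], key, mean)
    ids <- do.call(rbind, strsplit(names(y), ".", fixed = TRUE))
    data.frame(genotype_id = ids[, 1], env_id = ids[, 2],
               y = as.vector(y), stringsAsFactors = FALSE)
  } else {
    data.frame(genotype_id = phenotypes$genotype_id,
               env_id = phenotypes$env_id, y = phenotypes[[trait]],
               stringsAsFactors = FALSE)
  }
}

#' Cross-environment evaluation of one learner
#'
#' For each fold, the learner trains on all samples from the training
#' environments and predicts every sample of the held-out environments;
#' held-out predictions are concatenated across folds and summarised with
#' [pooled_metrics()]. Samples are genotype-by-environment observations,
#' rep-averaged by default; features are environment window aggregates
#' plus (optionally) genotype principal components, so no held-out
#' phenotype information can reach the model.
#'
#' @param model a [model_spec()].
#' @param env_features environments x window-features matrix.
#' @param phenotypes replicated phenotype table.
#' @param trait trait column.
#' @param folds an [make_env_folds()] plan covering the phenotype
#'   environments.
#' @param pcs optional [genotype_pcs()] scores to append.
#' @param rep_average average replicates per genotype-environment sample
#'   (default TRUE).
#' @return list of class `cv_result`: metrics plus a `predictions`
#'   data.frame (`genotype_id`, `env_id`, `fold`, `obs`, `pred`).
#' @export
cross_env_evaluate <- function(model, env_features, phenotypes, trait,
                               folds, pcs = NULL, rep_average = TRUE) {
  stopifnot(inherits(model, "model_spec"), inherits(folds, "env_folds"))
  samples <- harness_samples(phenotypes, trait, rep_average)
  fold_envs <- unlist(folds$folds)
  missing_envs <- setdiff(unique(samples$env_id), fold_envs)
  if (length(missing_envs)) {
    stop("environments absent from the fold plan: ",
         paste(missing_envs, collapse = ", "))
  }
  x <- sample_feature_matrix(env_features, pcs, samples)
  out <- vector("list", length(folds$folds))
  for (k in seq_along(folds$folds)) {
    held <- folds$folds[[k]]
    test <- samples$env_id %in% held
    fitted <- model$learner$fit(x[!test, , drop = FALSE],
                                samples$y[!test], model)
    pred <- model$learner$predict(fitted, x[test, , drop = FALSE])
    out[[k]] <- data.frame(genotype_id = samples$genotype_id[test],
                           env_id = samples$env_id[test], fold = k,
                           obs = samples$y[test], pred = pred,
                           stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, out)
  m <- pooled_metrics(pooled$pred, pooled$obs)
  structure(c(list(model = model$name, trait = trait), m,
              list(predictions = pooled)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-environment CV: %s on %s\n", x$model, x$trait))
  cat(sprintf("  PCC %.3f  R2 %.3f  MSE %.4f  (n = %d pooled predictions)\n",
              x$PCC, x$R2, x$MSE, x$n_pooled))
  invisible(x)
}

#' Compare full vs selected feature sets across learners
#'
#' Runs [cross_env_evaluate()] for every learner on the full window
#' feature matrix and on a selected subset (for example the key windows
#' chosen by [select_key_windows()]), and reports both metric sets, their
#' deltas, and the selection ratio (selected / full window columns).
#'
#' @param models list of [model_spec()] objects.
#' @param full,selected environments x window-features matrices; the
#'   selected columns must be a subset of the full ones and non-empty.
#' @inheritParams cross_env_evaluate
#' @return data.frame of class `feature_comparison`: one row per learner
#'   with `PCC_full`, `PCC_selected`, `delta_PCC` (same for R2, MSE) and
#'   `selection_ratio`.
#' @export
compare_feature_sets <- function(models, full, selected, phenotypes,
                                 trait, folds, pcs = NULL,
                                 rep_average = TRUE) {
  if (is.null(colnames(selected)) || ncol(selected) == 0) {
    stop("empty selected feature set")
  }
  if (!all(colnames(selected) %in% colnames(full))) {
    stop("selected features must be a subset of the full feature set")
  }
  if (inherits(models, "model_spec")) models <- list(models)
  rows <- lapply(models, function(m) {
    a <- cross_env_evaluate(m, full, phenotypes, trait, folds, pcs,
                            rep_average)
    b <- cross_env_evaluate(m, selected, phenotypes, trait, folds, pcs,
                            rep_average)
    data.frame(model = m$name, trait = trait,
               PCC_full = a$PCC, PCC_selected = b$PCC,
               delta_PCC = b$PCC - a$PCC,
               R2_full = a$R2, R2_selected = b$R2,
               delta_R2 = b$R2 - a$R2,
               MSE_full = a$MSE, MSE_selected = b$MSE,
               delta_MSE = b$MSE - a$MSE,
               selection_ratio = ncol(selected) / ncol(full),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("feature_comparison", "data.frame"))
}

#' @export
print.feature_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("feature-set comparison (%s): %d learner(s), selection ratio %.2f%%\n",
              x$trait[1], nrow(x), 100 * x$selection_ratio[1]))
  print.data.frame(x[, c("model", "PCC_full", "PCC_selected", "R2_full",
                         "R2_selected", "delta_R2")],
                   digits = digits, row.names = FALSE)
  invisible(x)
}
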