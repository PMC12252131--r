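# Learner registry for the cross-environment harness. Each learner is a
# fit/predict pair behind a common contract, so the harness owns no model
# code; learners whose backing package is not installed are simply absent
# from the registry.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evidence-maximisation Bayesian ridge regression (MacKay/Tipping update
# rules): gaussian prior precision `lambda` on the coefficients and noise
# precision `alpha`, both estimated by maximising the marginal likelihood.
bayesian_ridge_fit <- function(x, y, max_iter = 300, tol = 1e-3,
                               prior = 1e-6) {
  x <- as.matrix(x)
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2, xm); yc <- y - ym
  n <- nrow(xc); p <- ncol(xc)
  s <- svd(xc, nu = 0)
  ev <- s$d^2                       # eigenvalues of X'X
  Vty <- crossprod(s$v, crossprod(xc, yc))  # V' X' y  (p x 1, first cols)
  alpha <- 1 / max(var(yc), 1e-12)
  lambda <- 1
  coef_svd <- function(alpha, lambda) {
    as.vector(Vty * (alpha / (alpha * ev + lambda)))
  }
  for (it in seq_len(max_iter)) {
    w <- coef_svd(alpha, lambda)
    gamma <- sum(alpha * ev / (alpha * ev + lambda))
    coefs <- s$v %*% w
    rss <- sum((yc - xc %*% coefs)^2)
    lambda_new <- (gamma + 2 * prior) / (sum(coefs^2) + 2 * prior)
    alpha_new <- (n - gamma + 2 * prior) / (rss + 2 * prior)
    if (abs(lambda_new - lambda) < tol && abs(alpha_new - alpha) < tol) {
      lambda <- lambda_new; alpha <- alpha_new
      break
    }
    lambda <- lambda_new; alpha <- alpha_new
  }
  coefs <- as.vector(s$v %*% coef_svd(alpha, lambda))
  list(coef = coefs, intercept = ym - sum(xm * coefs),
       alpha = alpha, lambda = lambda)
}

learner_registry <- function() {
  reg <- list(
    Mean = list(
      fit = function(x, y, spec) mean(y),
      predict = function(m, x) rep(m, nrow(x))
    ),
    RandomForest = list(
      fit = function(x, y, spec) {
        hp <- spec$hyperparameters
        ranger::ranger(
          x = x, y = y,
          num.trees = hp$n_estimators %||% 500,
          mtry = min(hp$mtry %||% max(1L, floor(ncol(x) / 3)), ncol(x)),
          min.node.size = hp$min_node_size %||% 5,
          splitrule = "variance",        # squared-error criterion
          seed = spec$seed, num.threads = 1
        )
      },
      predict = function(m, x) {
        predict(m, data = x, num.threads = 1)$predictions
      }
    ),
    BayesianRidge = list(
      fit = function(x, y, spec) bayesian_ridge_fit(x, y),
      predict = function(m, x) {
        as.vector(as.matrix(x) %*% m$coef) + m$intercept
      }
    )
  )
  if (requireNamespace("xgboost", quietly = TRUE)) {
    reg$XGBoost <- list(
      fit = function(x, y, spec) {
        hp <- spec$hyperparameters
        xgboost::xgboost(
          data = as.matrix(x), label = y,
          nrounds = hp$nrounds %||% 100,
          params = list(objective = "reg:squarederror",
                        eta = hp$eta %||% 0.3,
                        max_depth = hp$max_depth %||% 6,
                        nthread = 1, seed = spec$seed),
          verbose = 0
        )
      },
      predict = function(m, x) predict(m, as.matrix(x))
    )
  }
  if (requireNamespace("lightgbm", quietly = TRUE)) {
    reg$LightGBM <- list(
      fit = function(x, y, spec) {
        hp <- spec$hyperparameters
        dtrain <- lightgbm::lgb.Dataset(as.matrix(x), label = y)
        lightgbm::lgb.train(
          params = list(objective = "regression",
                        num_threads = 1, seed = spec$seed,
                        verbosity = -1),
          data = dtrain, nrounds = hp$nrounds %||% 100
        )
      },
      predict = function(m, x) predict(m, as.matrix(x))
    )
  }
  if (requireNamespace("e1071", quietly = TRUE)) {
    reg$SVR <- list(
      fit = function(x, y, spec) {
        e1071::svm(x = as.matrix(x), y = y, type = "eps-regression",
                   kernel = "radial")
      },
      predict = function(m, x) {
        as.vector(predict(m, as.matrix(x)))
      }
    )
  }
  if (requireNamespace("glmnet", quietly = TRUE)) {
    reg$ElasticNet <- list(
      fit = function(x, y, spec) {
        set.seed(spec$seed)
        glmnet::cv.glmnet(as.matrix(x), y,
                          alpha = spec$hyperparameters$alpha %||% 0.5,
                          nfolds = 5)
      },
      predict = function(m, x) {
        as.vector(predict(m, as.matrix(x), s = "lambda.min"))
      }
    )
  }
  reg
}

#' Available learners
#'
#' Names accepted by [model_spec()]. `RandomForest`, `BayesianRidge` and
#' the `Mean` baseline are always available; `XGBoost`, `LightGBM`, `SVR`
#' and `ElasticNet` appear when their backing package is installed.
#'
#' @return character vector of learner names.
#' @export
available_models <- function() names(learner_registry())

#' Specify a learner for the cross-environment harness
#'
#' @param name a learner from [available_models()].
#' @param hyperparameters named list overriding the learner's defaults.
#'   The random forest defaults to 500 trees with the squared-error
#'   (variance) split criterion and `mtry = floor(p/3)`.
#' @param seed integer seed used by stochastic learners.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(name, hyperparameters = list(), seed = 1) {
  reg <- learner_registry()
  if (!name %in% names(reg)) {
    stop("unknown or unavailable learner '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  structure(list(name = name, hyperparameters = hyperparameters,
                 seed = as.integer(seed), learner = reg[[name]]),
            class = "model_spec")
}
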