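# Exhaustive sliding-window correlation scan: every (factor, start,
# duration) window's environment-mean value against per-environment
# population phenotype means.

#' Pearson correlation with a p-value
#'
#' Sample Pearson r with a two-sided p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' `r = +/-1` returns the numeric floor rather than a literal zero p. A
#' permutation p-value (random permutations of `y`) is available for
#' verification.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both non-constant.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @return list with `r` and `p`.
#' @export
pearson_with_p <- function(x, y, method = c("t", "permutation"),
                           n_perm = 10000) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: constant input vector")
  }
  r <- cor(x, y)
  if (method == "permutation") {
    perm <- vapply(seq_len(n_perm), function(i) cor(x, sample(y)), 0)
    p <- (sum(abs(perm) >= abs(r)) + 1) / (n_perm + 1)
  } else {
    p <- r_to_p(r, n)
  }
  list(r = r, p = p)
}

# Vectorized two-sided p from the t transform; p floored at the smallest
# positive double so -log10(p) stays finite at |r| = 1.
r_to_p <- function(r, n) {
  r2 <- pmin(r^2, 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  pmax(2 * pt(t, n - 2, lower.tail = FALSE), .Machine$double.xmin)
}

#' Sliding-window correlation scan
#'
#' For every factor and every window (start day in `start_range`, duration
#' in `duration_range`, end day bounded only by the season length), the
#' per-environment window mean is correlated across environments with the
#' per-environment population phenotype mean. Defaults follow the scan
#' convention for a 150-day season: starts 1-145 and durations 5-150,
#' 10,730 windows per factor.
#'
#' @param indices output of [derive_daily_indices()] for all environments.
#' @param env_phenotype_means named numeric vector, one phenotype mean per
#'   environment (mean over genotypes and replicates).
#' @param trait label carried into the result.
#' @param start_range,duration_range inclusive `(min, max)` pairs.
#' @param factors factors to scan (default all 13).
#' @return data.frame of class `window_scan` with columns `factor`,
#'   `start`, `duration`, `end`, `r`, `p`, `neg_log_p`.
#' @export
scan_windows <- function(indices, env_phenotype_means, trait = "trait",
                         start_range = c(1, 145),
                         duration_range = c(5, 150),
                         factors = SCAN_FACTORS) {
  mats <- factor_matrices(indices, factors)
  env_ids <- rownames(mats[[1]])
  n_days <- ncol(mats[[1]])
  if (is.null(names(env_phenotype_means))) {
    stop("env_phenotype_means must be named by environment id")
  }
  extra <- setdiff(env_ids, names(env_phenotype_means))
  orphan <- setdiff(names(env_phenotype_means), env_ids)
  if (length(extra) || length(orphan)) {
    stop("environment mismatch between weather and phenotypes; ",
         "weather-only: [", paste(extra, collapse = ", "),
         "], phenotype-only: [", paste(orphan, collapse = ", "), "]")
  }
  y <- env_phenotype_means[env_ids]
  n <- length(y)
  if (n < 3) stop("need at least 3 environments")

  grid <- expand.grid(start = seq.int(start_range[1], start_range[2]),
                      duration = seq.int(duration_range[1],
                                         duration_range[2]),
                      KEEP.OUT.ATTRS = FALSE)
  grid$end <- grid$start + grid$duration - 1L
  grid <- grid[grid$end <= n_days, c("start", "duration", "end")]

  yc <- y - mean(y)
  syy <- sum(yc^2)
  res <- lapply(factors, function(f) {
    cs <- cbind(0, t(apply(mats[[f]], 1, cumsum)))          # envs x (days+1)
    W <- (t(cs)[grid$end + 1L, , drop = FALSE] -
            t(cs)[grid$start, , drop = FALSE]) / grid$duration
    Wc <- W - rowMeans(W)
    sxx <- rowSums(Wc^2)
    r <- as.vector(Wc %*% yc) / sqrt(sxx * syy)
    r[sxx == 0] <- NA                                      # constant window
    cbind(grid, data.frame(factor = f, r = r))
  })
  out <- do.call(rbind, res)
  out$p <- r_to_p(out$r, n)
  out$neg_log_p <- -log10(out$p)
  out <- out[, c("factor", "start", "duration", "end", "r", "p",
                 "neg_log_p")]
  rownames(out) <- NULL
  structure(out, class = c("window_scan", "data.frame"), trait = trait,
            n_envs = n)
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf("window scan: %s, %d environments, %d factors, %d windows/factor\n",
              attr(x, "trait"), attr(x, "n_envs"),
              length(unique(x$factor)), sum(x$factor == x$factor[1])))
  best <- top_windows(x, per_factor = 1)
  cat("strongest window per factor (top 5 overall):\n")
  print.data.frame(head(best, 5), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Rank scan windows
#'
#' Within each factor, windows are ranked by absolute correlation; ties are
#' broken by larger `-log10(p)`, then earlier start, then shorter duration.
#' The returned table holds the top `per_factor` windows for every factor,
#' globally ordered by absolute correlation.
#'
#' @param result a [scan_windows()] result.
#' @param per_factor windows to keep per factor (default 1).
#' @return data.frame ordered by decreasing `|r|`.
#' @export
top_windows <- function(result, per_factor = 1) {
  stopifnot(nrow(result) > 0)
  x <- result[!is.na(result$r), , drop = FALSE]
  ord <- order(x$factor, -abs(x$r), -x$neg_log_p, x$start, x$duration)
  x <- x[ord, ]
  keep <- unlist(lapply(split(seq_len(nrow(x)), x$factor),
                        head, per_factor), use.names = FALSE)
  x <- x[sort(keep), ]
  x <- x[order(-abs(x$r), -x$neg_log_p, x$start, x$duration), ]
  rownames(x) <- NULL
  class(x) <- "data.frame"
  x
}
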