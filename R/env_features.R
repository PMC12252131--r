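# Derived environmental indices and window-aggregated feature matrices.

#' Derive the five daily indices from base weather
#'
#' Adds, per day: growing degree days `GDD = max(0, (tmax + tmin)/2 - 10)`
#' (base temperature 10 deg C, clamped at zero); diurnal temperature range
#' `DTR = tmax - tmin`; precipitation per diurnal range `PRDTR = pcp/DTR`
#' (0 when `DTR <= 0`); photothermal quotient `PTQ = radn/GDD` (0 when
#' `GDD <= 0`); and photothermal time `PTT = GDD * dh` (sunshine hours).
#' Together with the eight base variables these are the 13 factors used by
#' the window scan and the random-forest feature grid.
#'
#' @param weather daily weather table (see [generate_weather()] for the
#'   schema); invariants are validated and violations reported with the
#'   offending environment and day.
#' @return the input data.frame with columns `GDD`, `DTR`, `PRDTR`, `PTQ`,
#'   `PTT` appended.
#' @export
derive_daily_indices <- function(weather) {
  validate_weather(weather)
  gdd <- pmax((weather$tmax + weather$tmin) / 2 - GDD_TBASE, 0)
  dtr <- weather$tmax - weather$tmin
  weather$GDD <- gdd
  weather$DTR <- dtr
  weather$PRDTR <- ifelse(dtr > 0, weather$pcp / dtr, 0)
  weather$PTQ <- ifelse(gdd > 0, weather$radn / gdd, 0)
  weather$PTT <- gdd * weather$dh
  weather
}

#' Mean of a daily series over a closed day window
#'
#' Windows are closed intervals on the 1-based day-after-planting axis; the
#' window statistic is the arithmetic mean, so windows of different lengths
#' are comparable (cumulative totals are `mean * length`).
#'
#' @param series numeric vector of daily values, day 1 first.
#' @param start,end first and last day, `1 <= start <= end <= length(series)`.
#' @return scalar mean.
#' @export
aggregate_window <- function(series, start, end) {
  if (start < 1 || end > length(series) || start > end) {
    stop("window [", start, ", ", end, "] outside day range 1..",
         length(series))
  }
  mean(series[start:end])
}

# Internal: long weather+indices -> list of env x day matrices, one per
# factor. Checks all environments share the same day range.
factor_matrices <- function(indices, factors = SCAN_FACTORS) {
  env_ids <- unique(indices$env_id)
  days <- sort(unique(indices$day))
  n_days <- length(days)
  counts <- table(indices$env_id)
  if (length(unique(counts)) != 1 || !identical(days, seq_len(n_days))) {
    stop("environments must share an identical 1..n_days day range")
  }
  ord <- order(match(indices$env_id, env_ids), indices$day)
  x <- indices[ord, ]
  lapply(setNames(factors, factors), function(f) {
    matrix(x[[f]], nrow = length(env_ids), ncol = n_days, byrow = TRUE,
           dimnames = list(env_ids, NULL))
  })
}

#' Build the dense window feature matrix
#'
#' One column per (factor, start) pair with `end = start + window_size - 1`,
#' named `"<factor>_<start>_<end>"`; one row per environment, each entry the
#' window mean of that factor in that environment. With a 150-day season,
#' 5-day windows and stride 1 this yields 146 windows for each of the 13
#' factors (1898 columns), the grid the random-forest stage trains on.
#'
#' @param indices output of [derive_daily_indices()] for all environments.
#' @param window_size window length in days (default 5).
#' @param stride step between window starts in days (default 1).
#' @param factors factors to include (default all 13).
#' @return numeric matrix, environments x window features.
#' @export
build_window_features <- function(indices, window_size = 5, stride = 1,
                                  factors = SCAN_FACTORS) {
  stopifnot(window_size >= 1, stride >= 1)
  mats <- factor_matrices(indices, factors)
  n_days <- ncol(mats[[1]])
  starts <- seq.int(1L, n_days - window_size + 1L, by = stride)
  cols <- lapply(factors, function(f) {
    m <- mats[[f]]
    cs <- cbind(0, t(apply(m, 1, cumsum)))
    out <- (cs[, starts + window_size, drop = FALSE] -
              cs[, starts, drop = FALSE]) / window_size
    colnames(out) <- window_key(f, starts, starts + window_size - 1L)
    out
  })
  do.call(cbind, cols)
}

#' Principal components of a genotype matrix
#'
#' Column-centered (unscaled) PCA of the marker matrix; retains the
#' smallest number of components whose cumulative explained fraction of the
#' genotypic variance exceeds `cum_threshold` (default 0.90). Loadings
#' follow a deterministic sign convention: each component is flipped so its
#' largest-magnitude loading is positive.
#'
#' @param genotypes numeric matrix, lines x markers.
#' @param cum_threshold cumulative explained-variance fraction to exceed.
#' @return list of class `genotype_pcs`: `scores` (lines x k, columns
#'   `PC1..PCk`), `explained_fraction` (all components), `k`.
#' @export
genotype_pcs <- function(genotypes, cum_threshold = 0.90) {
  stopifnot(nrow(genotypes) >= 2)
  x <- scale(genotypes, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) {
    stop("degenerate input: all markers are constant across lines")
  }
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) > cum_threshold)[1]
  if (is.na(k)) k <- length(frac)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(genotypes)
  structure(list(scores = scores, explained_fraction = frac, k = k),
            class = "genotype_pcs")
}

#' @export
print.genotype_pcs <- function(x, ...) {
  cat(sprintf("genotype PCs: %d components (%.1f%% of variance)\n",
              x$k, 100 * sum(x$explained_fraction[seq_len(x$k)])))
  invisible(x)
}

#' Join environment window features with genotype PCs per sample
#'
#' Expands the environment-level window features to genotype-by-environment
#' samples and appends genotype PC scores, the design used for
#' cross-environment prediction: window columns depend only on the
#' environment, PC columns only on the genotype.
#'
#' @param env_features environments x window-features matrix from
#'   [build_window_features()].
#' @param pcs optional [genotype_pcs()] object.
#' @param samples data.frame with columns `genotype_id`, `env_id` (one row
#'   per sample).
#' @return numeric matrix with one row per sample.
#' @export
sample_feature_matrix <- function(env_features, pcs = NULL, samples) {
  stopifnot(all(c("genotype_id", "env_id") %in% names(samples)))
  ei <- match(samples$env_id, rownames(env_features))
  if (anyNA(ei)) {
    stop("environments missing from features: ",
         paste(unique(samples$env_id[is.na(ei)]), collapse = ", "))
  }
  out <- env_features[ei, , drop = FALSE]
  if (!is.null(pcs)) {
    gi <- match(samples$genotype_id, rownames(pcs$scores))
    if (anyNA(gi)) {
      stop("genotypes missing from PC scores: ",
           paste(unique(samples$genotype_id[is.na(gi)]), collapse = ", "))
    }
    out <- cbind(out, pcs$scores[gi, , drop = FALSE])
  }
  rownames(out) <- paste(samples$genotype_id, samples$env_id, sep = ":")
  out
}
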