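#' @useDynLib gxewindows, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats anova coef cor lm lm.fit median pf predict prcomp pt
#'   rbinom rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv
NULL

# The eight base weather variables recorded daily at each site.
BASE_WEATHER_VARS <- c("tmax", "tmin", "tmean", "pcp", "dh",
                       "rhmean", "radn", "wsmean")

# The five indices derived from them (base temperature 10 degrees C).
DERIVED_INDEX_VARS <- c("GDD", "DTR", "PRDTR", "PTQ", "PTT")

# The 13 factors eligible for window scanning and key-window selection.
SCAN_FACTORS <- c(BASE_WEATHER_VARS, DERIVED_INDEX_VARS)

# Trait columns understood by the simulator and the pipeline:
# boll weight (g), lint percentage (%), seed index (g), fiber length (mm),
# fiber strength (cN/tex), fiber micronaire (unitless).
TRAIT_NAMES <- c("BW", "LP", "SI", "FL", "FS", "FM")

GDD_TBASE <- 10

#' Build a window feature key
#'
#' Feature columns are named `"<factor>_<start>_<end>"`, e.g. `"tmax_111_115"`
#' for the mean daily maximum temperature over days 111 to 115 after planting.
#'
#' @param factor one of the 13 scan factors.
#' @param start,end first and last day after planting (1-based, inclusive).
#' @return character key.
#' @export
window_key <- function(factor, start, end) {
  sprintf("%s_%d_%d", factor, as.integer(start), as.integer(end))
}

#' Parse window feature keys
#'
#' Inverse of [window_key()]. Keys that do not parse to a known factor and a
#' valid day range raise an error.
#'
#' @param keys character vector of `"<factor>_<start>_<end>"` keys.
#' @return data.frame with columns `factor`, `start`, `end`.
#' @export
parse_window_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.*)_([0-9]+)_([0-9]+)$", keys))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed window key(s): ", paste(keys[bad], collapse = ", "))
  }
  out <- data.frame(
    factor = vapply(m, `[`, "", 2L),
    start  = as.integer(vapply(m, `[`, "", 3L)),
    end    = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  unknown <- !out$factor %in% SCAN_FACTORS
  if (any(unknown)) {
    stop("unknown factor in key(s): ",
         paste(unique(out$factor[unknown]), collapse = ", "))
  }
  if (any(out$start < 1L | out$start > out$end)) {
    stop("window keys must satisfy 1 <= start <= end")
  }
  out
}

# Internal: check a daily weather table and fail with the offending
# environment and day named.
validate_weather <- function(weather) {
  need <- c("env_id", "day", BASE_WEATHER_VARS)
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop("weather table lacks column(s): ",
                         paste(miss, collapse = ", "))
  for (env in unique(weather$env_id)) {
    w <- weather[weather$env_id == env, ]
    w <- w[order(w$day), ]
    if (!identical(as.integer(w$day), seq_len(nrow(w)))) {
      stop("environment ", env, ": days must run 1..n with no gaps")
    }
    bad <- which(w$tmin > w$tmax)
    if (length(bad)) stop("environment ", env, ", day ", w$day[bad[1]],
                          ": tmin exceeds tmax")
    bad <- which(w$rhmean < 0 | w$rhmean > 100)
    if (length(bad)) stop("environment ", env, ", day ", w$day[bad[1]],
                          ": rhmean outside [0, 100]")
    for (v in c("pcp", "dh", "radn", "wsmean")) {
      bad <- which(w[[v]] < 0)
      if (length(bad)) stop("environment ", env, ", day ", w$day[bad[1]],
                            ": negative ", v)
    }
  }
  invisible(weather)
}
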