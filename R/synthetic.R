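# Synthetic multi-environment trial generator.
#
# Emulates a 150-day cotton growing season across the three climate
# archetypes of China's main cotton regions (arid Northwest, semi-arid
# Yellow River, humid Yangtze River), a RIL-like inbred panel, and
# phenotypes driven by planted factor-specific time windows, so every
# downstream stage can be tested against known ground truth.

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Stationary AR(1) noise with marginal standard deviation `sd`.
ar1_noise <- function(n, rho, sd) {
  e <- rnorm(n, sd = sd * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd)
  for (i in seq_len(n)[-1]) x[i] <- rho * x[i - 1] + e[i]
  x
}

#' Climate archetype parameters
#'
#' Parameter sets for the three climate archetypes used by
#' [generate_weather()]: `arid` (high radiation, ~50% humidity, daily
#' precipitation 0.4–1.2 mm), `semi_arid` (2.0–5.1 mm, intermediate), and
#' `humid` (4.8–7.2 mm, moderate radiation, ~75% humidity).
#'
#' @param name one of `"arid"`, `"semi_arid"`, `"humid"`.
#' @return list of class `climate_archetype` with fields `name`,
#'   `pcp_mean_range` (mm/day), `radn_peak` (MJ/m2/day), `rh_level` (%),
#'   `temp_baseline` and `temp_amplitude` (deg C), `dtr_base` (deg C),
#'   `dh_base` (h/day), `wind_base` (m/s), `spring_gust` (m/s).
#' @export
climate_archetype <- function(name = c("arid", "semi_arid", "humid")) {
  name <- match.arg(name)
  pars <- switch(name,
    arid = list(pcp_mean_range = c(0.4, 1.2), radn_peak = 28,
                rh_level = 50, temp_baseline = 17, temp_amplitude = 6.5,
                dtr_base = 14, dh_base = 12, wind_base = 1.5,
                spring_gust = 4),
    semi_arid = list(pcp_mean_range = c(2.0, 5.1), radn_peak = 23,
                     rh_level = 62, temp_baseline = 18.5,
                     temp_amplitude = 7, dtr_base = 11, dh_base = 10,
                     wind_base = 2.4, spring_gust = 0),
    humid = list(pcp_mean_range = c(4.8, 7.2), radn_peak = 18,
                 rh_level = 75, temp_baseline = 20, temp_amplitude = 7,
                 dtr_base = 8.5, dh_base = 7.5, wind_base = 2.3,
                 spring_gust = 0)
  )
  structure(c(list(name = name), pars), class = "climate_archetype")
}

#' Generate one environment's daily weather
#'
#' Daily series are a smooth seasonal sinusoid plus stationary AR(1)
#' day-to-day variation, truncated at physical bounds (precipitation,
#' radiation, sunshine and wind nonnegative; relative humidity in
#' \[0, 100\]; `tmin <= tmean <= tmax` by construction). The environment's
#' mean precipitation level is drawn uniformly from the archetype's range.
#'
#' @param archetype a [climate_archetype()] object or archetype name.
#' @param n_days number of days after planting (default 150).
#' @param seed integer seed; identical seeds give identical tables.
#' @param env_id label for the `env_id` column.
#' @return data.frame with columns `env_id`, `day`, and the eight base
#'   weather variables `tmax, tmin, tmean, pcp, dh, rhmean, radn, wsmean`.
#' @export
generate_weather <- function(archetype, n_days = 150, seed = 1,
                             env_id = NULL) {
  if (is.character(archetype)) archetype <- climate_archetype(archetype)
  if (!inherits(archetype, "climate_archetype")) {
    stop("archetype must be a climate_archetype or its name")
  }
  stopifnot(n_days >= 1)
  if (is.null(env_id)) env_id <- paste0(archetype$name, "_", seed)
  with_seed(seed, {
    d <- seq_len(n_days)
    season <- sin(pi * d / (n_days + 1))

    tmean <- archetype$temp_baseline + archetype$temp_amplitude * season +
      ar1_noise(n_days, 0.7, 1.6)
    dtr <- pmax(archetype$dtr_base + ar1_noise(n_days, 0.5, 2), 0.5)
    tmax <- tmean + dtr / 2
    tmin <- tmean - dtr / 2

    pcp_level <- runif(1, archetype$pcp_mean_range[1],
                       archetype$pcp_mean_range[2])
    z <- ar1_noise(n_days, 0.4, 0.3)
    sig2 <- 0.3^2                        # marginal variance of log-noise
    pcp <- pcp_level * exp(z - sig2 / 2) # unit-mean lognormal modulation

    radn <- pmax(archetype$radn_peak * (0.5 + 0.5 * season) +
                   ar1_noise(n_days, 0.5, 1.8), 0)
    dh <- pmin(pmax(archetype$dh_base * (0.6 + 0.4 * season) +
                      ar1_noise(n_days, 0.5, 1.5), 0), 24)
    rhmean <- pmin(pmax(archetype$rh_level + ar1_noise(n_days, 0.6, 6),
                        0), 100)
    gust <- archetype$spring_gust * exp(-((d - 35) / 12)^2)
    wsmean <- pmax(archetype$wind_base + gust +
                     ar1_noise(n_days, 0.4, 0.5), 0)

    data.frame(env_id = env_id, day = d, tmax = tmax, tmin = tmin,
               tmean = tmean, pcp = pcp, dh = dh, rhmean = rhmean,
               radn = radn, wsmean = wsmean, stringsAsFactors = FALSE)
  })
}

#' Generate a biallelic inbred genotype matrix
#'
#' Homozygous RIL-like coding in \{0, 1\} (no heterozygotes). Markers come in
#' blocks sharing a latent haplotype; within a block each marker copies the
#' latent allele and flips with probability `flip_prob`, giving the
#' block-correlated structure that makes a low-dimensional principal
#' component representation meaningful. `flip_prob = 0` yields perfectly
#' correlated blocks (matrix rank equal to the number of blocks, at most).
#'
#' @param n_lines,n_markers at least 2 each.
#' @param seed integer seed.
#' @param n_blocks number of marker blocks (default ~20 markers per block).
#' @param flip_prob per-marker probability of flipping the latent allele.
#' @return integer matrix `n_lines x n_markers`, rownames `L001...`,
#'   colnames `m1...`.
#' @export
generate_genotypes <- function(n_lines, n_markers, seed = 1,
                               n_blocks = max(1L, n_markers %/% 20L),
                               flip_prob = 0.1) {
  stopifnot(n_lines >= 2, n_markers >= 2, n_blocks >= 1)
  with_seed(seed, {
    block_of <- sort(rep_len(seq_len(n_blocks), n_markers))
    latent <- matrix(rbinom(n_lines * n_blocks, 1, 0.5), n_lines, n_blocks)
    geno <- latent[, block_of, drop = FALSE]
    if (flip_prob > 0) {
      flips <- matrix(rbinom(n_lines * n_markers, 1, flip_prob),
                      n_lines, n_markers)
      geno <- abs(geno - flips)
    }
    dimnames(geno) <- list(sprintf("L%03d", seq_len(n_lines)),
                           paste0("m", seq_len(n_markers)))
    storage.mode(geno) <- "integer"
    geno
  })
}

#' Ground-truth record for the phenotype simulator
#'
#' Holds everything [generate_phenotypes()] needs and everything a recovery
#' test wants to check afterwards: the planted critical windows (trait,
#' factor, day range, effect per unit of window mean), per-genotype main
#' effects `g_i` and Finlay-Wilkinson slope deviations `b_i` (both drawn
#' normal and exactly centered so that the mean slope `1 + b_i` is exactly
#' 1), the replicate-effect and residual noise scales, and the seed.
#'
#' The default planted truth drives boll weight (BW) with a positive
#' radiation window at days 104-110 and a negative precipitation window at
#' days 50-56.
#'
#' @param n_lines number of genotypes.
#' @param planted_windows data.frame with columns `trait`, `factor`,
#'   `start`, `end`, `effect` (trait units per unit of the factor's
#'   window mean).
#' @param mu named grand means per trait (trait units).
#' @param g_sd,slope_sd standard deviations of genotype effects and slope
#'   deviations `b_i`.
#' @param rep_effect_sd,noise_sd replicate effect and residual standard
#'   deviations (trait units).
#' @param seed integer seed.
#' @return list of class `gxe_truth`.
#' @export
truth_record <- function(n_lines,
                         planted_windows = default_planted_windows(),
                         mu = c(BW = 5.8), g_sd = 0.35, slope_sd = 0.2,
                         rep_effect_sd = 0.05, noise_sd = 0.4, seed = 1) {
  stopifnot(n_lines >= 2, noise_sd >= 0, rep_effect_sd >= 0)
  if (nrow(planted_windows)) {
    stopifnot(all(planted_windows$start >= 1),
              all(planted_windows$start <= planted_windows$end),
              all(is.finite(planted_windows$effect)))
    bad <- setdiff(planted_windows$factor, SCAN_FACTORS)
    if (length(bad)) {
      stop("planted factor(s) not among the 13 scan factors: ",
           paste(bad, collapse = ", "))
    }
  }
  with_seed(seed, {
    g <- rnorm(n_lines, sd = g_sd)
    b <- if (slope_sd > 0) rnorm(n_lines, sd = slope_sd) else numeric(n_lines)
    g <- g - mean(g)   # centered so mu is the grand mean
    b <- b - mean(b)   # centered so the mean FW slope is exactly 1
    names(g) <- names(b) <- sprintf("L%03d", seq_len(n_lines))
    structure(list(planted_windows = planted_windows, mu = mu,
                   genotype_effects = g, genotype_slopes = b,
                   rep_effect_sd = rep_effect_sd, noise_sd = noise_sd,
                   seed = as.integer(seed)),
              class = "gxe_truth")
  })
}

#' @rdname truth_record
#' @export
default_planted_windows <- function() {
  data.frame(trait = c("BW", "BW"), factor = c("radn", "pcp"),
             start = c(104L, 50L), end = c(110L, 56L),
             effect = c(0.10, -0.15), stringsAsFactors = FALSE)
}

#' Simulate replicated phenotypes from weather and planted truth
#'
#' The phenotype model is
#' `y_ijk = mu + g_i + (1 + b_i) * E_j + rep_jk + eps_ijk`, where the
#' environment effect `E_j` is the sum over planted windows of
#' `effect * (window mean of the factor in environment j)`, centered across
#' environments so that Finlay-Wilkinson slopes are identifiable; `rep_jk`
#' is drawn once per environment-by-replicate; `eps` is i.i.d. normal.
#' Traits named in `mu` but without planted windows get `E_j = 0`.
#'
#' @param weather daily weather table for all environments (rows of
#'   [generate_weather()] stacked); all environments must share the day
#'   range and cover every planted window.
#' @param truth a [truth_record()].
#' @param n_reps replicates per environment (default 3).
#' @return list with `phenotypes` (data.frame `genotype_id`, `env_id`,
#'   `rep`, one column per trait), `env_effects` (trait x environment
#'   matrix of the planted `E_j`), and `truth` (the input record).
#' @export
generate_phenotypes <- function(weather, truth, n_reps = 3) {
  validate_weather(weather)
  stopifnot(inherits(truth, "gxe_truth"), n_reps >= 1)
  env_ids <- unique(weather$env_id)
  n_days <- max(weather$day)
  pw <- truth$planted_windows
  if (nrow(pw) && any(pw$end > n_days)) {
    stop("planted window extends past day ", n_days)
  }
  idx <- derive_daily_indices(weather)
  traits <- names(truth$mu)
  E <- matrix(0, length(traits), length(env_ids),
              dimnames = list(traits, env_ids))
  if (nrow(pw)) {
    for (i in seq_len(nrow(pw))) {
      if (!pw$trait[i] %in% traits) {
        stop("planted window trait ", pw$trait[i], " has no mu entry")
      }
      wm <- vapply(env_ids, function(e) {
        aggregate_window(idx[[pw$factor[i]]][idx$env_id == e],
                         pw$start[i], pw$end[i])
      }, 0)
      E[pw$trait[i], ] <- E[pw$trait[i], ] + pw$effect[i] * (wm - mean(wm))
    }
  }
  g <- truth$genotype_effects
  b <- truth$genotype_slopes
  n_lines <- length(g)
  with_seed(truth$seed + 1L, {
    grid <- expand.grid(genotype_id = names(g), env_id = env_ids,
                        rep = seq_len(n_reps), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    rep_eff <- matrix(rnorm(length(env_ids) * n_reps,
                            sd = truth$rep_effect_sd),
                      length(env_ids), n_reps,
                      dimnames = list(env_ids, NULL))
    gi <- match(grid$genotype_id, names(g))
    ei <- match(grid$env_id, env_ids)
    for (tr in traits) {
      y <- truth$mu[[tr]] + g[gi] + (1 + b[gi]) * E[tr, ei] +
        rep_eff[cbind(ei, grid$rep)]
      if (truth$noise_sd > 0) y <- y + rnorm(nrow(grid), sd = truth$noise_sd)
      grid[[tr]] <- y
    }
    list(phenotypes = grid, env_effects = E, truth = truth)
  })
}

#' Simulate a complete multi-environment trial
#'
#' One call producing weather for a mix of climate archetypes, a
#' block-correlated genotype matrix, and replicated phenotypes with known
#' planted truth. Defaults mirror the study conditions the package is built
#' around: 14 environments (4 arid, 6 semi-arid, 4 humid), 250 inbred
#' lines, 3 replicates, a 150-day season.
#'
#' @param archetypes named integer vector: environments per archetype.
#' @param n_lines,n_markers,n_reps,n_days dimensions of the trial.
#' @param seed master seed; all stage seeds derive from it.
#' @param truth optional [truth_record()]; default truth is drawn with
#'   `seed`.
#' @param ... passed to [truth_record()] when `truth` is NULL.
#' @return list with `weather`, `genotypes`, `phenotypes`, `env_effects`,
#'   `truth`.
#' @export
simulate_gxe <- function(archetypes = c(arid = 4L, semi_arid = 6L,
                                        humid = 4L),
                         n_lines = 250, n_markers = 500, n_reps = 3,
                         n_days = 150, seed = 1, truth = NULL, ...) {
  stopifnot(length(archetypes) >= 1, all(archetypes >= 1))
  base_seed <- as.integer(abs(seed) %% 1000000L)  # keep derived seeds < 2^31
  weather <- list(); k <- 0L
  for (a in names(archetypes)) {
    for (j in seq_len(archetypes[[a]])) {
      k <- k + 1L
      weather[[k]] <- generate_weather(a, n_days = n_days,
                                       seed = base_seed * 1000L + k,
                                       env_id = sprintf("%s_%d", a, j))
    }
  }
  weather <- do.call(rbind, weather)
  genotypes <- generate_genotypes(n_lines, n_markers, seed = seed + 1L)
  if (is.null(truth)) truth <- truth_record(n_lines, seed = seed, ...)
  sim <- generate_phenotypes(weather, truth, n_reps = n_reps)
  list(weather = weather, genotypes = genotypes,
       phenotypes = sim$phenotypes, env_effects = sim$env_effects,
       truth = sim$truth)
}
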