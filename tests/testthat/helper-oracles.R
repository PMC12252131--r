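# Shared fixtures and independent oracles, built in code at test time.

# Jaccard similarity of two closed day ranges.
day_jaccard <- function(s1, e1, s2, e2) {
  a <- seq.int(s1, e1); b <- seq.int(s2, e2)
  length(intersect(a, b)) / length(union(a, b))
}

# Best Jaccard of a planted (factor, start, end) against a key-window set.
best_jaccard <- function(kw, fac, s, e) {
  r <- kw[kw$factor == fac, , drop = FALSE]
  if (!nrow(r)) return(0)
  max(vapply(seq_len(nrow(r)), function(i) {
    day_jaccard(r$start_day[i], r$end_day[i], s, e)
  }, 0))
}

# Balanced factorial phenotype table with known independent effects.
random_balanced_pheno <- function(n_g, n_e, n_r, sd = 1) {
  grid <- expand.grid(genotype_id = sprintf("g%02d", seq_len(n_g)),
                      env_id = sprintf("e%02d", seq_len(n_e)),
                      rep = seq_len(n_r), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$BW <- rnorm(nrow(grid), sd = sd)
  grid
}

# Textbook group-mean ANOVA sums of squares for a balanced crossed design
# with strata G, E, Rep, G:E; independent of the package's lm route.
brute_force_anova_ss <- function(ph, trait = "BW") {
  y <- ph[[trait]]
  gm <- mean(y)
  mg <- tapply(y, ph$genotype_id, mean)
  me <- tapply(y, ph$env_id, mean)
  mr <- tapply(y, ph$rep, mean)
  mge <- tapply(y, list(ph$genotype_id, ph$env_id), mean)
  n <- length(y)
  n_g <- length(mg); n_e <- length(me); n_r <- length(mr)
  ss_g <- (n / n_g) * sum((mg - gm)^2)
  ss_e <- (n / n_e) * sum((me - gm)^2)
  ss_r <- (n / n_r) * sum((mr - gm)^2)
  ss_ge <- n_r * sum((mge - outer(mg, rep(1, n_e)) -
                        outer(rep(1, n_g), me) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_g - ss_e - ss_r - ss_ge
  c(Genotype = ss_g, ENVs = ss_e, Rep = ss_r, `Genotype:ENVs` = ss_ge,
    Residuals = ss_res)
}

# Small end-to-end simulation used by several test files.
small_sim <- function(seed = 1, n_lines = 12, n_reps = 2, ...) {
  simulate_gxe(n_lines = n_lines, n_markers = 100, n_reps = n_reps,
               seed = seed, ...)
}
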