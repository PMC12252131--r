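# Derived daily indices, window aggregation, the dense feature grid, and
# genotype principal components.

make_weather <- function(tmax, tmin, pcp = 0, dh = 0, radn = 0,
                         rhmean = 50, wsmean = 1) {
  n <- length(tmax)
  data.frame(env_id = "e1", day = seq_len(n), tmax = tmax, tmin = tmin,
             tmean = (tmax + tmin) / 2, pcp = pcp, dh = dh,
             rhmean = rhmean, radn = radn, wsmean = wsmean)
}

test_that("daily indices follow the stated formulas and clamping rules", {
  w <- make_weather(tmax = 30, tmin = 20, pcp = 5, dh = 10, radn = 20)
  d <- derive_daily_indices(w)
  expect_equal(d$GDD, 15)
  expect_equal(d$DTR, 10)
  expect_equal(d$PRDTR, 0.5)
  expect_equal(d$PTQ, 20 / 15)
  expect_equal(d$PTT, 150)
  # below the 10 C base: GDD clamps to 0 and PTQ's division is guarded
  w2 <- make_weather(tmax = 12, tmin = 6, radn = 15)
  d2 <- derive_daily_indices(w2)
  expect_equal(d2$GDD, 0)
  expect_equal(d2$PTQ, 0)
  expect_equal(d2$PTT, 0)
  # zero diurnal range guards PRDTR
  w3 <- make_weather(tmax = 25, tmin = 25, pcp = 3)
  expect_equal(derive_daily_indices(w3)$PRDTR, 0)
})

test_that("cumulative GDD matches a brute-force loop on random weather", {
  set.seed(42)
  w <- make_weather(tmax = runif(150, 15, 38), tmin = runif(150, 2, 15))
  d <- derive_daily_indices(w)
  acc <- 0
  for (i in 1:150) {
    acc <- acc + max(0, (w$tmax[i] + w$tmin[i]) / 2 - 10)
  }
  expect_equal(sum(d$GDD), acc)
})

test_that("weather invariant violations name the environment and day", {
  w <- make_weather(tmax = c(20, 10), tmin = c(10, 15))
  expect_error(derive_daily_indices(w), "e1, day 2")
  w2 <- make_weather(tmax = 25, tmin = 15, rhmean = 130)
  expect_error(derive_daily_indices(w2), "rhmean")
})

test_that("window aggregation is the closed-interval arithmetic mean", {
  expect_equal(aggregate_window(rep(7, 20), 3, 11), 7)
  expect_equal(aggregate_window(1:10, 1, 5), 3)
  set.seed(1)
  x <- rnorm(60)
  s <- 13; e <- 41
  acc <- 0
  for (i in s:e) acc <- acc + x[i]
  expect_equal(aggregate_window(x, s, e), acc / (e - s + 1))
  expect_error(aggregate_window(1:10, 0, 5), "outside")
  expect_error(aggregate_window(1:10, 8, 11), "outside")
})

test_that("window aggregation is affine-equivariant", {
  set.seed(2)
  x <- rnorm(50)
  expect_equal(aggregate_window(3 * x + 2, 10, 30),
               3 * aggregate_window(x, 10, 30) + 2)
})

test_that("the dense grid has one column per (factor, start) and keys parse back", {
  sim <- small_sim(seed = 3, n_lines = 4, n_reps = 1)
  idx <- derive_daily_indices(sim$weather)
  fx <- build_window_features(idx, window_size = 5, stride = 1)
  expect_equal(ncol(fx), 146 * 13)     # 150 - 5 + 1 starts per factor
  expect_true("tmax_111_115" %in% colnames(fx))
  # parse-and-recompute round trip on a random subset of columns
  set.seed(9)
  cols <- sample(colnames(fx), 25)
  meta <- parse_window_key(cols)
  for (i in seq_along(cols)) {
    env <- rownames(fx)[1 + (i %% nrow(fx))]
    series <- idx[idx$env_id == env, meta$factor[i]]
    expect_equal(fx[env, cols[i]],
                 aggregate_window(series, meta$start[i], meta$end[i]))
  }
  expect_error(parse_window_key("tmax_120_110"), "start <= end")
  expect_error(parse_window_key("foo_1_5"), "unknown factor")
})

test_that("inconsistent day ranges across environments are rejected", {
  w1 <- generate_weather("arid", n_days = 150, seed = 1, env_id = "a")
  w2 <- generate_weather("arid", n_days = 120, seed = 2, env_id = "b")
  idx <- derive_daily_indices(rbind(w1, w2))
  expect_error(build_window_features(idx), "day range")
})

test_that("genotype PCs match an eigendecomposition oracle", {
  set.seed(5)
  g <- matrix(rbinom(60 * 40, 1, 0.5), 60, 40)
  p <- genotype_pcs(g, cum_threshold = 0.90)
  ev <- eigen(cov(g), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(p$explained_fraction, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(p$explained_fraction) <= 1e-12))
  expect_equal(sum(p$explained_fraction), 1)
  expect_gt(sum(p$explained_fraction[seq_len(p$k)]), 0.90)
})

test_that("PC count honours rank and threshold edge cases", {
  gb <- generate_genotypes(40, 100, seed = 8, n_blocks = 10, flip_prob = 0)
  p <- genotype_pcs(gb, cum_threshold = 0.999)
  expect_lte(p$k, 10)
  expect_equal(genotype_pcs(gb, cum_threshold = 0)$k, 1)
  expect_error(genotype_pcs(matrix(1L, 10, 5)), "degenerate")
})

test_that("sample features replicate environment rows and align PCs", {
  sim <- small_sim(seed = 4, n_lines = 6, n_reps = 1)
  idx <- derive_daily_indices(sim$weather)
  fx <- build_window_features(idx)
  pcs <- genotype_pcs(sim$genotypes)
  samples <- unique(sim$phenotypes[c("genotype_id", "env_id")])
  x <- sample_feature_matrix(fx, pcs, samples)
  expect_equal(nrow(x), nrow(samples))
  i <- 17
  expect_equal(unname(x[i, colnames(fx)]),
               unname(fx[samples$env_id[i], ]))
  expect_equal(unname(x[i, paste0("PC", 1:pcs$k)]),
               unname(pcs$scores[samples$genotype_id[i], ]))
  bad <- data.frame(genotype_id = "L001", env_id = "nowhere")
  expect_error(sample_feature_matrix(fx, pcs, bad), "missing")
})
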