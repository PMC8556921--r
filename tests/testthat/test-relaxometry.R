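tsl <- c(1, 10, 20, 35)

test_that("log-linear initialization is exact on noiseless decays", {
  sig <- 100 * exp(-tsl / 50)
  init <- loglinear_init(sig, tsl)
  expect_equal(init$T, 50, tolerance = 1e-7)
  expect_equal(init$S0, 100, tolerance = 1e-7)
  expect_false(init$non_decaying)

  expect_true(loglinear_init(rep(80, 4), tsl)$non_decaying)
  expect_error(loglinear_init(c(-1, 2, 3, 4), tsl),
               class = "ligrelax_parameter_error")
  expect_error(loglinear_init(c(1, 2), c(1, 10)),
               class = "ligrelax_schedule_error")
})

test_that("log-linear start lands within 20% of the grid-search minimizer", {
  set.seed(42)
  for (i in 1:25) {
    Tt <- runif(1, 20, 80)
    y <- 100 * exp(-tsl / Tt) * exp(rnorm(4, 0, 0.05))
    init <- loglinear_init(y, tsl)
    oracle <- gridsearch_decay(y, tsl)
    expect_lt(abs(init$T - oracle$T) / oracle$T, 0.20)
  }
})

test_that("noiseless voxels are recovered exactly with R-squared of 1", {
  for (Tt in c(30, 40, 50)) {
    f <- fit_voxel(100 * exp(-tsl / Tt), tsl, fit_options())
    expect_equal(f$status, "ok")
    expect_lt(abs(f$T - Tt), 0.01)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("noise-floor exclusion fires before any fitting", {
  opt <- fit_options(noise_floor = 10)
  sig <- 100 * exp(-tsl / 20) # last sample 17.4 > 10
  expect_equal(fit_voxel(sig, tsl, opt)$status, "ok")
  sig2 <- c(sig[1:3], 9.9)
  f2 <- fit_voxel(sig2, tsl, opt)
  expect_equal(f2$status, "below_noise_floor")
  expect_true(is.na(f2$T))
})

test_that("pure-noise voxels above the floor are rejected as poor fits", {
  # about 6% of exchangeable 4-point noise patterns support a chance decay
  # with R^2 >= 0.8, so rejection plateaus just above 90%, not at 100%
  set.seed(99)
  n_poor <- 0
  for (i in 1:1000) {
    y <- sqrt(rnorm(4, 0, 2)^2 + rnorm(4, 0, 2)^2) # Rayleigh, zero true signal
    f <- fit_voxel(y, tsl, fit_options(noise_floor = 0))
    if (f$status == "poor_fit") n_poor <- n_poor + 1
  }
  expect_gte(n_poor / 1000, 0.90)
})

test_that("the LM fit never does worse than a dense grid search", {
  set.seed(7)
  for (i in 1:40) {
    Tt <- runif(1, 5, 300)
    y <- sqrt((100 * exp(-tsl / Tt) + rnorm(4, 0, 3))^2 + rnorm(4, 0, 3)^2)
    f <- ligrelax:::fit_decay_matrix(matrix(y, 1), tsl, fit_options())
    oracle <- gridsearch_decay(y, tsl)
    expect_lte(f$sse, oracle$sse + 1e-9)
  }
})

test_that("parameter recovery at SNR 50 attains the NLLS optimum with small bias", {
  for (Tt in c(30, 40, 50)) {
    Y <- noisy_voxels(400, Tt, seed = Tt)
    f <- ligrelax:::fit_decay_matrix(Y, tsl, fit_options())
    expect_lt(abs(mean(f$T) - Tt), 0.5)       # bias
    oracle_T <- apply(Y[1:50, ], 1, function(y)
      gridsearch_decay(y, tsl, seq(1, 500, by = 0.05))$T)
    expect_lt(max(abs(f$T[1:50] - oracle_T)), 0.05)
  }
  # at the short end of the admissible range the error is sub-millisecond
  Y30 <- noisy_voxels(1000, 30, seed = 30)
  f30 <- ligrelax:::fit_decay_matrix(Y30, tsl, fit_options())
  expect_lt(median(abs(f30$T - 30)), 1)
})

test_that("raising either exclusion threshold never adds ok voxels", {
  m <- tiny_tube()
  ser <- noiseless_series(m, 45)
  ser <- ser + array(abs(rnorm(length(ser), 0, 1)), dim = dim(ser))
  n_ok <- function(r2_min, floor) {
    map <- build_map(ser, m, tsl, fit_options(r2_min = r2_min,
                                              noise_floor = floor))
    sum(map$status == "ok")
  }
  base <- n_ok(0.5, 0)
  for (r2 in c(0.8, 0.9, 0.99, 0.9999)) {
    nxt <- n_ok(r2, 0)
    expect_lte(nxt, base)
    base <- nxt
  }
  base <- n_ok(0.8, 0)
  for (fl in c(5, 20, 40, 80)) {
    nxt <- n_ok(0.8, fl)
    expect_lte(nxt, base)
    base <- nxt
  }
})

test_that("noise-floor estimation matches Rayleigh moments and degenerate cases", {
  d <- c(30, 30, 30, 4)
  zero <- array(0, d)
  bg <- array(TRUE, d[1:3])
  expect_equal(estimate_noise_floor(zero, bg), 0)
  const <- array(7, d)
  expect_equal(estimate_noise_floor(const, bg), 7)
  sigma <- 2
  set.seed(3)
  ray <- array(sqrt(rnorm(prod(d), 0, sigma)^2 + rnorm(prod(d), 0, sigma)^2), d)
  expect_equal(estimate_noise_floor(ray, bg), 2.5635 * sigma, tolerance = 0.02)
  expect_error(estimate_noise_floor(ray, array(FALSE, d[1:3])),
               class = "ligrelax_parameter_error")
  # percentile fallback is a quantile of the first contrast
  expect_equal(estimate_noise_floor(ray, percentile = 25),
               quantile(ray[, , , 1], 0.25, names = FALSE))
})

test_that("map construction partitions every in-mask voxel into one status", {
  m <- tiny_tube()
  tm <- array(NA_real_, dim(m)); tm[m] <- 50
  ser <- simulate_series(tm, 100, default_schedules()$T1rho, 2, seed = 4)
  nf <- estimate_noise_floor(ser, background_mask = !m)
  map <- build_map(ser, m, tsl, fit_options(noise_floor = nf))
  expect_equal(sum(map$qc), sum(m))
  expect_gte(sum(map$status == "ok") / sum(m), 0.99)
  expect_equal(sum(map$status == "outside_mask"), sum(!m))
  # in-mask ok voxels carry estimates; everything else is NA
  expect_true(all(!is.na(map$T[map$status == "ok"])))
  expect_true(all(is.na(map$T[map$status != "ok"])))

  sq <- summarize_fit_quality(map)
  expect_equal(sum(sq$fraction), 1, tolerance = 1e-12)

  expect_warning(build_map(ser, array(FALSE, dim(m)), tsl, fit_options()),
                 "empty mask")
  expect_error(build_map(ser, m[1:10, , ], tsl, fit_options()),
               class = "ligrelax_shape_error")
})
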