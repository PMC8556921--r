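# Shared fixture builders: everything is generated in code at test time.

# A small straight-ish tube mask for partition/fitting tests.
tiny_tube <- function(grid = c(24, 24, 24), radius = 2,
                      from = c(8, 10, 4), to = c(16, 14, 21)) {
  make_ligament_mask(grid, rbind(from, to), radius)
}

# Noiseless mono-exponential series over a mask.
noiseless_series <- function(mask, T_ms, S0 = 100,
                             schedule = default_schedules()$T1rho) {
  Tmap <- array(NA_real_, dim = dim(mask))
  Tmap[mask] <- T_ms
  simulate_series(Tmap, S0, schedule, noise_sigma = 0, seed = 1)
}

# Rician-noise matrix of voxel signals with common true (S0, T).
noisy_voxels <- function(n, T_ms, S0 = 100, sigma = 2,
                         times = c(1, 10, 20, 35), seed = 1) {
  set.seed(seed)
  S <- outer(rep(S0, n), exp(-times / T_ms))
  sqrt((S + matrix(rnorm(n * length(times), 0, sigma), n))^2 +
         matrix(rnorm(n * length(times), 0, sigma), n)^2)
}

# Small cohort configuration used by pipeline tests (kept light on purpose).
small_cohort_config <- function(seed = 7, n_oa = 4, n_control = 3) {
  phantom_config(grid_shape = c(32, 32, 32), n_oa = n_oa,
                 n_control = n_control, tube_radius = 2, seed = seed)
}

# Variable-projection grid-search oracle for the mono-exponential SSE: for
# each candidate T the optimal S0 is closed-form, so the dense T grid
# bounds the attainable SSE independently of the fitter under test.
gridsearch_decay <- function(y, times, T_grid = seq(1, 500, by = 0.5)) {
  E <- exp(-outer(1 / T_grid, times))
  s0 <- as.vector(E %*% y) / rowSums(E^2)
  s0 <- pmax(s0, 0)
  sse <- rowSums((s0 * E - matrix(y, length(T_grid), length(times),
                                  byrow = TRUE))^2)
  i <- which.min(sse)
  list(T = T_grid[i], S0 = s0[i], sse = sse[i])
}
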