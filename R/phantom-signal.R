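#' Simulate a multi-contrast magnitude image series
#'
#' Generates the 4D magnitude series a relaxometry acquisition would
#' produce: noiseless intensity S(t) = S0 * exp(-t / T) wherever the true
#' map is defined, zero true signal elsewhere, then Rician magnitude noise
#' everywhere (magnitude of a complex Gaussian with per-channel SD
#' `noise_sigma`), so the background is Rayleigh-distributed.
#'
#' @param true_T_map numeric 3D array of true relaxation times (ms), `NA`
#'   where undefined.
#' @param true_S0_map numeric 3D array of true equilibrium signal, or a
#'   scalar applied to all defined voxels.
#' @param schedule an [acquisition_schedule()].
#' @param noise_sigma per-channel Gaussian SD in signal units, >= 0.
#' @param seed RNG seed; the series is bit-reproducible for a fixed seed.
#' @return numeric 4D array, contrast (time) axis last.
#' @export
simulate_series <- function(true_T_map, true_S0_map, schedule, noise_sigma, seed) {
  if (length(true_S0_map) == 1) {
    true_S0_map <- array(true_S0_map, dim = dim(true_T_map))
  }
  if (!identical(dim(true_T_map), dim(true_S0_map))) {
    stop_ligrelax("T and S0 maps must share a grid", "ligrelax_shape_error")
  }
  if (!inherits(schedule, "acquisition_schedule")) {
    stop_ligrelax("schedule must be an acquisition_schedule",
                  "ligrelax_parameter_error")
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop_ligrelax("noise_sigma must be >= 0", "ligrelax_parameter_error")
  }
  d <- dim(true_T_map)
  nt <- length(schedule$times)
  series <- array(0, dim = c(d, nt))
  Tvals <- as.vector(true_T_map)
  S0 <- as.vector(true_S0_map)
  defined <- !is.na(Tvals) & !is.na(S0)
  set.seed(seed)
  for (j in seq_len(nt)) {
    s <- numeric(length(Tvals))
    s[defined] <- S0[defined] * exp(-schedule$times[j] / Tvals[defined])
    if (noise_sigma > 0) {
      nre <- rnorm(length(s), 0, noise_sigma)
      nim <- rnorm(length(s), 0, noise_sigma)
      s <- sqrt((s + nre)^2 + nim^2)
    }
    series[(j - 1L) * length(s) + seq_along(s)] <- s
  }
  series
}
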