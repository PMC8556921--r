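#' Options for voxel-wise mono-exponential fitting
#'
#' @param r2_min minimum coefficient of determination for a fit to be kept;
#'   voxels below it are excluded as `poor_fit` (default 0.8).
#' @param t_bounds lower/upper admissible relaxation time in ms (default
#'   1-2000); fits pinned at a bound are reported `not_converged`, never
#'   silently clipped.
#' @param max_iterations Levenberg-Marquardt iteration cap (default 200).
#' @param convergence_tol relative SSE change below which a voxel is deemed
#'   converged (default 1e-8).
#' @param noise_floor signal level below which any sample invalidates the
#'   voxel (`below_noise_floor`); default 0, i.e. disabled until set from
#'   [estimate_noise_floor()].
#' @return `fit_options` list.
#' @export
fit_options <- function(r2_min = 0.8, t_bounds = c(1, 2000),
                        max_iterations = 200L, convergence_tol = 1e-8,
                        noise_floor = 0) {
  if (r2_min < 0 || r2_min > 1) {
    stop_ligrelax("r2_min must lie in [0, 1]", "ligrelax_parameter_error")
  }
  if (length(t_bounds) != 2 || t_bounds[1] <= 0 || t_bounds[2] <= t_bounds[1]) {
    stop_ligrelax("t_bounds must satisfy 0 < lower < upper", "ligrelax_parameter_error")
  }
  if (max_iterations < 1) {
    stop_ligrelax("max_iterations must be >= 1", "ligrelax_parameter_error")
  }
  if (noise_floor < 0) {
    stop_ligrelax("noise_floor must be >= 0", "ligrelax_parameter_error")
  }
  structure(list(r2_min = r2_min, t_bounds = as.numeric(t_bounds),
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol, noise_floor = noise_floor),
            class = "fit_options")
}

#' Estimate the magnitude-image noise floor
#'
#' Background-mask method: mean + 2 SD of the background intensities pooled
#' over all contrasts (for Rayleigh background with channel SD sigma this
#' converges to about 2.5635 sigma). When no background mask is available, a
#' percentile of the first-contrast volume serves as fallback.
#'
#' @param series 4D numeric array, contrast axis last.
#' @param background_mask 3D logical array of air/background voxels, or NULL.
#' @param percentile fallback percentile in (0, 50], used when
#'   `background_mask` is NULL.
#' @return non-negative scalar in signal units.
#' @export
estimate_noise_floor <- function(series, background_mask = NULL,
                                 percentile = NULL) {
  nd <- length(dim(series))
  if (nd != 4) {
    stop_ligrelax("series must be 4D with the contrast axis last",
                  "ligrelax_shape_error")
  }
  if (!is.null(background_mask)) {
    if (!is.logical(background_mask)) background_mask <- background_mask > 0
    if (sum(background_mask) == 0) {
      stop_ligrelax("background mask is empty", "ligrelax_parameter_error")
    }
    nt <- dim(series)[4]
    vals <- unlist(lapply(seq_len(nt), function(j) {
      v <- series[, , , j]
      v[background_mask]
    }))
    m <- mean(vals)
    s <- sd(vals)
    if (!is.finite(s)) s <- 0
    return(max(m + 2 * s, 0))
  }
  if (is.null(percentile) || percentile <= 0 || percentile > 50) {
    stop_ligrelax("need a background mask or a percentile in (0, 50]",
                  "ligrelax_parameter_error")
  }
  as.numeric(quantile(series[, , , 1], percentile / 100, names = FALSE))
}

#' Log-linear initial estimate for a mono-exponential decay
#'
#' Ordinary least squares of log signal on time: slope m and intercept b
#' give T = -1/m and S0 = exp(b). Exact on noiseless decays; used to seed
#' the non-linear fit.
#'
#' @param signal positive intensities, one per time point.
#' @param times acquisition times in ms (>= 3).
#' @return list `S0`, `T` (ms; `NA` when non-decaying), `non_decaying`.
#' @export
loglinear_init <- function(signal, times) {
  if (length(signal) != length(times) || length(times) < 3) {
    stop_ligrelax("need >= 3 matching (signal, time) samples",
                  "ligrelax_schedule_error")
  }
  if (any(signal <= 0)) {
    stop_ligrelax("log-linear initialization requires positive intensities; exclude the voxel first",
                  "ligrelax_parameter_error")
  }
  ly <- log(signal)
  mt <- mean(times); my <- mean(ly)
  m <- sum((times - mt) * (ly - my)) / sum((times - mt)^2)
  b <- my - m * mt
  if (m >= 0) {
    return(list(S0 = exp(b), T = NA_real_, non_decaying = TRUE))
  }
  list(S0 = exp(b), T = -1 / m, non_decaying = FALSE)
}

# Internal: vectorized Levenberg-Marquardt fit of S(t) = S0 exp(-t/T) to
# every row of Y (n_voxels x n_times), bounded in T, seeded by the
# log-linear estimate. Returns S0, T, sse, r_squared, converged, at_bound.
fit_decay_matrix <- function(Y, times, options) {
  nv <- nrow(Y); nt <- length(times)
  lo <- options$t_bounds[1]; hi <- options$t_bounds[2]

  # log-linear start (clamped into bounds; non-decaying rows start flat)
  ylog <- log(pmax(Y, 1e-12))
  mt <- mean(times)
  ct <- times - mt
  denom <- sum(ct^2)
  slope <- as.vector(ylog %*% ct) / denom
  icept <- rowMeans(ylog) - slope * mt
  T0 <- ifelse(slope < 0, -1 / slope, hi)
  T0 <- pmin(pmax(T0, lo), hi)
  S0 <- pmax(exp(icept), 1e-9)
  Tc <- T0

  sse_of <- function(S0v, Tv) {
    E <- exp(-outer(1 / Tv, times))
    R <- S0v * E - Y
    list(E = E, R = R, sse = rowSums(R^2))
  }

  cur <- sse_of(S0, Tc)
  lambda <- rep(1e-3, nv)
  active <- rep(TRUE, nv)
  converged <- rep(FALSE, nv)

  for (it in seq_len(options$max_iterations)) {
    if (!any(active)) break
    E <- cur$E; R <- cur$R
    tmat <- matrix(times, nv, nt, byrow = TRUE)
    J2 <- (S0 * E) * tmat / Tc^2          # d model / d T
    A11 <- rowSums(E * E)
    A12 <- rowSums(E * J2)
    A22 <- rowSums(J2 * J2)
    g1 <- rowSums(E * R)
    g2 <- rowSums(J2 * R)

    a11 <- A11 * (1 + lambda)
    a22 <- A22 * (1 + lambda)
    det <- a11 * a22 - A12^2
    det[abs(det) < 1e-300] <- 1e-300
    dS0 <- (-g1 * a22 + g2 * A12) / det
    dT <- (-g2 * a11 + g1 * A12) / det

    S0_new <- pmax(S0 + ifelse(active, dS0, 0), 0)
    T_new <- pmin(pmax(Tc + ifelse(active, dT, 0), lo), hi)
    prop <- sse_of(S0_new, T_new)

    better <- active & (prop$sse <= cur$sse)
    rel <- abs(cur$sse - prop$sse) / pmax(cur$sse, 1e-300)
    newly <- better & (rel < options$convergence_tol)

    S0 <- ifelse(better, S0_new, S0)
    Tc <- ifelse(better, T_new, Tc)
    repl <- which(better)
    if (length(repl)) {
      cur$E[repl, ] <- prop$E[repl, , drop = FALSE]
      cur$R[repl, ] <- prop$R[repl, , drop = FALSE]
      cur$sse[repl] <- prop$sse[repl]
    }
    lambda <- ifelse(better, pmax(lambda / 3, 1e-12), pmin(lambda * 5, 1e10))
    converged <- converged | newly
    # voxels whose rejected step is negligible have also stalled out
    stalled <- active & !better & (lambda >= 1e9)
    converged <- converged | stalled
    active <- active & !converged
  }

  ybar <- rowMeans(Y)
  sstot <- rowSums((Y - ybar)^2)
  r2 <- ifelse(sstot > 0, 1 - cur$sse / sstot, 0)
  eps_b <- 1e-9 * (hi - lo)
  at_bound <- (Tc <= lo + eps_b) | (Tc >= hi - eps_b)
  list(S0 = S0, T = Tc, sse = cur$sse, r_squared = r2,
       converged = converged, at_bound = at_bound)
}

# Internal: map fit results + exclusion rules to a status code per voxel.
# Evaluation order: noise floor, then fit quality, then convergence/bounds.
decide_status <- function(below_floor, r_squared, converged, at_bound, r2_min) {
  status <- rep("ok", length(r_squared))
  status[!converged | at_bound] <- "not_converged"
  status[r_squared < r2_min] <- "poor_fit"
  status[below_floor] <- "below_noise_floor"
  status
}

#' Fit a single voxel's decay curve
#'
#' Mono-exponential non-linear least squares on one voxel's signal with the
#' two exclusion rules applied: any sample below the noise floor invalidates
#' the voxel before fitting, and a fit with R-squared below `r2_min` is
#' discarded as poor.
#'
#' @param signal intensities, one per time point.
#' @param times acquisition times in ms.
#' @param options a [fit_options()].
#' @return list `S0`, `T` (ms), `r_squared`, `status` (one of ok,
#'   below_noise_floor, poor_fit, not_converged); estimates are `NA` for any
#'   non-`ok` status.
#' @examples
#' tsl <- c(1, 10, 20, 35)
#' fit_voxel(100 * exp(-tsl / 50), tsl, fit_options())
#' @export
fit_voxel <- function(signal, times, options = fit_options()) {
  if (length(signal) != length(times)) {
    stop_ligrelax("signal and schedule lengths differ", "ligrelax_schedule_error")
  }
  if (length(times) < 3) {
    stop_ligrelax("need at least 3 time points", "ligrelax_schedule_error")
  }
  if (any(signal < options$noise_floor)) {
    return(list(S0 = NA_real_, T = NA_real_, r_squared = NA_real_,
                status = "below_noise_floor"))
  }
  f <- fit_decay_matrix(matrix(signal, nrow = 1), times, options)
  status <- decide_status(FALSE, f$r_squared, f$converged, f$at_bound,
                          options$r2_min)
  if (status != "ok") {
    return(list(S0 = NA_real_, T = NA_real_, r_squared = f$r_squared,
                status = status))
  }
  list(S0 = f$S0, T = f$T, r_squared = f$r_squared, status = "ok")
}

#' Construct a parameter map from an image series
#'
#' Fits every in-mask voxel of a 4D magnitude series; out-of-mask voxels are
#' labelled `outside_mask`. Emits a per-status quality-control count.
#'
#' @param series 4D numeric array, contrast axis last.
#' @param mask 3D logical array on the same grid.
#' @param times acquisition times (ms) matching the 4th dimension, or an
#'   [acquisition_schedule()].
#' @param options a [fit_options()].
#' @return `parameter_map` object: arrays `T`, `S0`, `r_squared` (all `NA`
#'   where not fitted), `status` (character array), plus `times`, `options`
#'   and a `qc` count table.
#' @export
build_map <- function(series, mask, times, options = fit_options()) {
  if (inherits(times, "acquisition_schedule")) times <- times$times
  d <- dim(series)
  if (length(d) != 4 || d[4] != length(times)) {
    stop_ligrelax("series must be 4D with one volume per schedule time",
                  "ligrelax_shape_error")
  }
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), d[1:3])) {
    stop_ligrelax("series and mask grids differ", "ligrelax_shape_error")
  }
  nvox <- prod(d[1:3])
  Tm <- array(NA_real_, d[1:3]); S0m <- Tm; R2m <- Tm
  status <- array("outside_mask", d[1:3])

  idx <- which(mask)
  if (length(idx) == 0) {
    warning("build_map: empty mask, nothing fitted")
  } else {
    Y <- matrix(series, nrow = nvox)[idx, , drop = FALSE]
    below <- rowSums(Y < options$noise_floor) > 0
    st <- rep("below_noise_floor", length(idx))
    if (any(!below)) {
      f <- fit_decay_matrix(Y[!below, , drop = FALSE], times, options)
      st[!below] <- decide_status(FALSE, f$r_squared, f$converged, f$at_bound,
                                  options$r2_min)
      keep <- st[!below] == "ok"
      fitted_idx <- idx[!below]
      Tm[fitted_idx[keep]] <- f$T[keep]
      S0m[fitted_idx[keep]] <- f$S0[keep]
      R2m[fitted_idx[keep]] <- f$r_squared[keep]
    }
    status[idx] <- st
  }

  qc <- table(factor(status[mask], levels = c(
    "ok", "below_noise_floor", "poor_fit", "not_converged"
  )))
  structure(list(T = Tm, S0 = S0m, r_squared = R2m, status = status,
                 times = times, options = options, qc = qc),
            class = "parameter_map")
}

#' Quality-control summary of a parameter map
#'
#' @param map a [build_map()] result.
#' @return data.frame of per-status counts and fractions over in-mask
#'   voxels; fractions sum to 1.
#' @export
summarize_fit_quality <- function(map) {
  counts <- as.vector(map$qc)
  statuses <- names(map$qc)
  total <- sum(counts)
  data.frame(
    status = statuses,
    n = counts,
    fraction = if (total > 0) counts / total else rep(NA_real_, length(counts)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> grid %s, %d in-mask voxels (%s)\n",
              paste(dim(x$T), collapse = "x"), sum(x$qc),
              paste(sprintf("%s=%d", names(x$qc), as.vector(x$qc)),
                    collapse = ", ")))
  invisible(x)
}
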