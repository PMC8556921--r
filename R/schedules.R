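#' Acquisition schedule for a relaxometry series
#'
#' The preparation-time axis for a decaying image series: spin-lock times
#' (TSL) for T1rho mapping or echo times (TE) for T2 mapping, in ms. The
#' schedule drives both phantom simulation and voxel-wise fitting.
#'
#' @param mode `"spin_lock"` (T1rho) or `"echo"` (T2).
#' @param times numeric vector of at least 3 strictly increasing positive
#'   times in ms.
#' @return An object of class `acquisition_schedule` with fields `mode` and
#'   `times`.
#' @examples
#' acquisition_schedule("spin_lock", c(1, 10, 20, 35))
#' @export
acquisition_schedule <- function(mode = c("spin_lock", "echo"), times) {
  mode <- match.arg(mode)
  times <- as.numeric(times)
  if (length(times) < 3) {
    stop_ligrelax("an acquisition schedule needs at least 3 time points",
                  "ligrelax_schedule_error")
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop_ligrelax("schedule times must be finite and positive (ms)",
                  "ligrelax_schedule_error")
  }
  if (any(diff(times) <= 0)) {
    stop_ligrelax("schedule times must be strictly increasing",
                  "ligrelax_schedule_error")
  }
  structure(list(mode = mode, times = times), class = "acquisition_schedule")
}

#' Default T1rho and T2 acquisition schedules
#'
#' The pseudo-steady-state 3D FSE protocol timings used as simulation
#' defaults: TSL 1/10/20/35 ms for the spin-lock-prepared (T1rho) series and
#' TE 6.5/13.4/27.0/40.7 ms for the T2-prepared series.
#'
#' @return Named list with elements `T1rho` and `T2`, each an
#'   [acquisition_schedule()].
#' @export
default_schedules <- function() {
  list(
    T1rho = acquisition_schedule("spin_lock", c(1, 10, 20, 35)),
    T2 = acquisition_schedule("echo", c(6.5, 13.4, 27.0, 40.7))
  )
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf("<acquisition_schedule> mode=%s times(ms)=%s\n",
              x$mode, paste(x$times, collapse = "/")))
  invisible(x)
}
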