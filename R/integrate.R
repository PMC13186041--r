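#' Integrate a single spore's trajectory
#'
#' Solves the five-state network for one spore starting from the dormant
#' state `Ri = Ri0`, `Ra = 0`, `Cc = c_total`, `Cca = Co = 0`. The square-wave
#' germinant input is handled by restarting the adaptive solver
#' ([deSolve::lsoda]) at every pulse boundary, so a discontinuity never sits
#' inside an adaptive step. The first crossing of the germination threshold
#' (`Co >= germination_threshold`) is located to 0.01 min or better by a
#' fine re-integration of the bracketing output interval.
#'
#' @param Ri0 Initial inactive GR copy number (molecules/spore, >= 0).
#' @param params A [kinetic_params()].
#' @param protocol A [pulse_protocol()].
#' @param dt_out Output grid spacing (min). The grid always includes every
#'   pulse boundary.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return An object of class `spore_trajectory`: list with `times`, `states`
#'   (matrix with columns `Ri`, `Ra`, `Cc`, `Cca`, `Co`), `t_open` (min, or
#'   `NA` if the threshold is never reached within the horizon), `params`
#'   and `protocol`.
#' @examples
#' tr <- integrate_spore(1500, kinetic_params(), double_pulse_protocol(3.5, 5))
#' tr$t_open
#' @export
integrate_spore <- function(Ri0, params, protocol, dt_out = 0.05,
                            rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(protocol, "pulse_protocol"))
  if (!is.numeric(Ri0) || length(Ri0) != 1L || is.na(Ri0) || Ri0 < 0)
    stop("'Ri0' must be a single nonnegative copy number", call. = FALSE)

  y <- c(Ri = Ri0, Ra = 0, Cc = params$c_total, Cca = 0, Co = 0)
  breaks <- protocol_breaks(protocol)
  grid <- seq(0, protocol$horizon, by = dt_out)

  times <- 0
  states <- matrix(y, nrow = 1L, dimnames = list(NULL, names(y)))
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    S <- pulse_concentration(protocol, a)
    seg_times <- unique(c(a, grid[grid > a & grid < b], b))
    sol <- solve_segment(y, seg_times, S, params, rtol, atol, Ri0)
    times <- c(times, sol[-1L, 1L])
    states <- rbind(states, sol[-1L, -1L, drop = FALSE])
    y <- sol[nrow(sol), -1L]
  }

  traj <- structure(list(times = times, states = states, t_open = NA_real_,
                         params = params, protocol = protocol),
                    class = "spore_trajectory")
  traj$t_open <- detect_threshold_crossing(traj, params$germination_threshold)
  traj
}

# One constant-S segment through lsoda; errors carry the offending inputs.
solve_segment <- function(y, seg_times, S, params, rtol, atol, Ri0) {
  f <- function(t, y, parms) list(rhs_core(y, S, params))
  sol <- try(deSolve::lsoda(y = y, times = seg_times, func = f, parms = NULL,
                            rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || any(!is.finite(sol)))
    stop(sprintf(paste0("ODE solver failed on segment starting t = %g min ",
                        "(S = %g mM, Ri0 = %g, k1 = %g, k4 = %g)"),
                 seg_times[1L], S, Ri0, params$k1, params$k4), call. = FALSE)
  unclass(sol)
}

#' First crossing time of the germination threshold
#'
#' Scans the trajectory for the first grid point with
#' `Co >= threshold`, then refines the crossing within the bracketing output
#' interval by re-integrating it on a 0.002-min grid and interpolating
#' linearly between the two fine points that straddle the threshold.
#'
#' @param trajectory A `spore_trajectory` from [integrate_spore()].
#' @param threshold Open-channel count defining germination (> 0); defaults
#'   to the trajectory's own `germination_threshold`.
#' @return The crossing time `T_open` in min, or `NA_real_` if `Co` never
#'   reaches the threshold within the horizon.
#' @export
detect_threshold_crossing <- function(trajectory,
                                      threshold = trajectory$params$germination_threshold) {
  stopifnot(inherits(trajectory, "spore_trajectory"))
  if (threshold <= 0) stop("'threshold' must be > 0", call. = FALSE)
  co <- trajectory$states[, "Co"]
  idx <- which(co >= threshold)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(trajectory$times[1L])

  t0 <- trajectory$times[i - 1L]; t1 <- trajectory$times[i]
  # output grid contains every pulse boundary, so S is constant on [t0, t1]
  S <- pulse_concentration(trajectory$protocol, t0)
  fine <- seq(t0, t1, length.out = max(5L, ceiling((t1 - t0) / 0.002) + 1L))
  sol <- solve_segment(trajectory$states[i - 1L, ], fine, S,
                       trajectory$params, 1e-10, 1e-10,
                       trajectory$states[1L, "Ri"])
  cf <- sol[, "Co"]
  j <- which(cf >= threshold)[1L]
  if (is.na(j)) return(t1)          # crossing at the right edge to tolerance
  if (j == 1L) return(fine[1L])
  # linear interpolation inside one fine step (<= 0.002 min wide)
  tt <- fine[j - 1L] +
    (threshold - cf[j - 1L]) / (cf[j] - cf[j - 1L]) * (fine[j] - fine[j - 1L])
  as.numeric(tt)
}

#' Classify the germination outcome of a spore
#'
#' Splits spores into the three subpopulations of a double-pulse experiment:
#' `no_germination` (threshold never crossed), `first_pulse` (crossing before
#' the second pulse starts, or any crossing under a single-pulse protocol)
#' and `second_pulse` (crossing at or after the second pulse start). The lag
#' time is computed against `T_block`, the end of the pulse preceding the
#' crossing: `T_lag = T_open - T_block`.
#'
#' @param t_open Crossing time in min, or `NA` for no crossing.
#' @param protocol A [pulse_protocol()] with at least one pulse.
#' @return An object of class `germination_outcome`: list with `class` (one
#'   of `"no_germination"`, `"first_pulse"`, `"second_pulse"`), `t_open` and
#'   `t_lag` (both `NA` when the spore does not germinate).
#' @examples
#' pr <- double_pulse_protocol(3.5, 5)
#' classify_outcome(12, pr)$class  # "first_pulse"
#' classify_outcome(40, pr)$class  # "second_pulse"
#' @export
classify_outcome <- function(t_open, protocol) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  p <- protocol$pulses
  if (nrow(p) == 0L) stop("protocol must contain at least one pulse", call. = FALSE)
  if (is.null(t_open) || is.na(t_open)) {
    return(structure(list(class = "no_germination", t_open = NA_real_,
                          t_lag = NA_real_), class = "germination_outcome"))
  }
  cls <- if (nrow(p) == 1L || t_open < p$start[2L]) "first_pulse" else "second_pulse"
  started <- which(p$start < t_open)
  t_block <- if (length(started) > 0L) p$end[max(started)] else p$end[1L]
  structure(list(class = cls, t_open = as.numeric(t_open),
                 t_lag = as.numeric(t_open - t_block)),
            class = "germination_outcome")
}

#' @export
print.germination_outcome <- function(x, ...) {
  if (x$class == "no_germination") {
    cat("Outcome: no germination within the horizon\n")
  } else {
    cat(sprintf("Outcome: %s (T_open = %.2f min, T_lag = %.2f min)\n",
                x$class, x$t_open, x$t_lag))
  }
  invisible(x)
}

#' Channel-opening interval (release-time proxy)
#'
#' Experimental release intervals measure the time from onset to completion
#' of rapid CaDPA release. The model has no explicit efflux flux, so this is
#' operationalized on the open-channel trajectory as the time from the
#' germination threshold crossing to `Co` first reaching `plateau_frac *
#' c_total` (default 95% of all channels).
#'
#' @param trajectory A `spore_trajectory`.
#' @param plateau_frac Fraction of `c_total` defining the plateau.
#' @return Interval in min, or `NA_real_` if the trajectory has no threshold
#'   crossing or the plateau is not reached within the horizon.
#' @export
release_interval <- function(trajectory, plateau_frac = 0.95) {
  stopifnot(inherits(trajectory, "spore_trajectory"))
  if (is.na(trajectory$t_open)) return(NA_real_)
  target <- plateau_frac * trajectory$params$c_total
  co <- trajectory$states[, "Co"]
  idx <- which(co >= target)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  t_plateau <- if (i == 1L) trajectory$times[1L] else {
    t0 <- trajectory$times[i - 1L]; t1 <- trajectory$times[i]
    t0 + (target - co[i - 1L]) / (co[i] - co[i - 1L]) * (t1 - t0)
  }
  as.numeric(t_plateau - trajectory$t_open)
}

#' @export
print.spore_trajectory <- function(x, ...) {
  cat(sprintf("Spore trajectory: Ri0 = %g, %d time points over [0, %g] min\n",
              x$states[1L, "Ri"], length(x$times), max(x$times)))
  if (is.na(x$t_open)) cat("  no germination threshold crossing\n")
  else cat(sprintf("  T_open = %.3f min (Co >= %g)\n", x$t_open,
                   x$params$germination_threshold))
  invisible(x)
}

#' @export
as.data.frame.spore_trajectory <- function(x, ...) {
  data.frame(time_min = x$times, x$states, check.names = FALSE)
}
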