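#' Piecewise-constant germinant pulse protocol
#'
#' The germinant input `S(t)` is an exact square wave: a set of
#' non-overlapping timed pulses, each with a constant concentration, and zero
#' germinant elsewhere. Discontinuities at pulse boundaries are handled by
#' restarting the integrator there, never by smoothing.
#'
#' @param start,end Numeric vectors of pulse start/end times (min), sorted,
#'   non-overlapping, with `0 <= start < end <= horizon`.
#' @param concentration Germinant concentration during each pulse (mM, >= 0);
#'   recycled to the number of pulses.
#' @param horizon Total simulated time (min).
#' @return An object of class `pulse_protocol` with a `pulses` data frame
#'   (`start`, `end`, `concentration`) and `horizon`.
#' @examples
#' # two 5-min 3.5 mM pulses starting at 0 and 30 min
#' pulse_protocol(c(0, 30), c(5, 35), 3.5, horizon = 60)
#' @export
pulse_protocol <- function(start = numeric(), end = numeric(),
                           concentration = numeric(), horizon = 60) {
  if (length(start) != length(end))
    stop("'start' and 'end' must have the same length", call. = FALSE)
  np <- length(start)
  concentration <- rep_len(as.numeric(concentration), np)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("'horizon' must be a single positive time (min)", call. = FALSE)
  if (np > 0L) {
    if (any(start < 0) || any(end > horizon) || any(start >= end))
      stop("pulses must satisfy 0 <= start < end <= horizon", call. = FALSE)
    o <- order(start)
    start <- start[o]; end <- end[o]; concentration <- concentration[o]
    if (np > 1L && any(start[-1L] < end[-np]))
      stop("pulses must not overlap", call. = FALSE)
    if (any(concentration < 0))
      stop("pulse concentrations must be >= 0", call. = FALSE)
  }
  structure(list(pulses = data.frame(start = as.numeric(start),
                                     end = as.numeric(end),
                                     concentration = concentration),
                 horizon = horizon),
            class = "pulse_protocol")
}

#' Standard double-pulse protocol
#'
#' Convenience constructor for the memory experiments: two identical pulses,
#' the first starting at time zero and the second at `second_start`
#' (start-to-start spacing).
#'
#' @param concentration Germinant concentration during both pulses (mM).
#' @param duration Pulse duration (min).
#' @param second_start Start of the second pulse (min).
#' @param horizon Total simulated time (min).
#' @return A [pulse_protocol()].
#' @examples
#' double_pulse_protocol(3.5, duration = 5)   # pulses [0,5] and [30,35]
#' double_pulse_protocol(10, duration = 2)    # pulses [0,2] and [30,32]
#' @export
double_pulse_protocol <- function(concentration = 3.5, duration = 5,
                                  second_start = 30, horizon = 60) {
  pulse_protocol(start = c(0, second_start),
                 end = c(duration, second_start + duration),
                 concentration = concentration, horizon = horizon)
}

#' @export
print.pulse_protocol <- function(x, ...) {
  np <- nrow(x$pulses)
  cat(sprintf("Pulse protocol: %d pulse(s), horizon %g min\n", np, x$horizon))
  if (np > 0L)
    for (i in seq_len(np))
      cat(sprintf("  %g mM over %g < t < %g min\n",
                  x$pulses$concentration[i], x$pulses$start[i], x$pulses$end[i]))
  invisible(x)
}

#' Germinant concentration at a time point
#'
#' @param protocol A [pulse_protocol()].
#' @param t Time(s), min, >= 0 (vectorized).
#' @return Concentration(s) in mM: the concentration of the pulse containing
#'   `t` (pulses are half-open on the right, active on `start <= t < end`),
#'   zero outside all pulses.
#' @examples
#' pr <- double_pulse_protocol(3.5, 5)
#' pulse_concentration(pr, c(2, 10, 31))  # 3.5 0 3.5
#' @export
pulse_concentration <- function(protocol, t) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  p <- protocol$pulses
  for (i in seq_len(nrow(p))) {
    hit <- t >= p$start[i] & t < p$end[i]
    out[hit] <- p$concentration[i]
  }
  out
}

# Segment boundaries of the square wave on [0, horizon]: every pulse edge
# becomes an integrator restart point.
protocol_breaks <- function(protocol) {
  b <- c(0, protocol$pulses$start, protocol$pulses$end, protocol$horizon)
  b <- sort(unique(b[b >= 0 & b <= protocol$horizon]))
  b
}
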