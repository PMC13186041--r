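#' Deterministic receptor copy-number scan
#'
#' Integrates one spore per `Ri0` value under shared kinetics and protocol
#' and classifies each outcome, exposing the three contiguous subpopulations
#' of a double-pulse experiment: non-germinating spores at low receptor
#' numbers, spores triggered only by the second pulse, and spores already
#' triggered by the first. The default axis (600 to 1800 in steps of 50)
#' covers the wild-type receptor range.
#'
#' @param Ri_values Increasing vector of initial GR copy numbers.
#' @param params A [kinetic_params()].
#' @param protocol A [pulse_protocol()].
#' @param keep_trajectories Retain full trajectories (needed by
#'   [peak_channel_activation()]); defaults to on for scans of at most 100
#'   points.
#' @param dt_out Output grid spacing (min).
#' @return An object of class `gr_scan`: list with `table` (data frame:
#'   `Ri0`, `t_open`, `class`), `boundaries` (list: `max_no_germination`,
#'   `min_second_pulse`, `min_first_pulse`; `NA` when a class is absent) and
#'   `trajectories` (list or `NULL`).
#' @examples
#' \donttest{
#' sc <- gr_copy_scan(seq(600, 1800, 50), kinetic_params(),
#'                    double_pulse_protocol(3.5, 5))
#' sc$boundaries
#' }
#' @export
gr_copy_scan <- function(Ri_values, params, protocol,
                         keep_trajectories = length(Ri_values) <= 100L,
                         dt_out = 0.05) {
  if (length(Ri_values) == 0L || is.unsorted(Ri_values, strictly = TRUE))
    stop("'Ri_values' must be nonempty and strictly increasing", call. = FALSE)
  trajs <- if (keep_trajectories) vector("list", length(Ri_values)) else NULL
  t_open <- numeric(length(Ri_values))
  cls <- character(length(Ri_values))
  for (i in seq_along(Ri_values)) {
    tr <- integrate_spore(Ri_values[i], params, protocol, dt_out = dt_out)
    t_open[i] <- tr$t_open
    cls[i] <- classify_outcome(tr$t_open, protocol)$class
    if (keep_trajectories) trajs[[i]] <- tr
  }
  tab <- data.frame(Ri0 = Ri_values, t_open = t_open, class = cls,
                    stringsAsFactors = FALSE)
  pick <- function(cl, f) {
    v <- tab$Ri0[tab$class == cl]
    if (length(v)) f(v) else NA_real_
  }
  structure(list(
    table = tab,
    boundaries = list(max_no_germination = pick("no_germination", max),
                      min_second_pulse = pick("second_pulse", min),
                      min_first_pulse = pick("first_pulse", min)),
    trajectories = trajs), class = "gr_scan")
}

#' @export
print.gr_scan <- function(x, ...) {
  cat(sprintf("GR copy-number scan over %d values [%g, %g]:\n",
              nrow(x$table), min(x$table$Ri0), max(x$table$Ri0)))
  print(table(x$table$class))
  b <- x$boundaries
  cat(sprintf("  largest non-germinating Ri0: %g\n", b$max_no_germination))
  cat(sprintf("  smallest second-pulse Ri0:   %g\n", b$min_second_pulse))
  cat(sprintf("  smallest first-pulse Ri0:    %g\n", b$min_first_pulse))
  invisible(x)
}

#' Peak activated-closed channels and final open channels across a scan
#'
#' With the standard parameters only a handful of channels ever occupy the
#' activated-closed intermediate (signal amplification happens downstream,
#' through cooperative opening), so the scan-wide peak is a useful
#' fingerprint of the relay.
#'
#' @param scan A [gr_copy_scan()] result with trajectories retained.
#' @return List with `per_spore` (data frame: `Ri0`, `peak_cca`, `co_final`),
#'   `max_peak_cca` and `min_peak_cca`.
#' @export
peak_channel_activation <- function(scan) {
  stopifnot(inherits(scan, "gr_scan"))
  if (is.null(scan$trajectories))
    stop("scan was run without trajectory retention", call. = FALSE)
  per <- data.frame(
    Ri0 = scan$table$Ri0,
    peak_cca = vapply(scan$trajectories,
                      function(tr) max(tr$states[, "Cca"]), numeric(1)),
    co_final = vapply(scan$trajectories,
                      function(tr) tr$states[nrow(tr$states), "Co"],
                      numeric(1)))
  list(per_spore = per,
       max_peak_cca = max(per$peak_cca),
       min_peak_cca = min(per$peak_cca))
}

#' Germinant concentration scan over ensembles
#'
#' Re-runs a population ensemble for each pulse concentration, holding every
#' other setting (gamma distribution, kinetics, pulse timing, seed) fixed, so
#' differences in the pulse-window summaries are attributable to
#' concentration alone.
#'
#' @param S_values Germinant concentrations (mM, >= 0).
#' @param config An [ensemble_config()] template; its protocol's pulse
#'   concentrations are replaced by each `S` in turn, and the same seed is
#'   reused per concentration.
#' @param dt_out Output grid spacing.
#' @return Data frame with one row per concentration: `S_mM`,
#'   `first_window_pct`, `second_window_pct`, `horizon_pct`.
#' @export
concentration_scan <- function(S_values, config, dt_out = 0.1) {
  stopifnot(inherits(config, "ensemble_config"))
  if (any(S_values < 0)) stop("'S_values' must be >= 0", call. = FALSE)
  rows <- lapply(S_values, function(S) {
    pr <- config$protocol
    pr$pulses$concentration[] <- S
    cfg <- ensemble_config(config$gamma, config$params, pr,
                           n_spores = config$n_spores, seed = config$seed)
    ps <- pulse_summary(run_ensemble(cfg, dt_out = dt_out))
    data.frame(S_mM = S, first_window_pct = ps$first_window_pct,
               second_window_pct = ps$second_window_pct,
               horizon_pct = ps$horizon_pct)
  })
  do.call(rbind, rows)
}

#' Copy-number variance scan at fixed mean
#'
#' Varies the spread of the receptor copy-number distribution while holding
#' its mean fixed, recomputing the gamma parameters per standard deviation as
#' `a = (mean/sd)^2`, `b = sd^2/mean`. Wider distributions put more mass in
#' the high-copy tail, so more spores clear the first-pulse boundary.
#'
#' @param sd_values Standard deviations to scan (molecules/spore, > 0).
#' @param mean Fixed distribution mean (molecules/spore, > 0).
#' @param config An [ensemble_config()] template (its gamma spec is replaced
#'   per sd; seed reused).
#' @param dt_out Output grid spacing.
#' @return Data frame with one row per sd: `sd`, `shape`, `scale`,
#'   `first_window_pct`, `second_window_pct`, `horizon_pct`.
#' @export
variance_scan <- function(sd_values, mean, config, dt_out = 0.1) {
  stopifnot(inherits(config, "ensemble_config"))
  if (mean <= 0 || any(sd_values <= 0))
    stop("'mean' and 'sd_values' must be > 0", call. = FALSE)
  rows <- lapply(sd_values, function(sd) {
    g <- gamma_spec_from_moments(mean, sd)
    cfg <- ensemble_config(g, config$params, config$protocol,
                           n_spores = config$n_spores, seed = config$seed)
    ps <- pulse_summary(run_ensemble(cfg, dt_out = dt_out))
    data.frame(sd = sd, shape = g$shape, scale = g$scale,
               first_window_pct = ps$first_window_pct,
               second_window_pct = ps$second_window_pct,
               horizon_pct = ps$horizon_pct)
  })
  do.call(rbind, rows)
}
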