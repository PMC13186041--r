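#' Sample receptor copy numbers from a gamma distribution
#'
#' @param gamma A [gamma_spec()].
#' @param n Number of spores (>= 0).
#' @param seed Optional integer seed; when given, draws are reproducible.
#' @return Numeric vector of `n` gamma(shape, scale) variates, used as
#'   continuous initial `Ri0` copy numbers (no integer rounding — the ODEs
#'   treat copy numbers as continuous).
#' @examples
#' mean(sample_gr_counts(gamma_spec(25, 44), 1e4, seed = 1))  # ~1100
#' @export
sample_gr_counts <- function(gamma, n, seed = NULL) {
  stopifnot(inherits(gamma, "gamma_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 0)
    stop("'n' must be a single nonnegative count", call. = FALSE)
  if (n == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(n, shape = gamma$shape, scale = gamma$scale)
}

#' Maximum-likelihood gamma fit of copy-number draws
#'
#' Fits shape/scale by MLE (via [fitdistrplus::fitdist]) with asymptotic 95%
#' confidence intervals, mirroring how realized ensemble draws are summarized
#' alongside the generating distribution.
#'
#' @param draws Numeric vector of at least 10 positive draws with nonzero
#'   spread.
#' @return An object of class `gamma_fit`: list with `shape`, `scale`, their
#'   95% CIs (`shape_ci`, `scale_ci`), `mean`, `sd`, and the underlying
#'   `fitdistrplus` fit object.
#' @export
fit_gamma_mle <- function(draws) {
  if (!is.numeric(draws) || length(draws) < 10L)
    stop("need at least 10 draws to fit", call. = FALSE)
  if (any(!is.finite(draws)) || any(draws <= 0))
    stop("draws must all be positive and finite", call. = FALSE)
  if (stats::sd(draws) == 0)
    stop("draws are degenerate (zero variance); gamma fit is undefined",
         call. = FALSE)
  # fit on mean-normalized draws for numerical stability (shape is
  # scale-invariant; the scale estimate transforms back exactly)
  m <- mean(draws)
  y <- as.numeric(draws) / m
  # near-degenerate draws give a singular hessian; the point estimate is
  # still fine, so keep it and report NA intervals instead of warning
  fit <- suppressWarnings(fitdistrplus::fitdist(y, "gamma",
                                                start = moment_start(y)))
  est <- fit$estimate          # shape, rate (of the normalized data)
  se <- fit$sd
  if (is.null(se) || any(!is.finite(se))) se <- c(shape = NA_real_,
                                                  rate = NA_real_)
  z <- stats::qnorm(0.975)
  shape <- unname(est["shape"]); rate <- unname(est["rate"])
  scale <- m / rate
  # delta method for scale = m/rate
  scale_se <- m * unname(se["rate"]) / rate^2
  structure(list(
    shape = shape, scale = scale,
    shape_ci = shape + c(-1, 1) * z * unname(se["shape"]),
    scale_ci = scale + c(-1, 1) * z * scale_se,
    mean = shape * scale, sd = sqrt(shape) * scale,
    fit = fit), class = "gamma_fit")
}

moment_start <- function(x) {
  m <- mean(x); v <- stats::var(x)
  list(shape = m^2 / v, rate = m / v)
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("Gamma MLE fit: shape %.4f [%.4f, %.4f], scale %.4f [%.4f, %.4f]\n",
              x$shape, x$shape_ci[1], x$shape_ci[2],
              x$scale, x$scale_ci[1], x$scale_ci[2]))
  cat(sprintf("  estimated mean %.1f, sd %.1f molecules/spore\n", x$mean, x$sd))
  invisible(x)
}

#' Ensemble configuration
#'
#' @param gamma A [gamma_spec()] for the `Ri0` draws.
#' @param params A [kinetic_params()] shared by all spores (SpoVA copy
#'   numbers are identical across the population; only GR numbers vary).
#' @param protocol A [pulse_protocol()].
#' @param n_spores Ensemble size (default 500, one standard simulation cycle).
#' @param seed Integer seed; the single source of randomness for the cycle.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(gamma, params, protocol, n_spores = 500,
                            seed = 1) {
  stopifnot(inherits(gamma, "gamma_spec"), inherits(params, "kinetic_params"),
            inherits(protocol, "pulse_protocol"))
  if (!is.numeric(n_spores) || n_spores < 1)
    stop("'n_spores' must be >= 1", call. = FALSE)
  structure(list(gamma = gamma, params = params, protocol = protocol,
                 n_spores = as.integer(n_spores), seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Run a population ensemble (one simulation cycle)
#'
#' Draws `n_spores` receptor copy numbers from the gamma distribution, then
#' integrates each spore deterministically under the shared kinetics and
#' pulse protocol, records its threshold-crossing time and outcome class, and
#' fits a gamma distribution to the realized draws. All randomness comes from
#' `config$seed`, so identical configurations give bit-identical outcome
#' tables.
#'
#' @param config An [ensemble_config()].
#' @param dt_out Output grid spacing passed to [integrate_spore()].
#' @return An object of class `ensemble_result`: list with `records` (data
#'   frame: `spore_id`, `Ri0`, `t_open`, `class`), `fit` (a `gamma_fit` of
#'   the realized draws) and `config`.
#' @export
run_ensemble <- function(config, dt_out = 0.1) {
  stopifnot(inherits(config, "ensemble_config"))
  draws <- sample_gr_counts(config$gamma, config$n_spores, seed = config$seed)
  t_open <- numeric(config$n_spores)
  cls <- character(config$n_spores)
  for (i in seq_len(config$n_spores)) {
    tr <- tryCatch(
      integrate_spore(draws[i], config$params, config$protocol,
                      dt_out = dt_out),
      error = function(e) stop("spore ", i, " (Ri0 = ", signif(draws[i], 6),
                               "): ", conditionMessage(e), call. = FALSE))
    t_open[i] <- tr$t_open
    cls[i] <- classify_outcome(tr$t_open, config$protocol)$class
  }
  structure(list(
    records = data.frame(spore_id = seq_len(config$n_spores), Ri0 = draws,
                         t_open = t_open, class = cls,
                         stringsAsFactors = FALSE),
    fit = fit_gamma_mle(draws),
    config = config), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  tab <- table(factor(x$records$class,
                      levels = c("first_pulse", "second_pulse", "no_germination")))
  n <- nrow(x$records)
  cat(sprintf("Ensemble of %d spores (seed %d):\n", n, x$config$seed))
  for (nm in names(tab))
    cat(sprintf("  %-15s %4d  (%.1f%%)\n", nm, tab[[nm]], 100 * tab[[nm]] / n))
  invisible(x)
}

#' Cumulative percentage-germination curve
#'
#' The population observable of a germination experiment: the cumulative
#' distribution function of `T_open`, expressed as the percentage of the
#' whole population whose threshold crossing has occurred by time `t`.
#' Non-germinating spores (infinite `T_open`) stay in the denominator and
#' never contribute.
#'
#' @param result An [run_ensemble()] result.
#' @param grid Time grid in min (default: 0.25-min steps to the horizon).
#' @return An object of classes `germination_curve`/`data.frame` with
#'   columns `time_min` and `pct_germinated` (nondecreasing, in `[0, 100]`).
#' @export
germination_curve <- function(result, grid = NULL) {
  stopifnot(inherits(result, "ensemble_result"))
  if (nrow(result$records) == 0L) stop("empty ensemble result", call. = FALSE)
  if (is.null(grid))
    grid <- seq(0, result$config$protocol$horizon, by = 0.25)
  to <- result$records$t_open
  pct <- vapply(grid, function(t) 100 * mean(!is.na(to) & to <= t), numeric(1))
  structure(data.frame(time_min = grid, pct_germinated = pct),
            class = c("germination_curve", "data.frame"))
}

#' Pulse-window germination summary
#'
#' Splits germination between the pulse windows of a double-pulse protocol:
#' the first-window percentage (crossings before the second pulse starts, the
#' "asymptote after the 1st pulse"), the cumulative percentage at the horizon,
#' their difference (second-window increment), and the second-window
#' percentage among spores that survived the first window.
#'
#' @param result An [run_ensemble()] result.
#' @param protocol Protocol defining the windows (defaults to the one used).
#' @return List with `first_window_pct`, `horizon_pct`, `second_window_pct`
#'   and `second_among_survivors_pct`. For a single-pulse protocol only
#'   `horizon_pct` is meaningful; the window split is `NA`.
#' @export
pulse_summary <- function(result, protocol = result$config$protocol) {
  stopifnot(inherits(result, "ensemble_result"),
            inherits(protocol, "pulse_protocol"))
  to <- result$records$t_open
  n <- length(to)
  horizon_pct <- 100 * mean(!is.na(to))
  if (nrow(protocol$pulses) < 2L) {
    return(list(first_window_pct = NA_real_, horizon_pct = horizon_pct,
                second_window_pct = NA_real_,
                second_among_survivors_pct = NA_real_))
  }
  t2 <- protocol$pulses$start[2L]
  first <- 100 * mean(!is.na(to) & to < t2)
  survivors <- sum(is.na(to) | to >= t2)
  second_n <- sum(!is.na(to) & to >= t2)
  list(first_window_pct = first,
       horizon_pct = horizon_pct,
       second_window_pct = horizon_pct - first,
       second_among_survivors_pct =
         if (survivors > 0) 100 * second_n / survivors else NA_real_)
}
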