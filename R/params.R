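#' Kinetic parameters of the germination network
#'
#' Bundles the rate constants of the five-state germination network:
#' germinant receptors (GRs) in inactive (`Ri`) and active (`Ra`) states and
#' SpoVA channels in closed (`Cc`), activated-closed (`Cca`) and open (`Co`)
#' states. Channel opening carries a cooperative Hill-function positive
#' feedback term that makes the open-channel dynamics bistable.
#'
#' Units are minutes for time, mM for germinant concentration and
#' molecules/spore for copy numbers; rate constants are read in these units
#' (so `k4 = 195e2` means 19500 molecules/min). The defaults are the
#' wild-type L-valine memory parameter set used throughout.
#'
#' @param k1 Germinant binding rate constant (mM^-1 min^-1); converts an
#'   inactive GR to an active GR at rate `k1 * S * Ri`.
#' @param k_minus1 GR deactivation rate constant (min^-1).
#' @param k2 GR-to-channel activation rate constant (molecule^-1 min^-1);
#'   closed channels are activated at rate `k2 * Ra * Cc`.
#' @param k3 Activated-closed to open transition rate constant (min^-1).
#' @param k4 Maximum cooperative opening rate (molecules min^-1), the
#'   ceiling of the Hill production term.
#' @param k5 Open-channel closing rate constant (min^-1); closure returns
#'   channels to the inactive closed state.
#' @param n Hill coefficient (dimensionless, >= 1); `n > 1` gives the
#'   cooperativity required for bistability.
#' @param theta Hill half-saturation constant (molecules/spore); the open
#'   channel count at which cooperative production runs at half maximum.
#' @param c_total Total SpoVA channels per spore (`Cc + Cca + Co`).
#' @param germination_threshold Open-channel count whose first crossing
#'   defines the germination time `T_open`.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params()
#' p$k4  # 19500 molecules/min
#' @export
kinetic_params <- function(k1 = 14e-3, k_minus1 = 100e-3, k2 = 25e-7,
                           k3 = 60e-3, k4 = 195e2, k5 = 305e-2,
                           n = 3, theta = 20, c_total = 6500,
                           germination_threshold = 50) {
  p <- list(k1 = k1, k_minus1 = k_minus1, k2 = k2, k3 = k3, k4 = k4,
            k5 = k5, n = n, theta = theta, c_total = c_total,
            germination_threshold = germination_threshold)
  for (nm in c("k1", "k_minus1", "k2", "k3", "k4", "k5")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("rate constant '", nm, "' must be a single nonnegative number",
           call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("Hill coefficient 'n' must be >= 1", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("'theta' must be > 0", call. = FALSE)
  if (!is.numeric(c_total) || c_total <= 0)
    stop("'c_total' must be > 0", call. = FALSE)
  if (germination_threshold <= 0 || germination_threshold >= c_total)
    stop("'germination_threshold' must lie in (0, c_total)", call. = FALSE)
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (min, mM, molecules/spore):\n")
  cat(sprintf("  k1 = %g  k-1 = %g  k2 = %g  k3 = %g  k4 = %g  k5 = %g\n",
              x$k1, x$k_minus1, x$k2, x$k3, x$k4, x$k5))
  cat(sprintf("  Hill: n = %g, theta = %g;  channels: %g total, T_open threshold %g\n",
              x$n, x$theta, x$c_total, x$germination_threshold))
  invisible(x)
}

#' Gamma distribution of receptor copy numbers
#'
#' Spore-to-spore heterogeneity enters the model only through the initial
#' inactive GR copy number `Ri0`, drawn per spore from a gamma distribution
#' with shape `a` and scale `b` (mean `a*b`, sd `sqrt(a)*b`).
#'
#' @param shape Shape parameter `a` (> 0, dimensionless).
#' @param scale Scale parameter `b` (> 0, molecules/spore).
#' @return An object of class `gamma_spec` with fields `shape`, `scale`,
#'   `mean` and `sd`.
#' @examples
#' g <- gamma_spec(25, 44)
#' c(g$mean, g$sd)  # 1100, 220
#' @export
gamma_spec <- function(shape, scale) {
  if (!is.numeric(shape) || length(shape) != 1L || is.na(shape) || shape <= 0)
    stop("gamma 'shape' must be a single positive number", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    stop("gamma 'scale' must be a single positive number", call. = FALSE)
  structure(list(shape = shape, scale = scale,
                 mean = shape * scale, sd = sqrt(shape) * scale),
            class = "gamma_spec")
}

#' Gamma spec from mean and standard deviation
#'
#' Inverts the gamma moment identities `mean = a*b`, `sd = sqrt(a)*b`
#' to `a = (mean/sd)^2`, `b = sd^2/mean`. Used by the variance scans, which
#' hold the population mean fixed while the spread varies.
#'
#' @param mean Distribution mean (molecules/spore, > 0).
#' @param sd Distribution standard deviation (molecules/spore, > 0).
#' @return A [gamma_spec()].
#' @examples
#' gamma_spec_from_moments(1100, 220)  # shape 25, scale 44
#' @export
gamma_spec_from_moments <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("'mean' and 'sd' must be > 0", call. = FALSE)
  gamma_spec(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' @export
print.gamma_spec <- function(x, ...) {
  cat(sprintf("Gamma copy-number distribution: shape %g, scale %g (mean %g, sd %g)\n",
              x$shape, x$scale, x$mean, x$sd))
  invisible(x)
}
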