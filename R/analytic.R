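#' Steady-state fractional occupancy of active receptors
#'
#' Binding and dissociation of germinant alone give a two-state receptor
#' whose active fraction settles at `k1*S / (k_minus1 + k1*S)`.
#'
#' @param k1 Binding rate constant (mM^-1 min^-1).
#' @param S Germinant concentration (mM).
#' @param k_minus1 Deactivation rate constant (min^-1).
#' @return Fraction in `[0, 1]`.
#' @examples
#' steady_state_occupancy(350e-5, 10, 100e-3)  # 0.2593
#' steady_state_occupancy(14e-3, 3.5, 100e-3)  # 0.3289
#' @export
steady_state_occupancy <- function(k1, S, k_minus1) {
  if (any(c(k1, S, k_minus1) < 0))
    stop("'k1', 'S' and 'k_minus1' must be >= 0", call. = FALSE)
  denom <- k_minus1 + k1 * S
  if (denom == 0)
    stop("k1*S and k_minus1 cannot both be zero", call. = FALSE)
  k1 * S / denom
}

#' Characteristic receptor activation timescale
#'
#' `t_GR = 1 / (k1*S + k_minus1)`, the relaxation time with which the active
#' receptor pool approaches its steady state.
#'
#' @inheritParams steady_state_occupancy
#' @return Timescale in min.
#' @export
gr_timescale <- function(k1, S, k_minus1) {
  denom <- k1 * S + k_minus1
  if (denom <= 0)
    stop("k1*S + k_minus1 must be > 0", call. = FALSE)
  1 / denom
}

#' Closed-form active receptor trajectory under constant germinant
#'
#' With `S` constant and `Ra(0) = 0`, the receptor subsystem decouples and
#' solves to
#' `Ra(t) = R0 * k1*S/(k_minus1 + k1*S) * (1 - exp(-(k_minus1 + k1*S) * t))`,
#' rising monotonically to the steady state.
#'
#' @param t Time(s) in min, >= 0 (vectorized).
#' @param R0 Total receptor copies/spore.
#' @inheritParams steady_state_occupancy
#' @return `Ra(t)` in molecules/spore.
#' @export
ra_closed_form <- function(t, R0, k1, S, k_minus1) {
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  rate <- k_minus1 + k1 * S
  R0 * steady_state_occupancy(k1, S, k_minus1) * (1 - exp(-rate * t))
}

#' Reduced open-channel trajectory (no cooperativity, fast opening)
#'
#' In the limit of no cooperative feedback (`k4 = 0`) and very fast
#' activated-to-open conversion (large `k3`), with the receptor pool already
#' at a constant level `Ra`, the open-channel count follows
#' `Co(t) = (k2*Ra/beta) * c_total * (1 - exp(-beta*t))` with
#' `beta = k5 + k2*Ra`. The slow decay `beta` is what lets sub-threshold
#' open channels persist between pulses — the channel-borne memory.
#'
#' @param t Time(s) in min, >= 0 (vectorized).
#' @param Ra Constant active receptor count (molecules/spore).
#' @param k2 GR-to-channel activation rate constant (molecule^-1 min^-1).
#' @param k5 Channel closing rate constant (min^-1).
#' @param c_total Total channel copies/spore.
#' @return `Co(t)` in molecules/spore.
#' @export
co_reduced_closed_form <- function(t, Ra, k2, k5, c_total) {
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  beta <- k5 + k2 * Ra
  if (beta <= 0) stop("beta = k5 + k2*Ra must be > 0", call. = FALSE)
  (k2 * Ra / beta) * c_total * (1 - exp(-beta * t))
}

#' Fixed points of the generic autocatalytic switch
#'
#' Analyses the one-variable switch
#' `dX/dt = P + ks * X^n / (X^n + theta^n) - kd * X`,
#' the conceptual core of the channel-opening dynamics. All roots of the net
#' rate on `[0, (P + ks)/kd]` are located by a sign-change scan on a fine
#' grid followed by [stats::uniroot] refinement; stability comes from the
#' sign of the net-rate derivative at each root. The system is bistable when
#' at least two stable fixed points coexist.
#'
#' @param P Basal production rate (>= 0).
#' @param ks Maximum autocatalytic production rate (>= 0).
#' @param kd Linear decay rate (> 0).
#' @param n Hill coefficient (>= 1).
#' @param theta Half-saturation constant (> 0).
#' @param grid_n Number of scan points.
#' @return An object of class `switch_fixed_points`: list with `fixed_points`
#'   (data frame: `X`, `stability` in `{"stable", "unstable"}`) and
#'   `bistable` flag.
#' @examples
#' switch_fixed_points(P = 1, ks = 100, kd = 1, theta = 20, n = 3)
#' @export
switch_fixed_points <- function(P, ks, kd, n, theta, grid_n = 4000L) {
  if (kd <= 0) stop("'kd' must be > 0", call. = FALSE)
  if (P < 0 || ks < 0) stop("'P' and 'ks' must be >= 0", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (theta <= 0) stop("'theta' must be > 0", call. = FALSE)
  net <- function(x) P + ks * x^n / (x^n + theta^n) - kd * x
  upper <- (P + ks) / kd
  if (upper == 0) {  # P = ks = 0: only the origin
    return(structure(list(fixed_points = data.frame(X = 0,
                                                    stability = "stable"),
                          bistable = FALSE), class = "switch_fixed_points"))
  }
  xs <- seq(0, upper, length.out = grid_n)
  fs <- net(xs)
  roots <- xs[fs == 0]
  sign_change <- which(fs[-1L] * fs[-grid_n] < 0)
  for (i in sign_change)
    roots <- c(roots, stats::uniroot(net, c(xs[i], xs[i + 1L]),
                                     tol = 1e-10)$root)
  roots <- sort(unique(round(roots, 9)))
  if (length(roots) == 0L) roots <- upper   # net > 0 everywhere below cap
  h <- max(upper * 1e-7, 1e-9)
  slope <- vapply(roots, function(r) (net(r + h) - net(max(r - h, 0))) /
                    (r + h - max(r - h, 0)), numeric(1))
  stab <- ifelse(slope < 0, "stable", "unstable")
  structure(list(fixed_points = data.frame(X = roots, stability = stab),
                 bistable = sum(stab == "stable") >= 2L),
            class = "switch_fixed_points")
}

#' @export
print.switch_fixed_points <- function(x, ...) {
  cat("Fixed points of the autocatalytic switch:\n")
  print(x$fixed_points, row.names = FALSE)
  cat(if (x$bistable) "System is bistable.\n" else "System is monostable.\n")
  invisible(x)
}

#' Inner-membrane and germinosome geometry
#'
#' Approximates the spore inner membrane (IM) as a prolate ellipsoid with
#' surface area `A_im = 2*pi*(s^2 + l*s)`, spreads the SpoVA channel
#' complement uniformly over it, and asks how many channels a circular
#' germinosome patch of radius `r_ger` can contact directly. The default
#' semi-axes are electron-microscopy estimates for a typical spore.
#'
#' @param l Long semi-axis of the IM (nm).
#' @param s Short semi-axis of the IM (nm, `0 < s <= l`).
#' @param r_ger Germinosome radius (nm). The default 400 nm reproduces the
#'   published patch area of ~502,655 nm^2 (a 300 nm fluorescence FWHM is
#'   also quoted for the germinosome; the discrepancy is left to the caller,
#'   who can pass any radius).
#' @param c_total Total SpoVA channels per spore.
#' @param A_im Optional IM area override (nm^2); when supplied, downstream
#'   densities use it instead of the ellipsoid formula (the published area
#'   value is ~0.13% below the formula result for the default axes).
#' @return An object of class `im_geometry`: list with `l`, `s`, `A_im_formula`,
#'   `A_im` (the one used), `area_per_channel` (nm^2), `A_ger` (nm^2) and
#'   `germinosome_capacity` (ceiling of `A_ger / area_per_channel`, an
#'   "at most" count).
#' @examples
#' geo <- im_geometry()
#' geo$area_per_channel                       # ~744 nm^2 per channel
#' im_geometry(A_im = 4835800)$germinosome_capacity  # 676
#' @export
im_geometry <- function(l = 837, s = 554, r_ger = 400, c_total = 6500,
                        A_im = NULL) {
  if (!(s > 0 && l >= s)) stop("need l >= s > 0", call. = FALSE)
  if (r_ger <= 0) stop("'r_ger' must be > 0", call. = FALSE)
  A_formula <- 2 * pi * (s^2 + l * s)
  A_used <- if (is.null(A_im)) A_formula else A_im
  if (A_used <= 0) stop("'A_im' must be > 0", call. = FALSE)
  per_channel <- A_used / c_total
  A_ger <- pi * r_ger^2
  structure(list(l = l, s = s, A_im_formula = A_formula, A_im = A_used,
                 area_per_channel = per_channel, A_ger = A_ger,
                 germinosome_capacity = ceiling(A_ger / per_channel)),
            class = "im_geometry")
}

#' @export
print.im_geometry <- function(x, ...) {
  cat(sprintf("Inner-membrane ellipsoid (l = %g, s = %g nm):\n", x$l, x$s))
  cat(sprintf("  A_im = %.0f nm^2 (formula %.0f)\n", x$A_im, x$A_im_formula))
  cat(sprintf("  one channel per %.0f nm^2 of IM\n", x$area_per_channel))
  cat(sprintf("  germinosome area %.0f nm^2 -> at most %d channels\n",
              x$A_ger, x$germinosome_capacity))
  invisible(x)
}
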