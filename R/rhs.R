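#' Cooperative channel-opening rate (Hill production term)
#'
#' The positive feedback at the heart of the switch: open channels promote
#' the opening of further channels at rate `k4 * Co^n / (Co^n + theta^n)`,
#' bounded by `k4` and equal to `k4/2` at `Co = theta`. Defined as exactly 0
#' at `Co = 0` (no open channels, no feedback).
#'
#' @param Co Open-channel count (molecules/spore, >= 0; vectorized).
#' @param params A [kinetic_params()].
#' @return Production rate(s), molecules/min, in `[0, k4]`.
#' @examples
#' p <- kinetic_params()
#' hill_production(p$theta, p)  # k4 / 2
#' @export
hill_production <- function(Co, params) {
  stopifnot(inherits(params, "kinetic_params"))
  Co <- pmax(Co, 0)                      # guard tiny solver undershoots
  cn <- Co^params$n
  out <- params$k4 * cn / (cn + params$theta^params$n)
  out[Co == 0] <- 0
  out
}

# Derivatives of (Ri, Ra, Cc, Cca, Co) with a constant germinant
# concentration S. Mass-action kinetics; both conservation sums
# (Ri + Ra and Cc + Cca + Co) are zero by construction.
rhs_core <- function(y, S, p) {
  Ri <- y[1L]; Ra <- y[2L]; Cc <- y[3L]; Cca <- y[4L]; Co <- y[5L]
  bind <- p$k1 * S * Ri
  unbind <- p$k_minus1 * Ra
  activate <- p$k2 * Ra * Cc
  co_pos <- max(Co, 0)
  cn <- co_pos^p$n
  coop <- if (co_pos > 0) p$k4 * cn / (cn + p$theta^p$n) else 0
  open_lin <- p$k3 * Cca
  close <- p$k5 * Co
  c(-bind + unbind,
    bind - unbind,
    -activate - coop + close,
    activate - open_lin,
    open_lin + coop - close)
}

#' Right-hand side of the germination network ODEs
#'
#' Time derivatives of the five state variables under a pulse protocol:
#' \deqn{dRi/dt = -k_1 S Ri + k_{-1} Ra}
#' \deqn{dRa/dt = +k_1 S Ri - k_{-1} Ra}
#' \deqn{dCc/dt = -k_2 Ra Cc - k_4 Co^n/(Co^n+\theta^n) + k_5 Co}
#' \deqn{dCca/dt = k_2 Ra Cc - k_3 Cca}
#' \deqn{dCo/dt = k_3 Cca + k_4 Co^n/(Co^n+\theta^n) - k_5 Co}
#' with `S = pulse_concentration(protocol, t)`.
#'
#' @param state Named or positional numeric vector `(Ri, Ra, Cc, Cca, Co)`
#'   in molecules/spore.
#' @param t Time (min, >= 0).
#' @param params A [kinetic_params()].
#' @param protocol A [pulse_protocol()].
#' @return Named numeric vector of the five derivatives (molecules/min).
#' @examples
#' p <- kinetic_params()
#' pr <- double_pulse_protocol(3.5, 5)
#' germination_rhs(c(Ri = 1100, Ra = 0, Cc = 6500, Cca = 0, Co = 0), 2, p, pr)
#' @export
germination_rhs <- function(state, t, params, protocol) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(state) != 5L) stop("'state' must have 5 components", call. = FALSE)
  S <- pulse_concentration(protocol, t)
  d <- rhs_core(as.numeric(state), S, params)
  names(d) <- c("Ri", "Ra", "Cc", "Cca", "Co")
  d
}
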