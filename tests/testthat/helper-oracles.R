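# Independent oracles, written against the model equations directly and not
# against any package internals.

# Fixed-step classical RK4 integration of the five-state network under a
# square-wave germinant input. Steps never straddle a pulse edge because all
# edges are multiples of dt for the dt used here.
rk4_oracle <- function(Ri0, k1, k_minus1, k2, k3, k4, k5, n, theta,
                       c_total = 6500, pulses = rbind(c(0, 5, 3.5),
                                                      c(30, 35, 3.5)),
                       horizon = 60, dt = 0.001, save_every = 50L) {
  conc <- function(t) {
    for (r in seq_len(nrow(pulses)))
      if (t >= pulses[r, 1] && t < pulses[r, 2]) return(pulses[r, 3])
    0
  }
  deriv <- function(y, S) {
    hill <- if (y[5] > 0) k4 * y[5]^n / (y[5]^n + theta^n) else 0
    c(-k1 * S * y[1] + k_minus1 * y[2],
      k1 * S * y[1] - k_minus1 * y[2],
      -k2 * y[2] * y[3] - hill + k5 * y[5],
      k2 * y[2] * y[3] - k3 * y[4],
      k3 * y[4] + hill - k5 * y[5])
  }
  nsteps <- round(horizon / dt)
  y <- c(Ri0, 0, c_total, 0, 0)
  keep <- seq(0L, nsteps, by = save_every)
  out <- matrix(NA_real_, nrow = length(keep), ncol = 6L)
  colnames(out) <- c("time", "Ri", "Ra", "Cc", "Cca", "Co")
  out[1L, ] <- c(0, y)
  ki <- 2L
  t_open <- NA_real_
  prev_co <- y[5]
  for (step in seq_len(nsteps)) {
    t <- (step - 1L) * dt
    # steps are aligned with pulse edges, so S is constant within a step;
    # the midpoint value is that constant
    S <- conc(t + dt / 2)
    d1 <- deriv(y, S)
    d2 <- deriv(y + dt / 2 * d1, S)
    d3 <- deriv(y + dt / 2 * d2, S)
    d4 <- deriv(y + dt * d3, S)
    y <- y + dt / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
    if (is.na(t_open) && y[5] >= 50) {
      # linear interpolation inside the step
      t_open <- t + dt * (50 - prev_co) / (y[5] - prev_co)
    }
    prev_co <- y[5]
    if (step %in% keep) {
      out[ki, ] <- c(step * dt, y)
      ki <- ki + 1L
    }
  }
  list(table = out, t_open = t_open)
}

# default wild-type memory rate constants, written out once for the oracle
oracle_params <- list(k1 = 14e-3, k_minus1 = 100e-3, k2 = 25e-7, k3 = 60e-3,
                      k4 = 195e2, k5 = 305e-2, n = 3, theta = 20)

rk4_memory <- function(Ri0, horizon = 60, dt = 0.001, save_every = 50L) {
  do.call(rk4_oracle, c(list(Ri0 = Ri0, horizon = horizon, dt = dt,
                             save_every = save_every), oracle_params))
}
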