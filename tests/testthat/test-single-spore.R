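wt_params <- kinetic_params()
wt_protocol <- double_pulse_protocol(3.5, duration = 5)

test_that("trajectories conserve receptor and channel totals", {
  for (ri in c(900, 1500)) {
    tr <- integrate_spore(ri, wt_params, wt_protocol)
    tot_r <- rowSums(tr$states[, c("Ri", "Ra")])
    tot_c <- rowSums(tr$states[, c("Cc", "Cca", "Co")])
    expect_lt(max(abs(tot_r - ri)), 1e-6 * wt_params$c_total)
    expect_lt(max(abs(tot_c - wt_params$c_total)), 1e-6 * wt_params$c_total)
    expect_true(all(diff(tr$times) > 0))
    expect_true(all(tr$states > -1e-6))
  }
})

test_that("adaptive solver matches the fixed-step RK4 oracle", {
  # sup-norm over the shared grid, two representative receptor numbers
  for (ri in c(1200, 1500)) {
    oracle <- rk4_memory(ri, dt = 0.001, save_every = 50L)  # 0.05-min grid
    tr <- integrate_spore(ri, wt_params, wt_protocol, dt_out = 0.05)
    idx <- match(round(oracle$table[, "time"], 6), round(tr$times, 6))
    expect_false(anyNA(idx))
    dev <- abs(tr$states[idx, ] - oracle$table[, -1L])
    expect_lt(max(dev), 0.1)
  }
})

test_that("threshold crossing detection agrees with the oracle and handles edges", {
  oracle <- rk4_memory(1500)
  tr <- integrate_spore(1500, wt_params, wt_protocol)
  expect_lt(abs(tr$t_open - oracle$t_open), 0.05)
  expect_lt(tr$t_open, 30)

  # no stimulus, no crossing, Co identically zero
  quiet <- pulse_protocol(0, 5, 0, horizon = 60)
  tr0 <- integrate_spore(1500, wt_params, quiet)
  expect_true(is.na(tr0$t_open))
  expect_equal(max(abs(tr0$states[, "Co"])), 0)

  # low receptor numbers never germinate
  expect_true(is.na(integrate_spore(900, wt_params, wt_protocol)$t_open))

  # a threshold equal to the value at a grid point on the rising branch
  # is detected at (essentially) that grid time
  k <- which(tr$states[, "Co"] >= 50)[1L] + 5L   # well inside the blow-up
  expect_lt(abs(detect_threshold_crossing(tr, tr$states[k, "Co"]) -
                  tr$times[k]), 0.01)
})

test_that("outcomes split by which pulse triggers the crossing", {
  expect_equal(classify_outcome(NA, wt_protocol)$class, "no_germination")
  out1 <- classify_outcome(12, wt_protocol)
  expect_equal(out1$class, "first_pulse")
  expect_equal(out1$t_lag, 12 - 5)      # against end of first pulse
  out2 <- classify_outcome(40, wt_protocol)
  expect_equal(out2$class, "second_pulse")
  expect_equal(out2$t_lag, 40 - 35)
  # crossing inside the second pulse window is second_pulse
  expect_equal(classify_outcome(31, wt_protocol)$class, "second_pulse")
  expect_error(classify_outcome(10, pulse_protocol()), "at least one pulse")
  single <- pulse_protocol(0, 5, 3.5)
  expect_equal(classify_outcome(40, single)$class, "first_pulse")
})

test_that("t_open is nonincreasing in Ri0 over the germinating range", {
  ri <- seq(1000, 1800, by = 100)
  to <- vapply(ri, function(r)
    integrate_spore(r, wt_params, wt_protocol, dt_out = 0.1)$t_open,
    numeric(1))
  expect_false(anyNA(to))
  expect_true(all(diff(to) <= 1e-6))
})

test_that("channel-opening interval is constant across germinating spores", {
  tr1 <- integrate_spore(1500, wt_params, wt_protocol)
  tr2 <- integrate_spore(1700, wt_params, wt_protocol)
  r1 <- release_interval(tr1)
  r2 <- release_interval(tr2)
  expect_false(is.na(r1) || is.na(r2))
  expect_lt(abs(r1 - r2) / max(r1, r2), 0.2)

  # oracle check of the same quantity at Ri0 = 1500
  oracle <- rk4_memory(1500, save_every = 10L)   # 0.01-min oracle grid
  co <- oracle$table[, "Co"]
  i <- which(co >= 0.95 * 6500)[1L]
  t_plateau <- oracle$table[i - 1L, "time"] +
    (0.95 * 6500 - co[i - 1L]) / (co[i] - co[i - 1L]) * 0.01
  expect_lt(abs(r1 - (t_plateau - oracle$t_open)), 0.1)

  # no crossing, no interval
  expect_true(is.na(release_interval(integrate_spore(900, wt_params,
                                                     wt_protocol))))
})

test_that("memory persists even when active receptors fully relax between pulses", {
  alt <- kinetic_params(k_minus1 = 225e-3, k2 = 45e-7)
  for (ri in c(1100, 1250)) {
    tr <- integrate_spore(ri, alt, wt_protocol, dt_out = 0.05)
    before2 <- tr$times < 30
    ra <- tr$states[, "Ra"]
    expect_lt(ra[max(which(before2))], 0.01 * max(ra[before2]))
    expect_equal(classify_outcome(tr$t_open, wt_protocol)$class, "second_pulse")
  }
})
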