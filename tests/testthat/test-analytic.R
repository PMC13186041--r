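test_that("steady-state occupancy matches closed form and is monotone", {
  expect_equal(steady_state_occupancy(350e-5, 10, 100e-3), 0.035 / 0.135)
  expect_equal(round(100 * steady_state_occupancy(350e-5, 10, 100e-3), 1), 25.9)
  expect_equal(steady_state_occupancy(14e-3, 3.5, 100e-3), 0.049 / 0.149)
  expect_equal(steady_state_occupancy(1, 0, 0.1), 0)
  expect_error(steady_state_occupancy(0, 0, 0), "zero")

  s_grid <- seq(0, 20, by = 0.5)
  occ_s <- vapply(s_grid, function(s) steady_state_occupancy(14e-3, s, 0.1),
                  numeric(1))
  expect_true(all(diff(occ_s) > 0))
  expect_gt(steady_state_occupancy(2 * 14e-3, 3.5, 0.1),
            steady_state_occupancy(14e-3, 3.5, 0.1))
  expect_lt(steady_state_occupancy(14e-3, 3.5, 0.2),
            steady_state_occupancy(14e-3, 3.5, 0.1))
})

test_that("activation timescale is 1/(k1*S + k_minus1) and shrinks with S", {
  expect_equal(gr_timescale(14e-3, 3.5, 0.1), 1 / 0.149)
  expect_equal(gr_timescale(14e-3, 0, 0.1), 10)   # pure relaxation
  expect_lt(gr_timescale(14e-3, 7, 0.1), gr_timescale(14e-3, 3.5, 0.1))
  expect_error(gr_timescale(0, 0, 0), "> 0")
})

test_that("receptor closed form starts at zero, saturates, and solves its ODE", {
  k1 <- 14e-3; S <- 3.5; km1 <- 0.1; R0 <- 1100
  expect_equal(ra_closed_form(0, R0, k1, S, km1), 0)
  t_big <- 10 * gr_timescale(k1, S, km1)
  expect_equal(ra_closed_form(t_big, R0, k1, S, km1),
               R0 * steady_state_occupancy(k1, S, km1), tolerance = 1e-4)

  # numeric differentiation residual against its own ODE
  # dRa/dt = k1*S*(R0 - Ra) - km1*Ra
  h <- 1e-5
  for (t in c(0.5, 2, 8)) {
    lhs <- (ra_closed_form(t + h, R0, k1, S, km1) -
              ra_closed_form(t - h, R0, k1, S, km1)) / (2 * h)
    ra <- ra_closed_form(t, R0, k1, S, km1)
    rhs <- k1 * S * (R0 - ra) - km1 * ra
    expect_lt(abs(lhs - rhs) / (k1 * S * R0), 1e-6)
  }

  # matches the full network under constant S (single long pulse)
  p <- kinetic_params()
  pr <- pulse_protocol(0, 60, 3.5, horizon = 60)
  tr <- integrate_spore(1100, p, pr)
  for (t in c(1, 5)) {
    i <- which.min(abs(tr$times - t))
    expect_lt(abs(tr$states[i, "Ra"] -
                    ra_closed_form(tr$times[i], 1100, k1, S, km1)) /
                tr$states[i, "Ra"], 1e-6)
  }
})

test_that("reduced channel closed form solves its ODE and matches its limit", {
  k2 <- 25e-7; k5 <- 305e-2; Ra <- 362; ct <- 6500
  beta <- k5 + k2 * Ra
  expect_equal(co_reduced_closed_form(0, Ra, k2, k5, ct), 0)
  plateau <- (k2 * Ra / beta) * ct
  expect_equal(co_reduced_closed_form(1e4, Ra, k2, k5, ct), plateau)

  # residual of its own ODE, relative to the flux scale (the net rate
  # itself vanishes at the plateau, so it cannot serve as the denominator)
  h <- 1e-6
  for (t in c(0.3, 1, 5)) {
    lhs <- (co_reduced_closed_form(t + h, Ra, k2, k5, ct) -
              co_reduced_closed_form(t - h, Ra, k2, k5, ct)) / (2 * h)
    co <- co_reduced_closed_form(t, Ra, k2, k5, ct)
    rhs <- k2 * ct * Ra - beta * co
    expect_lt(abs(lhs - rhs) / (k2 * ct * Ra), 1e-6)
  }

  # limit of the full network: k4 = 0 (no cooperativity), k3 very large,
  # constant S; compare for t well beyond the receptor activation timescale
  p <- kinetic_params(k4 = 0, k3 = 1e3)
  pr <- pulse_protocol(0, 60, 3.5, horizon = 60)
  tr <- integrate_spore(1100, p, pr)
  ra_ss <- 1100 * steady_state_occupancy(p$k1, 3.5, p$k_minus1)
  t_gr <- gr_timescale(p$k1, 3.5, p$k_minus1)   # ~6.7 min
  late <- tr$times >= 8 * t_gr
  pred <- co_reduced_closed_form(tr$times[late], ra_ss, k2, k5, ct)
  expect_lt(max(abs(tr$states[late, "Co"] - pred) / pred), 0.01)
})

test_that("switch fixed points match a brute-force sign-change scan", {
  fp <- switch_fixed_points(P = 1, ks = 100, kd = 1, theta = 20, n = 3)
  # independent exhaustive scan at dX = 1e-3 over [0, 101]
  net <- function(x) 1 + 100 * x^3 / (x^3 + 20^3) - x
  xs <- seq(0, 101, by = 1e-3)
  fs <- net(xs)
  brute <- xs[which(fs[-1] * fs[-length(fs)] < 0)]
  expect_equal(nrow(fp$fixed_points), length(brute))
  expect_lt(max(abs(sort(fp$fixed_points$X) - brute)), 2e-3)
  expect_true(fp$bistable)
  expect_equal(fp$fixed_points$stability, c("stable", "unstable", "stable"))

  # ks = 0: unique stable balance point at P/kd
  fp0 <- switch_fixed_points(P = 3, ks = 0, kd = 1.5, theta = 20, n = 2)
  expect_equal(fp0$fixed_points$X, 2, tolerance = 1e-6)
  expect_equal(fp0$fixed_points$stability, "stable")
  expect_false(fp0$bistable)

  # P = 0 keeps the origin as a fixed point
  fpz <- switch_fixed_points(P = 0, ks = 50, kd = 1, theta = 20, n = 3)
  expect_true(any(abs(fpz$fixed_points$X) < 1e-9))

  # n = 1 with basal production: a single sign change (monostable),
  # cross-checked against the brute scan
  fp1 <- switch_fixed_points(P = 1, ks = 50, kd = 1, theta = 20, n = 1)
  net1 <- function(x) 1 + 50 * x / (x + 20) - x
  xs1 <- seq(0, 51, by = 1e-3)
  fs1 <- net1(xs1)
  expect_equal(nrow(fp1$fixed_points),
               sum(fs1[-1] * fs1[-length(fs1)] < 0))
  expect_false(fp1$bistable)
})

test_that("membrane geometry reproduces the channel density and germinosome cap", {
  # published area value: one channel per ~744 nm^2, at most 676 in the patch
  geo <- im_geometry(A_im = 4835800)
  expect_equal(geo$area_per_channel, 744, tolerance = 5e-4)
  expect_equal(geo$germinosome_capacity, 676)
  expect_equal(geo$A_ger, pi * 400^2)

  # ellipsoid formula with the default semi-axes lands within 0.2% of it
  geo2 <- im_geometry()
  expect_equal(geo2$A_im_formula, 2 * pi * (554^2 + 837 * 554))
  expect_lt(abs(geo2$A_im_formula - 4835800) / 4835800, 0.002)

  # degenerate sphere
  sph <- im_geometry(l = 500, s = 500)
  expect_equal(sph$A_im_formula, 4 * pi * 500^2)
  expect_error(im_geometry(l = 100, s = 200), "l >= s")
})
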