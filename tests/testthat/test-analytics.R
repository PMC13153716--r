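test_that("confinement rate matches the heating term and bounds the solver", {
  expect_equal(confinement_rate(7.62e5, 41.73, 1064, 4200), 14.2,
               tolerance = 3e-3)
  expect_equal(confinement_rate(0, 41.73, 1064, 4200), 0)
  # linear in I
  expect_equal(confinement_rate(2e5, 41.73, 1064, 4200),
               2 * confinement_rate(1e5, 41.73, 1064, 4200))

  # rate * exposure upper-bounds the diffusive focal temperature
  th <- dyn_thermal()
  grid <- dyn_grid()
  f <- intensity_field(evaluate_pressure(grid, t1_transducer(), t1_alpha()),
                       1064, 1540)
  rate_max <- confinement_rate(f$I_max, t1_alpha(), 1064, 4200)
  ctr <- (grid$dim + 1) / 2
  i4 <- match(0.4, th$times)
  expect_gte(rate_max * 0.4, th$dT[[i4]][ctr[1], ctr[2], ctr[3]])
})

test_that("resolution limit reproduces the improvement-factor endpoints", {
  expect_equal(resolution_limit(1, 3, 1)$improvement_factor, 7)
  expect_equal(resolution_limit(1, 4, 0.6)$improvement_factor, 14.33,
               tolerance = 1e-3)
  r <- resolution_limit(500, 0, 0.56)
  expect_equal(r$dX, 1 / 500)        # no switching benefit at dTth = 0
  expect_equal(r$improvement_factor, 1)
  z <- resolution_limit(0, 3, 1)
  expect_true(is.infinite(z$dX) && z$unresolved)

  # monotone in the threshold elevation, antitone in the bandwidth
  fs <- vapply(seq(0, 5, by = 0.5), function(d)
    resolution_limit(1, d, 0.56)$improvement_factor, numeric(1))
  expect_true(all(diff(fs) > 0))
  fs <- vapply(seq(0.2, 2, by = 0.2), function(bw)
    resolution_limit(1, 3, bw)$improvement_factor, numeric(1))
  expect_true(all(diff(fs) < 0))
})

test_that("pulse metrics give crossing times, width, and delay", {
  ag <- t1_agent()
  pm <- pulse_metrics(ag, 14.2)
  expect_equal(pm$dt_X12, 0)
  expect_equal(pm$dt_v, ag$T_BW / 14.2, tolerance = 1e-12)
  expect_equal(pm$dt_v, 0.039, tolerance = 0.01)
  expect_equal(pm$t_on[1], (ag$T_th - ag$T_BG) / 14.2, tolerance = 1e-12)
  expect_true(all(pm$t_on < pm$t_M & pm$t_M < pm$t_sa))

  pm2 <- pulse_metrics(ag, 14.2, 10.0, exposure = 0.15)
  expect_gt(pm2$dt_X12, 0)
  expect_equal(pm2$switched_within_exposure, c(TRUE, FALSE))
})

test_that("confinement timing is first-order consistent with the space limit", {
  # linearize the heating rate around a point with log-gradient g:
  # rate(x) = rate0 (1 - g x). To first order the peak delay between two
  # points dx apart is (T_M - T_BG) g dx / rate0, and the pulse width is
  # T_BW / rate0. Setting delay = width gives dx = T_BW / (g (T_M - T_BG)),
  # which is exactly twice the closed-form separation limit (whose bracket
  # uses the half-bandwidth T_BW/2).
  ag <- t1_agent()
  g <- 800
  rate0 <- 14.2
  dX <- resolution_limit(g, ag$T_th - ag$T_BG, ag$T_BW)$dX
  for (dx in c(dX, 2 * dX)) {
    rate2 <- rate0 * (1 - g * dx)
    pm <- pulse_metrics(ag, rate0, rate2)
    first_order <- (ag$T_M - ag$T_BG) * g * dx / rate0
    expect_equal(pm$dt_X12, first_order, tolerance = g * dx * 1.2)
  }
  # algebraic identity: the first-order delay/width ratio equals 1 exactly
  # at twice the closed-form separation limit, for any gradient
  for (gg in c(200, 800, 3000)) {
    dXg <- resolution_limit(gg, ag$T_th - ag$T_BG, ag$T_BW)$dX
    fo_ratio <- (ag$T_M - ag$T_BG) * gg * (2 * dXg) / ag$T_BW
    expect_equal(fo_ratio, 1, tolerance = 1e-12)
  }
})

test_that("log-intensity gradient matches an independent finite difference", {
  grid <- usf_grid(2.5e-5, 2.5e-5, 8.75e-5, 1e-3, 1e-3, 2e-3)
  f <- intensity_field(evaluate_pressure(grid, t1_transducer(), t1_alpha()),
                       1064, 1540)
  ctr <- (grid$dim + 1) / 2
  i0 <- which.min(abs(grid$x - 0.3e-3))
  lv <- log(f$I[, ctr[2], ctr[3]])
  ref <- abs((lv[i0 + 1] - lv[i0 - 1]) / (grid$x[i0 + 1] - grid$x[i0 - 1]))
  expect_equal(grad_log_intensity(f, "x", at = 0.3e-3), ref, tolerance = 1e-12)
  expect_gt(grad_log_intensity(f, "x", at = 0.3e-3),
            grad_log_intensity(f, "z", at = 0.3e-3))
})
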