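test_that("stable timestep follows the explicit-scheme bound", {
  tt <- t1_tissue()
  g <- usf_grid(50e-6, 50e-6, 175e-6, 1e-3, 1e-3, 1e-3)
  expect_equal(stable_timestep(g, tt, 0.9),
               0.9 / (2 * tt$alpha_th * (2 / 50e-6^2 + 1 / 175e-6^2)),
               tolerance = 1e-12)
  expect_equal(stable_timestep(g, tt, 0.9), 4.0e-3, tolerance = 0.01)

  gi <- usf_grid(1e-4, 1e-4, 1e-4, 1e-3, 1e-3, 1e-3)
  expect_equal(stable_timestep(gi, tt, 0.5), 0.5 * 1e-4^2 / (6 * tt$alpha_th),
               tolerance = 1e-12)
  gh <- usf_grid(5e-5, 5e-5, 5e-5, 1e-3, 1e-3, 1e-3)
  expect_equal(stable_timestep(gh, tt, 0.5), stable_timestep(gi, tt, 0.5) / 4,
               tolerance = 1e-12)
})

# without conduction and perfusion the focal update is an exact ODE
test_that("solver reduces to linear heating and exponential perfusion decay", {
  g <- usf_grid(1e-4, 1e-4, 1e-4, 3e-4, 3e-4, 3e-4)
  H0 <- 5e7
  src <- structure(list(H = array(H0, g$dim), exposure = 0.2, grid = g),
                   class = "heat_source")

  tt0 <- tissue_thermal(kt = 1e-12, omega_b = 1e-15)
  th <- solve_bioheat(src, tt0, g, c(0, 0.05, 0.1, 0.2))
  expect_equal(th$dT[[1]], array(0, g$dim))          # zero initial condition
  for (i in 2:4)
    expect_equal(max(th$dT[[i]]),
                 H0 * th$times[i] / (tt0$rho0 * tt0$Ct), tolerance = 1e-9)

  # uniform field + strong perfusion: dT(t) = H tau / (rho Ct) (1 - e^(-t/tau))
  # during heating, then pure exponential decay after the exposure
  ttp <- tissue_thermal(kt = 1e-12, omega_b = 0.5)
  thp <- solve_bioheat(src, ttp, g, c(0.2, 0.5, 0.8), safety = 0.01)
  ratio <- max(thp$dT[[3]]) / max(thp$dT[[2]])
  expect_equal(ratio, exp(-0.3 / ttp$tau), tolerance = 1e-3)
  sat <- H0 * ttp$tau / (ttp$rho0 * ttp$Ct)
  expect_equal(max(thp$dT[[1]]), sat * (1 - exp(-0.2 / ttp$tau)),
               tolerance = 1e-3)
})

test_that("heat is conserved with insulated boundaries and no perfusion", {
  g <- usf_grid(2e-4, 2e-4, 2e-4, 1.2e-3, 1.2e-3, 1.2e-3)
  co <- expand.grid(x = g$x, y = g$y, z = g$z)
  H <- 6e7 * exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * (0.3e-3)^2))
  dim(H) <- g$dim
  src <- structure(list(H = H, exposure = 0.4, grid = g),
                   class = "heat_source")
  tt <- tissue_thermal(omega_b = 1e-15)
  th <- solve_bioheat(src, tt, g, c(0.2, 0.4))
  for (i in 1:2) {
    stored <- tt$rho0 * tt$Ct * sum(th$dT[[i]]) * g$dV
    injected <- sum(H) * g$dV * th$times[i]
    expect_equal(stored / injected, 1, tolerance = 0.01)
  }
})

test_that("diffusive solution is bounded by the confinement closed form", {
  th <- dyn_thermal()
  grid <- dyn_grid()
  field <- evaluate_pressure(grid, t1_transducer(), t1_alpha())
  src <- heating_source(field, t1_alpha(), 1064, 1540, 0.4)
  tt <- t1_tissue()
  ctr <- (grid$dim + 1) / 2
  heating <- th$times[th$times > 0 & th$times <= 0.4]
  for (tq in heating[c(1, 10, 20, 40)]) {
    conf <- confinement_temperature(src, tt, tq)
    i <- match(tq, th$times)
    expect_lte(th$dT[[i]][ctr[1], ctr[2], ctr[3]],
               conf[ctr[1], ctr[2], ctr[3]] * (1 + 1e-12))
  }
  # confinement shape separates space and time: dT(r)/dT(0) == i_norm(r)
  f2 <- intensity_field(field, 1064, 1540)
  conf <- confinement_temperature(src, tt, 0.3)
  expect_equal(conf / max(conf), f2$i_norm, tolerance = 1e-12)
  expect_error(confinement_temperature(src, tt, 0.5), "exposure")

  # focal temperature is non-decreasing during the exposure, dT >= 0
  ctr_trace <- vapply(th$dT, function(u) u[ctr[1], ctr[2], ctr[3]], numeric(1))
  expect_true(all(diff(ctr_trace[th$times <= 0.4]) >= 0))
  expect_true(all(vapply(th$dT, min, numeric(1)) >= 0))
})

test_that("halving the time step leaves the focal peak essentially unchanged", {
  grid <- dyn_grid()
  field <- evaluate_pressure(grid, t1_transducer(), t1_alpha())
  src <- heating_source(field, t1_alpha(), 1064, 1540, 0.4)
  tt <- t1_tissue()
  a <- solve_bioheat(src, tt, grid, 0.4, safety = 0.9)
  b <- solve_bioheat(src, tt, grid, 0.4, safety = 0.45)
  expect_equal(max(a$dT[[1]]), max(b$dT[[1]]), tolerance = 0.005)
})

test_that("perfusion metrics give the soft-tissue time constant and losses", {
  pm <- perfusion_metrics(t1_tissue(), 0.4)
  expect_equal(pm$tau, 59, tolerance = 0.005)
  expect_equal(pm$attenuation_fraction, 0.007, tolerance = 0.05)
  expect_equal(pm$L_d, sqrt(4 * t1_tissue()$alpha_th * 0.4), tolerance = 1e-12)
  expect_equal(pm$L_d, 0.45e-3, tolerance = 0.04)
  tiny <- perfusion_metrics(t1_tissue(), 1e-9)
  expect_lt(tiny$attenuation_fraction, 1e-10)
  expect_lt(tiny$L_d, 1e-7)
})
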