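make_series <- function(scenario = "single_voxel", C0 = 4.4e-11, ...) {
  th <- dyn_thermal()
  map <- nanoagent_map(th$grid, scenario, C0 = C0, ...)
  usf_signal(th, map, t1_agent(), t1_geom(), t1_optics_ex(), t1_optics_fl(),
             t1_sd())
}

test_that("signal is baseline-subtracted and linear in concentration", {
  s1 <- make_series("single_voxel")
  su <- make_series("uniform")
  expect_equal(s1$phi[1], 0)
  expect_equal(su$phi[1], 0)

  s2 <- make_series("single_voxel", C0 = 2 * 4.4e-11)
  expect_equal(s2$phi, 2 * s1$phi, tolerance = 1e-10)
  v1 <- usf_velocity(s1)
  v2 <- usf_velocity(s2)
  expect_equal(v2$velocity, 2 * v1$velocity, tolerance = 1e-10)
})

test_that("single-voxel signal reduces to the closed one-point expression", {
  th <- dyn_thermal()
  s1 <- make_series("single_voxel")
  ag <- t1_agent()
  geom <- t1_geom()
  ex <- t1_optics_ex()
  fl <- t1_optics_fl()
  sd <- t1_sd()
  grid <- th$grid
  ctr <- (grid$dim + 1) / 2
  r <- c(0, 0, 0)
  ri <- mirror_across_ezb(r, geom)
  K <- ex$v * fl$v * sd$M0 * sd$epsilon_fl / ((4 * pi)^2 * ex$D * fl$D)
  gex <- excitation_fluence(geom, ex, r)$G
  kd <- gex * (emission_green(r, geom$r_D, fl) -
                 emission_green(ri, geom$r_D, fl))
  dT <- vapply(th$dT, function(u) u[ctr[1], ctr[2], ctr[3]], numeric(1))
  expected <- K * grid$dV * 4.4e-11 * kd *
    (quantum_yield(ag$T_BG + dT, ag) - quantum_yield(ag$T_BG, ag))
  expect_equal(s1$phi, unname(expected), tolerance = 1e-11)

  # the emission image term is present, positive, and smaller than the
  # direct term (it is sizeable because the detector sits on the surface,
  # close to the image emitter)
  g_dir <- gex * emission_green(r, geom$r_D, fl)
  g_img <- gex * emission_green(ri, geom$r_D, fl)
  expect_gt(g_img, 0)
  expect_lt(g_img, g_dir)
  # the excitation image source is likewise a genuine but sub-dominant
  # correction at the 10 mm-deep focus (image source ~3.8 mm farther)
  t_dir <- exp(-ex$mu_eff * sqrt(sum((geom$r_s - r)^2))) /
    sqrt(sum((geom$r_s - r)^2))
  t_img <- exp(-ex$mu_eff * sqrt(sum((geom$r_s_img - r)^2))) /
    sqrt(sum((geom$r_s_img - r)^2))
  expect_gt(t_img / t_dir, 0)
  expect_lt(t_img / t_dir, 0.5)
})

test_that("single-voxel signal plateaus while the uniform fill keeps rising", {
  s1 <- make_series("single_voxel")
  n1 <- s1$phi / max(s1$phi)
  tt <- s1$t
  # plateau reached before the end of the exposure and held through 0.52 s
  expect_gte(n1[match(0.39, tt)], 0.99)
  expect_gte(n1[match(0.52, tt)], 0.99)
  # non-decreasing while the focal temperature is non-decreasing
  heat <- which(tt <= 0.4)
  expect_true(all(diff(s1$dT_focal[heat]) >= 0))
  expect_true(all(diff(s1$phi[heat]) >= -1e-12 * max(s1$phi)))

  su <- make_series("uniform")
  expect_true(all(diff(su$phi[heat]) > 0))          # no saturation
  after <- match(c(0.4, 0.41, 0.42), tt)
  expect_true(all(diff(su$phi[after]) < 0))         # immediate fall

  # velocity of the single voxel: narrow positive pulse while heating,
  # peaking when the focal temperature crosses the transition midpoint,
  # then a broader negative pulse while cooling
  v1 <- usf_velocity(s1)
  ipk <- which.max(v1$velocity)
  expect_lt(tt[ipk], 0.4)
  ag <- t1_agent()
  t_cross <- tt[heat][which.min(abs(s1$dT_focal[heat] - (ag$T_M - ag$T_BG)))]
  expect_lt(abs(tt[ipk] - t_cross), 0.03)
  ineg <- which.min(v1$velocity)
  expect_gt(tt[ineg], 0.4)
  pos_w <- sum(v1$velocity > 0.5 * max(v1$velocity))
  neg_w <- sum(v1$velocity < 0.5 * min(v1$velocity))
  expect_gt(neg_w, pos_w)
})

test_that("numeric and analytic velocities agree on the sampling grid", {
  s1 <- make_series("single_voxel")
  vn <- usf_velocity(s1, "numeric")
  va <- usf_velocity(s1, "analytic")
  heat <- which(s1$t > 0 & s1$t < 0.4)
  err <- max(abs(vn$velocity[heat] - va$velocity[heat])) /
    max(abs(va$velocity[heat]))
  expect_lt(err, 0.03)

  const <- s1
  const$phi <- rep(1, length(s1$t))
  expect_true(all(usf_velocity(const)$velocity == 0))
  short <- s1
  short$t <- s1$t[1:2]
  short$phi <- s1$phi[1:2]
  expect_error(usf_velocity(short), "3 snapshots")
})

test_that("uniform-fill signal converges under grid refinement", {
  th1 <- dyn_thermal()
  fine <- usf_grid(0.5e-4, 0.5e-4, 1.75e-4, 1.5e-3, 1.5e-3, 4e-3)
  field <- evaluate_pressure(fine, t1_transducer(), t1_alpha())
  src <- heating_source(field, t1_alpha(), 1064, 1540, 0.4)
  th2 <- solve_bioheat(src, t1_tissue(), fine, c(0, 0.2, 0.4))

  args <- list(t1_agent(), t1_geom(), t1_optics_ex(), t1_optics_fl(), t1_sd())
  s1 <- do.call(usf_signal, c(list(th1, nanoagent_map(th1$grid, "uniform")),
                              args))
  s2 <- do.call(usf_signal, c(list(th2, nanoagent_map(fine, "uniform")), args))
  i1 <- match(c(0.2, 0.4), s1$t)
  expect_equal(s1$phi[i1], s2$phi[2:3], tolerance = 0.02)
})

test_that("surface maps peak on the source axis and are left-right symmetric", {
  th <- dyn_thermal()
  map <- nanoagent_map(th$grid, "single_voxel")
  m <- surface_map(th, map, t1_agent(), t1_geom(), t1_optics_ex(),
                   t1_optics_fl(), t1_sd(), t = 0.4,
                   raster_u = seq(-6e-3, 6e-3, by = 1.5e-3), normalize = TRUE)
  pk <- which(m$map == max(m$map), arr.ind = TRUE)
  expect_equal(m$u[pk[1]], 0)
  expect_equal(m$v[pk[2]], 0)
  expect_equal(m$map, m$map[rev(seq_along(m$u)), ], tolerance = 1e-10)
  expect_equal(m$map, m$map[, rev(seq_along(m$v))], tolerance = 1e-10)

  # plateau regime: maps at 0.4 s and 0.52 s agree pointwise after scaling
  m2 <- surface_map(th, map, t1_agent(), t1_geom(), t1_optics_ex(),
                    t1_optics_fl(), t1_sd(), t = 0.52,
                    raster_u = seq(-6e-3, 6e-3, by = 1.5e-3), normalize = TRUE)
  expect_lt(max(abs(m$map - m2$map)), 0.05)
})

test_that("two-point delay grows with separation and vanishes at zero", {
  th <- dyn_thermal()
  args <- list(thermal = th, agent = t1_agent(), geom = t1_geom(),
               optics_ex = t1_optics_ex(), optics_fl = t1_optics_fl(),
               sd = t1_sd())
  z0 <- do.call(two_point_experiment, c(list(separation = 0), args))
  expect_equal(z0$dt_X12, 0)
  expect_equal(z0$series_X1$phi, z0$series_X2$phi, tolerance = 1e-14)

  seps <- c(0.1e-3, 0.2e-3, 0.3e-3, 0.4e-3)
  delays <- vapply(seps, function(s)
    do.call(two_point_experiment, c(list(separation = s), args))$dt_X12,
    numeric(1))
  expect_true(all(delays > 0))
  expect_true(all(diff(delays) > 0))

  e3 <- do.call(two_point_experiment, c(list(separation = 0.3e-3), args))
  expect_lte(max(e3$velocity_X2$velocity), max(e3$velocity_X1$velocity))
  expect_gt(e3$dt_v, 0)
})
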