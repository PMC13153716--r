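sens_args <- function(orientation = "top") {
  list(agent = t1_agent(), geom = t1_geom(orientation),
       optics_ex = t1_optics_ex(), optics_fl = t1_optics_fl(), sd = t1_sd())
}

test_that("kernel and brute-force scan agree on a focal subgrid", {
  th <- dyn_thermal(times = seq(0, 0.4, by = 0.05))
  grid <- th$grid
  ctr <- (grid$dim + 1) / 2
  sub <- expand.grid(i = ctr[1] + (-4:4), j = ctr[2] + (-4:4),
                     k = ctr[3] + (-4:4))
  vox <- sub$i + grid$dim[1] * (sub$j - 1) +
    grid$dim[1] * grid$dim[2] * (sub$k - 1)
  a <- sens_args()
  Wk <- do.call(sensitivity_kernel, c(list(th), a, list(voxels = vox)))
  Ws <- do.call(sensitivity_scan, c(list(th), a, list(voxels = vox)))
  scale <- max(abs(Ws$W_signal))
  expect_lt(max(abs(Wk$W_signal - Ws$W_signal)) / scale, 1e-10)
  expect_lt(max(abs(Wk$W_velocity - Ws$W_velocity)) / max(abs(Ws$W_velocity)),
            1e-10)
})

test_that("signal weights are non-negative, growing, and focus-confined", {
  th <- dyn_thermal(times = seq(0, 0.4, by = 0.05))
  W <- do.call(sensitivity_kernel, c(list(th), sens_args()))
  expect_true(all(W$W_signal >= 0))
  # per-voxel growth in time during heating
  expect_true(all(apply(W$W_signal, 1, function(r) all(diff(r) >= -1e-300))))
  # voxels that never heat near the threshold carry ~no weight
  grid <- th$grid
  corner <- 1L  # grid corner, far outside the focus
  expect_lt(max(W$W_signal[corner, ]), 1e-6 * max(W$W_signal))

  # early frames: the strongest voxel sits on the focal axis, near the center
  i_early <- match(0.15, W$times)
  jmax <- which.max(W$W_signal[, i_early])
  co <- unname(W$coords[jmax, ])
  expect_equal(co[1], 0)
  expect_equal(co[2], 0)
  expect_lt(abs(co[3]), 1.1e-3)

  # late heating: the focal-center velocity weight has collapsed
  # (temperature far above saturation)
  ctr_vox <- (prod(grid$dim) + 1) / 2
  i_late <- match(0.4, W$times)
  expect_lt(abs(W$W_velocity[ctr_vox, i_late]),
            0.05 * max(abs(W$W_velocity[, i_late])))
})

test_that("velocity weights are sparser than signal weights, ring thicker in Z", {
  th <- dyn_thermal(times = seq(0, 0.4, by = 0.05))
  W <- do.call(sensitivity_kernel, c(list(th), sens_args()))
  sm_s <- support_metrics(W, 0.5, "signal")
  sm_v <- support_metrics(W, 0.5, "velocity")
  mid <- which(W$times >= 0.25 & W$times <= 0.4)
  expect_true(all(sm_v$support_fraction[mid] < sm_s$support_fraction[mid]))
  expect_true(all(sm_v$ring_z[mid] > sm_v$ring_x[mid]))
})

test_that("normalization modes scale without reordering", {
  th <- dyn_thermal(times = seq(0, 0.4, by = 0.1))
  W <- do.call(sensitivity_kernel, c(list(th), sens_args()))
  Wg <- normalize_sensitivity(W, "global")
  expect_equal(max(abs(Wg$W_signal)), 1)
  expect_equal(Wg$W_signal, W$W_signal / max(abs(W$W_signal)),
               tolerance = 1e-14)
  Wf <- normalize_sensitivity(W, "per_frame")
  late <- ncol(Wf$W_signal)
  expect_equal(max(abs(Wf$W_signal[, late])), 1)
  expect_error(normalize_sensitivity(Wg, "per_frame"), "already normalized")

  # support metrics are invariant to the normalization mode
  expect_equal(support_metrics(Wg, 0.5, "signal"),
               support_metrics(W, 0.5, "signal"), tolerance = 1e-12)
})

test_that("moving the SD pair shifts the weight toward the near half-volume", {
  th <- dyn_thermal(times = seq(0, 0.4, by = 0.1))
  Wt <- do.call(sensitivity_kernel, c(list(th), sens_args("top")))
  Wb <- do.call(sensitivity_kernel, c(list(th), sens_args("bottom")))
  zc <- Wt$coords[, 3]
  last <- ncol(Wt$W_signal)
  top_up <- sum(Wt$W_signal[zc < 0, last])
  top_dn <- sum(Wt$W_signal[zc > 0, last])
  bot_up <- sum(Wb$W_signal[zc < 0, last])
  bot_dn <- sum(Wb$W_signal[zc > 0, last])
  expect_gt(top_up, top_dn)   # SD above: shallow (z < 0) half dominates
  expect_gt(bot_dn, bot_up)   # SD below: deep half dominates
})

test_that("support metrics handle uniform and empty frames", {
  grid <- usf_grid(1e-4, 1e-4, 1e-4, 3e-4, 3e-4, 3e-4)
  n <- prod(grid$dim)
  W <- structure(list(
    W_signal = cbind(rep(1, n), rep(0, n)),
    W_velocity = cbind(rep(1, n), rep(0, n)),
    times = c(0, 0.1), voxels = seq_len(n),
    coords = matrix(0, n, 3), grid = grid,
    sd_label = "top", normalization = "raw"
  ), class = "sensitivity_matrix")
  sm <- support_metrics(W, 0.5, "signal")
  expect_equal(sm$support_fraction[1], 1)
  expect_false(sm$empty[1])
  expect_true(sm$empty[2])
  expect_equal(sm$ring_x[2], 0)
})
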