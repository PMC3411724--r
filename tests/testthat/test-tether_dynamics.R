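test_that("perpendicular wall drag has the closed-form limits", {
  eta <- 0.955e-3
  R <- 0.5
  stokes <- 6 * pi * eta * R * 1e-6
  ## h -> infinity: Stokes drag
  expect_equal(drag_coefficient_perpendicular(1e6, R, eta), stokes,
               tolerance = 1e-5)
  ## h = 2R: truncated series gives exactly 2x Stokes
  expect_equal(drag_coefficient_perpendicular(2 * R, R, eta), 2 * stokes,
               tolerance = 1e-12)
  ## monotone increasing towards the wall
  h <- seq(5, 0.6, length.out = 50)
  expect_true(all(diff(drag_coefficient_perpendicular(h, R, eta)) > 0))
  expect_error(drag_coefficient_perpendicular(0.4, R, eta), "exceed")
})

test_that("noise-free constant force converges to the WLC fixed point", {
  te <- tether_model(wlc_params(2.482, 50), bead_model(), F_0 = 3)
  pr <- sim_protocol(duration = 2, Z_start = 1, thermal = FALSE,
                     camera = NULL)
  tr <- simulate_trace(te, pr)
  z_eq <- wlc_extension_at_force(3, te$wlc)
  expect_equal(tail(tr$z, 1), z_eq, tolerance = 1e-6)
  expect_lt(sd(tail(tr$z, 100)), 1e-9)
})

test_that("thermal fluctuations satisfy equipartition against the analytic stiffness", {
  te <- tether_model(wlc_params(2.482, 50), bead_model(), F_0 = 1)
  pr <- sim_protocol(duration = 50, Z_start = 1, thermal = TRUE,
                     camera = NULL)
  tr <- simulate_trace(te, pr, seed = 11)
  k <- wlc_stiffness(wlc_extension_at_force(1, te$wlc), te$wlc) # pN/um
  var_expected <- kBT(te$wlc$temperature) / (k * 1e-6) * 1e12   # um^2
  expect_equal(var(tr$z), var_expected, tolerance = 0.1)
})

test_that("traces are reproducible under a seed and differ across seeds", {
  te <- tether_model(wlc_params(2.482, 50), bead_model(), F_0 = 2)
  pr <- sim_protocol(duration = 2, Z_start = 1, thermal = TRUE)
  t1 <- simulate_trace(te, pr, seed = 5)
  t2 <- simulate_trace(te, pr, seed = 5)
  t3 <- simulate_trace(te, pr, seed = 6)
  expect_identical(t1$z, t2$z)
  expect_gt(sd(t1$z - t3$z), 1e-4)
})

test_that("deterministic trajectory is converged in dt", {
  te <- tether_model(wlc_params(2.482, 50), bead_model(), F_0 = 6.4)
  ramp <- function(dt) {
    pr <- sim_protocol(duration = 20, dt = dt, Z_start = 1, v_mag = 0.1,
                       l_dec = 1.55, thermal = FALSE,
                       camera = camera_model(sigma_z = 0, sigma_xy = 0))
    simulate_trace(te, pr)$z
  }
  z1 <- ramp(1e-5)
  z2 <- ramp(5e-6)
  expect_lt(max(abs(z1 - z2) / z1), 1e-3)
})

test_that("the stability condition on dt is enforced", {
  te <- tether_model(wlc_params(2.482, 50), bead_model(), F_0 = 6.4)
  pr <- sim_protocol(duration = 1, dt = 5e-3, Z_start = 1, thermal = FALSE)
  expect_error(simulate_trace(te, pr), "stability")
})

test_that("drag force vanishes for a stationary magnet", {
  te <- tether_model(wlc_params(2.482, 50), bead_model(), F_0 = 2)
  pr <- sim_protocol(duration = 2, Z_start = 1, v_mag = 0, thermal = FALSE,
                     camera = NULL)
  dp <- drag_force_profile(te, pr)
  ## after the (instantaneous) equilibration, drag is numerically zero
  expect_lt(max(tail(dp$F_drag, nrow(dp) - 10)), 1e-6)
})

test_that("attachment offset transforms are identity at A = 0 and invertible", {
  te0 <- tether_model(wlc_params(2.482, 50), bead_model(radius = 0.5),
                      A = 0, F_0 = 6)
  pr <- sim_protocol(duration = 10, Z_start = 1, v_mag = 0.1, l_dec = 1.54,
                     thermal = FALSE,
                     camera = camera_model(sigma_z = 0, sigma_xy = 0))
  cv0 <- apparent_response_with_offset(te0, pr)
  tr <- simulate_trace(te0, pr)
  expect_equal(cv0$extension, tr$z, tolerance = 1e-9)
  ## with A > 0, the measured lengths come back after the correction
  teA <- tether_model(wlc_params(2.482, 50), bead_model(radius = 0.5),
                      A = 0.3, F_0 = 6)
  cvA <- apparent_response_with_offset(teA, pr)
  expect_equal(apply_attachment_correction(cvA$extension, 0.3), tr$z,
               tolerance = 1e-9)
})

test_that("camera model averages the exposure and adds tracking noise", {
  te <- tether_model(wlc_params(2.482, 50), bead_model(), F_0 = 2)
  pr_raw <- sim_protocol(duration = 10, Z_start = 1, thermal = TRUE,
                         camera = NULL)
  pr_cam <- sim_protocol(duration = 10, Z_start = 1, thermal = TRUE,
                         camera = camera_model(sigma_z = 0, sigma_xy = 0))
  raw <- simulate_trace(te, pr_raw, seed = 3)
  cam <- simulate_trace(te, pr_cam, seed = 3)
  expect_equal(nrow(cam), 10 * 50)
  ## motion blur: frame-averaged variance is attenuated
  expect_lt(var(cam$z), var(raw$z))
  expect_equal(mean(cam$z), mean(raw$z), tolerance = 0.01)
})
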