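test_that("Limacon degenerates to single circles when one radius vanishes", {
  tt <- seq(0, 4, by = 0.005)
  ## R_prec = 0: circle of radius R_att at omega_mag
  p1 <- limacon_params(R_att = 0.12, R_prec = 0, omega_mag = pi)
  c1 <- limacon_curve(p1, tt)
  r1 <- sqrt(c1$x^2 + c1$y^2)
  expect_equal(range(r1), c(0.12, 0.12), tolerance = 1e-12)
  ## R_att = 0: circle of radius R_prec at 2 omega_mag
  p2 <- limacon_params(R_att = 0, R_prec = 0.25, omega_mag = pi)
  c2 <- limacon_curve(p2, tt)
  expect_equal(sqrt(c2$x^2 + c2$y^2), rep(0.25, length(tt)),
               tolerance = 1e-12)
  ## periodicity with the magnet turn period
  p3 <- limacon_params(0.12, 0.05, 0.4, 1.2, c(1, 2), omega_mag = pi)
  expect_equal(limacon_curve(p3, 0)[, c("x", "y")],
               limacon_curve(p3, 2)[, c("x", "y")], tolerance = 1e-12)
})

test_that("inner-loop criterion agrees with a brute-force self-intersection scan", {
  tt <- seq(0, 2, length.out = 721) # one full turn, closed
  ## R_att = 0 is excluded from the scan: the curve degenerates to a
  ## circle traversed twice, which the segment scan cannot distinguish
  ## from a crossing (the rule itself is asserted below)
  cases <- expand.grid(R_att = c(0.04, 0.12, 0.3, 0.5),
                       R_prec = c(0, 0.02, 0.05, 0.25, 0.4))
  for (i in seq_len(nrow(cases))) {
    p <- limacon_params(cases$R_att[i], cases$R_prec[i], omega_mag = pi)
    geom <- curve_self_intersects(limacon_curve(p, tt))
    expect_identical(has_inner_loop(p), geom,
                     label = sprintf("R_att=%g R_prec=%g: has_inner_loop",
                                     cases$R_att[i], cases$R_prec[i]))
  }
  ## the printed examples
  expect_true(has_inner_loop(limacon_params(0.12, 0.25)))
  expect_false(has_inner_loop(limacon_params(0.12, 0.02)))
  expect_false(has_inner_loop(limacon_params(0, 0.3)))
})

test_that("noise-free Limacon fit recovers parameters exactly", {
  p <- limacon_params(0.12, 0.25, phi_att = 0.7, phi_prec = -1.2,
                      center = c(5, -3), omega_mag = pi)
  tt <- seq(0, 8, by = 0.02)
  fit <- fit_limacon(limacon_curve(p, tt), pi)
  expect_equal(fit$R_att, p$R_att, tolerance = 1e-9)
  expect_equal(fit$R_prec, p$R_prec, tolerance = 1e-9)
  expect_equal(fit$center, p$center, tolerance = 1e-9)
  expect_equal(fit$phi_att, p$phi_att, tolerance = 1e-9)
  ## a pure circle comes back as R_prec = 0
  pc <- limacon_params(0.12, 0, omega_mag = pi)
  fc <- fit_limacon(limacon_curve(pc, tt), pi)
  expect_lt(fc$R_prec, 1e-12)
  expect_equal(fc$R_att, 0.12, tolerance = 1e-9)
  ## too little data is rejected
  expect_error(fit_limacon(limacon_curve(p, seq(0, 1, by = 0.02)), pi),
               "two full magnet turns")
})

test_that("Limacon fit is accurate and unbiased at the tracking noise level", {
  ## 4 turns at 50 Hz with sigma_xy = 2.2 nm, 100 seeds
  p <- limacon_params(0.12, 0.08, phi_att = 0.3, phi_prec = 2.1,
                      center = c(1, 1), omega_mag = pi)
  tt <- seq(0, 8, by = 0.02)
  base <- limacon_curve(p, tt)
  ests <- t(vapply(1:100, function(s) {
    set.seed(s)
    tr <- base
    tr$x <- tr$x + rnorm(nrow(tr), 0, 0.0022)
    tr$y <- tr$y + rnorm(nrow(tr), 0, 0.0022)
    fit <- fit_limacon(tr, pi)
    c(fit$R_att, fit$R_prec)
  }, numeric(2)))
  expect_lt(max(abs(ests[, 1] - p$R_att)), 3e-3)
  expect_lt(max(abs(ests[, 2] - p$R_prec)), 3e-3)
  ## bias below 0.5 nm
  expect_lt(abs(mean(ests[, 1]) - p$R_att), 5e-4)
  expect_lt(abs(mean(ests[, 2]) - p$R_prec), 5e-4)
})

test_that("attachment offset geometry round-trips and matches the worked example", {
  expect_equal(attachment_offset_from_radius(0, 0.525), 0)
  expect_equal(attachment_offset_from_radius(0.525, 0.525), 0.525)
  ## R_att = 0.102 um on a MyOne bead hides about 10 nm of tether
  expect_equal(attachment_offset_from_radius(0.102, 0.525), 0.0100,
               tolerance = 1e-3)
  expect_error(attachment_offset_from_radius(0.6, 0.525), "R_att")
  ## round trip through the inverse relation
  A <- c(0.01, 0.1, 0.3)
  R_att <- sqrt(0.525^2 - (0.525 - A)^2)
  expect_equal(attachment_offset_from_radius(R_att, 0.525), A,
               tolerance = 1e-12)
})

test_that("attachment-offset density normalizes, vanishes at A = R and matches its CDF", {
  R <- 0.525
  I <- integrate(function(a) attachment_offset_pdf(a, R), 0, R,
                 rel.tol = 1e-9)
  expect_equal(I$value, 1, tolerance = 1e-6)
  expect_equal(attachment_offset_pdf(R, R), 0)
  expect_gt(attachment_offset_pdf(1e-6, R), 100) # integrable divergence at 0
  ## CDF is the antiderivative of the density
  a <- seq(0.01, 0.5, by = 0.01)
  h <- 1e-6
  dcdf <- (attachment_offset_cdf(a + h, R) -
             attachment_offset_cdf(a - h, R)) / (2 * h)
  expect_equal(dcdf, attachment_offset_pdf(a, R), tolerance = 1e-4)
})

test_that("density matches Monte-Carlo sphere sampling (KS < 0.002 at 1e6)", {
  ## oracle construction: uniform points on the sphere, bead free to rotate
  ## about the horizontal easy axis, offset A = R (1 - sin(alpha))
  R <- 0.525
  set.seed(99)
  n <- 1e6
  cos_alpha <- runif(n, -1, 1) # cosine of the angle to the easy axis
  A_mc <- R * (1 - sqrt(1 - cos_alpha^2))
  ks <- suppressWarnings(
    ks.test(A_mc, function(a) attachment_offset_cdf(a, R)))
  expect_lt(unname(ks$statistic), 0.002)
})

test_that("offset sampler is reproducible and matches the density mean", {
  R <- 0.525
  s1 <- sample_attachment_offsets(1000, R, seed = 7)
  s2 <- sample_attachment_offsets(1000, R, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= R))
  ## quadrature oracle for the mean, 1e6 samples within 3 standard errors
  m_exact <- integrate(function(a) a * attachment_offset_pdf(a, R), 0, R,
                       rel.tol = 1e-10)$value
  s <- sample_attachment_offsets(1e6, R, seed = 123)
  expect_lt(abs(mean(s) - m_exact), 3 * sd(s) / sqrt(1e6))
})

test_that("predicted precession radius grows with distance and field proximity", {
  asm <- default_assembly
  bead <- default_bead
  te <- tether_model(wlc_params(6.834, 50), bead, F_0 = 4)
  d <- c(0, 50, 100, 150)
  r1 <- predict_precession_radius(d, 1, asm, bead, te)
  expect_equal(r1[1], 0)
  expect_true(all(diff(r1) > 0))
  ## stronger dependence for a lower magnet height
  r02 <- predict_precession_radius(150, 0.2, asm, bead, te)
  expect_gt(r02, r1[4])
})

test_that("frequency doubling: rotation pattern has power only at omega and 2 omega", {
  p <- limacon_params(0.12, 0.25, omega_mag = pi)
  tt <- seq(0, 16 - 0.02, by = 0.02) # 8 turns at 50 Hz
  cv <- limacon_curve(p, tt)
  set.seed(4)
  xs <- cv$x - mean(cv$x) + rnorm(length(tt), 0, 0.0022)
  sp <- Mod(fft(xs))^2
  freq <- (seq_along(xs) - 1) / (length(xs) * 0.02) # Hz
  f_mag <- pi / (2 * pi)
  half <- freq <= 25
  peaks <- freq[half][sp[half] > 0.01 * max(sp[half])]
  expect_true(all(vapply(peaks, function(f)
    min(abs(f - c(f_mag, 2 * f_mag))) < 0.15, logical(1))))
})
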