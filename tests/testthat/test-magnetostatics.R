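test_that("sheet field matches the brute-force quadrature oracle", {
  sheet <- list(xlim = c(-2, 3), ylim = c(-1, 4), z0 = 0.5, sigma = 1.2)
  set.seed(42)
  pts <- cbind(runif(10, -6, 6), runif(10, -6, 6), runif(10, -8, -1))
  B <- sheet_field(pts, sheet)
  Bo <- oracle_sheet_field(pts, sheet, n = 1200)
  expect_lt(max(abs(B - Bo) / sqrt(rowSums(Bo^2))), 1e-3)
})

test_that("sheet field is linear in charge density and zero at zero charge", {
  sheet <- list(xlim = c(-1, 1), ylim = c(-1, 1), z0 = 0, sigma = 0)
  p <- c(0.3, -0.4, -2)
  expect_equal(sheet_field(p, sheet), c(0, 0, 0))
  sheet$sigma <- 0.7
  B1 <- sheet_field(p, sheet)
  sheet$sigma <- 1.4
  expect_equal(sheet_field(p, sheet), 2 * B1, tolerance = 1e-12)
})

test_that("far-field of a sheet approaches the point-charge law", {
  side <- 1
  sheet <- list(xlim = c(-side / 2, side / 2), ylim = c(-side / 2, side / 2),
                z0 = 0, sigma = 1)
  d <- 20 * side
  B <- sheet_field(c(0, 0, -d), sheet)
  Q <- sheet$sigma * side^2
  expect_equal(abs(B[3]), Q / (4 * pi * d^2) * 1e3, tolerance = 0.01)
  expect_equal(B[1:2], c(0, 0), tolerance = 1e-12)
})

test_that("mirror-symmetric points give mirrored sheet fields", {
  sheet <- list(xlim = c(-1, 1), ylim = c(-2, 2), z0 = 0, sigma = 1)
  Bp <- sheet_field(c(0.7, 0.3, -1.5), sheet)
  Bm <- sheet_field(c(-0.7, 0.3, -1.5), sheet)
  expect_equal(Bm, c(-Bp[1], Bp[2], Bp[3]), tolerance = 1e-12)
})

test_that("evaluation on the sheet itself is rejected as singular", {
  sheet <- list(xlim = c(-1, 1), ylim = c(-1, 1), z0 = 0, sigma = 1)
  expect_error(sheet_field(c(0.2, 0.1, 0), sheet), "singular")
})

test_that("total field of the antiparallel pair has the required symmetries", {
  asm <- default_assembly
  ## vertical component vanishes on the rotation axis
  B0 <- total_field(c(0, 0, -400), asm, Z_mag = 1)
  expect_lt(abs(B0[3]), 1e-12 * sqrt(sum(B0^2)))
  ## half-turn flips polarity, preserves magnitude
  asm_pi <- magnet_assembly(rotation_angle = pi)
  p <- c(150, -80, -400)
  B <- total_field(p, asm, 1)
  Bpi <- total_field(p, asm_pi, 1)
  expect_equal(Bpi, -B, tolerance = 1e-9)
  ## doubling the remanence doubles the field
  asm2 <- magnet_assembly(remanence = 2.8)
  expect_equal(total_field(p, asm2, 1), 2 * B, tolerance = 1e-12)
})

test_that("field is divergence-free away from the sheets", {
  asm <- default_assembly
  h <- 1 # um
  for (p in list(c(50, 30, -400), c(-120, 80, -700), c(0, 0, -1500))) {
    div <- 0
    for (k in 1:3) {
      e <- c(0, 0, 0); e[k] <- h
      div <- div + (total_field(p + e, asm, 1)[k] -
                    total_field(p - e, asm, 1)[k]) / (2 * h)
    }
    Bmag <- sqrt(sum(total_field(p, asm, 1)^2))
    expect_lt(abs(div), 1e-6 * Bmag / h)
  }
})

test_that("Langevin bead moment has the correct limits and shape", {
  bead <- default_bead
  expect_equal(bead_moment(0, bead), 0)
  m_sat <- bead$volume * bead$M_sat * 1e3
  expect_equal(bead_moment(1e5, bead), m_sat, tolerance = 1e-3)
  ## closed-form value at B = B_0: coth(1) - 1
  expect_equal(bead_moment(bead$B_0, bead) / m_sat, 0.3130352854993312,
               tolerance = 1e-12)
  ## monotone increasing
  m <- bead_moment(seq(0, 100, length.out = 200), bead)
  expect_true(all(diff(m) > 0))
  ## low-field linear susceptibility m ~ V M_sat B / (3 B_0)
  B <- seq(1e-3, 0.1 * bead$B_0, length.out = 20)
  expect_lt(max(abs(bead_moment(B, bead) / (m_sat * B / (3 * bead$B_0)) - 1)),
            0.01)
})

test_that("force symmetries: no lateral force on axis, reflection antisymmetry", {
  asm <- default_assembly
  bead <- default_bead
  F0 <- bead_force(c(0, 0, -400), asm, bead, 1)
  expect_lt(max(abs(F0[1:2])), 1e-9 * abs(F0[3]))
  Fp <- bead_force(c(120, 40, -400), asm, bead, 1)
  Fm <- bead_force(c(-120, 40, -400), asm, bead, 1)
  expect_equal(Fm[1], -Fp[1], tolerance = 1e-6)
  expect_equal(abs(Fm[3]), abs(Fp[3]), tolerance = 1e-9)
})

test_that("on-axis force decreases monotonically over the measurement range", {
  fc <- force_vs_height(default_assembly, default_bead, c(1, 20), 30)
  expect_true(all(diff(fc$F_z) < 0))
})

test_that("near saturation the force scales with the remanence", {
  bead <- default_bead
  f1 <- force_vs_height(default_assembly, bead, c(0.5, 2), 5)
  asm_s <- magnet_assembly(remanence = 1.4 * 1.2)
  f2 <- force_vs_height(asm_s, bead, c(0.5, 2), 5)
  expect_lt(max(abs(f2$F_z / f1$F_z - 1.2)), 0.05 * 1.2)
})

test_that("force angle is zero on axis and defined in degrees", {
  asm <- default_assembly
  bead <- default_bead
  expect_equal(force_angle(0, 0, 1, asm, bead), 0, tolerance = 1e-6)
  a <- force_angle(200, 0, 1, asm, bead)
  expect_gt(a, 0)
  expect_lt(a, 90)
})

test_that("force-map variation decreases with magnet height and vanishes with the FOV", {
  asm <- default_assembly
  bead <- default_bead
  v <- vapply(c(0, 0.5, 1, 2), function(zm)
    force_map(asm, bead, zm, fov_extent = 400, grid_n = 11)$variation_Fz,
    numeric(1))
  expect_true(all(diff(v) < 0))
  v_small <- force_map(asm, bead, 1, fov_extent = 4, grid_n = 11)$variation_Fz
  expect_lt(v_small, 0.01)
})

test_that("exponential decay fit recovers exact synthetic parameters", {
  zs <- seq(1, 8, length.out = 40)
  tb <- data.frame(Z_mag = zs, F_z = 3.2 * exp(-(zs - 1) / 1.7))
  fit <- fit_force_decay(tb)
  expect_equal(fit$F_0, 3.2, tolerance = 1e-9)
  expect_equal(fit$l_dec, 1.7, tolerance = 1e-9)
  expect_lt(fit$max_rel_err, 1e-7)
  expect_error(fit_force_decay(tb[1:5, ]), "at least 10")
})

test_that("central-difference force is converged in the step size", {
  p <- c(100, 50, -400)
  F1 <- bead_force(p, default_assembly, default_bead, 1, step = 1)
  F2 <- bead_force(p, default_assembly, default_bead, 1, step = 0.5)
  expect_lt(max(abs(F2 - F1)) / sqrt(sum(F1^2)), 1e-4)
})
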