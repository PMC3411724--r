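## Charge-sheet magnetostatics of the antiparallel permanent-magnet pair.
##
## The two magnets are modelled as uniformly magnetized blocks whose field is
## generated by fictitious magnetic surface charge on their top and bottom
## faces (Coulomb analogy).  The field of a uniformly charged rectangle has a
## closed form in arctan/log terms, so the total field is the signed sum of
## four sheet contributions and is exact for this geometry.
##
## Coordinate frame: origin on the rotation axis at the flow-cell top
## surface, z pointing up toward the magnets.  The gap axis is x when
## rotation_angle = 0.  Field-of-view positions are in micrometres; magnet
## geometry and Z_mag (bottom face of the magnets to flow-cell top) are in
## millimetres.

#' Magnet-pair assembly
#'
#' Geometry and magnetization of the vertically magnetized, antiparallel
#' permanent-magnet pair used to apply force in magnetic tweezers.
#'
#' The magnet dimensions are not a measured quantity here but an assumed
#' configuration (cube magnets of 5 mm side with remanent field 1.4 T and a
#' 2 mm gap, the standard magnet-pair layout for this instrument class); all
#' geometry is configurable.  `bead_depth` is the vertical distance from the
#' flow-cell top surface (the reference plane of `Z_mag`) down to the bead:
#' top cover glass (0.17 mm) plus channel height (0.23 mm).
#'
#' @param width,depth,height Magnet block dimensions in mm (x, y, z extents
#'   at `rotation_angle = 0`).
#' @param gap Distance between the inner magnet faces, mm. Must be positive.
#' @param remanence Remanent field of the magnet material, T. Converted
#'   internally to the fictitious sheet charge density.
#' @param rotation_angle Rotation of the pair about the vertical axis, rad.
#' @param bead_depth Depth of the bead below the flow-cell top surface, mm.
#' @return An object of class `magnet_assembly`.
#' @examples
#' asm <- magnet_assembly()
#' total_field(c(0, 0, -400), asm, Z_mag = 1)
#' @export
magnet_assembly <- function(width = 5, depth = 5, height = 5, gap = 2,
                            remanence = 1.4, rotation_angle = 0,
                            bead_depth = 0.4) {
  stopifnot(width > 0, depth > 0, height > 0, gap > 0, remanence > 0,
            bead_depth >= 0)
  structure(list(width = width, depth = depth, height = height, gap = gap,
                 remanence = remanence, rotation_angle = rotation_angle,
                 bead_depth = bead_depth),
            class = "magnet_assembly")
}

#' @export
print.magnet_assembly <- function(x, ...) {
  cat(sprintf(
    "Antiparallel magnet pair: %g x %g x %g mm blocks, gap %g mm,\n",
    x$width, x$depth, x$height, x$gap))
  cat(sprintf("  remanence %g T, rotation %g rad, bead depth %g mm\n",
              x$remanence, x$rotation_angle, x$bead_depth))
  invisible(x)
}

#' Superparamagnetic bead model
#'
#' Bead radius and Langevin magnetization parameters. Defaults are the
#' vendor-quoted values for MyOne beads (1.05 um diameter).
#'
#' @param radius Bead radius, um.
#' @param M_sat Saturation magnetization, kA/m.
#' @param B_0 Characteristic field of the Langevin magnetization curve, mT.
#' @return An object of class `bead_model` with derived `volume` (m^3).
#' @export
bead_model <- function(radius = 0.525, M_sat = 43.3, B_0 = 12) {
  stopifnot(radius > 0, M_sat > 0, B_0 > 0)
  structure(list(radius = radius, M_sat = M_sat, B_0 = B_0,
                 volume = 4 / 3 * pi * (radius * 1e-6)^3),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("Superparamagnetic bead: R = %g um, M_sat = %g kA/m, B_0 = %g mT\n",
              x$radius, x$M_sat, x$B_0))
  invisible(x)
}

#' Field of a uniformly charged rectangular sheet
#'
#' Closed-form magnetostatic field of a rectangle carrying uniform magnetic
#' surface charge, the elementary building block of the magnet-pair model.
#' The expressions are the standard arctan (vertical component) and log
#' (in-plane components) forms of the Coulomb integral over the rectangle.
#'
#' @param points Evaluation points in mm: a length-3 vector or an n x 3
#'   matrix. Points must not lie on the sheet itself.
#' @param sheet A list with `xlim`, `ylim` (length-2 extents, mm), `z0`
#'   (sheet plane height, mm) and `sigma` (surface charge density expressed
#'   as a field strength, T).
#' @return Field vector(s) in mT, same shape as `points`.
#' @export
sheet_field <- function(points, sheet) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  stopifnot(ncol(p) == 3, length(sheet$xlim) == 2, length(sheet$ylim) == 2)
  Z <- p[, 3] - sheet$z0
  on_sheet <- abs(Z) < 1e-12 &
    p[, 1] >= min(sheet$xlim) & p[, 1] <= max(sheet$xlim) &
    p[, 2] >= min(sheet$ylim) & p[, 2] <= max(sheet$ylim)
  if (any(on_sheet))
    stop("field evaluation point lies on the charge sheet (singular)")
  Bx <- By <- Bz <- numeric(nrow(p))
  for (i in 1:2) {
    for (j in 1:2) {
      s <- (-1)^(i + j)
      X <- p[, 1] - sheet$xlim[i]
      Y <- p[, 2] - sheet$ylim[j]
      R <- sqrt(X^2 + Y^2 + Z^2)
      Bx <- Bx + s * log(R - Y)
      By <- By + s * log(R - X)
      Bz <- Bz + s * atan(X * Y / (Z * R))
    }
  }
  out <- sheet$sigma / (4 * pi) * cbind(Bx, By, Bz) * 1e3 # T -> mT
  dimnames(out) <- NULL
  if (is.matrix(points)) out else drop(out)
}

## the four sheets of the antiparallel pair at magnet height Z_mag (mm)
.assembly_sheets <- function(assembly, Z_mag) {
  zb <- Z_mag
  zt <- Z_mag + assembly$height
  ylim <- c(-1, 1) * assembly$depth / 2
  x_pos <- c(assembly$gap / 2, assembly$gap / 2 + assembly$width)
  x_neg <- -rev(x_pos)
  s <- assembly$remanence
  list(# +x magnet, moment +z
       list(xlim = x_pos, ylim = ylim, z0 = zt, sigma = +s),
       list(xlim = x_pos, ylim = ylim, z0 = zb, sigma = -s),
       # -x magnet, moment -z
       list(xlim = x_neg, ylim = ylim, z0 = zt, sigma = -s),
       list(xlim = x_neg, ylim = ylim, z0 = zb, sigma = +s))
}

#' Total magnetic field of the magnet pair
#'
#' Signed sum of the four charge-sheet contributions (top and bottom face of
#' each magnet, opposite sign patterns for the antiparallel orientation).
#' Rotating the assembly by pi about the vertical axis flips the field sign
#' but leaves its magnitude unchanged everywhere.
#'
#' @param points Evaluation point(s) in the flow-cell frame, um: length-3
#'   vector or n x 3 matrix; z = 0 is the flow-cell top, negative z below it.
#' @param assembly A [magnet_assembly()].
#' @param Z_mag Height of the magnet bottom face above the flow-cell top, mm.
#' @return Field vector(s) in mT.
#' @export
total_field <- function(points, assembly, Z_mag) {
  stopifnot(inherits(assembly, "magnet_assembly"), Z_mag >= 0)
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  p <- p * 1e-3 # um -> mm
  th <- assembly$rotation_angle
  if (th != 0) { # evaluate in the magnet frame, rotate the field back
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    p <- p %*% Rz # frame rotation by -th
  }
  B <- matrix(0, nrow(p), 3)
  for (sh in .assembly_sheets(assembly, Z_mag))
    B <- B + sheet_field(p, sh)
  if (th != 0)
    B <- B %*% t(matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                          0, 0, 1), 3, 3))
  if (is.matrix(points)) B else drop(B)
}

.field_magnitude <- function(points, assembly, Z_mag) {
  B <- total_field(points, assembly, Z_mag)
  if (is.matrix(B)) sqrt(rowSums(B^2)) else sqrt(sum(B^2))
}

#' Langevin moment induced in a superparamagnetic bead
#'
#' `m = V * M_sat * (coth(b) - 1/b)` with `b = |B| / B_0`: linear at small
#' field (`m ~ V M_sat b / 3`), saturating at `V * M_sat`.  A series
#' expansion is used near zero field, so the function is continuous at 0.
#'
#' @param B_magnitude Field magnitude(s), mT.
#' @param bead A [bead_model()].
#' @return Induced moment(s) along the field direction, A m^2.
#' @export
bead_moment <- function(B_magnitude, bead) {
  stopifnot(inherits(bead, "bead_model"), all(B_magnitude >= 0))
  b <- B_magnitude / bead$B_0
  lang <- ifelse(b < 1e-4, b / 3 - b^3 / 45, 1 / tanh(b) - 1 / b)
  bead$volume * bead$M_sat * 1e3 * lang
}

## scalar used by the gradient: psi = |B| for mode "m_gradB",
## psi = m(|B|) * |B| for mode "grad_mB"; both in SI (T, A m^2)
.force_potential <- function(points, assembly, Z_mag, bead, mode) {
  B <- .field_magnitude(points, assembly, Z_mag) * 1e-3 # T
  if (mode == "grad_mB") bead_moment(B * 1e3, bead) * B else B
}

#' Magnetic force on a bead
#'
#' Default convention `F = m(|B|) * grad|B|`, the energy-consistent force on
#' an induced Langevin moment; the alternative `F = grad(m * |B|)` is
#' available via `mode`. The gradient is evaluated by central differences
#' (default step 1 um; halving the step changes the force by < 0.01 %).
#'
#' @param points Bead position(s) in the flow-cell frame, um (length-3
#'   vector or n x 3 matrix).
#' @param assembly A [magnet_assembly()].
#' @param bead A [bead_model()].
#' @param Z_mag Magnet height, mm.
#' @param mode Force convention, `"m_gradB"` (default) or `"grad_mB"`.
#' @param step Central-difference step, um.
#' @return Force vector(s) in pN.
#' @export
bead_force <- function(points, assembly, bead, Z_mag,
                       mode = c("m_gradB", "grad_mB"), step = 1) {
  mode <- match.arg(mode)
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  n <- nrow(p)
  grad <- matrix(0, n, 3)
  for (k in 1:3) {
    e <- matrix(0, n, 3)
    e[, k] <- step
    grad[, k] <- (.force_potential(p + e, assembly, Z_mag, bead, mode) -
                  .force_potential(p - e, assembly, Z_mag, bead, mode)) /
      (2 * step * 1e-6) # per metre
  }
  if (any(!is.finite(grad))) stop("non-finite force gradient")
  F <- if (mode == "m_gradB") {
    m <- bead_moment(.field_magnitude(p, assembly, Z_mag), bead)
    grad * m
  } else {
    grad
  }
  F <- F * 1e12 # N -> pN
  if (is.matrix(points)) F else drop(F)
}

#' Angle of the force vector to the vertical
#'
#' `alpha = atan(|F_lateral| / |F_z|)` in degrees; zero on the rotation axis
#' by symmetry. The bead is evaluated at its depth below the flow-cell top
#' (`assembly$bead_depth`).
#'
#' @param posX,posY Bead position in the field of view, um.
#' @inheritParams bead_force
#' @return Angle in degrees.
#' @export
force_angle <- function(posX, posY, Z_mag, assembly, bead,
                        mode = c("m_gradB", "grad_mB")) {
  mode <- match.arg(mode)
  F <- bead_force(cbind(posX, posY, -assembly$bead_depth * 1e3),
                  assembly, bead, Z_mag, mode = mode)
  if (!is.matrix(F)) F <- matrix(F, ncol = 3)
  if (any(F[, 3] == 0)) stop("force angle undefined where F_z = 0")
  drop(atan2(sqrt(F[, 1]^2 + F[, 2]^2), abs(F[, 3])) * 180 / pi)
}

#' Force map across the field of view
#'
#' Evaluates the force on a regular grid at fixed magnet height and reports
#' the force-uniformity metrics: the maximum relative variation
#' `100 * (max - min) / max` of `|F_z|` and of the force magnitude `|F|`,
#' and the maximum force angle on the grid.
#'
#' @inheritParams force_angle
#' @param fov_extent Side of the square field of view, um.
#' @param grid_n Grid points per side (>= 11).
#' @return An object of class `force_map`: the grid data frame (`posX`,
#'   `posY` um; `Fx`, `Fy`, `Fz`, `Fmag` pN; `B` mT) plus summary fields
#'   `variation_Fz`, `variation_Fmag` (percent), `max_angle` (degrees).
#' @export
force_map <- function(assembly, bead, Z_mag, fov_extent = 400, grid_n = 41,
                      mode = c("m_gradB", "grad_mB")) {
  mode <- match.arg(mode)
  stopifnot(grid_n >= 11, fov_extent > 0)
  xs <- seq(-fov_extent / 2, fov_extent / 2, length.out = grid_n)
  g <- expand.grid(posX = xs, posY = xs)
  pts <- cbind(g$posX, g$posY, -assembly$bead_depth * 1e3)
  F <- bead_force(pts, assembly, bead, Z_mag, mode = mode)
  Fmag <- sqrt(rowSums(F^2))
  absFz <- abs(F[, 3])
  grid <- data.frame(posX = g$posX, posY = g$posY,
                     Fx = F[, 1], Fy = F[, 2], Fz = F[, 3], Fmag = Fmag,
                     B = .field_magnitude(pts, assembly, Z_mag))
  structure(list(
    grid = grid,
    Z_mag = Z_mag, fov_extent = fov_extent, grid_n = grid_n, mode = mode,
    variation_Fz = 100 * (max(absFz) - min(absFz)) / max(absFz),
    variation_Fmag = 100 * (max(Fmag) - min(Fmag)) / max(Fmag),
    max_angle = max(atan2(sqrt(F[, 1]^2 + F[, 2]^2), absFz) * 180 / pi)),
    class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("Force map at Z_mag = %g mm (%g x %g um, %d x %d grid, mode %s)\n",
              x$Z_mag, x$fov_extent, x$fov_extent, x$grid_n, x$grid_n, x$mode))
  cat(sprintf("  |F_z| variation: %.3f %%   |F| variation: %.3f %%   max angle: %.2f deg\n",
              x$variation_Fz, x$variation_Fmag, x$max_angle))
  invisible(x)
}

#' @export
plot.force_map <- function(x, ...) {
  z <- matrix(x$grid$Fmag, x$grid_n, x$grid_n)
  xs <- unique(x$grid$posX)
  graphics::image(xs, xs, z, xlab = "posX (um)", ylab = "posY (um)",
                  main = sprintf("|F| (pN), Z_mag = %g mm", x$Z_mag), ...)
  invisible(x)
}

#' On-axis vertical force versus magnet height
#'
#' @inheritParams force_angle
#' @param Z_range Magnet-height range, mm (within 0 to 25).
#' @param n_points Number of heights.
#' @param posX,posY Bead position in the field of view, um.
#' @return A data frame with columns `Z_mag` (mm) and `F_z` (pN, magnitude),
#'   with the force convention stored in `attr(, "mode")`.
#' @export
force_vs_height <- function(assembly, bead, Z_range = c(0, 10),
                            n_points = 50, posX = 0, posY = 0,
                            mode = c("m_gradB", "grad_mB")) {
  mode <- match.arg(mode)
  stopifnot(Z_range[1] >= 0, Z_range[2] <= 25, n_points >= 2)
  zs <- seq(Z_range[1], Z_range[2], length.out = n_points)
  Fz <- vapply(zs, function(zm) {
    abs(bead_force(c(posX, posY, -assembly$bead_depth * 1e3),
                   assembly, bead, zm, mode = mode)[3])
  }, numeric(1))
  structure(data.frame(Z_mag = zs, F_z = Fz), mode = mode)
}

#' Single-exponential fit of force versus magnet height
#'
#' Least-squares fit of `F = F_0 * exp(-(Z_mag - Z_ref) / l_dec)` to an
#' on-axis force curve, with error metrics of the single-exponential
#' approximation over the fit range.
#'
#' @param table Data frame with columns `Z_mag` (mm) and `F_z` (pN), e.g.
#'   from [force_vs_height()].
#' @param fit_range Magnet-height range used for the fit, mm.
#' @param z_ref Reference height at which `F_0` is defined, mm.
#' @return A list of class `force_decay_fit`: `F_0` (pN), `l_dec` (mm),
#'   `max_rel_err` (percent), `max_abs_err` (fN), fit metadata.
#' @export
fit_force_decay <- function(table, fit_range = c(1, 8), z_ref = 1) {
  sel <- table$Z_mag >= fit_range[1] & table$Z_mag <= fit_range[2]
  d <- table[sel, ]
  if (nrow(d) < 10) stop("need at least 10 points inside the fit range")
  if (diff(range(d$Z_mag)) <= 0) stop("degenerate fit range")
  ## log-linear start values, then plain least squares
  lf <- lm(log(F_z) ~ Z_mag, data = d)
  start <- list(F0 = exp(coef(lf)[[1]] + z_ref * coef(lf)[[2]]),
                l = -1 / coef(lf)[[2]])
  fit <- minpack.lm::nlsLM(F_z ~ F0 * exp(-(Z_mag - z_ref) / l), data = d,
                           start = start)
  pred <- predict(fit)
  structure(list(F_0 = coef(fit)[["F0"]], l_dec = coef(fit)[["l"]],
                 max_rel_err = 100 * max(abs(pred - d$F_z) / d$F_z),
                 max_abs_err = 1e3 * max(abs(pred - d$F_z)),
                 z_ref = z_ref, fit_range = fit_range, n = nrow(d),
                 mode = attr(table, "mode")),
            class = "force_decay_fit")
}

#' @export
print.force_decay_fit <- function(x, ...) {
  cat(sprintf("Exponential force decay (Z_ref = %g mm, range %g-%g mm%s):\n",
              x$z_ref, x$fit_range[1], x$fit_range[2],
              if (is.null(x$mode)) "" else paste0(", mode ", x$mode)))
  cat(sprintf("  F_0 = %.3f pN   l_dec = %.3f mm\n", x$F_0, x$l_dec))
  cat(sprintf("  max relative error %.2f %%   max absolute error %.1f fN\n",
              x$max_rel_err, x$max_abs_err))
  invisible(x)
}
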