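## Bicircular (Limacon) analysis of the rotational response of a DNA-bead
## tether: a precession circle at twice the magnet rotation frequency
## superposed on a rotation about the DNA attachment point at the magnet
## frequency.  The pattern is fitted by linear least squares in quadrature
## amplitudes (the two frequencies are known from the magnet drive).

#' Limacon rotation-pattern parameters
#'
#' The rotational response combines rotation about the DNA attachment point
#' (radius `R_att`, frequency `omega_mag`) with precession about the magnet
#' rotation axis (radius `R_prec`, frequency `2 * omega_mag`); the frequency
#' doubling follows from the field being identical under a half turn of the
#' antiparallel pair.
#'
#' @param R_att Attachment-rotation radius, um (>= 0).
#' @param R_prec Precession radius, um (>= 0).
#' @param phi_att,phi_prec Phases, rad.
#' @param center Pattern centre `c(x0, y0)`, um.
#' @param omega_mag Magnet rotation rate, rad/s.
#' @return An object of class `limacon_params`.
#' @export
limacon_params <- function(R_att, R_prec, phi_att = 0, phi_prec = 0,
                           center = c(0, 0), omega_mag = pi) {
  stopifnot(R_att >= 0, R_prec >= 0, length(center) == 2, omega_mag > 0)
  structure(list(R_att = R_att, R_prec = R_prec, phi_att = phi_att,
                 phi_prec = phi_prec, center = center,
                 omega_mag = omega_mag),
            class = "limacon_params")
}

#' @export
print.limacon_params <- function(x, ...) {
  cat(sprintf(
    "Limacon pattern: R_att = %.4f um, R_prec = %.4f um, omega_mag = %g rad/s\n",
    x$R_att, x$R_prec, x$omega_mag))
  cat(sprintf("  phases (%.3f, %.3f) rad, centre (%.3f, %.3f) um%s\n",
              x$phi_att, x$phi_prec, x$center[1], x$center[2],
              if (has_inner_loop(x)) ", self-intersecting (inner loop)" else ""))
  invisible(x)
}

#' Parametric Limacon curve
#'
#' `x(t) = x0 + R_att cos(w t + phi_att) + R_prec cos(2 w t + phi_prec)` and
#' the sine analogue for y, with `w = omega_mag`; periodic with the magnet
#' turn period `2 pi / w`.
#'
#' @param params A [limacon_params()].
#' @param times Increasing time points, s.
#' @return Data frame with columns `t`, `x`, `y` (um).
#' @export
limacon_curve <- function(params, times) {
  stopifnot(inherits(params, "limacon_params"), !is.unsorted(times))
  w <- params$omega_mag
  data.frame(
    t = times,
    x = params$center[1] + params$R_att * cos(w * times + params$phi_att) +
      params$R_prec * cos(2 * w * times + params$phi_prec),
    y = params$center[2] + params$R_att * sin(w * times + params$phi_att) +
      params$R_prec * sin(2 * w * times + params$phi_prec))
}

#' Does the rotation pattern have an inner loop?
#'
#' The bicircular curve crosses itself, forming an inner loop, exactly when
#' `2 * R_prec > R_att > 0`.
#'
#' @param params A [limacon_params()].
#' @return `TRUE` or `FALSE`.
#' @export
has_inner_loop <- function(params) {
  stopifnot(inherits(params, "limacon_params"))
  2 * params$R_prec > params$R_att && params$R_att > 0
}

#' Fit the Limacon model to an xy rotation trace
#'
#' With the component frequencies pinned at `omega_mag` and `2 * omega_mag`
#' by the magnet drive, the model is linear in the quadrature amplitudes
#' and centre, and the x- and y-equations share them; the fit is therefore a
#' single linear least-squares projection (no nonlinear optimization).
#' Radii are non-negative by construction (sign ambiguities become phase
#' shifts of pi).
#'
#' @param trace Data frame with columns `t`, `x`, `y` (um), covering at
#'   least two full magnet turns.
#' @param omega_mag Magnet rotation rate, rad/s.
#' @param noise_rms Expected tracking noise (um) used for the residual
#'   warning threshold.
#' @return A [limacon_params()] with extra fields `rms_residual` (um) and
#'   `n` in attributes.
#' @export
fit_limacon <- function(trace, omega_mag, noise_rms = 0.0022) {
  stopifnot(all(c("t", "x", "y") %in% names(trace)), omega_mag > 0)
  if (diff(range(trace$t)) < 2 * (2 * pi / omega_mag))
    stop("need at least two full magnet turns of data")
  w <- omega_mag * trace$t
  n <- nrow(trace)
  zero <- numeric(n)
  one <- rep(1, n)
  ## unknowns: x0, y0, A1, B1, A2, B2 where
  ##   x = x0 + A1 cos(wt) + B1 sin(wt) + A2 cos(2wt) + B2 sin(2wt)
  ##   y = y0 + A1 sin(wt) - B1 cos(wt) + A2 sin(2wt) - B2 cos(2wt)
  Mx <- cbind(one, zero, cos(w), sin(w), cos(2 * w), sin(2 * w))
  My <- cbind(zero, one, sin(w), -cos(w), sin(2 * w), -cos(2 * w))
  M <- rbind(Mx, My)
  rhs <- c(trace$x, trace$y)
  beta <- unname(qr.coef(qr(M), rhs))
  res <- rhs - drop(M %*% beta)
  rms <- sqrt(mean(res^2))
  if (noise_rms > 0 && rms > 3 * noise_rms)
    warning(sprintf(
      "residual RMS %.4f um exceeds 3x the tracking noise (%.4f um)",
      rms, noise_rms))
  out <- limacon_params(
    R_att = sqrt(beta[3]^2 + beta[4]^2),
    R_prec = sqrt(beta[5]^2 + beta[6]^2),
    phi_att = atan2(-beta[4], beta[3]),
    phi_prec = atan2(-beta[6], beta[5]),
    center = c(beta[1], beta[2]),
    omega_mag = omega_mag)
  attr(out, "rms_residual") <- rms
  attr(out, "n") <- n
  out
}

#' Attachment offset from the attachment-rotation radius
#'
#' Sphere geometry: the DNA anchor sits on a horizontal circle of radius
#' `R_att` about the bead's rotation axis, so the hidden tether length is
#' `A = R_bead - sqrt(R_bead^2 - R_att^2)`.
#'
#' @param R_att Attachment-rotation radius, um (`0 <= R_att <= R_bead`).
#' @param R_bead Bead radius, um.
#' @return Attachment offset A, um.
#' @export
attachment_offset_from_radius <- function(R_att, R_bead) {
  if (any(R_att < 0 | R_att > R_bead))
    stop("R_att must lie in [0, R_bead]")
  R_bead - sqrt(R_bead^2 - R_att^2)
}

## inverse of the above (generator side)
.radius_from_attachment_offset <- function(A, R_bead) {
  sqrt(pmax(0, 2 * R_bead * A - A^2))
}

#' Probability density of DNA attachment offsets
#'
#' For DNA bound uniformly over the bead surface, with the bead free to
#' rotate about its horizontal magnetic easy axis, the offset is
#' `A = R (1 - sin alpha)` with `alpha` the angle between the attachment
#' direction and the easy axis. The resulting density is
#' `p(A) = (1 - A/R) / (R * sqrt(1 - (1 - A/R)^2))`:
#' integrably divergent at `A = 0`, zero at `A = R`, and normalized on
#' `[0, R]`.
#'
#' @param A Offset value(s), um, in `[0, R_bead]`.
#' @param R_bead Bead radius, um.
#' @return Density value(s), 1/um.
#' @export
attachment_offset_pdf <- function(A, R_bead) {
  if (any(A < 0 | A > R_bead)) stop("A must lie in [0, R_bead]")
  u <- 1 - A / R_bead
  ifelse(u >= 1, Inf, u / (R_bead * sqrt(1 - u^2)))
}

#' Cumulative distribution of attachment offsets
#'
#' Closed form `P(A <= a) = sqrt(1 - (1 - a/R)^2)` (the antiderivative of
#' [attachment_offset_pdf()]).
#'
#' @inheritParams attachment_offset_pdf
#' @return Probability(ies).
#' @export
attachment_offset_cdf <- function(A, R_bead) {
  if (any(A < 0 | A > R_bead)) stop("A must lie in [0, R_bead]")
  sqrt(pmax(0, 1 - (1 - A / R_bead)^2))
}

#' Sample attachment offsets
#'
#' Inverse-CDF sampling of the attachment-offset distribution:
#' `A = R (1 - sqrt(1 - q^2))` for uniform `q`.
#'
#' @param n Number of samples.
#' @param R_bead Bead radius, um.
#' @param seed Optional integer seed.
#' @return Vector of offsets in `[0, R_bead]`, um.
#' @export
sample_attachment_offsets <- function(n, R_bead = 0.525, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  q <- runif(n)
  R_bead * (1 - sqrt(1 - q^2))
}

#' Predicted precession radius from the force field
#'
#' Small-angle pendulum geometry: a tether at distance `d_center` from the
#' rotation axis experiences force angle `alpha` (from the charge-sheet
#' model), and the bead centre precesses on a circle of radius
#' `R_prec = (l_ext + R_bead) * tan(alpha)` where `l_ext` is the
#' equilibrium extension at the local force magnitude.
#'
#' @param d_center Distance(s) of the tether to the magnet rotation axis, um.
#' @param Z_mag Magnet height, mm.
#' @param assembly A [magnet_assembly()].
#' @param bead A [bead_model()].
#' @param tether A [tether_model()] (provides the WLC parameters).
#' @return Predicted precession radius(es), um.
#' @export
predict_precession_radius <- function(d_center, Z_mag, assembly, bead,
                                      tether) {
  vapply(d_center, function(d) {
    if (d == 0) return(0)
    F <- bead_force(c(d, 0, -assembly$bead_depth * 1e3), assembly, bead,
                    Z_mag)
    Fmag <- sqrt(sum(F^2))
    alpha <- atan2(sqrt(F[1]^2 + F[2]^2), abs(F[3]))
    l_ext <- wlc_extension_at_force(Fmag, tether$wlc)
    (l_ext + bead$radius) * tan(alpha)
  }, numeric(1))
}
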