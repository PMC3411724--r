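## Overdamped Langevin dynamics of a DNA-bead tether: vertical equation of
## motion with WLC elasticity, Faxen wall-corrected drag and thermal noise,
## integrated by Euler-Maruyama in compiled code; plus the measured-quantity
## transforms produced by an eccentric bead attachment.

#' DNA-bead tether model
#'
#' @param wlc A [wlc_params()] describing the DNA.
#' @param bead A [bead_model()].
#' @param A Attachment offset: height of the DNA anchor point above the
#'   bead's lowest point, um (`0 <= A <= bead$radius`).
#' @param F_0 Bead-specific force-calibration factor: force at the reference
#'   magnet height, pN.
#' @param posX,posY Tether position in the field of view, um.
#' @return An object of class `tether_model`.
#' @export
tether_model <- function(wlc, bead = bead_model(), A = 0, F_0 = 6.0,
                         posX = 0, posY = 0) {
  stopifnot(inherits(wlc, "wlc_params"), inherits(bead, "bead_model"),
            A >= 0, A <= bead$radius, F_0 > 0)
  structure(list(wlc = wlc, bead = bead, A = A, F_0 = F_0,
                 posX = posX, posY = posY),
            class = "tether_model")
}

#' @export
print.tether_model <- function(x, ...) {
  cat(sprintf("DNA-bead tether: L_c = %g um, L_p = %g nm, R_bead = %g um\n",
              x$wlc$L_c, x$wlc$L_p, x$bead$radius))
  cat(sprintf("  A = %g um, F_0 = %g pN, position (%g, %g) um\n",
              x$A, x$F_0, x$posX, x$posY))
  invisible(x)
}

#' Camera model for simulated traces
#'
#' Boxcar exposure averaging over the frame period followed by additive
#' Gaussian tracking noise. Defaults reproduce 50 Hz acquisition with
#' tracking resolutions sigma_z = 12 nm and sigma_xy = 2.2 nm.
#'
#' @param frame_rate Frames per second.
#' @param sigma_z,sigma_xy Tracking noise standard deviations, um.
#' @return A list of class `camera_model`.
#' @export
camera_model <- function(frame_rate = 50, sigma_z = 0.012, sigma_xy = 0.0022) {
  stopifnot(frame_rate > 0, sigma_z >= 0, sigma_xy >= 0)
  structure(list(frame_rate = frame_rate, sigma_z = sigma_z,
                 sigma_xy = sigma_xy), class = "camera_model")
}

#' Simulation protocol
#'
#' Time base, magnet trajectory, force model, noise and camera settings for
#' [simulate_trace()] and friends.
#'
#' The magnet moves as `Z_mag(t) = Z_start + v_mag * t`. With
#' `force_model = "exponential"` the force on the bead is
#' `F(t) = F_0 * exp(-(Z_mag(t) - z_ref) / l_dec)` with the bead-specific
#' `F_0` taken from the tether; with `"field"` it is the vertical
#' charge-sheet force at the tether position (requires `assembly`).
#'
#' `dt = "auto"` picks `min(1e-4 s, tau/10)` where `tau = gamma / k` is the
#' bead relaxation time at the stiffest point of the protocol, so the
#' stability condition is satisfied by construction; an explicit `dt` is
#' checked against the same condition.
#'
#' @param duration Simulated time, s.
#' @param dt Time step in seconds, or `"auto"`.
#' @param Z_start Initial magnet height, mm.
#' @param v_mag Magnet velocity, mm/s (0 for a hold).
#' @param force_model `"exponential"` or `"field"`.
#' @param l_dec Force decay length for the exponential model, mm.
#' @param z_ref Reference height of `F_0`, mm.
#' @param assembly A [magnet_assembly()], required for the field model.
#' @param thermal Include the Langevin noise force?
#' @param viscosity Medium viscosity, Pa s (default water at 22 C).
#' @param camera A [camera_model()], or `NULL` for raw full-rate output.
#' @param transverse Also simulate the transverse pendulum mode (holds only).
#' @return A list of class `sim_protocol`.
#' @export
sim_protocol <- function(duration, dt = "auto", Z_start = 1, v_mag = 0,
                         force_model = c("exponential", "field"),
                         l_dec = 1.55, z_ref = 1, assembly = NULL,
                         thermal = TRUE, viscosity = 0.955e-3,
                         camera = camera_model(), transverse = FALSE) {
  force_model <- match.arg(force_model)
  stopifnot(duration > 0, identical(dt, "auto") || dt > 0, l_dec > 0,
            viscosity > 0)
  if (force_model == "field" && !inherits(assembly, "magnet_assembly"))
    stop("force_model = \"field\" requires a magnet_assembly")
  structure(list(duration = duration, dt = dt, Z_start = Z_start,
                 v_mag = v_mag, force_model = force_model, l_dec = l_dec,
                 z_ref = z_ref, assembly = assembly, thermal = thermal,
                 viscosity = viscosity, camera = camera,
                 transverse = transverse),
            class = "sim_protocol")
}

#' Wall-corrected drag coefficient (perpendicular motion)
#'
#' Faxen's correction for a sphere moving perpendicular to a plane wall,
#' `gamma = 6 pi eta R / (1 - (9/8)(R/h) + (1/2)(R/h)^3)` with `h` the
#' distance of the sphere centre to the wall.
#'
#' @param h Centre height(s) above the wall, um (`h > R`).
#' @param R Bead radius, um.
#' @param viscosity Viscosity, Pa s.
#' @return Drag coefficient(s), N s/m.
#' @export
drag_coefficient_perpendicular <- function(h, R, viscosity = 0.955e-3) {
  if (any(h <= R)) stop("centre height h must exceed the bead radius")
  u <- R / h
  corr <- 1 - 9 / 8 * u + 1 / 2 * u^3
  if (any(corr < 0.05)) {
    warning("wall correction factor below 0.05; clamped")
    corr <- pmax(corr, 0.05)
  }
  6 * pi * viscosity * (R * 1e-6) / corr
}

## parallel-motion variant used for the transverse pendulum mode (internal)
.drag_parallel <- function(h, R, viscosity) {
  u <- R / h
  6 * pi * viscosity * (R * 1e-6) / (1 - 9 / 16 * u + 1 / 8 * u^3)
}

## magnet height (mm) and force schedule (pN) at given times (s)
.protocol_Zmag <- function(protocol, t) protocol$Z_start + protocol$v_mag * t

.protocol_force <- function(tether, protocol, t) {
  Z <- .protocol_Zmag(protocol, t)
  if (protocol$force_model == "exponential") {
    tether$F_0 * exp(-(Z - protocol$z_ref) / protocol$l_dec)
  } else {
    zg <- seq(min(Z), max(Z), length.out = 256)
    Fg <- vapply(zg, function(zm) {
      abs(bead_force(c(tether$posX, tether$posY,
                       -protocol$assembly$bead_depth * 1e3),
                     protocol$assembly, tether$bead, zm)[3])
    }, numeric(1))
    if (length(zg) > 1) stats::spline(zg, Fg, xout = Z)$y else Fg
  }
}

## resolve dt / frame structure; returns list(dt, n_steps, out_every)
.resolve_timebase <- function(tether, protocol) {
  F_max <- max(.protocol_force(tether, protocol,
                               c(0, protocol$duration)))
  l_max <- wlc_extension_at_force(F_max, tether$wlc)
  k <- wlc_stiffness(l_max, tether$wlc) * 1e-6            # N/m
  g <- drag_coefficient_perpendicular(l_max + tether$bead$radius,
                                      tether$bead$radius,
                                      protocol$viscosity)
  tau <- g / max(k, 1e-12)
  dt_max <- 0.1 * tau
  dt <- if (identical(protocol$dt, "auto")) min(1e-4, dt_max) else protocol$dt
  if (dt > dt_max)
    stop(sprintf(
      "dt = %g s violates the stability condition dt < 0.1 * gamma/k = %g s",
      dt, dt_max))
  if (!is.null(protocol$camera)) {
    frame <- 1 / protocol$camera$frame_rate
    out_every <- max(1L, as.integer(ceiling(frame / dt)))
    dt <- frame / out_every
    n_frames <- floor(protocol$duration * protocol$camera$frame_rate)
    n_steps <- n_frames * out_every
  } else {
    out_every <- 1L
    n_steps <- floor(protocol$duration / dt)
  }
  list(dt = dt, n_steps = n_steps, out_every = out_every)
}

#' Simulate a bead trajectory
#'
#' Finite-difference (Euler-Maruyama) integration of the overdamped
#' equation of motion of the tethered bead,
#' `dz = dt (F_mag(t) - F_WLC(z)) / gamma(h) + sqrt(2 kBT dt / gamma) xi`,
#' with Faxen-corrected drag at centre height `h = z + R_bead`, a reflecting
#' wall at `z = 0`, optional boxcar exposure averaging and additive tracking
#' noise from the camera model. The extension is initialized at mechanical
#' equilibrium with the initial force.
#'
#' For constant-force holds with `transverse = TRUE` in the protocol, the
#' lateral pendulum mode (stiffness `F / (l_ext + R_bead)`, parallel-motion
#' wall drag) is simulated independently for x and y.
#'
#' @param tether A [tether_model()].
#' @param protocol A [sim_protocol()].
#' @param seed Optional integer seed; identical seeds give identical traces.
#' @param bead_id Identifier stored in the trace.
#' @return A data frame of class `mt_trace` with columns `t` (s), `x`, `y`,
#'   `z` (um) and `bead_id`, with protocol metadata in attributes.
#' @export
simulate_trace <- function(tether, protocol, seed = NULL, bead_id = 1L) {
  stopifnot(inherits(tether, "tether_model"),
            inherits(protocol, "sim_protocol"))
  if (!is.null(seed)) set.seed(seed)
  tb <- .resolve_timebase(tether, protocol)
  step_t <- (seq_len(tb$n_steps) - 1) * tb$dt
  F_pN <- if (protocol$v_mag == 0 &&
              protocol$force_model == "exponential") {
    .protocol_force(tether, protocol, 0)
  } else {
    .protocol_force(tether, protocol, step_t)
  }
  z0 <- wlc_extension_at_force(F_pN[1], tether$wlc)
  sim <- .cpp_sim_tether(F_pN * 1e-12, tb$n_steps, tb$dt, z0 * 1e-6,
                         tether$wlc$L_c * 1e-6, tether$wlc$L_p * 1e-9,
                         kBT(tether$wlc$temperature),
                         tether$bead$radius * 1e-6, protocol$viscosity,
                         protocol$thermal, tb$out_every, 0.05)
  n_frames <- length(sim$z)
  t_frame <- (seq_len(n_frames) - 0.5) * tb$dt * tb$out_every
  z <- sim$z * 1e6
  x <- y <- numeric(n_frames)
  if (isTRUE(protocol$transverse)) {
    if (protocol$v_mag != 0)
      stop("transverse pendulum mode is only defined for constant-force holds")
    F0 <- F_pN[1]
    l_eq <- wlc_extension_at_force(F0, tether$wlc)
    k_x <- F0 * 1e-12 / ((l_eq + tether$bead$radius) * 1e-6)
    g_x <- .drag_parallel(l_eq + tether$bead$radius, tether$bead$radius,
                          protocol$viscosity)
    x <- .cpp_sim_ou(tb$n_steps, tb$dt, k_x, g_x,
                     kBT(tether$wlc$temperature), 0, protocol$thermal,
                     tb$out_every) * 1e6
    y <- .cpp_sim_ou(tb$n_steps, tb$dt, k_x, g_x,
                     kBT(tether$wlc$temperature), 0, protocol$thermal,
                     tb$out_every) * 1e6
  }
  if (!is.null(protocol$camera)) {
    cam <- protocol$camera
    z <- z + rnorm(n_frames, 0, cam$sigma_z)
    x <- x + rnorm(n_frames, 0, cam$sigma_xy)
    y <- y + rnorm(n_frames, 0, cam$sigma_xy)
  }
  tr <- data.frame(t = t_frame, x = x, y = y, z = z, bead_id = bead_id)
  class(tr) <- c("mt_trace", "data.frame")
  attr(tr, "frame_rate") <- if (is.null(protocol$camera)) 1 / (tb$dt)
                            else protocol$camera$frame_rate
  attr(tr, "dt") <- tb$dt
  attr(tr, "seed") <- seed
  attr(tr, "protocol") <- protocol[c("Z_start", "v_mag", "force_model",
                                     "l_dec", "z_ref", "thermal")]
  tr
}

#' Drag-force budget along a deterministic ramp
#'
#' Integrates the noise-free equation of motion along the magnet ramp and
#' reports the vertical drag force `gamma(h) |dz/dt|` (equal to
#' `|F_mag - F_WLC|` in the overdamped limit) together with the applied
#' magnetic force and their ratio.
#'
#' @inheritParams simulate_trace
#' @return A data frame with columns `t` (s), `F_drag` (fN), `F_mag` (pN)
#'   and `ratio`; attributes `max_drag_fN` and `max_ratio` hold the
#'   per-step maxima over the whole ramp.
#' @export
drag_force_profile <- function(tether, protocol) {
  protocol$thermal <- FALSE
  tb <- .resolve_timebase(tether, protocol)
  step_t <- (seq_len(tb$n_steps) - 1) * tb$dt
  F_pN <- .protocol_force(tether, protocol, step_t)
  z0 <- wlc_extension_at_force(F_pN[1], tether$wlc)
  sim <- .cpp_sim_tether(F_pN * 1e-12, tb$n_steps, tb$dt, z0 * 1e-6,
                         tether$wlc$L_c * 1e-6, tether$wlc$L_p * 1e-9,
                         kBT(tether$wlc$temperature),
                         tether$bead$radius * 1e-6, protocol$viscosity,
                         FALSE, tb$out_every, 0.05)
  n_frames <- length(sim$z)
  out <- data.frame(t = (seq_len(n_frames) - 0.5) * tb$dt * tb$out_every,
                    F_drag = sim$drag * 1e15,
                    F_mag = sim$F_mag * 1e12)
  out$ratio <- out$F_drag * 1e-3 / out$F_mag
  attr(out, "max_drag_fN") <- sim$drag_max * 1e15
  attr(out, "max_ratio") <- sim$ratio_max
  out
}

#' Apparent force-extension response with an eccentric attachment
#'
#' Simulates the (noise-free by default) force ramp and applies the
#' measured-quantity transforms caused by an attachment offset `A`: the
#' tracked bead height underestimates the end-to-end distance,
#' `L_meas = L_real - A`, and the force assigned from the bead calibration
#' is accordingly `F_measured = F_real * (L_meas / L_real)`. The result can
#' be fed to the fitting pipeline to quantify the persistence-length bias.
#'
#' @inheritParams simulate_trace
#' @return A [fe_curve()] in the measured convention.
#' @export
apparent_response_with_offset <- function(tether, protocol, seed = NULL) {
  tr <- simulate_trace(tether, protocol, seed = seed)
  t_mid <- tr$t
  F_real <- .protocol_force(tether, protocol, t_mid)
  L_real <- tr$z
  L_meas <- L_real - tether$A
  keep <- L_meas > 0
  F_meas <- F_real[keep] * L_meas[keep] / L_real[keep]
  fe_curve(force = F_meas, extension = L_meas[keep],
           meta = list(A = tether$A, transform = "measured"))
}
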