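## Synthetic multiplexed-experiment generator and trace/config I/O.
##
## The generator emulates the measurement protocol of a multiplexed
## magnetic-tweezers run: beads scattered over the field of view with a
## minimum separation, bead-to-bead spread of the force-calibration factor,
## attachment offsets drawn from the sphere-geometry density, and per bead
## the traces of each protocol step (constant-force hold, zero-force hold,
## rotation measurement, force ramp, and transverse calibration holds).

#' Configuration of a synthetic multiplexed experiment
#'
#' Defaults reproduce the study conditions: a 300 x 400 um field of view,
#' 15 um minimum bead separation, 50 Hz acquisition with tracking noise
#' sigma_z = 12 nm / sigma_xy = 2.2 nm, log-normal force-scale spread with
#' relative SD 0.11, measured decay length 1.54 mm, and the four dsDNA
#' length groups 2.2/7.3/11.9/20.1 kb (0.34 nm per base pair).
#'
#' @param n Number of tethers.
#' @param contour_lengths Contour length(s), um, recycled over beads as
#'   length groups.
#' @param L_p True persistence length, nm.
#' @param F0_mean,F0_rel_sd Mean (pN) and relative SD of the bead-specific
#'   force scale at `Z_mag` = `z_ref`.
#' @param l_dec Force decay length used both to generate and to analyze, mm.
#' @param z_ref Reference height of `F_0`, mm.
#' @param fov Field-of-view extents `c(x, y)`, um.
#' @param min_separation Minimum bead-to-bead distance, um.
#' @param frame_rate Acquisition rate, Hz.
#' @param sigma_z,sigma_xy Tracking noise, um.
#' @param thermal Simulate thermal noise?
#' @param bead A [bead_model()].
#' @param temperature Temperature, K.
#' @param viscosity Viscosity, Pa s.
#' @param surface_offset Apparent height of the surface in the raw traces,
#'   um (removed by the surface-reference correction).
#' @param hold_duration,noforce_duration,calib_duration Durations (s) of
#'   the constant-force hold, the zero-force hold and each transverse
#'   calibration hold.
#' @param noforce_Z Magnet height of the zero-force hold, mm.
#' @param calib_heights Magnet heights of the calibration holds, mm.
#' @param ramp_range,v_mag Magnet ramp `c(start, end)` (mm) and speed (mm/s).
#' @param omega_mag,rotation_turns Magnet rotation rate (rad/s) and number
#'   of turns recorded in the rotation measurement.
#' @param alpha_per_um Small-angle force-angle gradient (rad per um of
#'   distance to the rotation axis) used to emulate the precession radius;
#'   the default is the charge-sheet model value at `Z_mag` = 1 mm.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n = 60,
                            contour_lengths = c(0.748, 2.482, 4.046, 6.834),
                            L_p = 50, F0_mean = 6.0, F0_rel_sd = 0.11,
                            l_dec = 1.54, z_ref = 1,
                            fov = c(300, 400), min_separation = 15,
                            frame_rate = 50, sigma_z = 0.012,
                            sigma_xy = 0.0022, thermal = TRUE,
                            bead = bead_model(), temperature = 295.15,
                            viscosity = 0.955e-3, surface_offset = 0.3,
                            hold_duration = 25, noforce_duration = 130,
                            calib_duration = 20, noforce_Z = 20,
                            calib_heights = c(1, 2, 3),
                            ramp_range = c(1, 8), v_mag = 0.1,
                            omega_mag = pi, rotation_turns = 4,
                            alpha_per_um = 3.0e-4) {
  stopifnot(n >= 1, all(contour_lengths > 0), L_p > 0, F0_mean > 0,
            F0_rel_sd >= 0, length(fov) == 2, min_separation >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "ensemble_config"
  cfg
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic MMT ensemble: %d tethers, L_c groups {%s} um, L_p = %g nm\n",
    x$n, paste(x$contour_lengths, collapse = ", "), x$L_p))
  cat(sprintf("  F_0 = %g pN (rel SD %g), l_dec = %g mm, FOV %g x %g um, noise %s\n",
              x$F0_mean, x$F0_rel_sd, x$l_dec, x$fov[1], x$fov[2],
              if (x$thermal) "on" else "off"))
  invisible(x)
}

## deterministic per-bead sub-seed below 2^31
.sub_seed <- function(master, bead_id, step = 0L) {
  as.integer((as.double(master) * 48271 + bead_id * 7919 + step * 104729) %%
               2147483587)
}

## rejection-sampled positions with minimum separation
.place_beads <- function(n, fov, min_sep, max_attempts = 1e4) {
  pos <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- c(runif(1, -fov[1] / 2, fov[1] / 2),
             runif(1, -fov[2] / 2, fov[2] / 2))
      if (i == 1 ||
          min(sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - p)^2))) >=
            min_sep) {
        pos[i, ] <- p
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("bead placement failed: field of view too crowded for the ",
           "requested minimum separation")
  }
  pos
}

#' Generate a synthetic multiplexed experiment
#'
#' Draws the tether ensemble (positions, force scales, attachment offsets,
#' length groups) and simulates the traces of the requested protocol steps
#' for every bead. Everything downstream is fixed by `seed`; each bead uses
#' a deterministic sub-seed so individual trajectories do not depend on the
#' ensemble size.
#'
#' @param config An [ensemble_config()].
#' @param seed Master seed (integer).
#' @param steps Protocol steps to simulate, a subset of
#'   `c("hold", "noforce", "rotation", "ramp", "calibration")`.
#' @return A list of class `mt_ensemble` with elements `truth` (the
#'   ground-truth table), `tethers`, `traces` (per bead, per step) and
#'   `config`.
#' @export
generate_ensemble <- function(config, seed = 1,
                              steps = c("hold", "noforce", "rotation",
                                        "ramp", "calibration")) {
  stopifnot(inherits(config, "ensemble_config"))
  steps <- match.arg(steps, several.ok = TRUE)
  set.seed(seed)
  n <- config$n
  pos <- .place_beads(n, config$fov, config$min_separation)
  sdlog <- sqrt(log(1 + config$F0_rel_sd^2))
  F0 <- stats::rlnorm(n, log(config$F0_mean) - sdlog^2 / 2, sdlog)
  A <- sample_attachment_offsets(n, config$bead$radius)
  group_Lc <- rep(config$contour_lengths, length.out = n)
  group <- rep(sprintf("Lc=%.2fum", config$contour_lengths),
               length.out = n)
  truth <- data.frame(bead_id = seq_len(n), group = group, L_c = group_Lc,
                      L_p = config$L_p, F_0 = F0, A = A,
                      R_att = .radius_from_attachment_offset(
                        A, config$bead$radius),
                      posX = pos[, 1], posY = pos[, 2],
                      sub_seed = .sub_seed(seed, seq_len(n)))
  cam <- camera_model(config$frame_rate, config$sigma_z, config$sigma_xy)
  proto <- function(duration, Z, v = 0, transverse = FALSE)
    sim_protocol(duration = duration, Z_start = Z, v_mag = v,
                 l_dec = config$l_dec, z_ref = config$z_ref,
                 thermal = config$thermal, viscosity = config$viscosity,
                 camera = cam, transverse = transverse)
  tethers <- vector("list", n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    wlc <- wlc_params(group_Lc[i], config$L_p, config$temperature)
    te <- tether_model(wlc, config$bead, A = A[i], F_0 = F0[i],
                       posX = pos[i, 1], posY = pos[i, 2])
    tethers[[i]] <- te
    tr <- list()
    if ("hold" %in% steps)
      tr$hold <- .offset_z(simulate_trace(
        te, proto(config$hold_duration, config$z_ref),
        seed = .sub_seed(seed, i, 1L), bead_id = i),
        config$surface_offset, A[i])
    if ("noforce" %in% steps)
      tr$noforce <- .offset_z(simulate_trace(
        te, proto(config$noforce_duration, config$noforce_Z),
        seed = .sub_seed(seed, i, 2L), bead_id = i),
        config$surface_offset, A[i])
    if ("rotation" %in% steps)
      tr$rotation <- .rotation_trace(te, config,
                                     seed = .sub_seed(seed, i, 3L),
                                     bead_id = i)
    if ("ramp" %in% steps)
      tr$ramp <- .offset_z(simulate_trace(
        te, proto(diff(config$ramp_range) / config$v_mag,
                  config$ramp_range[1], v = config$v_mag),
        seed = .sub_seed(seed, i, 4L), bead_id = i),
        config$surface_offset, A[i])
    if ("calibration" %in% steps)
      tr$calibration <- lapply(seq_along(config$calib_heights), function(j) {
        .offset_z(simulate_trace(
          te, proto(config$calib_duration, config$calib_heights[j],
                    transverse = TRUE),
          seed = .sub_seed(seed, i, 4L + j), bead_id = i),
          config$surface_offset, A[i])
      })
    traces[[i]] <- tr
  }
  structure(list(config = config, seed = seed, steps = steps,
                 truth = truth, tethers = tethers, traces = traces),
            class = "mt_ensemble")
}

## measured-height convention: the tracked bead height underestimates the
## end-to-end extension by the attachment offset (clamped at surface
## contact) and is shifted by the apparent surface height
.offset_z <- function(trace, offset, A = 0) {
  trace$z <- pmax(trace$z - A, 0) + offset
  trace
}

## rotation measurement: Limacon pattern around the tether position with
## the attachment radius from the true offset and a precession radius from
## the small-angle force-field gradient, plus tracking noise
.rotation_trace <- function(tether, config, seed, bead_id) {
  set.seed(seed)
  d_center <- sqrt(tether$posX^2 + tether$posY^2)
  l_eq <- wlc_extension_at_force(tether$F_0, tether$wlc)
  par <- limacon_params(
    R_att = .radius_from_attachment_offset(tether$A, tether$bead$radius),
    R_prec = (l_eq + tether$bead$radius) *
      tan(config$alpha_per_um * d_center),
    phi_att = runif(1, 0, 2 * pi), phi_prec = runif(1, 0, 2 * pi),
    center = c(tether$posX, tether$posY), omega_mag = config$omega_mag)
  times <- seq(0, config$rotation_turns * 2 * pi / config$omega_mag,
               by = 1 / config$frame_rate)
  xy <- limacon_curve(par, times)
  xy$x <- xy$x + rnorm(length(times), 0, config$sigma_xy)
  xy$y <- xy$y + rnorm(length(times), 0, config$sigma_xy)
  tr <- data.frame(t = xy$t, x = xy$x, y = xy$y, z = 0, bead_id = bead_id)
  class(tr) <- c("mt_trace", "data.frame")
  attr(tr, "frame_rate") <- config$frame_rate
  attr(tr, "limacon_truth") <- par
  tr
}

#' Run the full characterization protocol on a synthetic ensemble
#'
#' Generates the ensemble and runs the per-bead analysis chain: surface
#' reference from the zero-force hold, attachment offset from the Limacon
#' fit of the rotation trace, equipartition force calibration at the
#' calibration heights (bypassed in favour of the true force scale when the
#' simulation is noise-free, where fluctuation-based calibration is
#' undefined), force assignment along the ramp, reordering, energy
#' integration and WLC fitting. Failures of individual beads are isolated
#' and flagged.
#'
#' @param config An [ensemble_config()].
#' @param seed Master seed.
#' @param force_window Calibrated-force window (pN) used in the fit.
#' @param verbose Print one progress line per stage?
#' @return A list of class `mt_protocol_result` with `results` (per-bead
#'   data frame), `report` (an `ensemble_report`), `truth`, and `failed`.
#' @export
run_full_protocol <- function(config, seed = 1,
                              force_window = c(0.01, 2), verbose = FALSE) {
  t0 <- Sys.time()
  steps <- c("noforce", "rotation", "ramp",
             if (config$thermal) "calibration")
  ens <- generate_ensemble(config, seed = seed, steps = steps)
  if (verbose)
    message(sprintf("[synth] %d beads, %d steps, %.1f s",
                    config$n, length(steps),
                    as.numeric(Sys.time() - t0, units = "secs")))
  rows <- list()
  failed <- integer(0)
  for (i in seq_len(config$n)) {
    row <- tryCatch(
      .characterize_bead(ens$tethers[[i]], ens$traces[[i]], config,
                         force_window),
      error = function(e) e)
    if (inherits(row, "error")) {
      failed <- c(failed, i)
      if (verbose) message(sprintf("[bead %d] failed: %s", i,
                                   conditionMessage(row)))
      next
    }
    row$bead_id <- i
    row$group <- ens$truth$group[i]
    rows[[length(rows) + 1]] <- row
  }
  results <- do.call(rbind, rows)
  report <- if (!is.null(results) && nrow(results) >= 5)
    ensemble_analysis(results, R_bead = config$bead$radius) else NULL
  if (verbose)
    message(sprintf("[pipeline] %d/%d beads characterized, %.1f s total",
                    nrow(results), config$n,
                    as.numeric(Sys.time() - t0, units = "secs")))
  structure(list(results = results, report = report, truth = ens$truth,
                 failed = failed, config = config, seed = seed),
            class = "mt_protocol_result")
}

## one bead through the measurement chain
.characterize_bead <- function(tether, traces, config, force_window) {
  reference <- min(traces$noforce$z)
  lim <- fit_limacon(traces$rotation, config$omega_mag,
                     noise_rms = config$sigma_xy)
  R_att <- min(lim$R_att, config$bead$radius)
  A_hat <- attachment_offset_from_radius(R_att, config$bead$radius)
  F0_hat <- if (config$thermal) {
    cal <- vapply(seq_along(config$calib_heights), function(j) {
      tr <- traces$calibration[[j]]
      l_ext <- mean(tr$z) - reference + A_hat
      calibrate_force_equipartition(tr, l_ext, config$bead,
                                    config$temperature,
                                    config$viscosity)$force
    }, numeric(1))
    fit_force_scale(data.frame(Z_mag = config$calib_heights, F = cal),
                    l_dec = config$l_dec, z_ref = config$z_ref)$F_0
  } else {
    tether$F_0 # fluctuation-based calibration is undefined without noise
  }
  ramp <- traces$ramp
  Z_t <- config$ramp_range[1] + config$v_mag * ramp$t
  force <- F0_hat * exp(-(Z_t - config$z_ref) / config$l_dec)
  extension <- apply_attachment_correction(ramp$z - reference, A_hat)
  keep <- force >= force_window[1] & force <= force_window[2] &
    extension > 0
  curve <- fe_curve(force[keep], extension[keep],
                    meta = list(F_0 = F0_hat, A = A_hat,
                                reference = reference))
  energy <- energy_from_force_extension(reorder_monotone(curve),
                                        config$temperature)
  fit <- fit_energy_wlc(energy)
  data.frame(L_p = fit$L_p, L_c = fit$L_c, F_0 = F0_hat, A = A_hat,
             R_att = R_att, R_prec = lim$R_prec,
             classification = fit$classification,
             residual = fit$residual,
             reference = reference)
}

#' @export
print.mt_protocol_result <- function(x, ...) {
  cat(sprintf("MMT protocol run: %d/%d beads characterized (seed %d)\n",
              if (is.null(x$results)) 0 else nrow(x$results),
              x$config$n, x$seed))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Write / read bead trajectory traces
#'
#' Traces are stored as tab-separated text with a header naming the units;
#' the round trip preserves values at full double precision.
#'
#' @param traces A trace data frame (columns `t`, `x`, `y`, `z`,
#'   `bead_id`) or a list of them (concatenated on write).
#' @param path File path.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns
#'   an `mt_trace` data frame.
#' @export
write_traces <- function(traces, path) {
  if (!is.data.frame(traces)) traces <- do.call(rbind, traces)
  .check_trace_schema(traces)
  header <- "# mmtweezers trace v1: t[s] x[um] y[um] z[um] bead_id"
  writeLines(header, path)
  data.table::fwrite(traces[c("t", "x", "y", "z", "bead_id")], path,
                     sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  tr <- as.data.frame(data.table::fread(path, sep = "\t", skip = 1,
                                        header = TRUE))
  .check_trace_schema(tr)
  if (is.unsorted(tr$t) && length(unique(tr$bead_id)) == 1)
    stop("trace times must be increasing")
  class(tr) <- c("mt_trace", "data.frame")
  tr
}

.check_trace_schema <- function(tr) {
  required <- c("t", "x", "y", "z", "bead_id")
  missing <- setdiff(required, names(tr))
  if (length(missing))
    stop("trace schema violation: missing column(s) ",
         paste(missing, collapse = ", "))
  if (!all(vapply(tr[required[1:4]], is.numeric, logical(1))))
    stop("trace schema violation: t, x, y, z must be numeric")
  if (any(!is.finite(as.matrix(tr[required[1:4]]))))
    stop("trace schema violation: non-finite values")
  invisible(TRUE)
}

#' Write / read an ensemble configuration
#'
#' YAML round trip of an [ensemble_config()].
#'
#' @param config An [ensemble_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ensemble_config"))
  x <- unclass(config)
  x$bead <- unclass(x$bead)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bead <- bead_model(x$bead$radius, x$bead$M_sat, x$bead$B_0)
  do.call(ensemble_config, x)
}
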