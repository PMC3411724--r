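## High-throughput tether characterization: surface-reference and
## attachment-offset corrections, equipartition force calibration, the
## reorder-then-integrate energy transform, WLC fitting of the energy curve
## and ensemble statistics.

#' Force-extension curve
#'
#' @param force Forces, pN.
#' @param extension End-to-end extensions, um.
#' @param meta Optional provenance list (calibration factors, corrections).
#' @return A data frame of class `fe_curve`.
#' @export
fe_curve <- function(force, extension, meta = list()) {
  stopifnot(length(force) == length(extension),
            all(is.finite(force)), all(is.finite(extension)))
  out <- data.frame(force = force, extension = extension)
  class(out) <- c("fe_curve", "data.frame")
  attr(out, "meta") <- meta
  out
}

#' Surface-reference height correction
#'
#' The lowest recorded bead height in the absence of applied force
#' corresponds to the apparent height of the bead in contact with the
#' surface; it is subtracted from the measurement trace. Adding a constant
#' to all heights therefore changes nothing downstream.
#'
#' @param trace_at_force Trace (data frame with `z`, um) measured under
#'   force.
#' @param trace_no_force Trace recorded at vanishing force (magnet retracted),
#'   at least 10 s of samples.
#' @return List with `trace` (height-corrected copy of `trace_at_force`)
#'   and `reference` (the subtracted height, um).
#'
#' @details A bead that actually reaches the surface piles up against it, so
#'   the height distribution is dense just above its minimum; a bead that
#'   never gets there leaves the minimum as an isolated tail event. The
#'   contact heuristic warns when the gap between the minimum and the 5th
#'   percentile is large compared to the 5th-to-50th percentile spread.
#' @export
surface_reference_correct <- function(trace_at_force, trace_no_force) {
  stopifnot("z" %in% names(trace_at_force), "z" %in% names(trace_no_force))
  fr <- attr(trace_no_force, "frame_rate")
  n_min <- if (is.null(fr)) 500 else ceiling(10 * fr)
  if (nrow(trace_no_force) < n_min)
    stop("no-force trace must cover at least 10 s of samples")
  reference <- min(trace_no_force$z)
  q <- stats::quantile(trace_no_force$z, c(0.05, 0.5), names = FALSE)
  spread <- q[2] - q[1]
  if (spread > 0 && (q[1] - reference) / spread > 0.5)
    warning("no-force trace barely approaches the surface; ",
            "height reference may be unreliable")
  corrected <- trace_at_force
  corrected$z <- corrected$z - reference
  list(trace = corrected, reference = reference)
}

#' Attachment-offset length correction
#'
#' An eccentric attachment hides tether length `A`; the measured lengths
#' are corrected by `l_ext = l_meas + A` (the inverse of the
#' measured-quantity transform in [apparent_response_with_offset()]).
#'
#' @param lengths Measured extensions, um.
#' @param A Attachment offset, um (>= 0).
#' @return Corrected extensions, um.
#' @export
apply_attachment_correction <- function(lengths, A) {
  stopifnot(A >= 0)
  lengths + A
}

## variance attenuation of an OU process boxcar-averaged over a window of
## phi = T_exp / tau relaxation times
.blur_factor <- function(phi) {
  ifelse(phi < 1e-6, 1 - phi / 3, 2 * (phi - 1 + exp(-phi)) / phi^2)
}

#' Equipartition force calibration from transverse fluctuations
#'
#' The tether-bead system behaves as an inverted pendulum in the transverse
#' direction with stiffness `k = F / (l_ext + R_bead)`, so
#' `F = kBT (l_ext + R_bead) / var(x)`. Camera exposure averaging
#' attenuates the observed variance; when the exposure time is known the
#' attenuation factor for the pendulum's Ornstein-Uhlenbeck dynamics is
#' inverted (one-dimensional root solve), giving a motion-blur-corrected
#' estimate. The standard error is obtained by blocking.
#'
#' @param trace Transverse trace: an `mt_trace` or data frame with an `x`
#'   column (um), at least 1000 stationary frames.
#' @param l_ext Mean tether extension during the trace, um.
#' @param bead A [bead_model()].
#' @param temperature Temperature, K.
#' @param viscosity Viscosity, Pa s (used only for the blur correction).
#' @param exposure Exposure (frame) time, s; defaults to the trace frame
#'   rate, `NULL` disables the blur correction.
#' @param n_blocks Number of blocks for the standard error.
#' @return List with `force` (pN), `se` (pN), `stiffness` (pN/um),
#'   `blur_corrected`.
#' @export
calibrate_force_equipartition <- function(trace, l_ext, bead = bead_model(),
                                          temperature = 295.15,
                                          viscosity = 0.955e-3,
                                          exposure = if (!is.null(attr(trace, "frame_rate")))
                                            1 / attr(trace, "frame_rate"),
                                          n_blocks = 10) {
  x <- trace$x
  if (length(x) < 1000)
    stop("equipartition calibration needs at least 1000 frames")
  v1 <- var(x[seq_len(length(x) %/% 2)])
  v2 <- var(x[-seq_len(length(x) %/% 2)])
  if (max(v1, v2) / min(v1, v2) > 2)
    warning("transverse trace looks non-stationary (half-trace variances ",
            "differ by more than 2x)")
  kT <- kBT(temperature)
  lever <- (l_ext + bead$radius) * 1e-6 # m
  est_k <- function(v_um2) {
    v <- v_um2 * 1e-12 # m^2
    k0 <- kT / v
    if (is.null(exposure)) return(k0)
    gam <- .drag_parallel(l_ext + bead$radius, bead$radius, viscosity)
    f <- function(k) kT / k * .blur_factor(k * exposure / gam) - v
    ## the blurred-variance equation always brackets within [k0/1e3, 10 k0]:
    ## attenuation pushes the root below the naive estimate k0 = kT/v
    uniroot(f, c(k0 * 1e-3, k0 * 10), tol = 1e-30)$root
  }
  k_hat <- est_k(var(x))
  blocks <- split(x, cut(seq_along(x), n_blocks, labels = FALSE))
  F_blocks <- vapply(blocks, function(b) est_k(var(b)) * lever * 1e12,
                     numeric(1))
  list(force = k_hat * lever * 1e12,
       se = sd(F_blocks) / sqrt(n_blocks),
       stiffness = k_hat * 1e6, # N/m -> pN/um
       blur_corrected = !is.null(exposure))
}

#' Bead-specific force scale from calibrations at several heights
#'
#' Log-linear least squares with the decay length fixed:
#' `F(Z) = F_0 exp(-(Z_mag - z_ref) / l_dec)` so
#' `log F_0 = mean(log F + (Z_mag - z_ref) / l_dec)`.
#'
#' @param calibrations Data frame with columns `Z_mag` (mm) and `F` (pN),
#'   at least three rows.
#' @param l_dec Force decay length, mm (default the experimentally measured
#'   1.54 mm).
#' @param z_ref Reference height, mm.
#' @return List with `F_0` (pN) and the residual log-RMS `log_rms`.
#' @export
fit_force_scale <- function(calibrations, l_dec = 1.54, z_ref = 1) {
  stopifnot(all(c("Z_mag", "F") %in% names(calibrations)))
  if (nrow(calibrations) < 3)
    stop("need force estimates at three or more magnet heights")
  lf0 <- log(calibrations$F) + (calibrations$Z_mag - z_ref) / l_dec
  list(F_0 = exp(mean(lf0)), log_rms = sqrt(mean((lf0 - mean(lf0))^2)))
}

#' Reorder a force-extension curve by ascending extension
#'
#' Stable sort of the points by extension (forces travel with their
#' points). Reordering before integration removes scatter from the energy
#' curve because thermal excursions in extension are re-assigned to their
#' proper place on the curve.
#'
#' @param curve An [fe_curve()].
#' @return The reordered [fe_curve()].
#' @export
reorder_monotone <- function(curve) {
  stopifnot(inherits(curve, "fe_curve"))
  o <- order(curve$extension) # stable
  out <- fe_curve(curve$force[o], curve$extension[o], attr(curve, "meta"))
  attr(out, "reordered") <- TRUE
  out
}

#' Energy versus extension by cumulative trapezoidal integration
#'
#' `E(l_k) = sum over i < k of (F_i + F_(i+1))/2 * (l_(i+1) - l_i)`,
#' starting at zero at the first (lowest-extension) point. Fluctuations in
#' bead position average out under the integral, so the energy curve is
#' much smoother than the underlying force-extension data.
#'
#' @param curve An [fe_curve()], reordered to monotone extension.
#' @param temperature Temperature (K) used to express energies in kBT.
#' @return A data frame of class `energy_curve` with columns `extension`
#'   (um) and `E` (kBT).
#' @export
energy_from_force_extension <- function(curve, temperature = 295.15) {
  stopifnot(inherits(curve, "fe_curve"))
  l <- curve$extension
  F <- curve$force
  n <- length(l)
  E_pNum <- if (n < 2) 0 else
    c(0, cumsum((F[-n] + F[-1]) / 2 * diff(l))) # pN um = 1e-18 J
  out <- data.frame(extension = l, E = E_pNum * 1e-18 / kBT(temperature))
  class(out) <- c("energy_curve", "data.frame")
  attr(out, "temperature") <- temperature
  attr(out, "meta") <- attr(curve, "meta")
  out
}

## model energy (kBT) with guarded relative extension
.energy_model <- function(l, L_p, L_c) {
  x <- pmin(l / L_c, 0.999)
  L_c * 1e3 / L_p * .wlc_poly_int(x)
}

#' Fit WLC parameters to an energy-extension curve
#'
#' Nonlinear least squares of
#' `E(l) = E_WLC(l; L_p, L_c) + E_offset` with free persistence length,
#' contour length and energy offset (the offset absorbs the unknown lower
#' integration bound). Tethers with fitted `L_p < 28 nm` are classified as
#' multiply tethered.
#'
#' @param energy An [energy_curve()] (>= 20 points).
#' @param L_p_start,L_c_start Start values (nm, um); `L_c_start` defaults
#'   to 1.05x the maximum extension.
#' @param L_p_bounds Reporting bounds for the persistence length, nm.
#' @return A list of class `tether_fit_result`: `L_p` (nm), `L_c` (um),
#'   `E_offset` (kBT), `residual` (RMS, kBT), `classification`
#'   (`"single"` or `"multiple"`), `bound_violation`.
#' @export
fit_energy_wlc <- function(energy, L_p_start = 50, L_c_start = NULL,
                           L_p_bounds = c(5, 150)) {
  stopifnot(inherits(energy, "energy_curve"))
  if (nrow(energy) < 20) stop("need at least 20 energy points")
  l_max <- max(energy$extension)
  if (is.null(L_c_start)) L_c_start <- 1.05 * l_max
  fit <- minpack.lm::nlsLM(
    E ~ .energy_model(extension, L_p, L_c) + E0,
    data = energy,
    start = list(L_p = L_p_start, L_c = L_c_start, E0 = 0),
    lower = c(L_p = 1, L_c = 1.0001 * l_max, E0 = -Inf),
    upper = c(L_p = 500, L_c = 10 * l_max, E0 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  bound_violation <- cf[["L_p"]] < L_p_bounds[1] ||
    cf[["L_p"]] > L_p_bounds[2] ||
    cf[["L_c"]] < 0.5 * l_max || cf[["L_c"]] > 1.5 * l_max
  structure(list(
    L_p = cf[["L_p"]], L_c = cf[["L_c"]], E_offset = cf[["E0"]],
    residual = sqrt(mean(stats::resid(fit)^2)),
    classification = if (cf[["L_p"]] < 28) "multiple" else "single",
    bound_violation = bound_violation,
    converged = fit$convInfo$isConv %||% TRUE),
    class = "tether_fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tether_fit_result <- function(x, ...) {
  cat(sprintf("WLC fit: L_p = %.1f nm, L_c = %.3f um (%s tether%s)\n",
              x$L_p, x$L_c, x$classification,
              if (x$bound_violation) ", bound violation" else ""))
  invisible(x)
}

#' Ensemble statistics of tether characterizations
#'
#' Removes multiply-tethered outliers (`L_p` below the threshold), reports
#' mean and SD of persistence and contour length per length group, the
#' spread of the normalized force-calibration factor `F_0 / <F_0>`, and a
#' Kolmogorov-Smirnov comparison of the measured attachment offsets with
#' their expected density.
#'
#' @param results Data frame with columns `L_p` (nm), `L_c` (um), and
#'   optionally `F_0` (pN), `A` (um), `group`; at least five rows.
#' @param R_bead Bead radius (um) for the attachment-offset comparison.
#' @param outlier_threshold Multiple-tether threshold on `L_p`, nm.
#' @return A list of class `ensemble_report`.
#' @export
ensemble_analysis <- function(results, R_bead = 0.525,
                              outlier_threshold = 28) {
  stopifnot(all(c("L_p", "L_c") %in% names(results)))
  if (nrow(results) < 5) stop("ensemble analysis needs at least 5 tethers")
  keep <- results$L_p >= outlier_threshold
  out <- list(n_total = nrow(results), n_outliers = sum(!keep),
              outlier_threshold = outlier_threshold,
              all_filtered = !any(keep))
  if (out$all_filtered) {
    out$group_stats <- NULL
    class(out) <- "ensemble_report"
    return(out)
  }
  r <- results[keep, , drop = FALSE]
  grp <- if ("group" %in% names(r)) as.character(r$group)
         else rep("all", nrow(r))
  gs <- do.call(rbind, lapply(split(seq_len(nrow(r)), grp), function(idx) {
    d <- r[idx, , drop = FALSE]
    data.frame(group = grp[idx[1]], n = nrow(d),
               mean_L_p = mean(d$L_p), sd_L_p = sd(d$L_p),
               mean_L_c = mean(d$L_c), sd_L_c = sd(d$L_c))
  }))
  rownames(gs) <- NULL
  out$group_stats <- gs[order(gs$mean_L_c), ]
  if ("F_0" %in% names(r)) {
    F0n <- r$F_0 / mean(r$F_0)
    out$F0_normalized <- F0n
    out$sigma_F0 <- sd(F0n)
  }
  if ("A" %in% names(r)) {
    out$A <- r$A
    ks <- suppressWarnings(
      ks.test(r$A, function(a) attachment_offset_cdf(a, R_bead)))
    out$A_ks_statistic <- unname(ks$statistic)
    out$A_ks_p <- ks$p.value
  }
  class(out) <- "ensemble_report"
  out
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("Ensemble of %d tethers (%d outliers with L_p < %g nm removed)\n",
              x$n_total, x$n_outliers, x$outlier_threshold))
  if (x$all_filtered) {
    cat("  all tethers classified as multiply tethered - nothing to report\n")
    return(invisible(x))
  }
  print(x$group_stats, digits = 3)
  if (!is.null(x$sigma_F0))
    cat(sprintf("  sigma of F_0/<F_0>: %.3f\n", x$sigma_F0))
  if (!is.null(x$A_ks_p))
    cat(sprintf("  attachment offsets vs expected density: KS D = %.3f (p = %.3f)\n",
                x$A_ks_statistic, x$A_ks_p))
  invisible(x)
}
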