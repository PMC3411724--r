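## Worm-like-chain elasticity: the Marko-Siggia interpolation formula with
## the Bouchiat et al. seven-parameter polynomial correction, its exact
## antiderivative (stretching energy), and the force -> extension inverse.
##
## Units contract: extensions and contour lengths in um, persistence length
## in nm, forces in pN, energies in kBT (and J on request).

#' Worm-like-chain parameters
#'
#' @param L_c Contour length, um.
#' @param L_p Persistence length, nm.
#' @param temperature Temperature, K (default 295.15 K = 22 C).
#' @return An object of class `wlc_params`.
#' @export
wlc_params <- function(L_c, L_p = 50, temperature = 295.15) {
  stopifnot(L_c > 0, L_p > 0, temperature > 0)
  structure(list(L_c = L_c, L_p = L_p, temperature = temperature),
            class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("WLC: L_c = %g um, L_p = %g nm, T = %g K\n",
              x$L_c, x$L_p, x$temperature))
  invisible(x)
}

## dimensionless force law f(x) = F * L_p / kBT; correction = TRUE adds the
## Bouchiat polynomial terms
.wlc_poly <- function(x, correction = TRUE) {
  p <- 1 / (4 * (1 - x)^2) - 1 / 4 + x
  if (correction)
    for (i in 2:7) p <- p + .bouchiat_a[i - 1] * x^i
  p
}

## its antiderivative, zero at x = 0 (integral of f dx)
.wlc_poly_int <- function(x, correction = TRUE) {
  e <- 1 / (4 * (1 - x)) - 1 / 4 - x / 4 + x^2 / 2
  if (correction)
    for (i in 2:7) e <- e + .bouchiat_a[i - 1] * x^(i + 1) / (i + 1)
  e
}

#' Worm-like-chain force at a given extension
#'
#' Entropic restoring force of the WLC,
#' `F = (kBT / L_p) * (1/(4(1-x)^2) - 1/4 + x + sum(a_i x^i))` with
#' `x = extension / L_c`; strictly increasing and divergent as `x -> 1`.
#' With `correction = FALSE` the plain interpolation formula (no polynomial
#' terms) is returned.
#'
#' @param extension End-to-end extension(s), um.
#' @param params A [wlc_params()].
#' @param correction Include the seven-parameter polynomial correction?
#' @return Force(s), pN.
#' @examples
#' wlc_force(1.24, wlc_params(L_c = 2.48, L_p = 50)) # ~0.088 pN at x = 0.5
#' @export
wlc_force <- function(extension, params, correction = TRUE) {
  x <- extension / params$L_c
  if (any(x < 0 | x >= 1)) stop("extension must satisfy 0 <= extension < L_c")
  kT <- kBT(params$temperature)
  kT / (params$L_p * 1e-9) * .wlc_poly(x, correction) * 1e12 # N -> pN
}

#' WLC stiffness dF/dz at a given extension
#'
#' @inheritParams wlc_force
#' @return Stiffness(es), pN/um.
#' @export
wlc_stiffness <- function(extension, params, correction = TRUE) {
  x <- extension / params$L_c
  if (any(x < 0 | x >= 1)) stop("extension must satisfy 0 <= extension < L_c")
  dp <- 1 / (2 * (1 - x)^3) + 1
  if (correction)
    for (i in 2:7) dp <- dp + i * .bouchiat_a[i - 1] * x^(i - 1)
  kT <- kBT(params$temperature)
  kT / (params$L_p * 1e-9) * dp / params$L_c * 1e12 # pN per um
}

#' Stretching energy of the WLC
#'
#' Work required to stretch the chain from zero extension,
#' `E(l) = integral of F from 0 to l`, evaluated from the exact
#' antiderivative of the force law (so `dE/dl = F` holds to numerical
#' precision).
#'
#' @inheritParams wlc_force
#' @param units `"kBT"` (default) or `"J"`.
#' @return Energy(ies) in the requested units.
#' @export
wlc_energy <- function(extension, params, correction = TRUE,
                       units = c("kBT", "J")) {
  units <- match.arg(units)
  x <- extension / params$L_c
  if (any(x < 0 | x >= 1)) stop("extension must satisfy 0 <= extension < L_c")
  E_kT <- params$L_c * 1e3 / params$L_p * .wlc_poly_int(x, correction)
  if (units == "kBT") E_kT else E_kT * kBT(params$temperature)
}

#' Extension at a given force (inverse WLC)
#'
#' Bracketed root of `wlc_force(l) = force`; returns 0 at zero force.
#'
#' @param force Force(s), pN (>= 0).
#' @inheritParams wlc_force
#' @return Extension(s), um.
#' @export
wlc_extension_at_force <- function(force, params, correction = TRUE) {
  stopifnot(all(force >= 0))
  vapply(force, function(f) {
    if (f == 0) return(0)
    g <- function(l) wlc_force(l, params, correction) - f
    uniroot(g, c(0, params$L_c * (1 - 1e-12)), tol = 1e-12)$root
  }, numeric(1))
}
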