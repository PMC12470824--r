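# Compton kinematics and Beer-Lambert attenuation primitives shared by the
# simulator, the projector and the metrics.  All angles are radians
# internally; conversion to degrees happens only at reporting boundaries.

#' Electron rest energy in keV
#' @return 511 (keV), the electron rest energy m_e c^2.
#' @export
electronRestEnergy <- function() 511

# Boundary guard for arccos arguments: round-off within this distance of
# +/-1 is clipped; anything farther out is a physically impossible event.
.COS_CLIP <- 1e-9

#' Signal a kinematically impossible (E1, E2) pair
#' @noRd
.invalidEvent <- function(msg, arg = NULL) {
  stop(structure(
    class = c("ccxfct_invalid_event", "error", "condition"),
    list(message = msg, call = sys.call(-1), cosArg = arg)))
}

#' Compton scattering angle from deposited energies
#'
#' Inverts the Compton relation for the scattering angle:
#' \deqn{\theta = \arccos\left(1 - m_e c^2 \left(\frac{1}{E_2} -
#'   \frac{1}{E_0}\right)\right), \qquad E_0 = E_1 + E_2,}
#' where `E1` is the energy deposited at the scatter point (recoil
#' electron) and `E2` the energy of the scattered photon (absorbed in the
#' second layer).
#'
#' @param E1 energy deposited in the scatter layer, keV (>= 0). Vectorized.
#' @param E2 energy deposited in the absorber layer, keV (> 0). Vectorized.
#' @return scattering angle(s) in radians, in `[0, pi]`; 0 iff `E1 == 0`.
#'   Cosine arguments outside `[-1, 1]` by more than a 1e-9 round-off
#'   guard raise an error of class `"ccxfct_invalid_event"`.
#' @examples
#' scatterAngleFromEnergies(0, 68.8)        # forward, 0
#' scatterAngleFromEnergies(11.083, 69.917) # ~ pi/2 at E0 = 81 keV
#' @export
scatterAngleFromEnergies <- function(E1, E2) {
  stopifnot(all(E1 >= 0), all(E2 > 0))
  E0 <- E1 + E2
  arg <- 1 - electronRestEnergy() * (1 / E2 - 1 / E0)
  bad <- abs(arg) > 1 + .COS_CLIP
  if (any(bad))
    .invalidEvent(sprintf(
      "kinematically impossible energy pair: cos(theta) argument %.6g outside [-1, 1]",
      arg[which(bad)[1L]]), arg[bad])
  acos(pmin(1, pmax(-1, arg)))
}

#' Deposited energies for a given scattering angle
#'
#' Inverse of [scatterAngleFromEnergies()]: for an incident photon of
#' energy `E0` scattered by `theta`, the scattered-photon energy is
#' \deqn{E_2 = \frac{E_0}{1 + (E_0/m_e c^2)(1 - \cos\theta)}}
#' and the recoil electron takes `E1 = E0 - E2`.
#'
#' @param E0 incident photon energy, keV (> 0). Vectorized.
#' @param theta scattering angle, radians in `[0, pi]`. Vectorized.
#' @return list with components `E1` and `E2` (keV); `E1 + E2 == E0`
#'   exactly.
#' @examples
#' energiesFromAngle(81, pi / 2)
#' @export
energiesFromAngle <- function(E0, theta) {
  stopifnot(all(E0 > 0), all(theta >= 0), all(theta <= pi + 1e-12))
  E2 <- E0 / (1 + (E0 / electronRestEnergy()) * (1 - cos(theta)))
  list(E1 = E0 - E2, E2 = E2)
}

#' Beer-Lambert transmission through a uniform slab
#'
#' @param mu linear attenuation coefficient, 1/mm (>= 0).
#' @param d path length, mm (>= 0).
#' @return transmitted fraction `exp(-mu * d)` in `(0, 1]`.
#' @export
transmission <- function(mu, d) {
  stopifnot(all(mu >= 0), all(d >= 0))
  exp(-mu * d)
}

#' Fraction of photons depositing energy in a slab
#'
#' @inheritParams transmission
#' @return `1 - exp(-mu * d)` in `[0, 1)`.
#' @export
depositionFraction <- function(mu, d) {
  1 - transmission(mu, d)
}

#' Survival probability along a piecewise-uniform path
#'
#' The product of per-segment transmissions
#' \eqn{\prod_k e^{-\mu_k d_k}}; equal to the transmission of the summed
#' optical depth.
#'
#' @param segments two-column matrix (or coercible data.frame/list of
#'   pairs) with columns `mu` (1/mm) and `d` (mm); zero rows give 1.
#' @return survival probability in `(0, 1]`.
#' @export
pathSurvival <- function(segments) {
  if (is.null(segments) || length(segments) == 0L) return(1)
  m <- as.matrix(as.data.frame(segments))
  if (nrow(m) == 0L) return(1)
  stopifnot(ncol(m) == 2L, all(m >= 0))
  exp(-sum(m[, 1L] * m[, 2L]))
}
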