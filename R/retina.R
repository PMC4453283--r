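#' Foveal-anchored cone density
#'
#' Cone density as a function of age and eccentricity, in relative density
#' units: \code{N_c(A, e) = (6952.7 - 38.70 A) exp(-0.35 e) + 300}. The
#' exponential term captures the foveal peak that declines with age; the
#' floor term the nearly age-stable peripheral density. Only density
#' ratios enter the CSF, so the absolute units cancel.
#'
#' @param age Age A, years.
#' @param eccentricity Eccentricity e, deg (>= 0). Default 0 (fovea).
#' @param constants A \code{\link{csf_constants}} list.
#' @return Cone density (> 0); decreasing in both age and eccentricity.
#' @examples
#' cone_density(30, 0)
#' @export
cone_density <- function(age, eccentricity = 0, constants = csf_constants()) {
  if (any(eccentricity < 0))
    stop("eccentricity must be >= 0 deg", call. = FALSE)
  nc <- (constants$cone_intercept - constants$cone_slope * age) *
    exp(-constants$cone_ecc_rate * eccentricity) + constants$cone_floor
  if (any(nc <= 0))
    stop("cone density is non-positive: age outside the model's range",
         call. = FALSE)
  nc
}

#' Eccentricity scale of the primary ganglion-density lobe
#'
#' The half-width (in deg, signed) of the dominant Lorentzian lobe of the
#' ganglion-cell density profile:
#' \code{a(A) = -0.404 exp(-0.01246 A) - 0.1792 exp(0.01525 A)}.
#' The value is negative for every age; only its square is consumed by
#' \code{\link{ganglion_density}}, so the sign is immaterial downstream.
#'
#' @param age Age in years.
#' @return The (negative) eccentricity scale in deg.
#' @examples
#' eccentricity_scale(c(20, 80))
#' @export
eccentricity_scale <- function(age) {
  -0.404 * exp(-0.01246 * age) - 0.1792 * exp(0.01525 * age)
}

#' Ganglion-cell density
#'
#' Ganglion-cell density versus age and eccentricity, anchored at three
#' times the foveal cone density (each ganglion cell is connected to about
#' three cones, at every age and eccentricity):
#' \deqn{N_g(A,e) = 3 N_c(A,0) [0.85 / (1 + (e/a(A))^2) +
#'   0.15 / (1 + (e/7.3)^2)]}
#' with \code{a(A)} from \code{\link{eccentricity_scale}}. The bracket
#' equals 1 at \code{e = 0}, so \code{N_g(A, 0) = 3 N_c(A, 0)} exactly.
#'
#' @inheritParams cone_density
#' @return Ganglion density in the same relative units as
#'   \code{\link{cone_density}}; strictly decreasing in eccentricity.
#' @examples
#' ganglion_density(30, c(0, 10, 45))
#' @export
ganglion_density <- function(age, eccentricity = 0,
                             constants = csf_constants()) {
  if (any(eccentricity < 0))
    stop("eccentricity must be >= 0 deg", call. = FALSE)
  nc0 <- cone_density(age, 0, constants)
  a <- eccentricity_scale(age)
  constants$ganglion_cone_ratio * nc0 *
    (0.85 / (1 + (eccentricity / a)^2) +
     0.15 / (1 + (eccentricity / constants$secondary_ecc_scale)^2))
}

# Eccentricity bracket of the foveal-anchored inhibition cut-off; the
# weights sum to exactly 1 at e = 0 (0.85 + 0.13 + 0.02).
inhibition_bracket <- function(eccentricity) {
  0.85 / (1 + (eccentricity / 4)^2) +
    0.13 / (1 + (eccentricity / 20)^2) + 0.02
}

#' Lateral-inhibition drop-off frequency
#'
#' Spatial drop-off frequency of the retinal lateral-inhibition (neural)
#' MTF. In the fovea it is a fixed 7 cpd at every age; away from the fovea
#' it scales with the age-dependent ganglion-cell density ratio
#' \code{N_g(A,e)/N_g(A,0)} and with a fixed eccentricity bracket:
#' \deqn{u_{inh}(A,e) = u_{inh}(0) \frac{N_g(A,e)}{N_g(A,0)}
#'   [0.85/(1+(e/4)^2) + 0.13/(1+(e/20)^2) + 0.02]^{-1/2}.}
#' With \code{constants$inhibition_ratio = "sqrt"} the density ratio enters
#' under a square root instead (an alternative reading of the same
#' density-scaling idea).
#'
#' @inheritParams cone_density
#' @return Drop-off frequency in cpd; exactly \code{constants$u0} (7 cpd)
#'   at \code{eccentricity = 0} for every age.
#' @examples
#' inhibition_cutoff(30, c(0, 10))
#' @export
inhibition_cutoff <- function(age, eccentricity = 0,
                              constants = csf_constants()) {
  ratio <- ganglion_density(age, eccentricity, constants) /
    ganglion_density(age, 0, constants)
  if (constants$inhibition_ratio == "sqrt") ratio <- sqrt(ratio)
  constants$u0 * ratio * inhibition_bracket(eccentricity)^(-0.5)
}

#' Lateral-inhibition (neural) MTF
#'
#' High-pass MTF of the centre-surround receptive-field architecture:
#' \code{M_lat(u) = sqrt(1 - exp(-(u / u_inh)^2))}. It vanishes at zero
#' frequency (full inhibition of uniform fields), rises monotonically and
#' tends to 1 well above the drop-off frequency.
#'
#' @param u Spatial frequency, cpd (>= 0); vectorised.
#' @param u_inh Drop-off frequency, cpd (> 0).
#' @return Modulation transfer in [0, 1).
#' @examples
#' lateral_mtf(c(0, 7, 30), 7)
#' @export
lateral_mtf <- function(u, u_inh) {
  if (any(u < 0)) stop("spatial frequency must be >= 0", call. = FALSE)
  if (any(!is.finite(u_inh)) || any(u_inh <= 0))
    stop("u_inh must be > 0 cpd", call. = FALSE)
  sqrt(1 - exp(-(u / u_inh)^2))
}

#' Photon-noise spectral density
#'
#' Noise spectral density due to the statistical fluctuation of absorbed
#' photons: \code{Phi_opt = 1 / (eta * p * E)}. Doubling the retinal
#' illuminance halves the photon noise.
#'
#' @param eta Quantum efficiency, fraction in (0, 1).
#' @param E Retinal illuminance, troland (> 0).
#' @param p Photon conversion factor, photons s^-1 deg^-2 Td^-1 (> 0).
#' @return Photon noise in s deg^2.
#' @examples
#' photon_noise(0.03, retinal_illuminance(3, 100))
#' @export
photon_noise <- function(eta, E, p = csf_constants()$p) {
  if (any(!is.finite(eta)) || any(eta <= 0) ||
      any(!is.finite(E)) || any(E <= 0) ||
      any(!is.finite(p)) || any(p <= 0))
    stop("eta, E and p must all be > 0", call. = FALSE)
  1 / (eta * p * E)
}

#' Neural-noise spectral density
#'
#' Illuminance-independent noise of the post-receptoral pathway. It is a
#' fixed \code{phi0 = 3e-8} s deg^2 in the fovea at every age, and grows
#' off-fovea in inverse proportion to the ganglion-cell density:
#' \code{Phi_neu(A, e) = phi0 * N_g(A, 0) / N_g(A, e)}.
#'
#' @inheritParams cone_density
#' @param phi0 Foveal neural noise, s deg^2 (> 0).
#' @return Neural noise in s deg^2; equals \code{phi0} at the fovea and is
#'   non-decreasing in eccentricity.
#' @examples
#' neural_noise(30, c(0, 45))
#' @export
neural_noise <- function(age, eccentricity = 0,
                         phi0 = csf_constants()$phi0,
                         constants = csf_constants()) {
  if (any(!is.finite(phi0)) || any(phi0 <= 0))
    stop("phi0 must be > 0", call. = FALSE)
  phi0 * ganglion_density(age, 0, constants) /
    ganglion_density(age, eccentricity, constants)
}
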