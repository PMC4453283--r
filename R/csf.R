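# Shared core of every CSF variant: a signal-to-noise detection rule.
# sensitivity = gain * M_opt(u)/k * sqrt(XYT / (2*(phi_opt + phi_neu/M_lat^2)))
# At u = 0 the lateral-inhibition MTF vanishes, the neural term diverges
# and the sensitivity is exactly 0 (uniform fields are invisible).
csf_core <- function(u, XYT, k, sigma_opt, u_opt, phi_opt, phi_neu_eff,
                     gain) {
  m_opt <- optical_mtf(u, sigma_opt, u_opt)
  gain * m_opt / k * sqrt(XYT / (2 * (phi_opt + phi_neu_eff)))
}

effective_T <- function(conditions, Te) min(Te, conditions$presentation_time)

#' Age-independent baseline CSF
#'
#' The classical signal-to-noise CSF: the grating is low-passed by the
#' eye's optics, corrupted by photon and neural noise (the latter
#' high-passed by lateral inhibition), and detected when its modulation
#' exceeds k times the internal noise modulation:
#' \deqn{CSF(u) = \frac{M_{opt}(u)}{k}
#'   \sqrt{\frac{XYT}{2 (\Phi_{opt} + \Phi_{neu}/M_{lat}^2(u))}}}
#' with \code{T = min(Te, To)}. The pupil diameter defaults to the
#' luminance-dependent unified formula (a reference-age observer); pass
#' \code{diameter} to override, which is how the age-resolved model
#' reuses this function.
#'
#' The baseline is a foveal model: unless \code{u_inh} and \code{phi_neu}
#' are supplied, the foveal constants (7 cpd, 3e-8 s deg^2) are used
#' regardless of the eccentricity stored in \code{conditions}.
#'
#' @param u Spatial frequencies, cpd (>= 0); vectorised.
#' @param conditions A \code{\link{viewing_conditions}} object.
#' @param params A \code{\link{csf_params}} object (default
#'   \code{\link{barten_params}()}).
#' @param diameter Optional pupil diameter in mm overriding the unified
#'   formula.
#' @param u_inh,phi_neu Optional overrides of the lateral-inhibition
#'   drop-off frequency (cpd) and neural noise (s deg^2).
#' @param constants A \code{\link{csf_constants}} list (supplies the
#'   global gain and the neural-term convention).
#' @return Contrast sensitivity (dimensionless), same length as \code{u}.
#' @examples
#' cnd <- viewing_conditions(60, 7, eyes = 1)
#' csf_barten(c(1, 2, 4, 8, 16), cnd)
#' @export
csf_barten <- function(u, conditions, params = barten_params(),
                       diameter = NULL, u_inh = params$u0,
                       phi_neu = params$phi0,
                       constants = csf_constants()) {
  stopifnot(inherits(conditions, "viewing_conditions"),
            inherits(params, "csf_params"))
  if (is.null(diameter))
    diameter <- stanley_davies_diameter(conditions$luminance,
                                        conditions$area, conditions$eyes)
  E <- retinal_illuminance(diameter, conditions$luminance)
  sigma_opt <- optical_sd(params$sigma0, diameter, params$Cab)
  phi_opt <- photon_noise(params$eta, E, params$p)
  m_lat <- lateral_mtf(u, u_inh)
  expo <- if (constants$squared_neural_term) 2 else 1
  XYT <- conditions$field_x * conditions$field_y *
    effective_T(conditions, params$Te)
  csf_core(u, XYT, params$k, sigma_opt, params$u_opt, phi_opt,
           phi_neu / m_lat^expo, constants$gain)
}

#' Age-dependent spatial CSF
#'
#' The baseline model with every optical and physiological component
#' resolved as a function of observer age: the pupil diameter follows the
#' age-corrected pupil model (hence so does the retinal illuminance and
#' the aberration part of the optical blur), sigma0, eta, k and u_opt
#' follow their fitted age curves, and off-fovea the neural noise and the
#' lateral-inhibition drop-off frequency scale with the age-dependent
#' ganglion-cell density.
#'
#' @param age Observer age in years (>= 17).
#' @param u Spatial frequencies, cpd; vectorised.
#' @param conditions A \code{\link{viewing_conditions}} object.
#' @param params A \code{\link{csf_params}} object; defaults to
#'   \code{\link{params_for_age}(age)}. Supplying explicit parameters
#'   keeps the age-resolved optics (pupil) and retinal topography while
#'   overriding the four fitted parameters, which is what the fitting
#'   engine does.
#' @param constants A \code{\link{csf_constants}} list.
#' @return Contrast sensitivity, same length as \code{u}.
#' @examples
#' cnd <- viewing_conditions(100, 5.5, eyes = 2)
#' csf_spatial(70, c(2, 4, 8, 16), cnd)
#' @export
csf_spatial <- function(age, u, conditions,
                        params = params_for_age(age, constants),
                        constants = csf_constants()) {
  stopifnot(length(age) == 1L)
  check_model_age(age)
  d <- pupil_diameter(age, conditions$luminance, conditions$area,
                      conditions$eyes)
  e <- conditions$eccentricity
  csf_barten(u, conditions, params, diameter = d,
             u_inh = inhibition_cutoff(age, e, constants),
             phi_neu = neural_noise(age, e, params$phi0, constants),
             constants = constants)
}

#' Temporal filter pair for the spatiotemporal CSF
#'
#' The spatiotemporal model needs two temporal MTFs: \code{H1}, the
#' temporal filtering of the signal captured by the photoreceptors, and
#' \code{H2}, the temporal component of lateral inhibition. Their exact
#' functional forms are left pluggable; the default identity filters
#' (\code{H1 = H2 = 1} at every frequency) reduce the model to the
#' spatial CSF scaled by the temporal signal-to-noise factor
#' \code{\link{kstar_of_w}}.
#'
#' @param H1,H2 Functions of temporal frequency (Hz) returning a
#'   modulation transfer in (0, 1], with \code{H(0) = 1} by convention.
#' @return An object of class \code{"temporal_filters"}.
#' @examples
#' temporal_filters()  # identity filters
#' temporal_filters(H1 = function(w) exp(-w / 40))
#' @export
temporal_filters <- function(H1 = function(w) rep(1, length(w)),
                             H2 = function(w) rep(1, length(w))) {
  stopifnot(is.function(H1), is.function(H2))
  for (f in list(H1, H2)) {
    probe <- f(c(0, 1, 10))
    if (any(!is.finite(probe)) || any(probe <= 0) || any(probe > 1))
      stop("temporal filters must return values in (0, 1]", call. = FALSE)
  }
  structure(list(H1 = H1, H2 = H2), class = "temporal_filters")
}

#' Age-dependent spatiotemporal CSF
#'
#' Extension of the spatial age model to drifting/flickering gratings at
#' temporal frequency \code{w}. Two changes relative to
#' \code{\link{csf_spatial}}: the detection threshold rises with temporal
#' frequency through the separable signal-to-noise factor
#' \code{k(A, w) = k(A) * kstar(w)}, and the neural noise term becomes
#' \code{Phi_neu / (H1(w) * (1 - H2(w) * (1 - M_lat(u))))^2}, i.e. the
#' spatial lateral-inhibition MTF is replaced by its temporally filtered
#' counterpart (with \code{constants$squared_neural_term = FALSE} the
#' denominator is used unsquared instead).
#'
#' @inheritParams csf_spatial
#' @param w Temporal frequency, Hz (>= 0; scalar).
#' @param filters A \code{\link{temporal_filters}} object.
#' @return Contrast sensitivity, same length as \code{u}. With identity
#'   filters and \code{w = 0.5} this equals
#'   \code{csf_spatial(...) / 1.0835}.
#' @examples
#' cnd <- viewing_conditions(100, 6, eyes = 1)
#' csf_spatiotemporal(30, c(1, 4, 8), w = 7.5, cnd)
#' @export
csf_spatiotemporal <- function(age, u, w, conditions,
                               params = params_for_age(age, constants),
                               filters = temporal_filters(),
                               constants = csf_constants()) {
  stopifnot(length(age) == 1L, length(w) == 1L,
            inherits(filters, "temporal_filters"),
            inherits(conditions, "viewing_conditions"),
            inherits(params, "csf_params"))
  check_model_age(age)
  if (!is.finite(w) || w < 0)
    stop("temporal frequency must be >= 0 Hz", call. = FALSE)
  d <- pupil_diameter(age, conditions$luminance, conditions$area,
                      conditions$eyes)
  e <- conditions$eccentricity
  E <- retinal_illuminance(d, conditions$luminance)
  sigma_opt <- optical_sd(params$sigma0, d, params$Cab)
  phi_opt <- photon_noise(params$eta, E, params$p)
  phi_neu <- neural_noise(age, e, params$phi0, constants)
  m_lat <- lateral_mtf(u, inhibition_cutoff(age, e, constants))
  h1 <- filters$H1(w)
  h2 <- filters$H2(w)
  m_lat_t <- h1 * (1 - h2 * (1 - m_lat))
  expo <- if (constants$squared_neural_term) 2 else 1
  XYT <- conditions$field_x * conditions$field_y *
    effective_T(conditions, params$Te)
  k_total <- params$k * kstar_of_w(w)
  csf_core(u, XYT, k_total, sigma_opt, params$u_opt, phi_opt,
           phi_neu / m_lat_t^expo, constants$gain)
}
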