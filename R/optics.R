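#' Viewing conditions
#'
#' Bundles the stimulus and adaptation parameters that the CSF model
#' needs: adaptation luminance, angular field size, stimulus area, number
#' of eyes, presentation time and retinal eccentricity.
#'
#' The experiments the model was calibrated on report a single square
#' field-of-view angle, so by default the stimulus is \code{X} by \code{Y}
#' degrees with area \code{S = X * Y}. The effective integration time used
#' by the model is \code{min(Te, To)}; an unbounded presentation time
#' (\code{To = Inf}, the default) leaves the eye's own integration time in
#' charge.
#'
#' @param luminance Adaptation luminance L, cd/m^2 (> 0).
#' @param field_x,field_y Angular field size X, Y in deg (> 0);
#'   \code{field_y} defaults to \code{field_x} (square field).
#' @param area Stimulus area S in deg^2; defaults to \code{field_x * field_y}.
#' @param eyes 1 (monocular) or 2 (binocular).
#' @param presentation_time Stimulus presentation time To in s (default
#'   \code{Inf}).
#' @param eccentricity Retinal eccentricity e in deg (>= 0, default 0:
#'   foveal viewing).
#' @return An object of class \code{"viewing_conditions"}.
#' @examples
#' viewing_conditions(100, 5.5, eyes = 2)
#' @export
viewing_conditions <- function(luminance, field_x, field_y = field_x,
                               area = field_x * field_y, eyes = 2,
                               presentation_time = Inf, eccentricity = 0) {
  stopifnot(is.numeric(luminance), length(luminance) == 1L,
            is.numeric(field_x), length(field_x) == 1L,
            is.numeric(field_y), length(field_y) == 1L,
            is.numeric(area), length(area) == 1L,
            length(eyes) == 1L, length(presentation_time) == 1L,
            length(eccentricity) == 1L)
  if (!is.finite(luminance) || luminance <= 0)
    stop("luminance must be > 0 cd/m^2", call. = FALSE)
  if (!is.finite(field_x) || field_x <= 0 || !is.finite(field_y) || field_y <= 0)
    stop("field sizes must be > 0 deg", call. = FALSE)
  if (!is.finite(area) || area <= 0)
    stop("stimulus area must be > 0 deg^2", call. = FALSE)
  if (!eyes %in% c(1, 2))
    stop("eyes must be 1 (monocular) or 2 (binocular)", call. = FALSE)
  if (is.na(presentation_time) || presentation_time <= 0)
    stop("presentation time must be > 0 s", call. = FALSE)
  if (!is.finite(eccentricity) || eccentricity < 0)
    stop("eccentricity must be >= 0 deg", call. = FALSE)
  structure(list(luminance = luminance, field_x = field_x, field_y = field_y,
                 area = area, eyes = as.integer(eyes),
                 presentation_time = presentation_time,
                 eccentricity = eccentricity),
            class = "viewing_conditions")
}

#' @export
print.viewing_conditions <- function(x, ...) {
  cat(sprintf(paste0("Viewing conditions: L = %g cd/m^2, field %g x %g deg",
                     " (S = %g deg^2), %s, To = %g s, e = %g deg\n"),
              x$luminance, x$field_x, x$field_y, x$area,
              if (x$eyes == 2) "binocular" else "monocular",
              x$presentation_time, x$eccentricity))
  invisible(x)
}

#' Luminance-dependent pupil diameter (unified formula)
#'
#' Pupil diameter of a standard (reference-age) observer as a function of
#' the adapting corneal flux: the Stanley-Davies/unified formula used as
#' the luminance-dependent core of Watson's age-dependent pupil model.
#' The effective flux is \code{L * S * F(n)} with a monocular attenuation
#' \code{F(1) = 0.1} and \code{F(2) = 1}.
#'
#' @param luminance Adaptation luminance, cd/m^2 (> 0).
#' @param area Stimulus (field) area, deg^2 (> 0).
#' @param eyes 1 or 2.
#' @return Pupil diameter D in mm, strictly between 2.0 and 7.75.
#' @examples
#' stanley_davies_diameter(100, 30.25, 2)
#' @seealso \code{\link{pupil_diameter}} for the age-corrected diameter.
#' @export
stanley_davies_diameter <- function(luminance, area, eyes = 2) {
  if (any(!is.finite(luminance)) || any(luminance <= 0))
    stop("luminance must be > 0", call. = FALSE)
  if (any(!is.finite(area)) || any(area <= 0))
    stop("area must be > 0", call. = FALSE)
  if (!all(eyes %in% c(1, 2)))
    stop("eyes must be 1 or 2", call. = FALSE)
  f <- ifelse(eyes == 2, 1, 0.1)
  x <- (luminance * area * f / 846)^0.41
  7.75 - 5.75 * x / (x + 2)
}

#' Age-dependent pupil diameter
#'
#' Watson's age correction applied to the luminance-dependent diameter
#' \code{D}: \code{d = D + (A - 28.58) * (0.02132 - 0.009562 * D)}. For
#' photopic diameters (D above about 2.23 mm) the slope is negative, i.e.
#' the pupil shrinks with age (senile miosis). At the reference age 28.58
#' years the correction vanishes.
#'
#' @param age Observer age A in years.
#' @param luminance,area,eyes As in \code{\link{stanley_davies_diameter}}.
#' @return Pupil diameter d in mm (> 0). Extreme extrapolations that would
#'   produce a non-positive diameter raise an error rather than being
#'   clamped, because a silently clamped pupil would corrupt the retinal
#'   illuminance and noise terms downstream.
#' @examples
#' pupil_diameter(70, 100, 30.25, 2)
#' @export
pupil_diameter <- function(age, luminance, area, eyes = 2) {
  if (any(!is.finite(age)))
    stop("age must be finite", call. = FALSE)
  D <- stanley_davies_diameter(luminance, area, eyes)
  d <- D + (age - 28.58) * (0.02132 - 0.009562 * D)
  if (any(d <= 0))
    stop("age-corrected pupil diameter is non-positive (age ",
         paste(age[d <= 0], collapse = ", "),
         " is outside the model's valid extrapolation range)", call. = FALSE)
  d
}

#' Retinal illuminance with Stiles-Crawford correction
#'
#' Converts adaptation luminance and pupil diameter to retinal illuminance
#' in trolands, \code{E = (pi L d^2 / 4) (1 - (d/9.7)^2 + (d/12.4)^4)},
#' where the bracket is the Stiles-Crawford correction for the reduced
#' luminous efficiency of rays entering near the pupil margin.
#'
#' @param diameter Pupil diameter d, mm (> 0; physiological range <= 9 mm).
#' @param luminance Adaptation luminance L, cd/m^2 (> 0).
#' @return Retinal illuminance in troland; linear in \code{luminance}.
#' @examples
#' retinal_illuminance(3, 100)
#' @export
retinal_illuminance <- function(diameter, luminance) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("pupil diameter must be > 0 mm", call. = FALSE)
  if (any(!is.finite(luminance)) || any(luminance <= 0))
    stop("luminance must be > 0 cd/m^2", call. = FALSE)
  pi * luminance * diameter^2 / 4 *
    (1 - (diameter / 9.7)^2 + (diameter / 12.4)^4)
}

#' Standard deviation of the optical point spread
#'
#' Combines the age-fitted intrinsic blur \code{sigma0} with the
#' pupil-dependent aberration term: \code{sigma_opt =
#' sqrt(sigma0^2 + (Cab * d)^2)}. Both components are treated as
#' dimensionless; the spatial-frequency normalisation happens in
#' \code{\link{optical_mtf}} through the optical cut-off frequency.
#'
#' @param sigma0 Intrinsic optical standard deviation (>= 0).
#' @param diameter Pupil diameter d, mm (> 0).
#' @param Cab Aberration coefficient, per mm (>= 0; default 0.08).
#' @return sigma_opt, never smaller than \code{sigma0}.
#' @examples
#' optical_sd(0.5, 3)
#' @export
optical_sd <- function(sigma0, diameter, Cab = 0.08) {
  if (any(sigma0 < 0) || any(Cab < 0))
    stop("sigma0 and Cab must be >= 0", call. = FALSE)
  if (any(diameter <= 0))
    stop("pupil diameter must be > 0", call. = FALSE)
  sqrt(sigma0^2 + (Cab * diameter)^2)
}

#' Optical modulation transfer function of the eye
#'
#' Gaussian low-pass MTF of the eye's optics:
#' \code{M_opt(u) = exp(-2 pi^2 sigma_opt^2 (u / u_opt)^2)}.
#'
#' @param u Spatial frequency, cpd (>= 0); vectorised.
#' @param sigma_opt Optical standard deviation (dimensionless, >= 0).
#' @param u_opt Optical cut-off frequency, cpd (> 0).
#' @return Modulation transfer in (0, 1]; equals 1 at \code{u = 0} and is
#'   strictly decreasing in \code{u} when \code{sigma_opt > 0}.
#' @examples
#' optical_mtf(c(0, 10, 30), 0.55, 35)
#' @export
optical_mtf <- function(u, sigma_opt, u_opt) {
  if (any(u < 0)) stop("spatial frequency must be >= 0", call. = FALSE)
  if (any(sigma_opt < 0)) stop("sigma_opt must be >= 0", call. = FALSE)
  if (any(!is.finite(u_opt)) || any(u_opt <= 0))
    stop("u_opt must be > 0 cpd", call. = FALSE)
  exp(-2 * pi^2 * sigma_opt^2 * (u / u_opt)^2)
}
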