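#' Model constants and configuration
#'
#' All fixed constants of the CSF model are collected in a single
#' configuration list so that every numerical choice is surfaced in one
#' place and can be overridden (programmatically or from a YAML file)
#' without touching the model code.
#'
#' The defaults are the photopic-vision values used throughout the model:
#' \describe{
#'   \item{Cab}{Chromatic/achromatic aberration coefficient linking the
#'     optical standard deviation to the pupil diameter, per mm (0.08).}
#'   \item{p}{Photon conversion factor, photons s^-1 deg^-2 Td^-1
#'     (1.285e6). The conversion from troland to photon flux is of order
#'     10^6; the fractional part 1.285 follows Barten's photopic value.}
#'   \item{phi0}{Foveal neural noise spectral density, s deg^2 (3e-8);
#'     age-independent in the fovea.}
#'   \item{u0}{Foveal lateral-inhibition drop-off frequency, cpd (7);
#'     age-independent.}
#'   \item{Te}{Integration time of the eye, s (0.1), photopic.}
#'   \item{gain}{Global multiplicative gain on the predicted sensitivity
#'     (default 1). Absolute sensitivity scale conventions differ by a
#'     factor sqrt(2) between renderings of the model; the gain exposes
#'     either convention.}
#'   \item{inhibition_ratio}{How the age-dependent ganglion-density ratio enters
#'     the inhibition cut-off: \code{"linear"} (default) or \code{"sqrt"}.}
#'   \item{squared_neural_term}{Whether the neural noise is divided by the
#'     squared lateral-inhibition MTF (default \code{TRUE}, as the
#'     noise-propagation derivation requires).}
#'   \item{cone_intercept, cone_slope, cone_floor, cone_ecc_rate}{Cone
#'     density model: N_c(A,e) = (intercept - slope*A) exp(-rate*e) + floor,
#'     in relative density units.}
#'   \item{ganglion_cone_ratio}{Cones per ganglion cell (3).}
#'   \item{secondary_ecc_scale}{Eccentricity scale of the secondary
#'     ganglion-density lobe, deg (7.3).}
#' }
#'
#' @param ... Named overrides of individual constants.
#' @param file Optional path to a YAML file whose top-level keys override
#'   the defaults (applied before \code{...}).
#' @return A named list of class \code{"csf_constants"}.
#' @examples
#' csf_constants()$u0
#' csf_constants(Cab = 0.1)$Cab
#' @export
csf_constants <- function(..., file = NULL) {
  defaults <- list(
    Cab = 0.08,
    p = 1.285e6,
    phi0 = 3e-8,
    u0 = 7,
    Te = 0.1,
    gain = 1,
    inhibition_ratio = "linear",
    squared_neural_term = TRUE,
    cone_intercept = 6952.7,
    cone_slope = 38.70,
    cone_floor = 300,
    cone_ecc_rate = 0.35,
    ganglion_cone_ratio = 3,
    secondary_ecc_scale = 7.3
  )
  if (!is.null(file)) {
    overrides <- yaml::read_yaml(file)
    defaults <- utils::modifyList(defaults, overrides)
  }
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("constant overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults <- utils::modifyList(defaults, dots)
  }
  if (!defaults$inhibition_ratio %in% c("linear", "sqrt"))
    stop("inhibition_ratio must be \"linear\" or \"sqrt\"", call. = FALSE)
  num <- setdiff(names(defaults), c("inhibition_ratio", "squared_neural_term"))
  for (nm in num) {
    if (!is.numeric(defaults[[nm]]) || length(defaults[[nm]]) != 1L ||
        !is.finite(defaults[[nm]]) || defaults[[nm]] <= 0)
      stop("constant '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(defaults, class = "csf_constants")
}

#' @export
print.csf_constants <- function(x, ...) {
  cat("CSF model constants:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
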