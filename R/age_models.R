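#' Fitted age curve for the intrinsic optical standard deviation
#'
#' Analytical age model fitted to per-age-group grid-search estimates of
#' the intrinsic blur parameter:
#' \code{sigma0(A) = 0.42 + 0.26 (1 - exp(-((A - 17)/27.1837)^1.547))}.
#' It rises from 0.42 at age 17 towards an asymptote of 0.68, reflecting
#' the growing optical scatter of the ageing eye.
#'
#' @param age Age in years (>= 17; the curve involves a fractional power
#'   of \code{age - 17} and is undefined below, so younger ages raise an
#'   error rather than extrapolating).
#' @return sigma0 in [0.42, 0.68); strictly increasing.
#' @examples
#' sigma0_of_age(c(17, 45, 62))
#' @export
sigma0_of_age <- function(age) {
  check_model_age(age)
  0.42 + 0.26 * (1 - exp(-((age - 17) / 27.1837)^1.547))
}

#' Fitted age curve for the quantum efficiency
#'
#' Analytical age model for the fraction of incoming photons that
#' productively excite photoreceptors:
#' \code{eta(A) = 0.019 + 0.023 (1 - exp(-((A - 17)/13.0645)^-1.753))}.
#' The negative inner exponent makes the curve decrease from 0.042 at the
#' age-17 limit towards an asymptote of 0.019: older retinas convert
#' photons less efficiently.
#'
#' @param age Age in years (>= 17). At exactly 17 the curve is defined by
#'   its right limit, 0.042.
#' @return eta, a fraction in (0.019, 0.042]; strictly decreasing.
#' @examples
#' eta_of_age(c(25, 34))
#' @export
eta_of_age <- function(age) {
  check_model_age(age)
  out <- ifelse(age == 17, 0.042,
                0.019 + 0.023 *
                  (1 - exp(-((age - 17) / 13.0645)^(-1.753))))
  out
}

#' Piecewise age model for the signal-to-noise ratio k
#'
#' The fitted per-group estimates of the detection signal-to-noise ratio
#' are roughly constant below and above 50 years with a step in between;
#' the model is piecewise constant: k = 3 up to age 50 (inclusive), k = 4
#' above.
#'
#' @param age Age in years.
#' @return 3 or 4.
#' @examples
#' k_of_age(c(30, 70))
#' @export
k_of_age <- function(age) {
  ifelse(age <= 50, 3, 4)
}

#' Piecewise age model for the optical cut-off frequency
#'
#' Like \code{\link{k_of_age}}: u_opt = 35 cpd up to age 50 (inclusive),
#' 30 cpd above.
#'
#' @param age Age in years.
#' @return 35 or 30, cpd.
#' @examples
#' uopt_of_age(c(30, 70))
#' @export
uopt_of_age <- function(age) {
  ifelse(age <= 50, 35, 30)
}

#' Temporal-frequency factor of the signal-to-noise ratio
#'
#' In the spatiotemporal extension the signal-to-noise ratio factorises as
#' \code{k(A, w) = k(A) * kstar(w)} with
#' \code{kstar(w) = 1.0835 + 3.1045 (1 - exp(-((w - 0.5)/8.4785)^2.497))}.
#' Below 0.5 Hz (static or very slow stimuli) the factor is clamped at its
#' 0.5 Hz value, 1.0835, since the fitted curve involves a fractional
#' power of \code{w - 0.5}.
#'
#' @param w Temporal frequency, Hz (>= 0).
#' @return kstar in [1.0835, 4.188); non-decreasing in \code{w}.
#' @examples
#' kstar_of_w(c(0.5, 7.5))
#' @export
kstar_of_w <- function(w) {
  if (any(w < 0)) stop("temporal frequency must be >= 0 Hz", call. = FALSE)
  wc <- pmax(w, 0.5)
  1.0835 + 3.1045 * (1 - exp(-((wc - 0.5) / 8.4785)^2.497))
}

check_model_age <- function(age) {
  if (any(!is.finite(age)))
    stop("age must be finite", call. = FALSE)
  if (any(age < 17))
    stop("the fitted age curves are defined for ages >= 17 years",
         call. = FALSE)
  invisible(age)
}

#' CSF model parameter set
#'
#' Bundles the four free parameters of the CSF model (signal-to-noise
#' ratio k, optical cut-off u_opt, intrinsic blur sigma0, quantum
#' efficiency eta) with the fixed physiological constants. The constants
#' default to the shared \code{\link{csf_constants}} block.
#'
#' @param k Signal-to-noise ratio (>= 0.5).
#' @param u_opt Optical cut-off frequency, cpd (> 0).
#' @param sigma0 Intrinsic optical standard deviation (> 0).
#' @param eta Quantum efficiency, fraction in (0, 1).
#' @param constants A \code{\link{csf_constants}} list supplying Cab, p,
#'   u0, phi0 and Te.
#' @return An object of class \code{"csf_params"}.
#' @examples
#' csf_params(k = 3, u_opt = 35, sigma0 = 0.5, eta = 0.03)
#' @seealso \code{\link{params_for_age}}, \code{\link{barten_params}}
#' @export
csf_params <- function(k, u_opt, sigma0, eta,
                       constants = csf_constants()) {
  stopifnot(length(k) == 1L, length(u_opt) == 1L,
            length(sigma0) == 1L, length(eta) == 1L)
  if (!is.finite(k) || k < 0.5)
    stop("k must be >= 0.5", call. = FALSE)
  if (!is.finite(u_opt) || u_opt <= 0)
    stop("u_opt must be > 0 cpd", call. = FALSE)
  if (!is.finite(sigma0) || sigma0 <= 0)
    stop("sigma0 must be > 0", call. = FALSE)
  if (!is.finite(eta) || eta <= 0 || eta >= 1)
    stop("eta must be a fraction in (0, 1)", call. = FALSE)
  structure(list(k = k, u_opt = u_opt, sigma0 = sigma0, eta = eta,
                 Cab = constants$Cab, p = constants$p, u0 = constants$u0,
                 phi0 = constants$phi0, Te = constants$Te),
            class = "csf_params")
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf(paste0("CSF parameters: k = %g, u_opt = %g cpd, ",
                     "sigma0 = %g, eta = %g\n"),
              x$k, x$u_opt, x$sigma0, x$eta))
  cat(sprintf("  constants: Cab = %g /mm, p = %g, u0 = %g cpd, phi0 = %g s.deg^2, Te = %g s\n",
              x$Cab, x$p, x$u0, x$phi0, x$Te))
  invisible(x)
}

#' Age-resolved parameter set
#'
#' Assembles the full \code{\link{csf_params}} for an observer of a given
#' age by evaluating the fitted age curves: \code{\link{k_of_age}},
#' \code{\link{uopt_of_age}}, \code{\link{sigma0_of_age}} and
#' \code{\link{eta_of_age}}.
#'
#' @param age Age in years (>= 17).
#' @param constants A \code{\link{csf_constants}} list.
#' @return A \code{\link{csf_params}} object.
#' @examples
#' params_for_age(70)
#' @export
params_for_age <- function(age, constants = csf_constants()) {
  stopifnot(length(age) == 1L)
  csf_params(k = k_of_age(age), u_opt = uopt_of_age(age),
             sigma0 = sigma0_of_age(age), eta = eta_of_age(age),
             constants = constants)
}

#' Barten's age-independent default parameters
#'
#' The classical photopic defaults of the age-independent baseline model:
#' k = 3, u_opt = 35 cpd, sigma0 = 0.5, eta = 0.03.
#'
#' @param constants A \code{\link{csf_constants}} list.
#' @return A \code{\link{csf_params}} object.
#' @examples
#' barten_params()
#' @export
barten_params <- function(constants = csf_constants()) {
  csf_params(k = 3, u_opt = 35, sigma0 = 0.5, eta = 0.03,
             constants = constants)
}

#' Serialize / deserialize a parameter set as JSON
#'
#' @param params A \code{\link{csf_params}} object.
#' @param path Optional file path; if \code{NULL} the JSON string is
#'   returned.
#' @return \code{params_to_json}: a JSON string (invisibly, if written to
#'   a file); \code{params_from_json}: a \code{\link{csf_params}} object.
#' @examples
#' p <- params_for_age(30)
#' identical(params_from_json(params_to_json(p)), p)
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "csf_params"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE,
                         digits = I(17))
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname params_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
params_from_json <- function(json) {
  x <- lapply(jsonlite::fromJSON(json), as.numeric)
  constants <- csf_constants(Cab = x$Cab, p = x$p, u0 = x$u0,
                             phi0 = x$phi0, Te = x$Te)
  csf_params(k = x$k, u_opt = x$u_opt, sigma0 = x$sigma0, eta = x$eta,
             constants = constants)
}
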