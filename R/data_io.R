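#' CSF measurement dataset
#'
#' A thin data.frame subclass holding tabulated CSF measurements: one row
#' per (age group, spatial frequency) with the sensitivity and the
#' viewing conditions under which it was measured.
#'
#' @param age Age label in years (group mean).
#' @param frequency_cpd Spatial frequency, cpd (> 0).
#' @param sensitivity Contrast sensitivity (> 0).
#' @param luminance_cd_m2 Adaptation luminance, cd/m^2.
#' @param field_deg Square field-of-view angle, deg.
#' @param eyes 1 or 2.
#' @param temporal_hz Temporal frequency, Hz (optional; 0.5 denotes the
#'   quasi-static presentations used in the reference experiments).
#' @param source Free-text provenance tag stored as an attribute.
#' @return An object of class \code{"csf_dataset"} (a data.frame).
#' @examples
#' csf_dataset(age = 30, frequency_cpd = c(1, 4, 16),
#'             sensitivity = c(80, 200, 40),
#'             luminance_cd_m2 = 100, field_deg = 5.5, eyes = 2)
#' @export
csf_dataset <- function(age, frequency_cpd, sensitivity,
                        luminance_cd_m2, field_deg, eyes,
                        temporal_hz = 0.5, source = "unspecified") {
  df <- data.frame(age = age, frequency_cpd = frequency_cpd,
                   sensitivity = sensitivity,
                   luminance_cd_m2 = luminance_cd_m2,
                   field_deg = field_deg, eyes = as.integer(eyes),
                   temporal_hz = temporal_hz)
  validate_csf_dataset(df)
  attr(df, "source") <- source
  class(df) <- c("csf_dataset", "data.frame")
  df
}

validate_csf_dataset <- function(df) {
  required <- c("age", "frequency_cpd", "sensitivity", "luminance_cd_m2",
                "field_deg", "eyes")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in c(required, intersect("temporal_hz", names(df)))) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("non-numeric or missing value in column '", col, "', row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  for (col in c("frequency_cpd", "sensitivity", "luminance_cd_m2",
                "field_deg")) {
    bad <- which(df[[col]] <= 0)
    if (length(bad))
      stop("non-positive ", col, " in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$eyes %in% c(1, 2))
  if (length(bad))
    stop("eyes must be 1 or 2; bad row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Coerce to a CSF dataset
#'
#' @param x A \code{"csf_dataset"} or a data.frame with the required
#'   columns.
#' @return A validated \code{"csf_dataset"}.
#' @export
as_csf_dataset <- function(x) {
  if (inherits(x, "csf_dataset")) return(x)
  if (!is.data.frame(x))
    stop("cannot coerce to csf_dataset", call. = FALSE)
  if (!"temporal_hz" %in% names(x)) x$temporal_hz <- rep(0.5, nrow(x))
  validate_csf_dataset(x)
  class(x) <- c("csf_dataset", "data.frame")
  x
}

# Build viewing_conditions from a (homogeneous) dataset's condition
# columns. Square field assumed: S = field^2.
conditions_from_data <- function(data) {
  for (col in c("luminance_cd_m2", "field_deg", "eyes")) {
    if (length(unique(data[[col]])) != 1L)
      stop("dataset conditions are not homogeneous (column '", col,
           "'); pass conditions explicitly or split the data",
           call. = FALSE)
  }
  viewing_conditions(luminance = data$luminance_cd_m2[1],
                     field_x = data$field_deg[1],
                     eyes = data$eyes[1])
}

#' Read / write CSF measurement tables as CSV
#'
#' The on-disk format is a plain UTF-8 CSV with a header and columns
#' \code{age, frequency_cpd, sensitivity, luminance_cd_m2, field_deg,
#' eyes[, temporal_hz]} (comma separator, dot decimal). Malformed rows
#' are reported with their row numbers.
#'
#' @param path File path.
#' @return \code{read_csf_csv}: a \code{\link{csf_dataset}}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cnd <- viewing_conditions(100, 5.5, eyes = 2)
#' write_csf_csv(synthesize_dataset(30, cnd, seed = 1), f)
#' nrow(read_csf_csv(f))
#' @export
read_csf_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("age", "frequency_cpd", "sensitivity", "luminance_cd_m2",
                "field_deg", "eyes")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c(required, intersect("temporal_hz", names(df)))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  ds <- as_csf_dataset(df)
  attr(ds, "source") <- path
  ds
}

#' @rdname read_csf_csv
#' @param data A \code{\link{csf_dataset}}.
#' @export
write_csf_csv <- function(data, path) {
  data <- as_csf_dataset(data)
  df <- as.data.frame(data)
  # 17 significant digits so that write -> read round-trips doubles
  # without loss
  for (col in names(df))
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate synthetic CSF measurements
#'
#' Draws a synthetic CSF table of the kind the model is fitted to:
#' photopic luminance, a handful of spatial frequencies between 0.5 and
#' 22 cpd, and sensitivities given by the forward model corrupted by
#' multiplicative lognormal noise. Psychophysical thresholds are
#' ratio-scale quantities, so the noise is multiplicative (and keeps
#' every synthetic sensitivity positive); the lognormal multiplier has
#' mean 1 and coefficient of variation \code{noise_cv}.
#'
#' @param params Either a \code{\link{csf_params}} object or a single age
#'   in years (in which case \code{\link{params_for_age}} is used).
#' @param conditions A \code{\link{viewing_conditions}} object.
#' @param frequencies Spatial frequencies, cpd. The default ladder
#'   \code{c(0.5, 1, 2, 4, 8, 16, 22)} mirrors the spans of the reference
#'   experiments.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 returns exact model predictions). Default 0.05.
#' @param seed Integer seed; required so that every synthetic dataset is
#'   reproducible.
#' @param age Age label attached to the measurements (needed when
#'   \code{params} is a parameter set; defaults to the age when
#'   \code{params} is an age).
#' @param constants A \code{\link{csf_constants}} list.
#' @return A \code{\link{csf_dataset}} with one row per frequency.
#' @examples
#' cnd <- viewing_conditions(100, 5.5, eyes = 2)
#' synthesize_dataset(70, cnd, noise_cv = 0.05, seed = 1)
#' @export
synthesize_dataset <- function(params, conditions,
                               frequencies = c(0.5, 1, 2, 4, 8, 16, 22),
                               noise_cv = 0.05, seed, age = NULL,
                               constants = csf_constants()) {
  stopifnot(inherits(conditions, "viewing_conditions"))
  if (missing(seed) || !is.finite(seed))
    stop("a seed is required for reproducible synthesis", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (any(frequencies <= 0))
    stop("frequencies must be > 0 cpd", call. = FALSE)
  if (is.numeric(params) && length(params) == 1L) {
    if (is.null(age)) age <- params
    params <- params_for_age(params, constants)
  } else if (inherits(params, "csf_params")) {
    if (is.null(age))
      stop("an age label is required when params is a parameter set",
           call. = FALSE)
  } else {
    stop("params must be an age or a csf_params object", call. = FALSE)
  }
  mu <- csf_spatial(age, frequencies, conditions, params = params,
                    constants = constants)
  # mean-1 lognormal multiplier: CV -> sdlog = sqrt(log(1 + cv^2))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  mult <- if (noise_cv == 0) rep(1, length(mu)) else {
    sdlog <- sqrt(log(1 + noise_cv^2))
    exp(stats::rnorm(length(mu), mean = -sdlog^2 / 2, sd = sdlog))
  }
  csf_dataset(age = age, frequency_cpd = frequencies,
              sensitivity = mu * mult,
              luminance_cd_m2 = conditions$luminance,
              field_deg = conditions$field_x, eyes = conditions$eyes,
              source = sprintf("synthetic (seed %d, cv %g)",
                               as.integer(seed), noise_cv))
}
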