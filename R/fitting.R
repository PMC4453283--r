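#' Root mean square error
#'
#' RMSE between predicted and observed contrast sensitivities, on the
#' linear sensitivity scale (the scale on which the model's fit quality
#' is reported).
#'
#' @param predicted,observed Numeric vectors of equal, positive length.
#' @return \code{sqrt(mean((predicted - observed)^2))}.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0L || length(predicted) != length(observed))
    stop("predicted and observed must have equal length >= 1",
         call. = FALSE)
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("RMSE inputs must be finite", call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Parameter grid for the CSF fit
#'
#' The four free parameters are estimated on a finite grid whose default
#' ranges and samplings are: eta in [0.005, 0.150] step 0.0001, sigma0 in
#' [0.01, 2.00] step 0.01, u_opt in [1, 100] step 2.5 cpd, k in
#' [0.5, 20.0] step 0.25.
#'
#' @param eta,sigma0,u_opt,k Each either a numeric vector of candidate
#'   values (sorted ascending) or a list \code{list(range = c(lo, hi),
#'   step = s)}.
#' @return An object of class \code{"csf_grid"}: a list of four ascending
#'   candidate vectors.
#' @examples
#' g <- grid_spec()
#' lengths(unclass(g))
#' @export
grid_spec <- function(eta = list(range = c(0.005, 0.150), step = 0.0001),
                      sigma0 = list(range = c(0.01, 2.00), step = 0.01),
                      u_opt = list(range = c(1, 100), step = 2.5),
                      k = list(range = c(0.5, 20.0), step = 0.25)) {
  axis <- function(x, name) {
    if (is.list(x)) {
      stopifnot(length(x$range) == 2L, x$step > 0,
                x$range[2] > x$range[1])
      n <- floor((x$range[2] - x$range[1]) / x$step + 1e-9)
      x <- x$range[1] + x$step * (0:n)
    }
    if (!is.numeric(x) || length(x) < 1L || is.unsorted(x, strictly = TRUE))
      stop("grid axis '", name, "' must be strictly ascending",
           call. = FALSE)
    x
  }
  structure(list(eta = axis(eta, "eta"), sigma0 = axis(sigma0, "sigma0"),
                 u_opt = axis(u_opt, "u_opt"), k = axis(k, "k")),
            class = "csf_grid")
}

#' @export
print.csf_grid <- function(x, ...) {
  cat("CSF parameter grid:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-7s %d values in [%g, %g]\n", nm, length(v),
                v[1], v[length(v)]))
  }
  cat(sprintf("  total:  %.3g combinations\n",
              prod(vapply(x, length, 1))))
  invisible(x)
}

#' Thin a parameter grid
#'
#' Keeps every \code{every}-th candidate on each axis (always including
#' the first). Used to build reduced grids on which the exhaustive search
#' is cheap.
#'
#' @param grid A \code{\link{grid_spec}} object.
#' @param every Positive integer stride, recycled over the four axes
#'   (order: eta, sigma0, u_opt, k).
#' @return A \code{"csf_grid"} object.
#' @examples
#' grid_thin(grid_spec(), 10)
#' @export
grid_thin <- function(grid, every) {
  stopifnot(inherits(grid, "csf_grid"), all(every >= 1))
  every <- rep_len(as.integer(every), 4L)
  out <- grid
  for (i in seq_along(out))
    out[[i]] <- out[[i]][seq(1L, length(out[[i]]), by = every[i])]
  out
}

# Precomputed quantities shared by every candidate at fixed data,
# conditions and age: the age-resolved pupil chain and the
# frequency-dependent neural term.
fit_context <- function(freq, obs, age, conditions, constants) {
  d <- pupil_diameter(age, conditions$luminance, conditions$area,
                      conditions$eyes)
  E <- retinal_illuminance(d, conditions$luminance)
  e <- conditions$eccentricity
  phi_neu <- neural_noise(age, e, constants$phi0, constants)
  m_lat <- lateral_mtf(freq, inhibition_cutoff(age, e, constants))
  expo <- if (constants$squared_neural_term) 2 else 1
  XYT <- conditions$field_x * conditions$field_y *
    min(constants$Te, conditions$presentation_time)
  list(freq = freq, obs = obs, d = d, E = E, XYT = XYT,
       neural = phi_neu / m_lat^expo, gain = constants$gain,
       Cab = constants$Cab, p = constants$p)
}

# Exhaustive SSE minimisation over explicit candidate vectors, exact up
# to floating point. Factorisation: the prediction is
#   pred(u) = gain * A(u; sigma0, u_opt) * B(u; eta) / k
# with A the optical MTF and B the noise factor, so
#   SSE = (gain/k)^2 * sum(A^2 B^2) - 2 (gain/k) * sum(A B obs) + sum(obs^2)
# and the two sums are matrix products over (sigma0 x u_opt) rows and eta
# columns. Ties are broken by the lexicographically smallest
# (eta, sigma0, u_opt, k). eta columns are chunked to bound memory.
search_grid <- function(ctx, eta, sigma0, u_opt, k, chunk = 512L) {
  nf <- length(ctx$freq)
  combos <- expand.grid(u_opt = u_opt, sigma0 = sigma0,
                        KEEP.OUT.ATTRS = FALSE)  # u_opt fastest
  sig_opt <- optical_sd(combos$sigma0, ctx$d, ctx$Cab)
  A <- exp(-2 * pi^2 * outer(sig_opt^2 / combos$u_opt^2, ctx$freq^2))
  A2 <- A * A
  Aobs <- sweep(A, 2L, ctx$obs, `*`)
  obs2 <- sum(ctx$obs^2)
  inv_k <- ctx$gain / k
  best <- list(sse = Inf, eta_i = NA, s0_i = NA, uo_i = NA, k_i = NA)
  n_eval <- 0L
  for (start in seq(1L, length(eta), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(eta))
    phi_opt <- 1 / (eta[idx] * ctx$p * ctx$E)
    # B[j, u] for this eta chunk
    B <- sqrt(ctx$XYT / (2 * (outer(phi_opt, ctx$neural, `+`))))
    S2 <- A2 %*% t(B * B)     # rows: (u_opt x sigma0), cols: eta chunk
    S1 <- Aobs %*% t(B)
    n_eval <- n_eval + nrow(S2) * ncol(S2) * length(k)
    for (ki in seq_along(k)) {
      sse <- inv_k[ki]^2 * S2 - 2 * inv_k[ki] * S1 + obs2
      m <- min(sse)
      if (m <= best$sse) {
        hits <- which(sse == m, arr.ind = TRUE)
        # candidate tuples, lexicographic on (eta, sigma0, u_opt, k)
        cand <- data.frame(
          eta_i = idx[hits[, 2L]],
          s0_i = ((hits[, 1L] - 1L) %/% length(u_opt)) + 1L,
          uo_i = ((hits[, 1L] - 1L) %% length(u_opt)) + 1L)
        o <- order(cand$eta_i, cand$s0_i, cand$uo_i)[1L]
        tup <- c(cand$eta_i[o], cand$s0_i[o], cand$uo_i[o], ki)
        cur <- c(best$eta_i, best$s0_i, best$uo_i, best$k_i)
        take <- m < best$sse ||
          (m == best$sse && !all(is.na(cur)) &&
             lex_less(tup, cur))
        if (take)
          best <- list(sse = m, eta_i = tup[1], s0_i = tup[2],
                       uo_i = tup[3], k_i = tup[4])
      }
    }
  }
  list(eta = eta[best$eta_i], sigma0 = sigma0[best$s0_i],
       u_opt = u_opt[best$uo_i], k = k[best$k_i],
       idx = c(eta = best$eta_i, sigma0 = best$s0_i,
               u_opt = best$uo_i, k = best$k_i),
       sse = best$sse, n_evaluated = n_eval)
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Grid-search estimation of the CSF parameters
#'
#' Deterministic minimisation of the RMSE between the model and a
#' measured CSF over the four free parameters (eta, sigma0, u_opt, k) on
#' a finite grid. The default \code{"staged"} strategy first scans a
#' thinned (eta, sigma0) subgrid (u_opt and k are always searched in
#' full: those axes are cheap), then re-searches at full resolution in a
#' window around the coarse optimum; \code{"exhaustive"} scans every grid
#' point. Both are exact SSE evaluations; ties are broken by the
#' lexicographically smallest (eta, sigma0, u_opt, k).
#'
#' The fit is conditioned on the observer age carried by the data (the
#' pupil, retinal illuminance and retinal-density chain are age-resolved
#' and held fixed); only the four free parameters move.
#'
#' @param data A \code{\link{csf_dataset}} (or data.frame with columns
#'   \code{frequency_cpd} and \code{sensitivity}), with a single age
#'   group and homogeneous conditions.
#' @param conditions A \code{\link{viewing_conditions}} object; if
#'   omitted, built from the dataset's condition columns.
#' @param grid A \code{\link{grid_spec}} object.
#' @param strategy \code{"staged"} (default) or \code{"exhaustive"}. The
#'   full default grid holds about 9e8 combinations; exhaustive search
#'   over it is supported but deliberately opt-in.
#' @param constants A \code{\link{csf_constants}} list.
#' @return An object of class \code{"csf_fit"}: best \code{csf_params},
#'   the achieved \code{rmse} (recomputed through the forward model at
#'   the returned optimum), per-point \code{residuals}
#'   (observed - fitted), \code{fitted} values, the grid, the number of
#'   SSE evaluations and the strategy.
#' @examples
#' cnd <- viewing_conditions(100, 5.5, eyes = 2)
#' dat <- synthesize_dataset(30, cnd, noise_cv = 0, seed = 1)
#' fit <- grid_fit(dat, cnd, grid_thin(grid_spec(), c(10, 10, 1, 1)))
#' fit$best
#' @export
grid_fit <- function(data, conditions = NULL, grid = grid_spec(),
                     strategy = c("staged", "exhaustive"),
                     constants = csf_constants()) {
  strategy <- match.arg(strategy)
  data <- as_csf_dataset(data)
  if (nrow(data) == 0L) stop("dataset is empty", call. = FALSE)
  age <- unique(data$age)
  if (length(age) != 1L)
    stop("grid_fit expects a single age group; use compare_models() or ",
         "split the data for multi-group fits", call. = FALSE)
  if (is.null(conditions)) conditions <- conditions_from_data(data)
  freq <- data$frequency_cpd
  if (any(freq <= 0))
    stop("all frequencies must be > 0 cpd for fitting", call. = FALSE)
  ctx <- fit_context(freq, data$sensitivity, age, conditions, constants)

  if (strategy == "exhaustive") {
    res <- search_grid(ctx, grid$eta, grid$sigma0, grid$u_opt, grid$k)
  } else {
    # The (sigma0, u_opt) plane carries a ridge (only sigma_opt/u_opt
    # enters the optical MTF), so those axes -- and k -- are always
    # searched in full; only the long eta axis is staged: a thinned scan
    # locates the basin, then the window around it is re-searched at
    # full resolution, expanding whenever the optimum sits on an edge.
    n_eta <- length(grid$eta)
    s_eta <- max(1L, round(n_eta / 150))
    i_eta <- seq(1L, n_eta, by = s_eta)
    coarse <- search_grid(ctx, grid$eta[i_eta], grid$sigma0,
                          grid$u_opt, grid$k)
    n_eval <- coarse$n_evaluated
    lo <- max(1L, i_eta[coarse$idx["eta"]] - 2L * s_eta)
    hi <- min(n_eta, i_eta[coarse$idx["eta"]] + 2L * s_eta)
    repeat {
      fine <- search_grid(ctx, grid$eta[lo:hi], grid$sigma0,
                          grid$u_opt, grid$k)
      n_eval <- n_eval + fine$n_evaluated
      at <- lo + fine$idx["eta"] - 1L
      if (at == lo && lo > 1L) {
        lo <- max(1L, lo - 2L * s_eta)
      } else if (at == hi && hi < n_eta) {
        hi <- min(n_eta, hi + 2L * s_eta)
      } else break
    }
    res <- pick_best(coarse, fine)
    res$n_evaluated <- n_eval
  }

  best <- csf_params(k = res$k, u_opt = res$u_opt, sigma0 = res$sigma0,
                     eta = res$eta, constants = constants)
  fitted <- csf_spatial(age, freq, conditions, params = best,
                        constants = constants)
  structure(list(best = best, rmse = rmse(fitted, data$sensitivity),
                 residuals = data$sensitivity - fitted, fitted = fitted,
                 grid = grid, n_evaluated = res$n_evaluated,
                 strategy = strategy, age = age, conditions = conditions),
            class = "csf_fit")
}

# Between two search results prefer smaller SSE; on exact SSE ties, the
# lexicographically smaller parameter tuple.
pick_best <- function(a, b) {
  if (b$sse < a$sse) return(b)
  if (a$sse < b$sse) return(a)
  if (lex_less(c(b$eta, b$sigma0, b$u_opt, b$k),
               c(a$eta, a$sigma0, a$u_opt, a$k))) b else a
}

#' @export
print.csf_fit <- function(x, ...) {
  cat(sprintf("CSF grid fit (%s search, age %g, n = %d points)\n",
              x$strategy, x$age, length(x$residuals)))
  print(x$best)
  cat(sprintf("  RMSE = %.4g over %d points (%d SSE evaluations)\n",
              x$rmse, length(x$residuals), x$n_evaluated))
  invisible(x)
}

#' Compare two CSF models on measured data
#'
#' Computes the per-age-group RMSE of two forward models on the same
#' dataset and flags the winner for each group. The defaults compare the
#' age-resolved model against the age-independent baseline with its
#' classical parameters.
#'
#' @param data A \code{\link{csf_dataset}}; may contain several age
#'   groups (grouped by the \code{age} column).
#' @param model_a,model_b Functions \code{(age, u, conditions)} returning
#'   predicted sensitivities.
#' @param conditions A \code{\link{viewing_conditions}}; if omitted,
#'   built per group from the dataset's condition columns.
#' @param labels Character vector of length 2 naming the models in the
#'   report.
#' @param constants A \code{\link{csf_constants}} list (used by the
#'   default models).
#' @return An object of class \code{"csf_comparison"}: a data.frame with
#'   one row per age group (columns \code{age}, \code{n},
#'   \code{rmse_a}, \code{rmse_b}, \code{winner}).
#' @examples
#' cnd <- viewing_conditions(100, 5.5, eyes = 2)
#' dat <- synthesize_dataset(70, cnd, noise_cv = 0.05, seed = 7)
#' compare_models(dat, conditions = cnd)
#' @export
compare_models <- function(data,
                           model_a = function(age, u, conditions)
                             csf_spatial(age, u, conditions,
                                         constants = constants),
                           model_b = function(age, u, conditions)
                             csf_barten(u, conditions,
                                        barten_params(constants),
                                        constants = constants),
                           conditions = NULL,
                           labels = c("age_model", "baseline"),
                           constants = csf_constants()) {
  data <- as_csf_dataset(data)
  if (nrow(data) == 0L) stop("dataset is empty", call. = FALSE)
  stopifnot(is.function(model_a), is.function(model_b),
            length(labels) == 2L)
  groups <- split(data, data$age)
  rows <- lapply(groups, function(g) {
    cnd <- if (is.null(conditions)) conditions_from_data(g) else conditions
    a <- rmse(model_a(g$age[1], g$frequency_cpd, cnd), g$sensitivity)
    b <- rmse(model_b(g$age[1], g$frequency_cpd, cnd), g$sensitivity)
    winner <- if (a < b) labels[1] else if (b < a) labels[2] else "tie"
    data.frame(age = g$age[1], n = nrow(g), rmse_a = a, rmse_b = b,
               winner = winner)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  class(out) <- c("csf_comparison", "data.frame")
  out
}

#' @export
print.csf_comparison <- function(x, ...) {
  labels <- attr(x, "labels")
  cat(sprintf("CSF model comparison (A = %s, B = %s):\n",
              labels[1], labels[2]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Serialize a model comparison to JSON and back
#'
#' @param comparison A \code{\link{compare_models}} result.
#' @param path Optional output file.
#' @return \code{comparison_to_json}: JSON string;
#'   \code{comparison_from_json}: the \code{"csf_comparison"} object.
#' @examples
#' cnd <- viewing_conditions(100, 5.5, eyes = 2)
#' cmp <- compare_models(synthesize_dataset(30, cnd, seed = 1),
#'                       conditions = cnd)
#' identical(comparison_from_json(comparison_to_json(cmp)), cmp)
#' @export
comparison_to_json <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "csf_comparison"))
  payload <- list(labels = attr(comparison, "labels"),
                  groups = as.data.frame(comparison))
  # 17 significant digits so doubles survive the round trip unchanged
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname comparison_to_json
#' @param json JSON string or file path.
#' @export
comparison_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  out <- x$groups
  for (col in c("age", "rmse_a", "rmse_b"))
    out[[col]] <- as.numeric(out[[col]])
  out$n <- as.integer(out$n)
  attr(out, "labels") <- x$labels
  class(out) <- c("csf_comparison", "data.frame")
  out
}
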