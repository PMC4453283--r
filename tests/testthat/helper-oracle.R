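# Independent scalar oracles: straight one-expression transcriptions of
# the model formulas, sharing no code with the package. Used to check
# the composed pipeline against a flat re-derivation.

# Ganglion-cell density, scalar.
oracle_ganglion <- function(A, e) {
  3 * ((6952.7 - 38.70 * A) + 300) *
    (0.85 / (1 + (e / (-0.404 * exp(-0.01246 * A) -
                         0.1792 * exp(0.01525 * A)))^2) +
       0.15 / (1 + (e / 7.3)^2))
}

# Lateral-inhibition drop-off frequency, scalar.
oracle_inhibition_cutoff <- function(A, e) {
  7 * (0.85 / (1 + (e / (-0.404 * exp(-0.01246 * A) -
                           0.1792 * exp(0.01525 * A)))^2) +
         0.15 / (1 + (e / 7.3)^2)) *
    (0.85 / (1 + (e / 4)^2) + 0.13 / (1 + (e / 20)^2) + 0.02)^(-0.5)
}

# Baseline CSF with explicit parameters and the reference-age
# (luminance-only) pupil. Scalar in u.
oracle_csf_barten <- function(u, L, X, Y, S, n, To, k, u_opt, sigma0,
                              eta, Cab = 0.08, p = 1.285e6, u0 = 7,
                              phi0 = 3e-8, Te = 0.1) {
  f <- if (n == 2) 1 else 0.1
  x <- (L * S * f / 846)^0.41
  D <- 7.75 - 5.75 * x / (x + 2)
  E <- pi * L * D^2 / 4 * (1 - (D / 9.7)^2 + (D / 12.4)^4)
  exp(-2 * pi^2 * (sigma0^2 + (Cab * D)^2) * (u / u_opt)^2) / k *
    sqrt(X * Y * min(Te, To) /
           (2 * (1 / (eta * p * E) +
                   phi0 / (1 - exp(-(u / u0)^2)))))
}

# Full age-resolved spatial CSF: age curves, age-corrected pupil and
# eccentricity-resolved retinal terms, all inline. Scalar in u.
oracle_csf_age <- function(A, u, L, X, Y, S, n, To, e = 0,
                           Cab = 0.08, p = 1.285e6, phi0 = 3e-8,
                           Te = 0.1) {
  f <- if (n == 2) 1 else 0.1
  x <- (L * S * f / 846)^0.41
  D <- 7.75 - 5.75 * x / (x + 2)
  d <- D + (A - 28.58) * (0.02132 - 0.009562 * D)
  E <- pi * L * d^2 / 4 * (1 - (d / 9.7)^2 + (d / 12.4)^4)
  sigma0 <- 0.42 + 0.26 * (1 - exp(-((A - 17) / 27.1837)^1.547))
  eta <- if (A == 17) 0.042 else
    0.019 + 0.023 * (1 - exp(-((A - 17) / 13.0645)^(-1.753)))
  k <- if (A <= 50) 3 else 4
  u_opt <- if (A <= 50) 35 else 30
  a <- -0.404 * exp(-0.01246 * A) - 0.1792 * exp(0.01525 * A)
  dens_ratio <- 0.85 / (1 + (e / a)^2) + 0.15 / (1 + (e / 7.3)^2)
  u_inh <- 7 * dens_ratio *
    (0.85 / (1 + (e / 4)^2) + 0.13 / (1 + (e / 20)^2) + 0.02)^(-0.5)
  phi_neu <- phi0 / dens_ratio
  exp(-2 * pi^2 * (sigma0^2 + (Cab * d)^2) * (u / u_opt)^2) / k *
    sqrt(X * Y * min(Te, To) /
           (2 * (1 / (eta * p * E) +
                   phi_neu / (1 - exp(-(u / u_inh)^2)))))
}
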