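test_that("baseline CSF equals the independent scalar oracle and behaves band-pass", {
  cnd <- viewing_conditions(60, 7, eyes = 1)
  u <- c(1, 2, 4, 8, 16)
  got <- csf_barten(u, cnd)
  want <- vapply(u, function(ui)
    oracle_csf_barten(ui, L = 60, X = 7, Y = 7, S = 49, n = 1,
                      To = Inf, k = 3, u_opt = 35, sigma0 = 0.5,
                      eta = 0.03), 0)
  expect_equal(got, want, tolerance = 1e-12)
  # zero frequency is invisible; far frequencies are attenuated to nothing
  expect_identical(csf_barten(0, cnd), 0)
  expect_equal(csf_barten(1e4, cnd), 0, tolerance = 1e-12)
  # band-pass: the peak lies at intermediate frequencies
  dense <- seq(0.1, 40, by = 0.1)
  s <- csf_barten(dense, cnd)
  expect_true(all(s >= 0))
  peak <- dense[which.max(s)]
  expect_gte(peak, 1)
  expect_lte(peak, 8)
})

test_that("baseline CSF approaches its closed-form photon-noise limit", {
  # with no intrinsic blur/aberration and negligible neural noise at a
  # frequency where lateral inhibition has saturated, the sensitivity is
  # sqrt(XYT / (2 phi_opt)) / k scaled by the (near-1) optical MTF
  cst <- csf_constants(Cab = 1e-9)
  p <- csf_params(k = 3, u_opt = 1e6, sigma0 = 1e-9, eta = 0.03,
                  constants = cst)
  cnd <- viewing_conditions(60, 7, eyes = 1)
  D <- stanley_davies_diameter(60, 49, 1)
  phi_opt <- photon_noise(0.03, retinal_illuminance(D, 60))
  got <- csf_barten(50, cnd, p, phi_neu = 1e-30, constants = cst)
  expect_equal(got, sqrt(49 * 0.1 / (2 * phi_opt)) / 3,
               tolerance = 1e-8)
})

test_that("age-resolved CSF is the baseline with the age-resolved pupil and parameters", {
  cnd <- viewing_conditions(100, 5.5, eyes = 2)
  u <- c(0.5, 2, 8, 22)
  for (A in c(25, 50, 75)) {
    d <- pupil_diameter(A, 100, 5.5^2, 2)
    expect_identical(csf_spatial(A, u, cnd),
                     csf_barten(u, cnd, params_for_age(A), diameter = d))
  }
})

test_that("full age pipeline matches the independent one-expression oracle at random conditions", {
  set.seed(2024)
  n <- 200
  A <- runif(n, 17, 90)
  u <- runif(n, 0.1, 40)
  L <- runif(n, 12.5, 300)
  fld <- runif(n, 2, 10)
  eyes <- sample(c(1, 2), n, replace = TRUE)
  To <- sample(c(Inf, 0.05, 2), n, replace = TRUE)
  ecc <- sample(c(0, 5, 20), n, replace = TRUE)
  for (i in seq_len(n)) {
    cnd <- viewing_conditions(L[i], fld[i], eyes = eyes[i],
                              presentation_time = To[i],
                              eccentricity = ecc[i])
    expect_equal(csf_spatial(A[i], u[i], cnd),
                 oracle_csf_age(A[i], u[i], L[i], fld[i], fld[i],
                                fld[i]^2, eyes[i], To[i], ecc[i]),
                 tolerance = 1e-10)
  }
})

test_that("vectorised evaluation over frequency equals the scalar loop exactly", {
  cnd <- viewing_conditions(100, 5.5, eyes = 2)
  u <- c(0, 0.5, 1, 2, 4, 8, 16, 22, 32)
  vec <- csf_spatial(40, u, cnd)
  scl <- vapply(u, function(ui) csf_spatial(40, ui, cnd), 0)
  expect_identical(vec, scl)
})

test_that("sensitivity declines with age, fastest at high spatial frequencies", {
  cnd <- viewing_conditions(100, 5.5, eyes = 2)
  ages <- seq(20, 80, by = 10)
  for (u in c(2, 4, 8, 16)) {
    s <- vapply(ages, function(A) csf_spatial(A, u, cnd), 0)
    expect_true(all(diff(s) <= 0))
  }
  ratio <- function(u) csf_spatial(70, u, cnd) / csf_spatial(30, u, cnd)
  expect_lt(ratio(16), ratio(2))
})

test_that("spatiotemporal model reduces to the spatial one and attenuates with flicker", {
  cnd <- viewing_conditions(100, 6, eyes = 1)
  u <- c(0.5, 1, 4, 12)
  for (A in c(30, 65)) {
    expect_equal(csf_spatiotemporal(A, u, 0.5, cnd),
                 csf_spatial(A, u, cnd) / 1.0835, tolerance = 1e-12)
    # with identity filters, w only enters through kstar
    expect_equal(csf_spatiotemporal(A, u, 7.5, cnd),
                 csf_spatial(A, u, cnd) / kstar_of_w(7.5),
                 tolerance = 1e-12)
  }
  # total signal-to-noise at A=30, w=7.5 is k * kstar = 3 * 2.5175
  expect_equal(3 * kstar_of_w(7.5), 7.5525, tolerance = 1e-4)
  # decreasing in w when the filters are non-increasing
  filt <- temporal_filters(H1 = function(w) exp(-w / 30),
                           H2 = function(w) 1 / (1 + w / 50))
  s_by_w <- vapply(c(0.5, 2, 8, 16), function(w)
    csf_spatiotemporal(40, 4, w, cnd, filters = filt), 0)
  expect_true(all(diff(s_by_w) < 0))
  # the unsquared-denominator reading is reachable by configuration
  cst <- csf_constants(squared_neural_term = FALSE)
  sq <- csf_spatiotemporal(40, 4, 3, cnd)
  unsq <- csf_spatiotemporal(40, 4, 3, cnd, constants = cst)
  expect_false(isTRUE(all.equal(sq, unsq)))
  expect_error(temporal_filters(H1 = function(w) w + 2), "0, 1")
})
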