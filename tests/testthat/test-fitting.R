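owsley_conditions <- function() viewing_conditions(100, 5.5, eyes = 2)

# on-grid truth under the default grid (u_opt axis is 1, 3.5, ..., 98.5)
ongrid_truth <- function() csf_params(k = 3, u_opt = 36, sigma0 = 0.5,
                                      eta = 0.033)

test_that("RMSE is the root mean squared difference on the linear scale", {
  expect_identical(rmse(c(10, 20, 40), c(10, 20, 40)), 0)
  expect_identical(rmse(10, 13), 3)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5), tolerance = 1e-12)
  expect_error(rmse(numeric(0), numeric(0)), "length")
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("the default grid follows the printed ranges and samplings", {
  g <- grid_spec()
  expect_equal(range(g$eta), c(0.005, 0.150))
  expect_equal(diff(g$eta)[1], 1e-4)
  expect_equal(range(g$sigma0), c(0.01, 2.00))
  expect_equal(diff(g$sigma0)[1], 0.01)
  expect_equal(g$u_opt[1], 1)
  expect_equal(diff(g$u_opt)[1], 2.5)
  expect_lte(max(g$u_opt), 100)
  expect_equal(range(g$k), c(0.5, 20))
  expect_equal(diff(g$k)[1], 0.25)
  # the eta sampling reading (0.01% = 0.0001 on the fractional scale) is
  # pinned by the granularity of the printed per-group eta estimates:
  # every one of them lies on the grid
  printed_eta <- c(0.0330, 0.0235, 0.0190, 0.0420, 0.0400, 0.0300,
                   0.0250, 0.0230, 0.0220, 0.0415, 0.0200)
  for (v in printed_eta) expect_true(min(abs(g$eta - v)) < 1e-12)
  expect_error(grid_spec(k = c(3, 2, 4)), "ascending")
})

test_that("noise-free data from an on-grid parameter set is recovered exactly", {
  cnd <- owsley_conditions()
  truth <- ongrid_truth()
  dat <- synthesize_dataset(truth, cnd, noise_cv = 0, seed = 1, age = 30)
  fit <- grid_fit(dat, cnd)
  expect_identical(fit$best$k, truth$k)
  expect_identical(fit$best$u_opt, truth$u_opt)
  expect_identical(fit$best$sigma0, truth$sigma0)
  expect_identical(fit$best$eta, truth$eta)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
})

test_that("the reported RMSE equals an independent recomputation at the optimum", {
  cnd <- owsley_conditions()
  dat <- synthesize_dataset(ongrid_truth(), cnd, noise_cv = 0.05,
                            seed = 3, age = 30)
  fit <- grid_fit(dat, cnd)
  pred <- csf_spatial(30, dat$frequency_cpd, cnd, params = fit$best)
  expect_identical(fit$rmse, rmse(pred, dat$sensitivity))
  expect_equal(fit$residuals, dat$sensitivity - pred, tolerance = 1e-14)
})

test_that("sigma0 and u_opt enter the model only through the blur ratio sigma_opt/u_opt", {
  # the exact ridge that limits per-parameter recovery: two parameter
  # sets with equal sigma_opt/u_opt predict identical sensitivities
  cnd <- owsley_conditions()
  u <- c(0.5, 1, 2, 4, 8, 16, 22)
  d <- pupil_diameter(30, 100, 5.5^2, 2)
  s1 <- optical_sd(0.5, d)
  scale <- 2.5
  sigma0_b <- sqrt((s1 * scale)^2 - (0.08 * d)^2)
  p1 <- csf_params(k = 3, u_opt = 20, sigma0 = 0.5, eta = 0.033)
  p2 <- csf_params(k = 3, u_opt = 20 * scale, sigma0 = sigma0_b,
                   eta = 0.033)
  expect_equal(csf_spatial(30, u, cnd, params = p1),
               csf_spatial(30, u, cnd, params = p2), tolerance = 1e-12)
})

test_that("under 5% noise the identifiable quantities are recovered", {
  # empirically pinned recovery tolerances (the signal-to-noise ratio k
  # and the optical blur ratio are identifiable; see the vignette for
  # why sigma0, u_opt and eta individually are not)
  cnd <- owsley_conditions()
  truth <- ongrid_truth()
  d <- pupil_diameter(30, 100, 5.5^2, 2)
  ratio_true <- optical_sd(truth$sigma0, d) / truth$u_opt
  for (seed in c(1, 5, 42)) {
    dat <- synthesize_dataset(truth, cnd, noise_cv = 0.05, seed = seed,
                              age = 30)
    fit <- grid_fit(dat, cnd)
    expect_lte(abs(fit$best$k - truth$k), 0.25)  # within one k step
    ratio_hat <- optical_sd(fit$best$sigma0, d) / fit$best$u_opt
    expect_lt(abs(ratio_hat / ratio_true - 1), 0.05)
    # the fit explains the data down to the noise floor
    expect_lt(fit$rmse / max(dat$sensitivity), 0.05)
  }
})

test_that("staged search returns the exhaustive argmin on reduced grids", {
  cnd <- owsley_conditions()
  reduced <- grid_thin(grid_spec(), 10)
  fixtures <- list(
    synthesize_dataset(ongrid_truth(), cnd, noise_cv = 0, seed = 1,
                       age = 30),
    synthesize_dataset(ongrid_truth(), cnd, noise_cv = 0.05, seed = 42,
                       age = 30),
    synthesize_dataset(70, owsley_conditions(), noise_cv = 0.1,
                       seed = 9))
  for (dat in fixtures) {
    st <- grid_fit(dat, cnd, reduced, strategy = "staged")
    ex <- grid_fit(dat, cnd, reduced, strategy = "exhaustive")
    expect_identical(unclass(st$best), unclass(ex$best))
    expect_identical(st$rmse, ex$rmse)
  }
  # and on an asymmetrically thinned grid
  reduced2 <- grid_thin(grid_spec(), c(7, 5, 2, 3))
  dat <- synthesize_dataset(55, cnd, noise_cv = 0.05, seed = 17)
  st <- grid_fit(dat, cnd, reduced2, strategy = "staged")
  ex <- grid_fit(dat, cnd, reduced2, strategy = "exhaustive")
  expect_identical(unclass(st$best), unclass(ex$best))
})

test_that("grid ties are broken by the lexicographically smallest parameters", {
  # a flat dataset at a single frequency cannot separate many grid
  # points; the argmin must be reproducible and lexicographically first
  cnd <- owsley_conditions()
  dat <- csf_dataset(age = 30, frequency_cpd = 4, sensitivity = 500,
                     luminance_cd_m2 = 100, field_deg = 5.5, eyes = 2)
  g <- grid_thin(grid_spec(), c(100, 50, 10, 10))
  f1 <- grid_fit(dat, cnd, g, strategy = "exhaustive")
  f2 <- grid_fit(dat, cnd, g, strategy = "staged")
  expect_identical(unclass(f1$best), unclass(f2$best))
})

test_that("grid_fit validates its inputs", {
  cnd <- owsley_conditions()
  expect_error(grid_fit(data.frame(), cnd), "missing column")
  dat <- synthesize_dataset(30, cnd, seed = 1)
  mixed <- rbind(as.data.frame(dat), as.data.frame(
    synthesize_dataset(70, cnd, seed = 2)))
  expect_error(grid_fit(mixed, cnd), "single age group")
})

test_that("model comparison reports per-group RMSE, winners and survives JSON", {
  cnd <- owsley_conditions()
  # identical models tie
  same <- function(age, u, conditions) csf_spatial(age, u, conditions)
  dat <- synthesize_dataset(40, cnd, noise_cv = 0.05, seed = 4)
  cmp0 <- compare_models(dat, model_a = same, model_b = same,
                         conditions = cnd)
  expect_identical(cmp0$winner, "tie")
  expect_identical(cmp0$rmse_a, cmp0$rmse_b)
  # data generated by the age model at 70 favours the age model over the
  # age-independent baseline
  old <- synthesize_dataset(70, cnd, noise_cv = 0.05, seed = 8)
  cmp <- compare_models(old, conditions = cnd)
  expect_lt(cmp$rmse_a, cmp$rmse_b)
  expect_identical(cmp$winner, "age_model")
  # several age groups, one row each
  multi <- as_csf_dataset(rbind(as.data.frame(old),
                                as.data.frame(synthesize_dataset(
                                  30, cnd, noise_cv = 0.05, seed = 8))))
  cmp2 <- compare_models(multi, conditions = cnd)
  expect_identical(nrow(cmp2), 2L)
  expect_setequal(cmp2$age, c(30, 70))
  # lossless JSON round trip
  rt <- comparison_from_json(comparison_to_json(cmp2))
  expect_identical(rt, cmp2)
})
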