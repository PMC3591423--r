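test_that("residual noise s.d. follows sqrt(ssr/df)", {
  expect_equal(noise_sd_from_fit(list(ssr = 95.2, df = 56)),
               sqrt(95.2 / 56), tolerance = 1e-12)  # ~1.304
  expect_equal(noise_sd_from_fit(list(ssr = 290.5, df = 74)),
               sqrt(290.5 / 74), tolerance = 1e-12)  # ~1.981
  expect_equal(noise_sd_from_fit(list(ssr = 0, df = 56)), 0)
  expect_error(noise_sd_from_fit(list(ssr = 10, df = 0)), "positive")
})

test_that("a perfect fit yields a degenerate Monte Carlo ensemble", {
  truth <- lifespan_model(lognormal_law(4.5, 0.3))
  lab <- labeling_config(e1 = 0.88)
  ds <- generate_dataset(truth, lab, sem_percent = 0, n_replicates = 3,
                         seed = 1, grid_points = 400)
  fit <- quick_fit(ds, "LS", patience = 4, grid = 400, seed = 51)
  expect_lt(noise_sd_from_fit(fit), 1e-5)
  ens <- monte_carlo(fit, ds, n_iterations = 5, n_replicates = 3, seed = 52,
                     n_restarts = 0)
  # sigma_e ~ 0: every refit lands on the original best fit
  expect_lt(diff(range(ens$samples$m)), 1e-4)
  expect_lt(ensemble_iqr(ens, "f"), 1e-6)
  ci <- ensemble_ci(ens, "f")
  expect_lt(ci[["upper"]] - ci[["lower"]], 1e-6)
})

test_that("ensembles are reproducible under a fixed seed and exchangeable", {
  truth <- study_model(0.4)
  lab <- labeling_config(e1 = 0.9)
  ds <- generate_dataset(truth, lab, sem_percent = 0.4, n_replicates = 3,
                         seed = 6, grid_points = 400)
  fit <- quick_fit(ds, "DLS", patience = 4, grid = 400, seed = 61)
  ens_a <- monte_carlo(fit, ds, n_iterations = 8, n_replicates = 3, seed = 7,
                       n_restarts = 1)
  ens_b <- monte_carlo(fit, ds, n_iterations = 8, n_replicates = 3, seed = 7,
                       n_restarts = 1)
  expect_identical(ens_a$samples, ens_b$samples)
  # percentiles are invariant to iteration order
  shuffled <- ens_a$samples[sample(nrow(ens_a$samples)), ]
  expect_equal(unname(quantile(shuffled$f, c(.025, .25, .5, .75, .975))),
               unname(ens_a$percentiles[, "f"]))
  # percentile vectors are monotone (R and S are NA here: no platelet count)
  finite <- colSums(is.finite(ens_a$percentiles)) == 5L
  expect_true(all(apply(ens_a$percentiles[, finite], 2,
                        function(x) all(diff(x) >= 0))))
})

test_that("parameter correlation recovers exact and null relationships", {
  ens <- structure(list(samples = data.frame(x = 1:20, y = 2 * (1:20))),
                   class = "platekin_ensemble")
  pc <- parameter_correlation(ens, "x", "y")
  expect_equal(pc$r_squared, 1)
  expect_equal(pc$slope, 2, tolerance = 1e-12)
  set.seed(8)
  ens$samples <- data.frame(x = rnorm(400), y = rnorm(400))
  pc <- parameter_correlation(ens, "x", "y")
  expect_lt(pc$r_squared, 0.05)
  expect_true(pc$slope_ci[[1]] < 0 && pc$slope_ci[[2]] > 0)
  ens$samples <- data.frame(x = rep(1, 10), y = 1:10)
  expect_error(parameter_correlation(ens, "x", "y"), "zero-variance")
  expect_error(parameter_correlation(ens, "nope", "y"), "unknown")
})

test_that("the loss fraction trades off mainly against the mean lifespan", {
  # DLS ensemble at the wild-type-like operating point: the f-mu correlation
  # must dominate the f-sigma and f-e1 correlations
  truth <- study_model(0.3)
  lab <- labeling_config(e1 = 0.9)
  ds <- generate_dataset(truth, lab, sem_percent = 0.56, n_replicates = 6,
                         seed = 9, grid_points = 400)
  fit <- quick_fit(ds, "DLS", patience = 5, grid = 400, seed = 71)
  ens <- monte_carlo(fit, ds, n_iterations = 40, seed = 72, n_restarts = 1)
  r2_mu <- parameter_correlation(ens, "f", "mu")$r_squared
  r2_sigma <- parameter_correlation(ens, "f", "sigma")$r_squared
  r2_e1 <- parameter_correlation(ens, "f", "e1")$r_squared
  expect_gt(r2_mu, r2_sigma)
  expect_gt(r2_mu, r2_e1)
  expect_gt(r2_mu, 0.5)
})
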