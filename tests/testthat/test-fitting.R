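test_that("predict_observed scales the survival curve by label efficiency", {
  m <- wt_ls()
  expect_equal(predict_observed(m, labeling_config(e1 = 0.9), 0, "population"),
               90)
  expect_equal(predict_observed(m, labeling_config(e1 = 0.879), 0, "population"),
               87.9)
  expect_lt(predict_observed(m, labeling_config(e1 = 0.9), 500, "population"),
            1e-6)
})

test_that("survival_dataset validates its schema", {
  obs <- data.frame(time_hr = c(0, 24, 0, 24), percent = c(90, 60, 89, 61),
                    replicate = c(1, 1, 2, 2), curve = "population")
  ds <- survival_dataset(obs, platelet_count = 1183, count_sem = 70)
  expect_s3_class(ds, "survival_dataset")
  expect_error(survival_dataset(obs[, -2]), "columns")
  bad <- obs; bad$percent[1] <- 150
  expect_error(survival_dataset(bad), "\\[-10, 110\\]")
  bad <- obs; bad$time_hr[1] <- -5
  expect_error(survival_dataset(bad), ">= 0")
  one_t <- obs[obs$time_hr == 0, ]
  expect_error(survival_dataset(one_t), "distinct")
})

test_that("noise-free LS data are recovered essentially exactly", {
  truth <- lifespan_model(lognormal_law(4.5, 0.3))
  lab <- labeling_config(e1 = 0.88)
  ds <- generate_dataset(truth, lab, sem_percent = 0, n_replicates = 3,
                         seed = 1, grid_points = 500)
  fit <- quick_fit(ds, "LS", patience = 6, seed = 11)
  expect_lt(abs(fit$par[["m"]] - 4.5) / 4.5, 1e-4)
  expect_lt(abs(fit$par[["s"]] - 0.3) / 0.3, 1e-4)
  expect_lt(abs(fit$par[["e1"]] - 0.88) / 0.88, 1e-4)
  expect_lt(fit$ssr, 1e-8)
  expect_equal(fit$df, 3 * 13 - 3)
})

test_that("noise-free DLS data in the high-loss regime are recovered", {
  truth <- study_model(0.8)
  lab <- labeling_config(e1 = 0.9)
  ds <- generate_dataset(truth, lab, sem_percent = 0, n_replicates = 3,
                         seed = 2, grid_points = 500)
  fit <- quick_fit(ds, "DLS", patience = 6, seed = 12)
  mo <- lognormal_to_moments(fit$model$law)
  expect_lt(abs(mo[["mu"]] - 100) / 100, 0.01)
  expect_lt(abs(mo[["sigma"]] - 25) / 25, 0.01)
  expect_lt(abs(random_loss_fraction(fit$model) - 0.8), 0.01)
  expect_lt(abs(fit$par[["e1"]] - 0.9) / 0.9, 0.01)
  expect_equal(fit$n_params, 4L)
})

test_that("fits are invariant to replicate order and to the start seed", {
  truth <- study_model(0.4)
  lab <- labeling_config(e1 = 0.9)
  ds <- generate_dataset(truth, lab, sem_percent = 0.3, n_replicates = 4,
                         seed = 3, grid_points = 500)
  fit_a <- quick_fit(ds, "LS", patience = 5, seed = 21)
  # permute observation rows: the objective is a sum, so nothing may change
  perm <- ds
  perm$observations <- perm$observations[rev(seq_len(nrow(perm$observations))), ]
  fit_b <- quick_fit(perm, "LS", patience = 5, seed = 21)
  expect_equal(fit_b$ssr, fit_a$ssr, tolerance = 1e-10)
  # a different multi-start seed reaches the same optimum
  fit_c <- quick_fit(ds, "LS", patience = 5, seed = 99)
  expect_equal(fit_c$ssr, fit_a$ssr, tolerance = 1e-6)
})

test_that("nested models are properly ordered in fit quality", {
  truth <- study_model(0.4)
  lab <- labeling_config(e1 = 0.9)
  ds <- generate_dataset(truth, lab, sem_percent = 0.3, n_replicates = 4,
                         seed = 4, grid_points = 500)
  fit_dls <- quick_fit(ds, "DLS", patience = 5, seed = 31)
  fit_ls <- fit_dls$nested$LS
  fit_dorn <- fit_dls$nested$DORNHORST
  expect_lte(fit_dls$ssr, fit_ls$ssr + 1e-9)
  expect_lte(fit_dls$ssr, fit_dorn$ssr + 1e-9)
  expect_equal(fit_ls$n_params, 3L)
  expect_equal(fit_dorn$n_params, 3L)
  expect_equal(fit_dls$n_params, 4L)
})

test_that("DLS fit of fixed-lifespan data drives s to its floor and recovers (T, r)", {
  truth <- lifespan_model(delta_law(110), r = 0.006)
  lab <- labeling_config(e1 = 0.9)
  ds <- generate_dataset(truth, lab, sem_percent = 0, n_replicates = 3,
                         seed = 5, grid_points = 500)
  fit <- quick_fit(ds, "DLS", patience = 5, seed = 41)
  spec <- platekin:::fit_parspec("DLS", FALSE)
  expect_lt(fit$par[["s"]], 0.02)  # pushed toward the lower bound
  expect_lt(abs(exp(fit$par[["m"]]) - 110) / 110, 0.02)
  expect_lt(abs(fit$par[["r"]] - 0.006), 5e-4)
})

test_that("degenerate fitting inputs raise explicit errors", {
  obs <- data.frame(time_hr = c(0, 24, 48), percent = c(90, 60, 30),
                    replicate = 1, curve = "population")
  ds <- survival_dataset(obs)
  expect_error(fit_survival(ds, "LS"), "degrees of freedom")
  expect_error(fit_survival(ds, "DLS", use_cohort = TRUE), "no cohort")
})
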