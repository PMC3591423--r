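test_that("cohort initial density applies the labelling-efficiency weights", {
  m <- wt_dls()
  # perfect first label: no cells older than the delay are in the cohort
  lab <- labeling_config(e1 = 1, e2 = 1, d = 24)
  expect_identical(cohort_initial_density(m, lab, c(24, 50, 100)), rep(0, 3))
  expect_gt(cohort_initial_density(m, lab, 10), 0)
  # vanishing delay with a perfect first label leaves no cohort
  lab0 <- labeling_config(e1 = 1, e2 = 1, d = 1e-9)
  expect_lt(cohort_curve(m, lab0, 0), 1e-9)

  # area at t = 0 equals e2 * [Pr(age < d) + (1 - e1) Pr(age >= d)] under
  # the steady age density, computed here by independent adaptive quadrature
  lab <- labeling_config(e1 = 0.9, e2 = 0.6, d = 24)
  ls <- wt_ls()
  norm <- integrate(function(a) survival_to_age(ls, a), 0, Inf,
                    rel.tol = 1e-10)$value
  p_young <- integrate(function(a) survival_to_age(ls, a), 0, 24,
                       rel.tol = 1e-10)$value / norm
  expected <- lab$e2 * (p_young + (1 - lab$e1) * (1 - p_young))
  expect_equal(cohort_curve(ls, lab, 0), expected, tolerance = 1e-4)
})

test_that("boundary inflow decays at the label half-life", {
  m <- wt_dls()
  lab <- labeling_config(e1 = 0.9, e2 = 0.6, b_half = 10)
  at0 <- cohort_boundary_inflow(m, lab, 0)
  expect_equal(at0, lab$e2 * steady_age_density(m, 0), tolerance = 1e-12)
  expect_equal(cohort_boundary_inflow(m, lab, 10), at0 / 2, tolerance = 1e-12)
  expect_equal(cohort_boundary_inflow(m, lab, 30), at0 / 8, tolerance = 1e-12)
  # total extra labelled influx over [0, Inf) = e2 * p(0) * b_half / ln 2
  total <- integrate(function(t) cohort_boundary_inflow(m, lab, t), 0, Inf)$value
  expect_equal(total, lab$e2 * steady_age_density(m, 0) * lab$b_half / log(2),
               tolerance = 1e-6)
  expect_error(labeling_config(b_half = 0), "positive")
})

test_that("cohort curve solves pure transport exactly for a fixed lifespan", {
  # e1 = e2 = 1, negligible carry-over, r = 0, T = 100, d = 24: the cohort is
  # a uniform age band of width d that advects until it falls off at T
  m <- lifespan_model(delta_law(100))
  lab <- labeling_config(e1 = 1, e2 = 1, b_half = 1e-6, d = 24)
  expect_equal(cohort_curve(m, lab, 0), 0.24, tolerance = 1e-3)
  expect_equal(cohort_curve(m, lab, 50), 0.24, tolerance = 1e-3)
  # band straddles T: linear ramp down, exhausted at t = T; when the jump
  # falls between grid nodes the trapezoid rule is O(h) accurate, so the
  # check is against the absolute grid resolution
  expect_lt(abs(cohort_curve(m, lab, 88) - 0.12), 1e-3)
  expect_equal(cohort_curve(m, lab, 100), 0)
  expect_equal(cohort_curve(m, lab, 130), 0)
})

test_that("characteristics solution agrees with the upwind finite-difference solver", {
  for (m in list(wt_dls(), wt_ls())) {
    lab <- labeling_config(e1 = 0.9, e2 = 0.6, b_half = 12, d = 24)
    fd <- platekin:::cohort_curve_fd(m, lab, t_max = 200, grid_points = 1000L,
                                     n_out = 21L)
    moc <- cohort_curve(m, lab, fd$t, grid_points = 1000L)
    expect_lt(max(abs(moc - fd$cohort)), 1e-3)
  }
})

test_that("cohort fraction is monotone in the labelling efficiencies", {
  m <- wt_dls()
  tt <- c(0, 24, 72, 120)
  base <- cohort_curve(m, labeling_config(e1 = 0.9, e2 = 0.6), tt)
  hi_e2 <- cohort_curve(m, labeling_config(e1 = 0.9, e2 = 0.8), tt)
  hi_e1 <- cohort_curve(m, labeling_config(e1 = 0.99, e2 = 0.6), tt)
  expect_true(all(hi_e2 >= base - 1e-12))
  expect_true(all(hi_e1 <= base + 1e-12))
})

test_that("with negligible carry-over the cohort curve is nonincreasing", {
  m <- wt_dls()
  lab <- labeling_config(e1 = 0.9, e2 = 0.6, b_half = 1e-6, d = 24)
  cc <- cohort_curve(m, lab, seq(0, 250, length.out = 40))
  expect_true(all(diff(cc) <= 1e-10))
})
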