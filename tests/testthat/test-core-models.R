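test_that("survival_to_age obeys its closed forms and monotonicity", {
  models <- list(wt_ls(), wt_dls(), wt_dorn(), study_model(0.6))
  for (m in models) {
    expect_identical(survival_to_age(m, 0), 1)
    a <- seq(0, platekin:::law_amax(m$law) * 1.2, length.out = 80)
    P <- survival_to_age(m, a)
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(diff(P) <= 1e-12))
  }
  # Dornhorst closed form: pure exponential before T
  expect_equal(survival_to_age(lifespan_model(delta_law(100), 0.01), 50),
               exp(-0.5), tolerance = 1e-12)
  # with r = 0 the lognormal median age has survival 1/2
  expect_equal(survival_to_age(wt_ls(), exp(4.45)), 0.5, tolerance = 1e-12)
  expect_error(survival_to_age(wt_ls(), -1), "non-negative")
})

test_that("steady age density normalises to 1 and has the stated normaliser", {
  for (m in list(wt_ls(), wt_dls(), wt_dorn())) {
    g <- platekin:::curve_grid(m, 1000L)
    # independent adaptive quadrature of the normalised density
    upper <- if (inherits(m$law, "delta_law")) m$law$T else Inf
    total <- integrate(function(a) steady_age_density(m, a), 0, upper,
                       rel.tol = 1e-10)$value
    expect_lt(abs(total - 1), 1e-4)
    # density is proportional to the survival-to-age probability
    a <- g$ages
    expect_equal(steady_age_density(m, a) * g$norm, survival_to_age(m, a),
                 tolerance = 1e-12)
  }
  # fixed lifespan with no random loss: uniform ages on [0, T]
  m <- lifespan_model(delta_law(120))
  expect_equal(steady_age_density(m, c(10, 60, 110)), rep(1 / 120, 3),
               tolerance = 1e-9)
  # r > 0 normaliser equals f / r (published wild-type DLS parameters)
  m <- wt_dls()
  g <- platekin:::curve_grid(m, 1000L)
  expect_equal(g$norm, random_loss_fraction(m) / m$r, tolerance = 1e-4)
})

test_that("population survival curve: boundary values, monotone decay, limits", {
  for (m in list(wt_ls(), wt_dls(), wt_dorn())) {
    tt <- seq(0, platekin:::law_amax(m$law) * 1.1, length.out = 60)
    D <- population_survival_curve(m, tt)
    expect_equal(D[1], 1, tolerance = 1e-12)
    expect_true(all(diff(D) <= 1e-12))
    expect_lt(D[length(D)], 1e-6)
  }
  # fixed lifespan, r -> 0: linear decay 1 - t/T
  expect_equal(population_survival_curve(lifespan_model(delta_law(100)), 40),
               0.6, tolerance = 1e-12)
})

test_that("DLS reduces to LS at r = 0 and to Dornhorst as s -> 0", {
  tt <- seq(0, 300, length.out = 61)
  ls <- lifespan_model(lognormal_law(4.45, 0.307))
  dls0 <- lifespan_model(lognormal_law(4.45, 0.307), r = 0)
  expect_lt(max(abs(population_survival_curve(dls0, tt) -
                    population_survival_curve(ls, tt))), 1e-8)
  expect_equal(random_loss_fraction(dls0), 0)

  Tfix <- 100; r <- 0.005
  near_delta <- lifespan_model(lognormal_law(log(Tfix), 1e-4 * log(Tfix)), r = r)
  dorn <- lifespan_model(delta_law(Tfix), r = r)
  expect_lt(max(abs(population_survival_curve(near_delta, tt) -
                    population_survival_curve(dorn, tt))), 1e-3)
  expect_lt(abs(random_loss_fraction(near_delta) - random_loss_fraction(dorn)),
            1e-3)
})

test_that("random loss fraction: zero iff r = 0, increasing in r, quadrature check", {
  law <- study_law()
  expect_identical(random_loss_fraction(lifespan_model(law, 0)), 0)
  rs <- c(0.0005, 0.002, 0.005, 0.02)
  fs <- vapply(rs, function(r) random_loss_fraction(lifespan_model(law, r)),
               numeric(1))
  expect_true(all(fs > 0 & fs < 1))
  expect_true(all(diff(fs) > 0))
  # general integrated-by-parts quadrature equals the closed forms
  for (m in list(wt_dorn(), bclx_dorn(), wt_dls())) {
    expect_lt(abs(random_loss_fraction(m, "quadrature") -
                  random_loss_fraction(m)), 1e-9)
  }
  # published values (2 d.p.)
  expect_equal(round(random_loss_fraction(wt_dorn()), 2), 0.55)
  expect_equal(round(random_loss_fraction(bclx_dorn()), 2), 0.15)
  expect_equal(round(random_loss_fraction(wt_dls()), 2), 0.31)
})

test_that("steady-state identities f = R/S and N = S * mean lifespan hold", {
  set.seed(7)
  for (i in 1:12) {
    law <- if (i %% 2) {
      lognormal_from_moments(runif(1, 40, 200), runif(1, 5, 50))
    } else delta_law(runif(1, 40, 200))
    m <- lifespan_model(law, r = runif(1, 1e-4, 0.02))
    N <- runif(1, 300, 2000)
    ss <- steady_state(m, N)
    expect_lt(abs(ss$f - ss$R / (24 * ss$S)), 1e-9)  # both per day
    expect_lt(abs(ss$N - ss$S * ss$mean_realized_lifespan), 1e-9)
  }
  # r = 0 handled via the mean-lifespan limit (no division by zero)
  ss0 <- steady_state(wt_ls(), 1183)
  expect_equal(ss0$R, 0)
  expect_equal(ss0$mean_realized_lifespan,
               lognormal_to_moments(wt_ls()$law)[["mu"]])
  # published steady-state values
  expect_equal(round(steady_state(bclx_dorn(), 847)$R), 59)
  expect_equal(round(steady_state(wt_dls(), 1183)$R), 108)
})

test_that("model JSON descriptors round-trip", {
  for (m in list(wt_ls(), wt_dls(), wt_dorn())) {
    m2 <- model_from_json(model_to_json(m))
    expect_identical(model_kind(m2), model_kind(m))
    expect_equal(m2$r, m$r)
    expect_equal(unclass(m2$law), unclass(m$law))
  }
  # moment-parameterised descriptor accepted
  m3 <- model_from_json('{"model":"DLS","mu":99.5,"sigma":26.1,"r":0.0038}')
  expect_equal(lognormal_to_moments(m3$law)[["mu"]], 99.5, tolerance = 1e-9)
  expect_error(model_from_json('{"model":"LS","m":4,"s":0.3,"r":0.01}'), "DLS")
  expect_error(model_from_json('{"model":"XX","m":4,"s":0.3}'), "unknown")
})
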