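#' Solve for the random-loss rate giving a target loss fraction
#'
#' Inverts the map r -> f (see [random_loss_fraction()]) for a fixed natural
#' lifespan law by root finding; f is strictly increasing in r, so the root
#' is unique.
#'
#' @param law A lifespan law ([lognormal_law()] or [delta_law()]).
#' @param f_target Target random loss fraction in \[0, 1).
#' @return The rate constant r (per hour) with
#'   `random_loss_fraction(lifespan_model(law, r)) == f_target` to within
#'   1e-8; 0 when `f_target` is 0.
#' @examples
#' r_from_f(lognormal_from_moments(100, 25), 0.2)
#' @export
r_from_f <- function(law, f_target) {
  stopifnot(inherits(law, "lifespan_law"))
  if (!is.numeric(f_target) || length(f_target) != 1L || !is.finite(f_target) ||
      f_target < 0 || f_target >= 1)
    stop("`f_target` must be in [0, 1)", call. = FALSE)
  if (f_target == 0) return(0)
  g <- function(r) random_loss_fraction(lifespan_model(law, r)) - f_target
  hi <- 1 / law_mean(law)
  while (g(hi) < 0) hi <- hi * 2
  stats::uniroot(g, c(0, hi), tol = 1e-12)$root
}

#' Generate a synthetic survival dataset
#'
#' Simulates replicate survival curves around the model prediction with
#' independent Gaussian noise. Noise magnitude is specified as the standard
#' error of the mean curve (`sem_percent`, in percent): each individual
#' replicate point receives noise with s.d. `sem_percent * sqrt(n_replicates)`
#' so that the replicate mean has the stated s.e.m.
#'
#' @param model A [lifespan_model()].
#' @param lab A [labeling_config()].
#' @param sem_percent Standard error of the mean curve, percent, >= 0.
#' @param times Observation times (hours). Default: 13 equally spaced points
#'   from 0 to the upper end of the lifespan support (about mu + 4 sigma),
#'   echoing the ~5-day designs of the motivating experiments.
#' @param n_replicates Number of replicate curves (default 6).
#' @param curves Which curves to simulate: `"population"` and/or `"cohort"`.
#' @param platelet_count,count_sem Optional platelet count carried into the
#'   dataset (needed for derived R and S).
#' @param seed RNG seed; fixed seeds reproduce the dataset exactly.
#' @param grid_points Quadrature nodes for the noiseless predictions.
#' @return A [survival_dataset()].
#' @export
generate_dataset <- function(model, lab, sem_percent, times = NULL,
                             n_replicates = 6L, curves = "population",
                             platelet_count = NA_real_, count_sem = NA_real_,
                             seed = NULL, grid_points = 1000L) {
  stopifnot(inherits(model, "lifespan_model"), inherits(lab, "labeling_config"))
  if (!is.numeric(sem_percent) || sem_percent < 0)
    stop("`sem_percent` must be >= 0", call. = FALSE)
  if (!all(curves %in% c("population", "cohort")))
    stop("`curves` must be a subset of {population, cohort}", call. = FALSE)
  if (is.null(times))
    times <- seq(0, law_amax(model$law), length.out = 13L)
  if (!is.null(seed)) set.seed(seed)
  sd_rep <- sem_percent * sqrt(n_replicates)
  obs <- do.call(rbind, lapply(curves, function(cv) {
    truth <- predict_observed(model, lab, times, cv, grid_points)
    do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
      data.frame(time_hr = times,
                 percent = pmin(pmax(truth + stats::rnorm(length(times), 0,
                                                          sd_rep), -10), 110),
                 replicate = rep, curve = cv)
    }))
  }))
  survival_dataset(obs, platelet_count = platelet_count,
                   count_sem = count_sem, label = "synthetic")
}

#' Simulation-study grid
#'
#' Describes the parameter-constraint-versus-noise study: DLS curves with a
#' fixed lognormal natural lifespan (defaults mean 100 hr, s.d. 25 hr) are
#' generated at each random loss fraction in `f_values` and each noise level
#' in `sem_values`, then fitted and bootstrapped by [monte_carlo()].
#'
#' @param f_values Random loss fractions (default 0, 0.2, 0.4, 0.6, 0.8).
#' @param sem_values Noise levels as s.e.m. of the mean curve, percent.
#' @param mu,sigma Mean and s.d. of the natural lifespan (hours).
#' @param e1 First-label efficiency used for the synthetic curves.
#' @return An object of class `study_grid`.
#' @export
study_grid <- function(f_values = c(0, 0.2, 0.4, 0.6, 0.8),
                       sem_values = c(0.1, 0.2, 0.4), mu = 100, sigma = 25,
                       e1 = 0.9) {
  if (any(f_values < 0 | f_values >= 1))
    stop("f_values must lie in [0, 1)", call. = FALSE)
  structure(list(f_values = f_values, sem_values = sem_values, mu = mu,
                 sigma = sigma, e1 = e1), class = "study_grid")
}

#' Parameter-constraint-versus-noise study
#'
#' For every (f, sem) cell of the grid: solve for the rate constant giving
#' the target loss fraction, simulate one dataset at that noise level, fit
#' the DLS model, run the Monte Carlo procedure, and record how well the
#' random loss fraction is constrained — its interquartile range and 2.5 and
#' 97.5 percentiles across the ensemble.
#'
#' @param grid A [study_grid()].
#' @param seed RNG seed controlling the whole study.
#' @param n_replicates Replicate curves per simulated dataset (default 6).
#' @param mc_iterations Monte Carlo iterations per cell. The motivating
#'   analysis used 1000; smaller values give a quicker, coarser study.
#' @param starts_patience,n_restarts Optimiser schedule for the initial fit
#'   and the Monte Carlo refits.
#' @param grid_points Quadrature nodes.
#' @return A data.frame (class `platekin_study`) with one row per cell:
#'   `f_true`, `sem`, `r_true`, `f_hat` (best fit), `f_iqr`, `f_lo`, `f_hi`
#'   (95% interval), `n_failed`.
#' @export
constraint_study <- function(grid, seed = NULL, n_replicates = 6L,
                             mc_iterations = 100L, starts_patience = 10L,
                             n_restarts = 2L, grid_points = 1000L) {
  stopifnot(inherits(grid, "study_grid"))
  law <- lognormal_from_moments(grid$mu, grid$sigma)
  lab <- labeling_config(e1 = grid$e1)
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(f_true = grid$f_values, sem = grid$sem_values)
  # pre-draw independent sub-seeds so cell order does not couple the RNG
  cells$cell_seed <- sample.int(.Machine$integer.max, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    f_true <- cells$f_true[i]
    sem <- cells$sem[i]
    r_true <- r_from_f(law, f_true)
    truth <- lifespan_model(law, r = r_true)
    ds <- generate_dataset(truth, lab, sem_percent = sem,
                           n_replicates = n_replicates,
                           seed = cells$cell_seed[i],
                           grid_points = grid_points)
    fit <- fit_survival(ds, "DLS", starts_patience = starts_patience,
                        grid_points = grid_points)
    if (sem == 0) {
      # noiseless cell: the ensemble is degenerate at the best fit
      fh <- random_loss_fraction(fit$model)
      return(data.frame(f_true = f_true, sem = sem, r_true = r_true,
                        f_hat = fh, f_iqr = 0, f_lo = fh, f_hi = fh,
                        n_failed = 0L))
    }
    ens <- monte_carlo(fit, ds, n_iterations = mc_iterations,
                       n_replicates = n_replicates, n_restarts = n_restarts)
    ci <- ensemble_ci(ens, "f")
    data.frame(f_true = f_true, sem = sem, r_true = r_true,
               f_hat = random_loss_fraction(fit$model),
               f_iqr = ensemble_iqr(ens, "f"),
               f_lo = ci[["lower"]], f_hi = ci[["upper"]],
               n_failed = ens$n_failed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("platekin_study", class(out))
  out
}

#' Individual-based stochastic simulation of the labelling experiment
#'
#' An independent validation oracle for the analytic steady-state results:
#' cells are born at a constant rate, assigned a natural lifespan from the
#' model's law and an exponential random-loss time with rate r, and live to
#' the minimum of the two. Labelling events mark extant cells with the
#' configured efficiencies; residual second-label activity marks newly born
#' cells with probability decaying at the label half-life. Empirical
#' survival curves and the realised random-loss fraction are returned with
#' binomial standard errors.
#'
#' With `lab = NULL` a single perfect label is applied at time 0 and only
#' the population curve is returned. With a [labeling_config()], the first
#' label is applied at time `-d` and the second at time 0; the population
#' curve is the fraction of circulating cells carrying the first label
#' (compare `e1 * D(t + d)`), and the cohort curve is the fraction carrying
#' the second label but not the first (compare [cohort_curve()]).
#'
#' @param model A [lifespan_model()].
#' @param lab A [labeling_config()], or `NULL` for a single perfect label.
#' @param n_cells Number of simulated birth events (>= 1e4).
#' @param times Output time grid (hours since the last labelling event).
#'   Default: 20 points across the lifespan support.
#' @param seed RNG seed.
#' @return A list: `population` (data.frame `t`, `fraction`, `se`),
#'   `cohort` (same, or `NULL`), `realized_f`, `realized_f_se`, `n_alive0`.
#' @export
stochastic_oracle <- function(model, lab = NULL, n_cells = 2e5L,
                              times = NULL, seed = NULL) {
  stopifnot(inherits(model, "lifespan_model"))
  if (n_cells < 1e4) stop("`n_cells` must be at least 1e4", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A <- law_amax(model$law) * 1.05
  if (is.null(times)) times <- seq(0, law_amax(model$law), length.out = 20L)
  horizon <- max(times)
  d <- if (is.null(lab)) 0 else lab$d

  births <- stats::runif(n_cells, -A - d, if (is.null(lab)) 0 else horizon)
  L <- if (inherits(model$law, "delta_law")) {
    rep(model$law$T, n_cells)
  } else {
    stats::rlnorm(n_cells, model$law$m, model$law$s)
  }
  E <- if (model$r > 0) stats::rexp(n_cells, model$r) else rep(Inf, n_cells)
  life <- pmin(L, E)
  death <- births + life
  realized_f <- mean(E < L)
  realized_f_se <- sqrt(realized_f * (1 - realized_f) / n_cells)

  alive_at <- function(t) births <= t & death > t

  if (is.null(lab)) {
    lab0 <- alive_at(0)
    n0 <- sum(lab0)
    frac <- vapply(times, function(t) sum(lab0 & death > t) / n0, numeric(1L))
    pop <- data.frame(t = times, fraction = frac,
                      se = sqrt(pmax(frac * (1 - frac), 1e-12) / n0))
    return(list(population = pop, cohort = NULL, realized_f = realized_f,
                realized_f_se = realized_f_se, n_alive0 = n0))
  }

  u1 <- stats::runif(n_cells)
  u2 <- stats::runif(n_cells)
  label1 <- alive_at(-d) & u1 < lab$e1
  alive0 <- alive_at(0)
  label2 <- (alive0 & u2 < lab$e2) |
    (births > 0 & u2 < lab$e2 * 2^(-births / lab$b_half))
  cohort <- label2 & !label1

  n_at <- vapply(times, function(t) sum(alive_at(t)), numeric(1L))
  pop_frac <- vapply(times, function(t) sum(label1 & alive_at(t)),
                     numeric(1L)) / n_at
  coh_frac <- vapply(times, function(t) sum(cohort & alive_at(t)),
                     numeric(1L)) / n_at
  list(
    population = data.frame(t = times, fraction = pop_frac,
                            se = sqrt(pmax(pop_frac * (1 - pop_frac), 1e-12) / n_at)),
    cohort = data.frame(t = times, fraction = coh_frac,
                        se = sqrt(pmax(coh_frac * (1 - coh_frac), 1e-12) / n_at)),
    realized_f = realized_f, realized_f_se = realized_f_se,
    n_alive0 = sum(alive0))
}
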