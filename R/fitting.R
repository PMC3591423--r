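#' Survival dataset
#'
#' Container for observed labelled-fraction time series: replicate
#' measurements of the percent of platelets carrying the population label
#' and, optionally, the cohort (second) label.
#'
#' @param observations A data.frame with columns `time_hr` (>= 0), `percent`,
#'   `replicate`, and `curve` (`"population"` or `"cohort"`). Percents are
#'   expected in \[0, 100\]; values in \[-10, 110\] are tolerated (simulated
#'   noisy data may stray slightly outside the physical range), anything
#'   beyond is an error.
#' @param platelet_count Platelet count N in 1e3/uL, or `NA` if not measured.
#' @param count_sem Standard error of `platelet_count` (same units).
#' @param label Free-text genotype or sample label.
#' @return An object of class `survival_dataset`.
#' @export
survival_dataset <- function(observations, platelet_count = NA_real_,
                             count_sem = NA_real_, label = "") {
  need <- c("time_hr", "percent", "replicate", "curve")
  if (!is.data.frame(observations) || !all(need %in% names(observations)))
    stop("`observations` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  obs <- as.data.frame(observations)[need]
  obs$time_hr <- as.numeric(obs$time_hr)
  obs$percent <- as.numeric(obs$percent)
  obs$curve <- as.character(obs$curve)
  if (anyNA(obs$time_hr) || anyNA(obs$percent))
    stop("non-numeric time or percent values", call. = FALSE)
  if (any(obs$time_hr < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(obs$percent < -10 | obs$percent > 110))
    stop("percent values outside [-10, 110]", call. = FALSE)
  if (!all(obs$curve %in% c("population", "cohort")))
    stop("`curve` must be \"population\" or \"cohort\"", call. = FALSE)
  if (length(unique(obs$time_hr[obs$curve == "population"])) < 2L)
    stop("need at least 2 distinct population time points", call. = FALSE)
  structure(list(observations = obs, platelet_count = platelet_count,
                 count_sem = count_sem, label = label),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  obs <- x$observations
  cat(sprintf("Survival dataset%s: %d points (%d population, %d cohort), %d replicates\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(obs), sum(obs$curve == "population"),
              sum(obs$curve == "cohort"), length(unique(obs$replicate))))
  if (!is.na(x$platelet_count))
    cat(sprintf("  platelet count N = %g +/- %g x10^3/uL\n",
                x$platelet_count, x$count_sem))
  invisible(x)
}

#' Predict observed label percentages
#'
#' Maps a model to the observation scale: the population-label curve is
#' `100 * e1 * D(t)` (the theoretical survival curve scaled by the
#' first-label efficiency), and the cohort curve is `100 *`
#' [cohort_curve()], the absolute percent of all platelets in the labelled
#' cohort.
#'
#' @param model A [lifespan_model()].
#' @param lab A [labeling_config()]; only `e1` is used for population curves.
#' @param times Times in hours (>= 0).
#' @param curve `"population"` or `"cohort"`.
#' @param grid_points Quadrature nodes.
#' @return Predicted percents.
#' @export
predict_observed <- function(model, lab, times,
                             curve = c("population", "cohort"),
                             grid_points = 1000L) {
  curve <- match.arg(curve)
  if (curve == "population") {
    100 * lab$e1 * population_survival_curve(model, times, grid_points)
  } else {
    100 * cohort_curve(model, lab, times, grid_points)
  }
}

# --- internal parameterisation of the fit ----------------------------------
# Each model kind maps a bounded parameter vector to (model, lab). Bounds are
# wide; multi-start sampling uses the narrower intervals in fit_start().
fit_parspec <- function(kind, use_cohort) {
  base <- switch(kind,
    LS = list(names = c("m", "s", "e1"),
              lower = c(log(2), 1e-3, 0), upper = c(log(2000), 2, 1)),
    DORNHORST = list(names = c("T", "r", "e1"),
                     lower = c(2, 0, 0), upper = c(2000, 0.2, 1)),
    DLS = list(names = c("m", "s", "r", "e1"),
               lower = c(log(2), 1e-3, 0, 0), upper = c(log(2000), 2, 0.2, 1)))
  if (use_cohort) {
    base$names <- c(base$names, "e2", "b_half")
    base$lower <- c(base$lower, 0, 0.1)
    base$upper <- c(base$upper, 1, 200)
  }
  base
}

# Sampling intervals for random multi-start points (configurable via
# options$start_ranges); bracket all plausible murine/human platelet fits
# with wide margin.
fit_start_ranges <- function() {
  list(m = c(log(12), log(400)), s = c(0.01, 1), r = c(0, 0.05),
       T = c(12, 400), e1 = c(0.5, 1), e2 = c(0.5, 1), b_half = c(1, 48))
}

fit_start <- function(spec, ranges) {
  vapply(spec$names, function(nm) stats::runif(1L, ranges[[nm]][1L],
                                               ranges[[nm]][2L]), numeric(1L))
}

fit_build <- function(kind, theta) {
  if (kind == "DORNHORST") {
    model <- lifespan_model(delta_law(theta[["T"]]), r = theta[["r"]])
  } else if (kind == "LS") {
    model <- lifespan_model(lognormal_law(theta[["m"]], theta[["s"]]))
  } else {
    model <- lifespan_model(lognormal_law(theta[["m"]], theta[["s"]]),
                            r = theta[["r"]])
  }
  lab <- labeling_config(
    e1 = min(max(theta[["e1"]], 0), 1),
    e2 = if ("e2" %in% names(theta)) min(max(theta[["e2"]], 0), 1) else 0.6,
    b_half = if ("b_half" %in% names(theta)) theta[["b_half"]] else 12)
  list(model = model, lab = lab)
}

fit_objective <- function(obs, kind, spec, grid_points) {
  pop <- obs[obs$curve == "population", , drop = FALSE]
  coh <- obs[obs$curve == "cohort", , drop = FALSE]
  pop_t <- sort(unique(pop$time_hr))
  coh_t <- if (nrow(coh)) sort(unique(coh$time_hr)) else numeric()
  pop_i <- match(pop$time_hr, pop_t)
  coh_i <- if (nrow(coh)) match(coh$time_hr, coh_t) else integer()
  function(theta) {
    names(theta) <- spec$names
    mb <- tryCatch(fit_build(kind, theta), error = function(e) NULL)
    if (is.null(mb)) return(1e10)
    pred_p <- predict_observed(mb$model, mb$lab, pop_t, "population",
                               grid_points)
    ssr <- sum((pop$percent - pred_p[pop_i])^2)
    if (length(coh_t)) {
      pred_c <- predict_observed(mb$model, mb$lab, coh_t, "cohort",
                                 grid_points)
      ssr <- ssr + sum((coh$percent - pred_c[coh_i])^2)
    }
    if (!is.finite(ssr)) 1e10 else ssr
  }
}

#' Fit a lifespan model to survival data
#'
#' Multi-start bounded least squares: the sum of squared residuals (in
#' percent squared, against every replicate point) is minimised with a
#' bound-constrained quasi-Newton optimiser (`optim` L-BFGS-B) from random
#' starting points, stopping once `starts_patience` consecutive starts have
#' failed to improve the best fit. DLS fits are additionally seeded from the
#' nested LS and Dornhorst optima, which guarantees
#' ssr(DLS) <= min(ssr(LS), ssr(Dornhorst)) on every dataset.
#'
#' @param dataset A [survival_dataset()].
#' @param model_kind `"LS"`, `"DORNHORST"` or `"DLS"`.
#' @param use_cohort If `TRUE`, fit population and cohort curves jointly
#'   (adds the `e2` and `b_half` parameters).
#' @param starts_patience Number of consecutive non-improving random starts
#'   before termination. Default 100 for population-only fits, 10 when the
#'   cohort curve is included.
#' @param grid_points Quadrature nodes for curve evaluation (default 1000).
#' @param seed RNG seed for the start-point sampling (recorded in the
#'   result); `NULL` leaves the RNG state alone.
#' @param nested_seeding For DLS fits, first fit the nested LS and Dornhorst
#'   models and use their optima as additional starts (default `TRUE`).
#' @param max_starts Hard cap on the number of random starts.
#' @param start_ranges Named list of sampling intervals for start points;
#'   see `platekin:::fit_start_ranges()` for the defaults.
#' @param init Optional list of extra starting parameter vectors (named as in
#'   the fit parameterisation) tried before the random schedule.
#' @param optim_control `control` list for the L-BFGS-B runs (iteration cap
#'   and convergence factor); loosen it for cheap refits where starts are
#'   already near the optimum.
#' @param polish_maxit The bound-constrained optimiser can stall in the flat
#'   valley created by the trade-off between mean lifespan and random loss
#'   (its finite-difference gradients lose accuracy there), so the best
#'   multi-start solution is polished with a derivative-free Nelder-Mead
#'   pass of at most this many evaluations (0 disables).
#' @return An object of class `platekin_fit`: best-fit `model`, `lab`,
#'   `par`, `ssr`, `df`, `n_params`, `n_points`, `predicted` (data.frame on
#'   the data's time grid), plus bookkeeping (`kind`, `use_cohort`, `seed`,
#'   `n_starts`).
#' @examples
#' truth <- lifespan_model(lognormal_from_moments(100, 25))
#' ds <- generate_dataset(truth, labeling_config(e1 = 0.9), sem_percent = 0,
#'                        n_replicates = 2, seed = 1)
#' fit <- fit_survival(ds, "LS", starts_patience = 3, seed = 1)
#' fit$ssr
#' @export
fit_survival <- function(dataset, model_kind = c("LS", "DORNHORST", "DLS"),
                         use_cohort = FALSE,
                         starts_patience = if (use_cohort) 10L else 100L,
                         grid_points = 1000L, seed = NULL,
                         nested_seeding = TRUE, max_starts = 1000L,
                         start_ranges = fit_start_ranges(), init = list(),
                         polish_maxit = 1500L,
                         optim_control = list(maxit = 300L, factr = 1e6)) {
  stopifnot(inherits(dataset, "survival_dataset"))
  kind <- match.arg(model_kind)
  obs <- dataset$observations
  if (!use_cohort) obs <- obs[obs$curve == "population", , drop = FALSE]
  if (use_cohort && !any(obs$curve == "cohort"))
    stop("use_cohort = TRUE but the dataset has no cohort observations",
         call. = FALSE)
  spec <- fit_parspec(kind, use_cohort)
  n_params <- length(spec$names)
  n_points <- nrow(obs)
  df <- n_points - n_params
  if (df <= 0)
    stop(sprintf("degrees of freedom must be positive (%d points, %d parameters)",
                 n_points, n_params), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  objective <- fit_objective(obs, kind, spec, grid_points)
  run_local <- function(theta0) {
    theta0 <- pmin(pmax(theta0, spec$lower), spec$upper)
    tryCatch(
      stats::optim(theta0, objective, method = "L-BFGS-B",
                   lower = spec$lower, upper = spec$upper,
                   control = optim_control),
      error = function(e) NULL)
  }

  # deterministic seeds: caller-supplied, then nested optima for DLS
  seeds <- lapply(init, function(v) {
    out <- stats::setNames(rep(NA_real_, n_params), spec$names)
    out[names(v)] <- unlist(v)
    miss <- is.na(out)
    out[miss] <- (spec$lower[miss] + spec$upper[miss]) / 2
    out
  })
  nested <- list()
  if (kind == "DLS" && nested_seeding) {
    for (nk in c("LS", "DORNHORST")) {
      nf <- fit_survival(dataset, nk, use_cohort = use_cohort,
                         starts_patience = starts_patience,
                         grid_points = grid_points, seed = NULL,
                         max_starts = max_starts, start_ranges = start_ranges,
                         polish_maxit = polish_maxit,
                         optim_control = optim_control)
      nested[[nk]] <- nf
      th <- stats::setNames(rep(NA_real_, n_params), spec$names)
      if (nk == "LS") {
        th[c("m", "s", "r", "e1")] <- c(nf$par[["m"]], nf$par[["s"]], 0,
                                        nf$par[["e1"]])
      } else {
        # a delta law is the s -> 0 limit of a lognormal centred on log(T)
        th[c("m", "s", "r", "e1")] <- c(log(nf$par[["T"]]), spec$lower[2L],
                                        nf$par[["r"]], nf$par[["e1"]])
      }
      if (use_cohort) th[c("e2", "b_half")] <- nf$par[c("e2", "b_half")]
      seeds <- c(seeds, list(th))
    }
  }

  best <- NULL
  best_ssr <- Inf
  since_improved <- 0L
  n_starts <- 0L
  for (th0 in seeds) {
    res <- run_local(th0)
    n_starts <- n_starts + 1L
    if (!is.null(res) && res$value < best_ssr - 1e-9) {
      best <- res; best_ssr <- res$value
    }
  }
  while (since_improved < starts_patience && n_starts < max_starts) {
    res <- run_local(fit_start(spec, start_ranges))
    n_starts <- n_starts + 1L
    if (!is.null(res) && res$value < best_ssr - 1e-6) {
      best <- res; best_ssr <- res$value; since_improved <- 0L
    } else {
      since_improved <- since_improved + 1L
    }
  }
  if (is.null(best))
    stop("optimizer failed to converge from every starting point",
         call. = FALSE)

  if (polish_maxit > 0L) {
    # out-of-bound proposals hit the objective's validity penalty, so the
    # unconstrained simplex respects the hard constraints
    pol <- tryCatch(
      stats::optim(best$par, objective, method = "Nelder-Mead",
                   control = list(maxit = polish_maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value) best <- pol
  }

  par <- stats::setNames(pmin(pmax(best$par, spec$lower), spec$upper),
                         spec$names)
  mb <- fit_build(kind, par)
  pred <- do.call(rbind, lapply(unique(obs$curve), function(cv) {
    tg <- sort(unique(obs$time_hr[obs$curve == cv]))
    data.frame(time_hr = tg, curve = cv,
               percent_pred = predict_observed(mb$model, mb$lab, tg, cv,
                                               grid_points))
  }))
  structure(list(model = mb$model, lab = mb$lab, par = par,
                 ssr = best$value, df = df, n_params = n_params,
                 n_points = n_points, predicted = pred, kind = kind,
                 use_cohort = use_cohort, grid_points = grid_points,
                 seed = seed, n_starts = n_starts, nested = nested,
                 platelet_count = dataset$platelet_count,
                 label = dataset$label),
            class = "platekin_fit")
}

#' @export
print.platekin_fit <- function(x, ...) {
  cat(sprintf("%s model fit%s%s\n", x$kind,
              if (x$use_cohort) " (population + cohort)" else " (population)",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat("  parameters:\n")
  for (nm in names(x$par))
    cat(sprintf("    %-7s = %.6g\n", nm, x$par[[nm]]))
  if (x$kind != "DORNHORST") {
    mo <- lognormal_to_moments(x$model$law)
    cat(sprintf("    mu      = %.4g hr, sigma = %.4g hr\n",
                mo[["mu"]], mo[["sigma"]]))
  }
  cat(sprintf("    f       = %.3f\n", random_loss_fraction(x$model)))
  cat(sprintf("  ssr = %.4g percent^2 on %d points, df = %d (%d starts)\n",
              x$ssr, x$n_points, x$df, x$n_starts))
  invisible(x)
}
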