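#' Residual noise standard deviation of a fit
#'
#' The experimental error about the best-fit curve is modelled as Gaussian
#' noise with standard deviation sigma_e = sqrt(ssr / df), where `ssr` is the
#' sum of squared residuals of the fit and `df` its degrees of freedom
#' (number of points minus number of parameters). Units: percent.
#'
#' @param fit A [fit_survival()] result (or any list with `ssr` and `df`).
#' @return sigma_e in percent.
#' @export
noise_sd_from_fit <- function(fit) {
  if (is.null(fit$df) || fit$df <= 0)
    stop("degrees of freedom must be positive", call. = FALSE)
  sqrt(fit$ssr / fit$df)
}

# Parameter vector plus derived quantities recorded per Monte Carlo
# iteration. N may be NA, in which case R and S are NA too.
ensemble_row <- function(fit, N) {
  out <- as.list(fit$par)
  if (fit$kind != "DORNHORST") {
    mo <- lognormal_to_moments(fit$model$law)
    out$mu <- mo[["mu"]]
    out$sigma <- mo[["sigma"]]
  } else {
    out$mu <- fit$model$law$T
    out$sigma <- 0
  }
  out$r <- fit$model$r
  out$f <- random_loss_fraction(fit$model)
  if (!is.na(N)) {
    ss <- steady_state(fit$model, N)
    out$R <- ss$R
    out$S <- ss$S
  } else {
    out$R <- NA_real_
    out$S <- NA_real_
  }
  out$ssr <- fit$ssr
  out
}

#' Monte Carlo confidence intervals by refitting simulated data
#'
#' Repeatedly simulates datasets from the best-fit curve — Gaussian noise of
#' magnitude [noise_sd_from_fit()] added independently to every point of
#' `n_replicates` simulated survival curves — refits the same model to each,
#' and summarises the empirical distribution of the refit parameters
#' (including the derived random loss fraction f, absolute loss rate
#' R = 24 r N, and production rate S). The 95% confidence interval of a
#' parameter is its 2.5–97.5 percentile range.
#'
#' Each refit starts from the original best-fit parameters plus
#' `n_restarts` random starting points rather than repeating the full
#' multi-start schedule; iterations whose refit fails are dropped and
#' counted in `n_failed`.
#'
#' @param fit A [fit_survival()] result.
#' @param dataset The [survival_dataset()] that was fitted (provides the
#'   observation time grid and the platelet count).
#' @param n_iterations Number of simulated datasets (default 1000).
#' @param n_replicates Number of simulated survival curves per iteration
#'   (default 6, the replicate count of the motivating experiments).
#' @param seed RNG seed; fixed seeds give bit-reproducible ensembles.
#' @param n_restarts Random restarts per refit in addition to the best-fit
#'   start (default 3).
#' @param starts_patience Patience passed to the restart schedule; the
#'   restarts are plain extra starts, so this only matters if increased.
#' @param optim_control L-BFGS-B control for the refits; defaults looser
#'   than a from-scratch fit because each refit starts at the original
#'   optimum.
#' @param polish_maxit Nelder-Mead polish budget per refit (see
#'   [fit_survival()]); smaller than the default for a full fit because each
#'   refit starts near the optimum already.
#' @return An object of class `platekin_ensemble`: `samples` (data.frame,
#'   one row per successful iteration), `percentiles` (matrix with rows
#'   2.5/25/50/75/97.5), `sigma_e`, `n_iterations`, `n_replicates`,
#'   `n_failed`, `seed`.
#' @export
monte_carlo <- function(fit, dataset, n_iterations = 1000L,
                        n_replicates = 6L, seed = NULL, n_restarts = 3L,
                        starts_patience = n_restarts, polish_maxit = 300L,
                        optim_control = list(maxit = 60L, factr = 1e7)) {
  stopifnot(inherits(fit, "platekin_fit"), inherits(dataset, "survival_dataset"))
  sigma_e <- noise_sd_from_fit(fit)
  if (!is.null(seed)) set.seed(seed)
  pred <- fit$predicted
  if (!fit$use_cohort) pred <- pred[pred$curve == "population", , drop = FALSE]
  n_pt <- nrow(pred)
  rows <- vector("list", n_iterations)
  n_failed <- 0L
  for (it in seq_len(n_iterations)) {
    sim <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
      data.frame(time_hr = pred$time_hr,
                 percent = pred$percent_pred + stats::rnorm(n_pt, 0, sigma_e),
                 replicate = rep, curve = pred$curve)
    }))
    # percents are deliberately not clipped to [0,100]: the refit target is
    # plain least squares, and clipping would bias it
    sim$percent <- pmin(pmax(sim$percent, -10), 110)
    ds <- survival_dataset(sim, dataset$platelet_count, dataset$count_sem)
    refit <- tryCatch(
      fit_survival(ds, fit$kind, use_cohort = fit$use_cohort,
                   starts_patience = starts_patience,
                   grid_points = fit$grid_points, nested_seeding = FALSE,
                   max_starts = 1L + n_restarts,
                   init = list(as.list(fit$par)), polish_maxit = polish_maxit,
                   optim_control = optim_control),
      error = function(e) NULL)
    if (is.null(refit)) { n_failed <- n_failed + 1L; next }
    rows[[it]] <- ensemble_row(refit, dataset$platelet_count)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("every Monte Carlo refit failed", call. = FALSE)
  if (n_failed > 0L)
    message(sprintf("monte_carlo: %d of %d refits failed and were excluded",
                    n_failed, n_iterations))
  samples <- do.call(rbind, lapply(rows, as.data.frame))
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  percentiles <- vapply(samples, stats::quantile, numeric(5L),
                        probs = probs, na.rm = TRUE, names = FALSE)
  rownames(percentiles) <- paste0(probs * 100, "%")
  structure(list(samples = samples, percentiles = percentiles,
                 sigma_e = sigma_e, n_iterations = n_iterations,
                 n_replicates = n_replicates, n_failed = n_failed,
                 seed = seed, kind = fit$kind),
            class = "platekin_ensemble")
}

#' 95% confidence interval of an ensemble parameter
#'
#' @param ensemble A [monte_carlo()] ensemble.
#' @param parameter Column name in `ensemble$samples` (e.g. `"f"`, `"mu"`).
#' @return `c(lower, upper)` — the 2.5 and 97.5 percentiles.
#' @export
ensemble_ci <- function(ensemble, parameter) {
  stopifnot(inherits(ensemble, "platekin_ensemble"))
  if (!parameter %in% colnames(ensemble$percentiles))
    stop("unknown parameter: ", parameter, call. = FALSE)
  stats::setNames(ensemble$percentiles[c("2.5%", "97.5%"), parameter],
                  c("lower", "upper"))
}

#' Interquartile range of an ensemble parameter
#'
#' @inheritParams ensemble_ci
#' @return The 25–75 percentile width.
#' @export
ensemble_iqr <- function(ensemble, parameter) {
  stopifnot(inherits(ensemble, "platekin_ensemble"))
  diff(ensemble$percentiles[c("25%", "75%"), parameter])
}

#' @export
print.platekin_ensemble <- function(x, ...) {
  cat(sprintf("Monte Carlo ensemble (%s): %d iterations (%d failed), sigma_e = %.3g%%\n",
              x$kind, x$n_iterations, x$n_failed, x$sigma_e))
  print(round(x$percentiles, 4))
  invisible(x)
}

#' Correlation between two ensemble parameters
#'
#' Ordinary least-squares regression of `y` on `x` across the Monte Carlo
#' samples, reporting Pearson's r squared, the regression slope, and the
#' slope's 95% confidence interval — the diagnostic used to expose
#' trade-offs such as the strong coupling between the random loss fraction
#' and the mean natural lifespan.
#'
#' @param ensemble A [monte_carlo()] ensemble.
#' @param x,y Parameter (column) names.
#' @return List with `r_squared`, `slope`, `slope_ci` (length-2), `n`.
#' @export
parameter_correlation <- function(ensemble, x, y) {
  stopifnot(inherits(ensemble, "platekin_ensemble"))
  xs <- ensemble$samples[[x]]
  ys <- ensemble$samples[[y]]
  if (is.null(xs) || is.null(ys))
    stop("unknown parameter name", call. = FALSE)
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("zero-variance input: correlation undefined", call. = FALSE)
  fit <- stats::lm(ys ~ xs)
  # a numerically exact linear relation triggers a harmless precision
  # warning inside confint; the interval itself is still what we want
  ci <- suppressWarnings(stats::confint(fit, "xs", level = 0.95))
  list(r_squared = stats::cor(xs, ys)^2,
       slope = unname(stats::coef(fit)[["xs"]]),
       slope_ci = c(lower = ci[1L], upper = ci[2L]),
       n = length(xs))
}
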