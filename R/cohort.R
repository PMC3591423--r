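#' Double-labelling configuration
#'
#' Parameters of the in-vivo double-label experiment: a first "population"
#' label applied to (nearly) all circulating cells, then, after a delay `d`,
#' a second label that defines the "cohort" of cells born in between. The
#' second label (biotin in the motivating experiments) keeps labelling newly
#' produced cells for a while after injection; its residual activity decays
#' with half-life `b_half`.
#'
#' @param e1 First-label efficiency, fraction in \[0, 1\] (default 0.9).
#' @param e2 Second-label efficiency, fraction in \[0, 1\] (default 0.6).
#' @param b_half Second-label half-life in hours, > 0 (default 12).
#' @param d Delay between the two labelling events, hours, > 0 (default 24).
#' @return An object of class `labeling_config`.
#' @export
labeling_config <- function(e1 = 0.9, e2 = 0.6, b_half = 12, d = 24) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("`%s` must be a single number in [0, 1]", nm), call. = FALSE)
  }
  chk01(e1, "e1"); chk01(e2, "e2")
  if (!is.numeric(b_half) || length(b_half) != 1L || !is.finite(b_half) || b_half <= 0)
    stop("`b_half` must be a single positive number of hours", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("`d` must be a single positive number of hours", call. = FALSE)
  structure(list(e1 = e1, e2 = e2, b_half = b_half, d = d),
            class = "labeling_config")
}

#' @export
print.labeling_config <- function(x, ...) {
  cat(sprintf(
    "Labelling: e1 = %.3f, e2 = %.3f, b_half = %.3g hr, delay d = %.3g hr\n",
    x$e1, x$e2, x$b_half, x$d))
  invisible(x)
}

#' @rdname labeling_config
#' @param json JSON string or file with keys `e1`, `e2`, `b_half`, `d`.
#' @export
labeling_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(labeling_config, x[intersect(names(x), c("e1", "e2", "b_half", "d"))])
}

#' Initial age density of the labelled cohort
#'
#' At the moment of the second labelling (time 0 of the cohort curve), the
#' cohort — second-label positive, first-label negative — consists of cells
#' younger than the inter-label delay `d` (born between the labellings,
#' labelled with efficiency `e2`) plus older cells that escaped the first
#' label (weight `e2 * (1 - e1)`). Density is per hour of age, relative to
#' the whole steady-state population, so its area is the initial cohort
#' fraction. With `e1 = 1` it reduces to `e2` times the steady age density
#' truncated at `d`.
#'
#' @param model A [lifespan_model()].
#' @param lab A [labeling_config()].
#' @param a Age(s), hours, >= 0. Vectorised.
#' @param grid_points Quadrature nodes for the normalising integral.
#' @return Density values, >= 0.
#' @export
cohort_initial_density <- function(model, lab, a, grid_points = 1000L) {
  stopifnot(inherits(lab, "labeling_config"))
  w <- ifelse(a < lab$d, lab$e2, lab$e2 * (1 - lab$e1))
  w * steady_age_density(model, a, grid_points)
}

#' Boundary inflow of newly born labelled cells
#'
#' Residual second-label activity continues to label cells born after the
#' injection: the labelled birth inflow at time `t` is
#' `e2 * 2^(-t / b_half)` times the steady-state birth-rate density
#' (the steady age density at age 0). It halves every `b_half` hours and
#' equals `e2` times the birth density at `t = 0`.
#'
#' @param model A [lifespan_model()].
#' @param lab A [labeling_config()].
#' @param t Time(s) since second labelling, hours, >= 0. Vectorised.
#' @param grid_points Quadrature nodes for the normalising integral.
#' @return Labelled inflow density at age 0 (per hour of age).
#' @export
cohort_boundary_inflow <- function(model, lab, t, grid_points = 1000L) {
  stopifnot(inherits(lab, "labeling_config"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  lab$e2 * 2^(-t / lab$b_half) * steady_age_density(model, 0, grid_points)
}

#' Predicted cohort survival curve
#'
#' Area under the cohort age density p(a, t), which obeys the age-structured
#' transport equation dp/dt + dp/da = -(h(a) + r) p, with h(a) the senescent
#' hazard, [cohort_initial_density()] as initial condition and
#' [cohort_boundary_inflow()] as the age-0 boundary condition. Solved exactly
#' along characteristics: a cell of age `a` at time `t` was either in the
#' initial cohort (at age `a - t`, surviving with probability P(a)/P(a-t))
#' or was born labelled at time `t - a` (surviving with probability P(a)).
#' The returned value is the labelled-cohort fraction of the steady-state
#' population (multiply by 100 for percent of platelets).
#'
#' @param model A [lifespan_model()].
#' @param lab A [labeling_config()].
#' @param t Time(s) since the second labelling, hours, >= 0. Vectorised.
#' @param grid_points Number of age-grid nodes (default 1000).
#' @return Cohort fraction(s), >= 0.
#' @export
cohort_curve <- function(model, lab, t, grid_points = 1000L) {
  stopifnot(inherits(model, "lifespan_model"), inherits(lab, "labeling_config"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  g <- curve_grid(model, grid_points)
  birth_dens <- 1 / g$norm          # steady birth-rate density at age 0
  amax <- law_amax(model$law)
  d <- min(lab$d, amax)
  trap <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2
  # along characteristics p(b + t, t) = p0(b) P(b + t) / P(b), and p0 is
  # w(b) P(b) / norm, so the survivor area is an integral of w(b) P(b + t):
  # split the weight at the discontinuity b = d so each piece is smooth
  b_all <- g$ages
  b_young <- seq(0, d, length.out = grid_points)
  vapply(t, function(tt) {
    area <- (lab$e2 * (1 - lab$e1) * trap(b_all, survival_to_age(model, b_all + tt)) +
             lab$e2 * lab$e1 * trap(b_young, survival_to_age(model, b_young + tt))) /
      g$norm
    # cells born labelled at times u in (0, t], aged t - u now: product
    # integration — the residual-label decay 2^(-u/b_half) is integrated
    # exactly on each interval so that half-lives far below the grid
    # spacing are still resolved
    if (tt > 0) {
      u <- seq(0, tt, length.out = grid_points)
      smooth <- lab$e2 * birth_dens * survival_to_age(model, tt - u)
      wexp <- (lab$b_half / log(2)) * (-diff(2^(-u / lab$b_half)))
      area <- area + sum(wexp * (smooth[-1L] + smooth[-length(smooth)]) / 2)
    }
    area
  }, numeric(1L))
}

# Explicit upwind finite-difference solution of the cohort transport
# equation, kept as an independent numerical cross-check of the
# method-of-characteristics solution in cohort_curve(). First-order upwind
# in age at CFL number 1 (unit-speed ageing makes the advection step an
# exact shift, so the scheme's error is the Euler treatment of the
# senescent-hazard sink, not numerical diffusion).
cohort_curve_fd <- function(model, lab, t_max, grid_points = 1000L,
                            n_out = 25L) {
  g <- curve_grid(model, grid_points)
  a <- g$ages
  h <- a[2L] - a[1L]
  dt <- h
  # senescent hazard h(a) = L(a) / Pr(lifespan > a), evaluated midway along
  # each advection step and applied as an exponential decay factor; capped
  # where the survival function underflows in the far tail
  mid <- a - h / 2
  S <- law_survival(model$law, pmax(mid, 0))
  haz <- ifelse(S > 1e-12,
                law_density(model$law, pmax(mid, 0)) / pmax(S, 1e-12), 0)
  haz <- pmin(haz, 2 / dt)
  decay <- exp(-dt * (haz + model$r))
  # initial condition with the labelling-weight jump at age d averaged over
  # each grid cell (node sampling would misplace up to h/2 of the cohort)
  frac_below <- pmin(pmax((lab$d - (a - h / 2)) / h, 0), 1)
  w0 <- lab$e2 * (frac_below + (1 - frac_below) * (1 - lab$e1))
  p <- w0 * g$P / g$norm
  birth_dens <- 1 / g$norm
  t_out <- seq(0, t_max, length.out = n_out)
  areas <- numeric(n_out)
  area_of <- function(p) h * sum((p[-1L] + p[-length(p)]) / 2)
  areas[1L] <- area_of(p)
  tt <- 0
  k <- 2L
  area_prev <- areas[1L]
  n_steps <- ceiling(t_max / dt)
  for (i in seq_len(n_steps)) {
    # boundary cell: labelled births over [tt, tt + dt], with the residual
    # label decay averaged exactly over the step
    born <- lab$e2 * birth_dens * (lab$b_half / (log(2) * dt)) *
      (2^(-tt / lab$b_half) - 2^(-(tt + dt) / lab$b_half))
    p <- c(born, p[-length(p)]) * decay
    area_new <- area_of(p)
    # output times rarely coincide with step times: interpolate linearly
    while (k <= n_out && t_out[k] <= tt + dt + 1e-9) {
      areas[k] <- area_prev + (area_new - area_prev) *
        min((t_out[k] - tt) / dt, 1)
      k <- k + 1L
    }
    tt <- tt + dt
    area_prev <- area_new
  }
  list(t = t_out, cohort = areas)
}
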