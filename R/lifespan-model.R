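#' Competing-fates lifespan model
#'
#' Combines an age-dependent natural (senescent) lifespan law with
#' age-independent random loss at a constant first-order rate `r` (per hour).
#' A cell born at age 0 dies at the minimum of its natural lifespan, drawn
#' from `law`, and an exponential random-loss time with rate `r`. Three named
#' special cases are distinguished:
#'
#' * **LS** (lognormal-senescent): lognormal law, `r = 0`;
#' * **Dornhorst**: fixed lifespan `T` ([delta_law()]), any `r`;
#' * **DLS**: lognormal law with `r > 0` (reduces exactly to LS at `r = 0`).
#'
#' @param law A [lognormal_law()] or [delta_law()].
#' @param r Random-loss (consumption/destruction) rate constant, per hour,
#'   >= 0. Default 0.
#' @return An object of class `lifespan_model`.
#' @examples
#' m <- lifespan_model(lognormal_from_moments(100, 25), r = 0.004)
#' model_kind(m)
#' random_loss_fraction(m)
#' @export
lifespan_model <- function(law, r = 0) {
  stopifnot(inherits(law, "lifespan_law"))
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0)
    stop("`r` must be a single non-negative number", call. = FALSE)
  structure(list(law = law, r = r), class = "lifespan_model")
}

#' @rdname lifespan_model
#' @param model A `lifespan_model`.
#' @return `model_kind()` returns `"LS"`, `"DORNHORST"` or `"DLS"`.
#' @export
model_kind <- function(model) {
  stopifnot(inherits(model, "lifespan_model"))
  if (inherits(model$law, "delta_law")) return("DORNHORST")
  if (model$r > 0) "DLS" else "LS"
}

#' @export
print.lifespan_model <- function(x, ...) {
  cat(sprintf("%s lifespan model\n", model_kind(x)))
  print(x$law)
  cat(sprintf("  random loss rate constant r = %.4g hr^-1 (f = %.3f)\n",
              x$r, random_loss_fraction(x)))
  invisible(x)
}

#' Probability of surviving to a given age
#'
#' P(a) = exp(-r a) * Pr(natural lifespan > a): a cell reaches age `a` only
#' if it has neither exhausted its natural lifespan nor been randomly lost.
#' With `r = 0` this is the plain lifespan survival function.
#'
#' @param model A [lifespan_model()].
#' @param a Age(s) in hours, >= 0. Vectorised.
#' @return Survival probabilities in \[0, 1\], nonincreasing in `a`.
#' @export
survival_to_age <- function(model, a) {
  stopifnot(inherits(model, "lifespan_model"))
  if (any(!is.finite(a)) || any(a < 0))
    stop("ages must be finite and non-negative", call. = FALSE)
  exp(-model$r * a) * law_survival(model$law, a)
}

# Quadrature grid shared by the steady-state curve computations: uniform
# composite trapezoid over [0, amax], amax = exp(m + 4 s) (lognormal) or T
# (delta law). `tail` is the right-tail integral of P from each node to amax,
# so tail[1] is the normalisation constant (f/r for r > 0, mu for r = 0).
curve_grid <- function(model, grid_points = 1000L) {
  if (grid_points < 10L) stop("grid_points must be at least 10", call. = FALSE)
  ages <- seq(0, law_amax(model$law), length.out = grid_points)
  P <- survival_to_age(model, ages)
  if (inherits(model$law, "delta_law")) {
    # P is exp(-r a) truncated at T: integrate the tail in closed form to
    # avoid the O(h) loss at the jump
    r <- model$r
    T <- model$law$T
    tail <- if (r > 0) (exp(-r * ages) - exp(-r * T)) / r else T - ages
  } else {
    h <- ages[2L] - ages[1L]
    # reverse cumulative trapezoid
    seg <- h * (P[-1L] + P[-grid_points]) / 2
    tail <- c(rev(cumsum(rev(seg))), 0)
  }
  list(ages = ages, P = P, tail = tail, norm = tail[1L])
}

#' Steady-state age density of the population
#'
#' At steady state the density of cell ages in the circulating population is
#' proportional to the probability of surviving to that age:
#' p(a) = P(a) / integral of P. The normalisation constant equals f/r when
#' r > 0 and the mean natural lifespan when r = 0.
#'
#' @inheritParams survival_to_age
#' @param grid_points Number of quadrature nodes for the normalising
#'   integral (default 1000).
#' @return Density values (per hour), vectorised over `a`.
#' @export
steady_age_density <- function(model, a, grid_points = 1000L) {
  g <- curve_grid(model, grid_points)
  survival_to_age(model, a) / g$norm
}

#' Population survival curve D(t)
#'
#' Fraction of the cells present (and labelled) at time 0 that are still
#' present at time `t`: D(t) = \[integral of P from t to Inf\] /
#' \[integral of P from 0 to Inf\]. D(0) = 1, D is nonincreasing and reaches
#' 0 once `t` exceeds the maximum natural lifespan. For the Dornhorst model
#' the closed form (exp(-r t) - exp(-r T)) / (1 - exp(-r T)) is used (with
#' the linear limit 1 - t/T as r -> 0); for lognormal laws the tail integral
#' is evaluated on the quadrature grid and interpolated.
#'
#' @param model A [lifespan_model()].
#' @param t Time(s) since labelling, hours, >= 0. Vectorised.
#' @param grid_points Quadrature nodes (default 1000).
#' @return Values of D(t) in \[0, 1\].
#' @export
population_survival_curve <- function(model, t, grid_points = 1000L) {
  stopifnot(inherits(model, "lifespan_model"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (inherits(model$law, "delta_law")) {
    T <- model$law$T
    r <- model$r
    out <- numeric(length(t))
    inside <- t < T
    if (r * T < 1e-12) {
      out[inside] <- 1 - t[inside] / T
    } else {
      out[inside] <- (exp(-r * t[inside]) - exp(-r * T)) / (-expm1(-r * T))
    }
    return(out)
  }
  g <- curve_grid(model, grid_points)
  D <- stats::approx(g$ages, g$tail / g$norm, xout = pmin(t, max(g$ages)),
                     rule = 2)$y
  D[t >= max(g$ages)] <- 0
  D
}

#' Random loss (consumption) fraction
#'
#' The proportion of cells that are removed by the random, age-independent
#' process before reaching the end of their natural lifespan:
#' f = 1 - E\[exp(-r L)\], where L is the natural lifespan. For the Dornhorst
#' model this has the closed form f = 1 - exp(-r T).
#'
#' @param model A [lifespan_model()].
#' @param method `"closed"` (default) evaluates the expectation directly
#'   (closed form for the delta law, adaptive quadrature of
#'   exp(-r l) L(l) for lognormal laws); `"quadrature"` evaluates the
#'   equivalent integrated-by-parts form r * integral of P(a), which only
#'   needs the survival function and serves as an internal cross-check.
#' @return f in \[0, 1\]; 0 iff `r` = 0.
#' @export
random_loss_fraction <- function(model, method = c("closed", "quadrature")) {
  stopifnot(inherits(model, "lifespan_model"))
  method <- match.arg(method)
  r <- model$r
  if (r == 0) return(0)
  if (method == "quadrature") {
    # f = r * \int_0^inf e^{-ra} Pr(L > a) da; the integrand vanishes beyond
    # the lifespan support (T, or far into the lognormal upper tail)
    upper <- if (inherits(model$law, "delta_law")) model$law$T
             else exp(model$law$m + 8 * model$law$s)
    val <- stats::integrate(function(a) survival_to_age(model, a),
                            lower = 0, upper = upper,
                            rel.tol = 1e-11, subdivisions = 500L)$value
    return(r * val)
  }
  if (inherits(model$law, "delta_law")) return(-expm1(-r * model$law$T))
  law <- model$law
  # finite bounds keep the adaptive rule on the density's support even when
  # s is tiny and the lognormal is nearly a spike
  val <- stats::integrate(function(l) exp(-r * l) * law_density(law, l),
                          lower = exp(law$m - 10 * law$s),
                          upper = exp(law$m + 10 * law$s),
                          rel.tol = 1e-11, subdivisions = 500L)$value
  1 - val
}

#' Steady-state turnover quantities
#'
#' Given a lifespan model and the steady-state platelet count `N`, derives
#' the production rate S (count balance N = S * mean realised lifespan), the
#' absolute random loss rate R = 24 r N (per day; Hanson et al.'s "fixed
#' requirement for platelets" when random loss is hemostatic consumption),
#' the random loss fraction f, and the mean realised lifespan f/r (mean
#' natural lifespan when r = 0). The identity f = R/S holds when both are
#' expressed per day.
#'
#' @param model A [lifespan_model()].
#' @param N Platelet count, in units of 1e3 per microlitre, > 0.
#' @return An object of class `steady_state`: list with `N`, `S` (1e3/uL/hr),
#'   `R` (1e3/uL/day), `f`, `mean_realized_lifespan` (hours).
#' @examples
#' wt <- lifespan_model(lognormal_law(4.45, 0.307))  # LS wild-type
#' steady_state(wt, N = 1183)
#' @export
steady_state <- function(model, N) {
  stopifnot(inherits(model, "lifespan_model"))
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0)
    stop("`N` must be a single positive count", call. = FALSE)
  f <- random_loss_fraction(model)
  mean_realized <- if (model$r > 0) f / model$r else law_mean(model$law)
  S <- N / mean_realized
  structure(list(N = N, S = S, R = 24 * model$r * N, f = f,
                 mean_realized_lifespan = mean_realized),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Steady-state turnover:\n")
  cat(sprintf("  platelet count N        = %.4g x10^3/uL\n", x$N))
  cat(sprintf("  production rate S       = %.4g x10^3/uL/hr (%.4g /day)\n",
              x$S, 24 * x$S))
  cat(sprintf("  random loss rate R      = %.4g x10^3/uL/day\n", x$R))
  cat(sprintf("  random loss fraction f  = %.3f\n", x$f))
  cat(sprintf("  mean realised lifespan  = %.4g hr\n",
              x$mean_realized_lifespan))
  invisible(x)
}

#' Serialise a lifespan model to/from a JSON descriptor
#'
#' The descriptor is `{"model": "LS"|"DORNHORST"|"DLS", ...}` with either
#' log-scale (`m`, `s`) or moment (`mu`, `sigma`) lognormal parameters, or
#' `T` for the Dornhorst model, plus the rate constant `r`.
#'
#' @param model A [lifespan_model()].
#' @return `model_to_json()` returns a JSON string; `model_from_json()`
#'   returns a `lifespan_model`.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "lifespan_model"))
  kind <- model_kind(model)
  x <- if (kind == "DORNHORST") {
    list(model = kind, T = model$law$T, r = model$r)
  } else {
    list(model = kind, m = model$law$m, s = model$law$s, r = model$r)
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' @rdname model_to_json
#' @param json JSON string or path to a JSON file.
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (is.null(x$model)) stop("descriptor lacks a \"model\" field", call. = FALSE)
  r <- if (is.null(x$r)) 0 else as.numeric(x$r)
  kind <- toupper(x$model)
  if (kind == "DORNHORST") {
    if (is.null(x$T)) stop("Dornhorst descriptor needs \"T\"", call. = FALSE)
    return(lifespan_model(delta_law(as.numeric(x$T)), r = r))
  }
  if (!kind %in% c("LS", "DLS"))
    stop("unknown model kind: ", x$model, call. = FALSE)
  law <- if (!is.null(x$m)) {
    lognormal_law(as.numeric(x$m), as.numeric(x$s))
  } else if (!is.null(x$mu)) {
    lognormal_from_moments(as.numeric(x$mu), as.numeric(x$sigma))
  } else stop("lognormal descriptor needs (m, s) or (mu, sigma)", call. = FALSE)
  if (kind == "LS" && r != 0)
    stop("LS descriptor must have r = 0 (use DLS)", call. = FALSE)
  lifespan_model(law, r = r)
}
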