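#' Lognormal natural-lifespan law
#'
#' Constructs a lognormal law for the natural (senescent) lifespan of a cell,
#' parameterised by the mean and standard deviation of log-lifespan. This is
#' the canonical internal parameterisation; use [lognormal_from_moments()] to
#' construct the same law from the arithmetic mean and standard deviation of
#' lifespan in hours.
#'
#' @param m Mean of log-lifespan (log-hours).
#' @param s Standard deviation of log-lifespan (log-hours, > 0).
#' @return An object of class `lognormal_law`.
#' @seealso [delta_law()], [lognormal_from_moments()], [lifespan_model()]
#' @examples
#' law <- lognormal_law(m = 4.45, s = 0.307)
#' lognormal_to_moments(law)
#' @export
lognormal_law <- function(m, s) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("`s` must be a single positive number", call. = FALSE)
  structure(list(m = m, s = s), class = c("lognormal_law", "lifespan_law"))
}

#' Fixed (degenerate) natural-lifespan law
#'
#' All cells die of senescence at exactly age `T` unless removed earlier by
#' random loss. This is the lifespan law of the classic Dornhorst model,
#' originally developed for red-cell survival curves.
#'
#' @param T Fixed natural lifespan (hours, > 0).
#' @return An object of class `delta_law`.
#' @export
delta_law <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("`T` must be a single positive number", call. = FALSE)
  structure(list(T = T), class = c("delta_law", "lifespan_law"))
}

#' Convert between log-scale and arithmetic lifespan moments
#'
#' Lognormal laws are stored as (m, s), the mean and s.d. of log-lifespan, but
#' results tables conventionally also report the arithmetic mean and s.d. of
#' lifespan in hours, (mu, sigma). These helpers apply the standard lognormal
#' moment relations mu = exp(m + s^2/2), sigma^2 = mu^2 (exp(s^2) - 1), and
#' their inverse; the round trip is an identity.
#'
#' @param mu Arithmetic mean lifespan (hours, > 0).
#' @param sigma Arithmetic standard deviation of lifespan (hours, > 0).
#' @return `lognormal_from_moments()` returns a `lognormal_law`;
#'   `lognormal_to_moments()` returns a named numeric vector `c(mu, sigma)`.
#' @examples
#' lognormal_to_moments(lognormal_from_moments(100, 25))
#' @export
lognormal_from_moments <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  s2 <- log1p((sigma / mu)^2)
  lognormal_law(m = log(mu) - s2 / 2, s = sqrt(s2))
}

#' @rdname lognormal_from_moments
#' @param law A `lognormal_law`.
#' @export
lognormal_to_moments <- function(law) {
  stopifnot(inherits(law, "lognormal_law"))
  mu <- exp(law$m + law$s^2 / 2)
  c(mu = mu, sigma = mu * sqrt(expm1(law$s^2)))
}

# Survival function of the natural lifespan, Pr(lifespan > a). Vectorised in a.
law_survival <- function(law, a) UseMethod("law_survival")

#' @export
law_survival.lognormal_law <- function(law, a) {
  stats::plnorm(a, meanlog = law$m, sdlog = law$s, lower.tail = FALSE)
}

#' @export
law_survival.delta_law <- function(law, a) as.numeric(a < law$T)

# Density of the natural lifespan. Undefined (Dirac) for delta_law.
law_density <- function(law, a) UseMethod("law_density")

#' @export
law_density.lognormal_law <- function(law, a) {
  stats::dlnorm(a, meanlog = law$m, sdlog = law$s)
}

# Mean natural lifespan in hours.
law_mean <- function(law) UseMethod("law_mean")

#' @export
law_mean.lognormal_law <- function(law) exp(law$m + law$s^2 / 2)

#' @export
law_mean.delta_law <- function(law) law$T

# Upper end of the integration range: exp(m + 4s) for lognormal laws, T for
# the delta law. Integrals over age/lifespan are truncated here.
law_amax <- function(law) UseMethod("law_amax")

#' @export
law_amax.lognormal_law <- function(law) exp(law$m + 4 * law$s)

#' @export
law_amax.delta_law <- function(law) law$T

#' @export
print.lognormal_law <- function(x, ...) {
  mo <- lognormal_to_moments(x)
  cat(sprintf(
    "Lognormal lifespan law: m = %.4g, s = %.4g (mean %.4g hr, sd %.4g hr)\n",
    x$m, x$s, mo[["mu"]], mo[["sigma"]]))
  invisible(x)
}

#' @export
print.delta_law <- function(x, ...) {
  cat(sprintf("Fixed lifespan law: T = %.4g hr\n", x$T))
  invisible(x)
}
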