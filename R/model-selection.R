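#' F-test for nested least-squares models
#'
#' Tests whether the reduction in the sum of squared residuals achieved by a
#' more complex model justifies its extra parameters:
#' F = ((ssr_null - ssr_alt) / (df_null - df_alt)) / (ssr_alt / df_alt),
#' with the p-value from the upper tail of the F distribution on
#' (df_null - df_alt, df_alt) degrees of freedom. Valid only for nested
#' models — here the LS model (r fixed at 0) and the Dornhorst model
#' (lifespan s.d. fixed at 0) are both special cases of the DLS model.
#'
#' @param ssr_null,ssr_alt Sums of squared residuals of the simpler (null)
#'   and more complex (alternative) fits; requires ssr_null >= ssr_alt.
#' @param df_null,df_alt Degrees of freedom (points minus parameters);
#'   requires df_null > df_alt > 0.
#' @return An object of class `platekin_ftest`: `F`, `p`, `df_num`,
#'   `df_den`, `ssr_null`, `ssr_alt`, and `degenerate` (`TRUE` when
#'   ssr_alt = 0, giving infinite F).
#' @examples
#' f_test(106.7, 57, 95.2, 56)  # F ~ 6.76, p ~ 0.012
#' @export
f_test <- function(ssr_null, df_null, ssr_alt, df_alt) {
  if (!(df_null > df_alt) || !(df_alt > 0))
    stop("nesting requires df_null > df_alt > 0", call. = FALSE)
  if (ssr_null < 0 || ssr_alt < 0)
    stop("sums of squared residuals must be non-negative", call. = FALSE)
  if (ssr_null < ssr_alt)
    stop("ssr_null < ssr_alt: fits are not properly nested ",
         "(the alternative must fit at least as well)", call. = FALSE)
  df_num <- df_null - df_alt
  degenerate <- ssr_alt == 0
  if (degenerate) {
    F <- Inf
    p <- 0
  } else {
    F <- ((ssr_null - ssr_alt) / df_num) / (ssr_alt / df_alt)
    p <- stats::pf(F, df_num, df_alt, lower.tail = FALSE)
  }
  structure(list(F = F, p = p, df_num = df_num, df_den = df_alt,
                 ssr_null = ssr_null, ssr_alt = ssr_alt,
                 degenerate = degenerate),
            class = "platekin_ftest")
}

#' @rdname f_test
#' @param fit_null,fit_alt Fits from [fit_survival()]; the null must be the
#'   simpler model on the same data.
#' @export
compare_fits <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "platekin_fit"), inherits(fit_alt, "platekin_fit"))
  if (fit_null$n_points != fit_alt$n_points)
    stop("fits are not on the same data (point counts differ)", call. = FALSE)
  f_test(fit_null$ssr, fit_null$df, fit_alt$ssr, fit_alt$df)
}

#' @export
print.platekin_ftest <- function(x, ...) {
  cat("Nested-model F-test\n")
  cat(sprintf("  ssr_null = %.4g (df %d), ssr_alt = %.4g (df %d)\n",
              x$ssr_null, x$df_num + x$df_den, x$ssr_alt, x$df_den))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.2g%s\n", x$df_num, x$df_den, x$F,
              x$p, if (x$degenerate) "  [degenerate: ssr_alt = 0]" else ""))
  invisible(x)
}
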