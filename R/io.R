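#' Read and write survival-curve CSV files
#'
#' The on-disk schema is a UTF-8 CSV with header
#' `time_hr,percent,replicate,curve` and dot decimal separators; `curve` is
#' `"population"` or `"cohort"`. Percents slightly outside \[0, 100\] (down
#' to -10 / up to 110) are accepted with a warning — replicate noise can
#' legitimately take a near-zero measurement negative — and anything beyond
#' that band is a hard error. Malformed rows are reported with their line
#' numbers.
#'
#' @param path File path.
#' @param platelet_count,count_sem Optional platelet count (1e3/uL) and its
#'   s.e.m. attached to the returned dataset.
#' @param label Free-text label attached to the returned dataset.
#' @return `read_survival_csv()` returns a [survival_dataset()];
#'   `write_survival_csv()` returns `path` invisibly.
#' @export
read_survival_csv <- function(path, platelet_count = NA_real_,
                              count_sem = NA_real_, label = "") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("time_hr", "percent", "replicate", "curve")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  t <- suppressWarnings(as.numeric(raw$time_hr))
  p <- suppressWarnings(as.numeric(raw$percent))
  bad <- which(is.na(t) | is.na(p))
  if (length(bad))
    stop("non-numeric time_hr/percent at line(s) ",
         paste(line[bad], collapse = ", "), " of ", path, call. = FALSE)
  bad <- which(!raw$curve %in% c("population", "cohort"))
  if (length(bad))
    stop("invalid curve value at line(s) ", paste(line[bad], collapse = ", "),
         " of ", path, call. = FALSE)
  bad <- which(p < -10 | p > 110)
  if (length(bad))
    stop("percent outside [-10, 110] at line(s) ",
         paste(line[bad], collapse = ", "), " of ", path, call. = FALSE)
  soft <- which(p < 0 | p > 100)
  if (length(soft))
    warning(length(soft), " percent value(s) outside [0, 100] in ", path,
            " (line(s) ", paste(utils::head(line[soft], 5L), collapse = ", "),
            if (length(soft) > 5L) ", ..." else "", ")", call. = FALSE)
  survival_dataset(
    data.frame(time_hr = t, percent = p, replicate = raw$replicate,
               curve = raw$curve),
    platelet_count = platelet_count, count_sem = count_sem, label = label)
}

#' @rdname read_survival_csv
#' @param dataset A [survival_dataset()].
#' @export
write_survival_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "survival_dataset"))
  utils::write.csv(dataset$observations, path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# `value [lo,hi]` cell, as results tables conventionally print parameters
# with Monte Carlo confidence intervals
format_ci <- function(value, lo = NA, hi = NA, digits = 3) {
  v <- signif(value, digits)
  if (is.na(lo)) return(format(v))
  sprintf("%s [%s,%s]", format(v), format(signif(lo, digits)),
          format(signif(hi, digits)))
}

#' Render a fit (with optional ensemble and F-test) as a report
#'
#' Produces a parameter table with one `value [lo,hi]` row per parameter —
#' confidence bounds being the 2.5/97.5 Monte Carlo percentiles when an
#' ensemble is supplied — plus, when available, the steady-state turnover
#' quantities and a nested-model F-test row. The `json` element mirrors the
#' report in machine-readable form.
#'
#' @param fit A [fit_survival()] result.
#' @param ensemble Optional [monte_carlo()] ensemble for the same fit.
#' @param ftest Optional [f_test()] result.
#' @return An object of class `platekin_report`; `print()`ing it writes the
#'   human-readable table, and `$json` is the machine-readable mirror.
#' @export
report <- function(fit, ensemble = NULL, ftest = NULL) {
  stopifnot(inherits(fit, "platekin_fit"))
  ci <- function(par) {
    if (is.null(ensemble) || !par %in% colnames(ensemble$percentiles))
      return(c(NA_real_, NA_real_))
    ensemble$percentiles[c("2.5%", "97.5%"), par]
  }
  pars <- c(names(fit$par), "mu", "sigma", "f",
            if (!is.na(fit$platelet_count)) c("S", "R"))
  pars <- unique(pars)
  row <- ensemble_row(fit, fit$platelet_count)
  tab <- do.call(rbind, lapply(pars, function(nm) {
    if (is.null(row[[nm]]) || is.na(row[[nm]])) return(NULL)
    b <- ci(nm)
    data.frame(parameter = nm, value = row[[nm]], ci_lower = b[1L],
               ci_upper = b[2L],
               formatted = format_ci(row[[nm]], b[1L], b[2L]))
  }))
  rownames(tab) <- NULL
  js <- list(
    model = fit$kind,
    label = fit$label,
    n_points = fit$n_points, n_params = fit$n_params, df = fit$df,
    ssr = fit$ssr,
    parameters = stats::setNames(as.list(tab$value), tab$parameter),
    ci = if (!is.null(ensemble))
      stats::setNames(lapply(seq_len(nrow(tab)),
                             function(i) c(tab$ci_lower[i], tab$ci_upper[i])),
                      tab$parameter))
  if (!is.null(ftest))
    js$f_test <- list(F = ftest$F, p = ftest$p, df_num = ftest$df_num,
                      df_den = ftest$df_den, ssr_null = ftest$ssr_null,
                      ssr_alt = ftest$ssr_alt)
  structure(list(fit = fit, table = tab, ftest = ftest, json = js),
            class = "platekin_report")
}

#' @export
print.platekin_report <- function(x, ...) {
  f <- x$fit
  cat(sprintf("%s model%s  (%d points, %d parameters, df = %d, ssr = %.4g)\n",
              f$kind,
              if (nzchar(f$label)) paste0(" [", f$label, "]") else "",
              f$n_points, f$n_params, f$df, f$ssr))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %-7s %s\n", x$table$parameter[i], x$table$formatted[i]))
  if (!is.null(x$ftest)) {
    ft <- x$ftest
    cat(sprintf(
      "  F-test vs null: ssr_null %.4g (df %d), ssr_alt %.4g (df %d), F = %.2f, p = %.2g\n",
      ft$ssr_null, ft$df_num + ft$df_den, ft$ssr_alt, ft$df_den, ft$F,
      signif(ft$p, 2)))
  }
  invisible(x)
}

#' Write a report to a JSON file
#'
#' @param x A [report()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  stopifnot(inherits(x, "platekin_report"))
  jsonlite::write_json(x$json, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialise a fit to/from JSON
#'
#' Stores the model descriptor, labelling parameters, fit statistics and
#' enough metadata to reuse the fit (e.g. as the centre of a Monte Carlo
#' run) in another session.
#'
#' @param fit A [fit_survival()] result.
#' @param path Output path.
#' @return `fit_to_json()` returns `path` invisibly; `fit_from_json()`
#'   cannot fully reconstruct predictions and therefore returns a
#'   `platekin_fit` whose `predicted` element is rebuilt from the stored
#'   time grid.
#' @export
fit_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "platekin_fit"))
  x <- list(kind = fit$kind, use_cohort = fit$use_cohort,
            par = as.list(fit$par), ssr = fit$ssr, df = fit$df,
            n_params = fit$n_params, n_points = fit$n_points,
            grid_points = fit$grid_points, seed = fit$seed,
            n_starts = fit$n_starts, platelet_count = fit$platelet_count,
            label = fit$label,
            times = stats::setNames(
              lapply(unique(fit$predicted$curve), function(cv)
                fit$predicted$time_hr[fit$predicted$curve == cv]),
              unique(fit$predicted$curve)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname fit_to_json
#' @export
fit_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  par <- unlist(x$par)
  mb <- fit_build(x$kind, par)
  pred <- do.call(rbind, lapply(names(x$times), function(cv) {
    tg <- as.numeric(x$times[[cv]])
    data.frame(time_hr = tg, curve = cv,
               percent_pred = predict_observed(mb$model, mb$lab, tg, cv,
                                               x$grid_points))
  }))
  structure(list(model = mb$model, lab = mb$lab, par = par, ssr = x$ssr,
                 df = x$df, n_params = x$n_params, n_points = x$n_points,
                 predicted = pred, kind = x$kind, use_cohort = x$use_cohort,
                 grid_points = x$grid_points, seed = x$seed,
                 n_starts = x$n_starts,
                 platelet_count = if (is.null(x$platelet_count)) NA_real_
                                  else as.numeric(x$platelet_count),
                 label = if (is.null(x$label)) "" else x$label),
            class = "platekin_fit")
}
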