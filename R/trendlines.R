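# Storage-time trendline modelling. The abundance of a quality-marker
# metabolite as a function of hours of whole-blood storage at 25 degC is
# described by one of three laws: power y = a*x^b, linear y = a*x + b, or
# logarithmic y = a*ln(x) + b.

TRENDLINE_KINDS <- c("linear", "logarithmic", "power")

#' Construct a trendline fit
#'
#' @param kind one of `"linear"`, `"logarithmic"`, `"power"`.
#' @param a,b coefficients: slope/intercept for linear, slope on `ln(x)`
#'   and intercept for logarithmic, scale and exponent for power.
#' @param r2 coefficient of determination in the original y space.
#' @param n_points number of points the fit used.
#' @return An object of class `trendline_fit`.
#' @export
trendline_fit <- function(kind, a, b, r2 = NA_real_, n_points = NA_integer_) {
  kind <- match.arg(kind, TRENDLINE_KINDS)
  stopifnot(is.finite(a), is.finite(b))
  if (is.finite(r2) && r2 > 1 + 1e-12) stop("r2 cannot exceed 1")
  structure(list(kind = kind, a = a, b = b, r2 = r2,
                 n_points = as.integer(n_points)),
            class = "trendline_fit")
}

#' @export
print.trendline_fit <- function(x, ...) {
  eq <- switch(x$kind,
    linear = sprintf("y = %g x + %g", x$a, x$b),
    logarithmic = sprintf("y = %g ln(x) + %g", x$a, x$b),
    power = sprintf("y = %g x^%g", x$a, x$b))
  cat(sprintf("trendline_fit (%s): %s  [R2 = %s, n = %s]\n", x$kind, eq,
              format(x$r2), format(x$n_points)))
  invisible(x)
}

#' Evaluate a trendline at given storage times
#'
#' @param fit a [trendline_fit()].
#' @param hours storage time(s) at 25 degC, in hours; must be positive for
#'   the power and logarithmic kinds.
#' @return Predicted abundance(s).
#' @export
evaluate_trendline <- function(fit, hours) {
  if (fit$kind %in% c("logarithmic", "power") && any(hours <= 0)) {
    stop("hours must be > 0 for the ", fit$kind, " trendline")
  }
  switch(fit$kind,
    linear = fit$a * hours + fit$b,
    logarithmic = fit$a * log(hours) + fit$b,
    power = fit$a * hours^fit$b)
}

#' Fit one trendline kind by least squares
#'
#' The linear kind is an ordinary least-squares fit of `y ~ x`; the
#' logarithmic kind of `y ~ ln(x)`; the power kind is fitted in log-log
#' space (`ln(y) ~ ln(x)`) and back-transformed. In every case the reported
#' R-squared is `1 - SSres/SStot` computed in the ORIGINAL y space, so the
#' three kinds are comparable. Points inadmissible for the kind
#' (nonpositive x for power/logarithmic, nonpositive y for power) are
#' excluded with a warning; at least three admissible points are required
#' (two for the linear kind).
#'
#' @param hours,nla numeric vectors of equal length: storage times (h) and
#'   normalized abundances.
#' @param kind one of `"linear"`, `"logarithmic"`, `"power"`.
#' @return A [trendline_fit()].
#' @export
fit_trendline <- function(hours, nla, kind = c("linear", "logarithmic",
                                               "power")) {
  kind <- match.arg(kind)
  if (length(hours) != length(nla)) stop("hours and nla differ in length")
  keep <- is.finite(hours) & is.finite(nla)
  if (kind %in% c("logarithmic", "power")) keep <- keep & hours > 0
  if (kind == "power") keep <- keep & nla > 0
  if (sum(!keep & is.finite(hours) & is.finite(nla)) > 0L) {
    warning(sprintf("%d point(s) inadmissible for the %s trendline excluded",
                    sum(!keep & is.finite(hours) & is.finite(nla)), kind))
  }
  x <- hours[keep]
  y <- nla[keep]
  min_n <- if (kind == "linear") 2L else 3L
  if (length(x) < min_n) {
    stop("too few admissible points (", length(x), ") for a ", kind, " fit")
  }
  cf <- switch(kind,
    linear = stats::coef(stats::lm(y ~ x)),
    logarithmic = stats::coef(stats::lm(y ~ log(x))),
    power = stats::coef(stats::lm(log(y) ~ log(x))))
  if (kind == "power") {
    a <- exp(unname(cf[1L])); b <- unname(cf[2L])
  } else {
    a <- unname(cf[2L]); b <- unname(cf[1L])
  }
  fit <- trendline_fit(kind, a, b, n_points = length(x))
  yhat <- evaluate_trendline(fit, x)
  ssres <- sum((y - yhat)^2)
  sstot <- sum((y - mean(y))^2)
  fit$r2 <- if (sstot > 0) 1 - ssres / sstot
            else if (ssres <= .Machine$double.eps) 1 else 0
  fit
}

#' Select the best-fitting trendline kind
#'
#' Fits every admissible kind and returns the one with the highest
#' R-squared (original y space); near-exact ties are broken in the order
#' linear < logarithmic < power.
#'
#' @inheritParams fit_trendline
#' @return A [trendline_fit()].
#' @export
select_trendline <- function(hours, nla) {
  fits <- list()
  for (kind in TRENDLINE_KINDS) {
    fits[[kind]] <- tryCatch(
      suppressWarnings(fit_trendline(hours, nla, kind)),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no trendline kind is admissible for these points")
  r2 <- vapply(fits, `[[`, numeric(1L), "r2")
  best <- max(r2)
  fits[[which(r2 >= best - 1e-12)[1L]]]  # list order = preference order
}
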