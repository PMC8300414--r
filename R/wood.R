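#' Wood lactation-curve parameters
#'
#' Constructs and validates the parameter triple of Wood's gamma-type
#' lactation model \eqn{y = a \, x^{b} e^{-c x}}, where \eqn{x} is days in
#' milk and \eqn{y} the trait value on the test day (kg/day for milk yield,
#' percent for fat/protein/lactose, mg/L for milk urea).
#'
#' @param a Scale parameter, in trait units; must be strictly positive.
#' @param b Dimensionless slope of the increasing (pre-peak) phase. May be
#'   negative (monotone decreasing curve); must exceed \eqn{-1} for a
#'   cumulative integral from day 0 to exist.
#' @param c Per-day slope of the decreasing phase. Negative values are valid
#'   and describe a curve still rising at the end of the window.
#' @param trait Optional trait label carried as metadata (e.g. \code{"milk"}).
#'
#' @return An object of class \code{wood_params}: a named list with elements
#'   \code{a}, \code{b}, \code{c} and attribute \code{trait}.
#'
#' @examples
#' wood_params(13.7833, 0.3056, 0.0029, trait = "milk")
#' @export
wood_params <- function(a, b, c, trait = "milk") {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive finite number", call. = FALSE)
  for (nm in c("b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c)),
            trait = as.character(trait)[1L], class = "wood_params")
}

as_wood_params <- function(x) {
  if (inherits(x, "wood_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    nm <- names(x)
    if (!is.null(nm) && all(c("a", "b", "c") %in% nm))
      return(wood_params(x[["a"]], x[["b"]], x[["c"]]))
    return(wood_params(x[[1L]], x[[2L]], x[[3L]]))
  }
  stop("cannot interpret 'params' as Wood parameters (a, b, c)", call. = FALSE)
}

#' @export
print.wood_params <- function(x, digits = 6, ...) {
  cat(sprintf("Wood lactation curve (trait: %s)\n", attr(x, "trait") %||% "?"))
  cat(sprintf("  a = %.*g, b = %.*g, c = %.*g\n",
              digits, x$a, digits, x$b, digits, x$c))
  pk <- wood_peak(x)
  if (pk$exists)
    cat(sprintf("  peak: day %.1f (~day %d), value %.*g\n",
                pk$peak_day, pk$peak_day_int, digits, pk$peak_value))
  else
    cat("  no interior peak (curve monotone over day > 0)\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a Wood lactation curve
#'
#' Daily trait value \eqn{a \, x^{b} e^{-c x}} at the given days in milk.
#'
#' @param params A \code{\link{wood_params}} object (or numeric vector
#'   \code{c(a, b, c)}).
#' @param day Days in milk; vectorised. Must be \eqn{> 0}, except that
#'   \code{day = 0} is accepted when \eqn{b \ge 0} (the curve's limit there
#'   is 0 for \eqn{b > 0} and \eqn{a} for \eqn{b = 0}).
#'
#' @return Numeric vector of trait values (finite and positive for
#'   \code{day > 0}).
#'
#' @examples
#' p <- wood_params(13.7833, 0.3056, 0.0029)
#' wood_eval(p, c(10, 105, 305))
#' @export
wood_eval <- function(params, day) {
  p <- as_wood_params(params)
  if (!is.numeric(day) || any(!is.finite(day)))
    stop("'day' must be finite numeric", call. = FALSE)
  if (any(day < 0))
    stop("'day' must be non-negative (days in milk)", call. = FALSE)
  if (any(day == 0) && p$b < 0)
    stop("day = 0 is outside the curve's domain when b < 0", call. = FALSE)
  # x^b at x = 0: limit is 0 for b > 0, 1 for b = 0 (R's 0^0 convention)
  p$a * day^p$b * exp(-p$c * day)
}

#' Peak coordinates of a Wood curve
#'
#' An interior maximum exists iff \eqn{b > 0} and \eqn{c > 0}, at day
#' \eqn{b/c} with value \eqn{a (b/c)^b e^{-b}}; otherwise the curve is
#' monotone over \code{day > 0}.
#'
#' @inheritParams wood_eval
#' @return A list of class \code{wood_peak} with \code{exists},
#'   \code{peak_day} (real-valued), \code{peak_day_int} (rounded to the
#'   nearest whole day, for display) and \code{peak_value} (\code{NA} when no
#'   interior peak exists).
#'
#' @examples
#' wood_peak(wood_params(13.7833, 0.3056, 0.0029))   # ~day 105, ~42.1 kg
#' wood_peak(wood_params(15.0170, 0.2425, -0.0013))  # monotone: no peak
#' @export
wood_peak <- function(params) {
  p <- as_wood_params(params)
  if (p$b > 0 && p$c > 0) {
    d <- p$b / p$c
    out <- list(exists = TRUE, peak_day = d,
                peak_day_int = as.integer(round(d)),
                peak_value = p$a * d^p$b * exp(-p$b))
  } else {
    out <- list(exists = FALSE, peak_day = NA_real_,
                peak_day_int = NA_integer_, peak_value = NA_real_)
  }
  class(out) <- "wood_peak"
  out
}

#' @export
print.wood_peak <- function(x, ...) {
  if (x$exists)
    cat(sprintf("Lactation peak: day %.2f (day %d), value %.3f\n",
                x$peak_day, x$peak_day_int, x$peak_value))
  else
    cat("No interior lactation peak (monotone curve)\n")
  invisible(x)
}

#' Cumulative yield under a Wood curve
#'
#' The definite integral \eqn{\int_{t_0}^{t_1} a x^{b} e^{-c x}\,dx},
#' i.e. the total trait production over a lactation interval (kg for milk).
#' For \eqn{c > 0} the closed form via the lower incomplete gamma function
#' \eqn{a c^{-(b+1)} [\gamma(b+1, c t_1) - \gamma(b+1, c t_0)]} is used; for
#' \eqn{c \le 0} the integral is computed by adaptive quadrature (absolute
#' tolerance 1e-6). Both routes agree where both apply.
#'
#' @inheritParams wood_eval
#' @param t0,t1 Interval bounds in days, \code{0 <= t0 <= t1}. Starting at
#'   calving (\code{t0 = 0}) requires \eqn{b > -1} (integrability at the
#'   origin).
#' @param method \code{"auto"} (closed form when \code{c > 0}, quadrature
#'   otherwise), \code{"gamma"} (force closed form; errors when \code{c <= 0})
#'   or \code{"quadrature"}.
#'
#' @return A single numeric: yield in trait-units times days (kg of milk).
#'
#' @examples
#' p <- wood_params(13.7833, 0.3056, 0.0029)
#' wood_cumulative(p, 0, 305)            # full-lactation milk yield
#' wood_cumulative(p, 100, 200)          # mid-lactation phase
#' @export
wood_cumulative <- function(params, t0, t1,
                            method = c("auto", "gamma", "quadrature")) {
  p <- as_wood_params(params)
  method <- match.arg(method)
  if (!is.numeric(t0) || !is.numeric(t1) || length(t0) != 1L ||
      length(t1) != 1L || !is.finite(t0) || !is.finite(t1))
    stop("'t0' and 't1' must be single finite numbers", call. = FALSE)
  if (t0 < 0) stop("'t0' must be >= 0", call. = FALSE)
  if (t1 < t0) stop("'t1' must be >= 't0'", call. = FALSE)
  if (t0 == 0 && p$b <= -1)
    stop("integral from day 0 diverges for b <= -1", call. = FALSE)
  if (t1 == t0) return(0)
  if (method == "gamma" && p$c <= 0)
    stop("closed incomplete-gamma form requires c > 0", call. = FALSE)
  use_gamma <- (method == "gamma") || (method == "auto" && p$c > 0)
  if (use_gamma) {
    s <- p$b + 1
    # lower incomplete gamma(s, x) = pgamma(x, s) * gamma(s)
    p$a * p$c^(-s) * gamma(s) *
      (stats::pgamma(p$c * t1, s) - stats::pgamma(p$c * t0, s))
  } else {
    stats::integrate(function(x) p$a * x^p$b * exp(-p$c * x),
                     lower = t0, upper = t1,
                     abs.tol = 1e-6, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }
}

#' Phase shares of total lactation yield
#'
#' Splits the cumulative yield over \code{[0, total_day]} at the given
#' breakpoints (e.g. the 100- and 200-day lines of a 305-day lactation) and
#' returns each phase's share of the total.
#'
#' @inheritParams wood_eval
#' @param breakpoints Strictly increasing days, all in \code{(0, total_day)}.
#' @param total_day Upper end of the lactation window (days).
#'
#' @return Named numeric vector of proportions, one per phase; sums to 1.
#'
#' @examples
#' p <- wood_params(13.7833, 0.3056, 0.0029)
#' phase_shares(p, c(100, 200), 305)
#' @export
phase_shares <- function(params, breakpoints, total_day = 305) {
  p <- as_wood_params(params)
  if (length(breakpoints)) {
    if (any(diff(c(0, breakpoints)) <= 0) || any(breakpoints > total_day))
      stop("'breakpoints' must be strictly increasing and <= 'total_day'",
           call. = FALSE)
  }
  bounds <- unique(c(0, breakpoints, total_day))
  total <- wood_cumulative(p, 0, total_day)
  if (total <= 0) stop("total yield over the window is not positive",
                       call. = FALSE)
  shares <- vapply(seq_len(length(bounds) - 1L), function(i)
    wood_cumulative(p, bounds[i], bounds[i + 1L]) / total, numeric(1))
  names(shares) <- paste0(bounds[-length(bounds)], "-", bounds[-1L], "d")
  shares
}
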