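#' @title Fitting Wood curves to test-day records
#' @name fitting
#' @description Per-herd or per-cow Wood-model fits to monthly test-day
#'   records, on the natural scale by Levenberg-Marquardt least squares
#'   initialised from the classical log-linearisation, or by the
#'   log-linearisation alone.
NULL

# shared pre-flight: pull (day, y) for a trait out of a record table
fit_data <- function(records, trait) {
  if (!is.data.frame(records))
    stop("'records' must be a data frame of test-day records", call. = FALSE)
  if (!all(c("day", trait) %in% names(records)))
    stop(sprintf("records need columns 'day' and '%s'", trait), call. = FALSE)
  d <- data.frame(x = as.numeric(records[["day"]]),
                  y = as.numeric(records[[trait]]))
  d <- d[is.finite(d$x) & is.finite(d$y), , drop = FALSE]
  if (any(d$x <= 0))
    stop("test-day 'day' values must be >= 1", call. = FALSE)
  # canonical ordering: fits are invariant to the records' input order
  d[order(d$x, d$y), , drop = FALSE]
}

new_wood_fit <- function(params, trait, data, rss, method, converged,
                         n_excluded = 0L) {
  structure(list(params = params, trait = trait,
                 window = c(min = min(data$x), max = max(data$x)),
                 n_obs = nrow(data), rss = rss, method = method,
                 converged = converged, n_excluded = n_excluded),
            class = "wood_fit")
}

#' @export
print.wood_fit <- function(x, ...) {
  cat(sprintf("Wood fit (%s, %s): n = %d over days [%g, %g]\n",
              x$trait, x$method, x$n_obs, x$window[1], x$window[2]))
  cat(sprintf("  a = %.4f, b = %.4f, c = %.4f | rss = %.4g | converged: %s\n",
              x$params$a, x$params$b, x$params$c, x$rss, x$converged))
  if (x$n_excluded > 0L)
    cat(sprintf("  (%d non-positive record(s) excluded from log-linear step)\n",
                x$n_excluded))
  invisible(x)
}

#' @export
coef.wood_fit <- function(object, ...) {
  c(a = object$params$a, b = object$params$b, c = object$params$c)
}

#' Log-linear Wood fit
#'
#' Ordinary least squares of \eqn{\ln y} on \eqn{(1, \ln x, -x)}: the
#' classical linearisation of Wood's model, here used both as a fit in its
#' own right and as the initialiser for \code{\link{fit_wood}}. With exactly
#' three distinct days the solve is exact interpolation.
#'
#' @param records Data frame of test-day records with columns \code{day} and
#'   the trait column.
#' @param trait Name of the trait column to fit (default \code{"milk"}).
#' @param on_nonpositive \code{"error"} (default) to reject non-positive
#'   trait values, or \code{"omit"} to drop them (count kept in the fit).
#'
#' @return A \code{wood_fit} object; its \code{rss} is on the original
#'   (not log) scale.
#' @export
fit_loglinear <- function(records, trait = "milk",
                          on_nonpositive = c("error", "omit")) {
  on_nonpositive <- match.arg(on_nonpositive)
  d <- fit_data(records, trait)
  n_bad <- sum(d$y <= 0)
  if (n_bad > 0L) {
    if (on_nonpositive == "error")
      stop(sprintf("%d record(s) with non-positive '%s' values: %s",
                   n_bad, trait,
                   "log-linear fit needs y > 0 (use on_nonpositive = 'omit')"),
           call. = FALSE)
    d <- d[d$y > 0, , drop = FALSE]
  }
  if (length(unique(d$x)) < 3L)
    stop("need records on at least 3 distinct days to fit 3 parameters",
         call. = FALSE)
  fm <- stats::lm(log(y) ~ log(x) + x, data = d)
  cf <- stats::coef(fm)
  params <- wood_params(exp(cf[[1L]]), cf[[2L]], -cf[[3L]], trait = trait)
  rss <- sum((d$y - wood_eval(params, d$x))^2)
  new_wood_fit(params, trait, d, rss, "loglinear", TRUE, n_excluded = n_bad)
}

#' Fit Wood's lactation model to test-day records
#'
#' Nonlinear least squares on the natural scale,
#' \eqn{\min_{a,b,c} \sum_i (y_i - a x_i^b e^{-c x_i})^2}, by
#' Levenberg-Marquardt, started from the log-linear fit. The scale is kept
#' positive by optimising \eqn{\ln a}; \code{b} and \code{c} are
#' unconstrained in sign (truncated lactations still rising at the window's
#' end genuinely yield negative \code{c}). Records with non-positive trait
#' values are dropped from the initialiser but retained for the nonlinear
#' step.
#'
#' @inheritParams fit_loglinear
#' @param method \code{"nls"} (default) or \code{"loglinear"} to stop at the
#'   linearised fit.
#' @param control Passed to \code{\link[minpack.lm]{nls.lm.control}}:
#'   defaults to \code{ftol = 1e-10}, \code{maxiter = 500}.
#'
#' @return A \code{wood_fit}: fitted \code{\link{wood_params}}, data window,
#'   \code{n_obs}, residual sum of squares \code{rss}, \code{method} tag and
#'   \code{converged} flag. The nonlinear fit never reports a higher
#'   \code{rss} than its initialiser.
#'
#' @examples
#' herd <- simulate_herd(herd_sim_config(n_cows = 40, seed = 7))
#' fit_wood(herd$records)
#' @export
fit_wood <- function(records, trait = "milk", method = c("nls", "loglinear"),
                     control = list(ftol = 1e-10, maxiter = 500)) {
  method <- match.arg(method)
  init <- fit_loglinear(records, trait, on_nonpositive = "omit")
  if (method == "loglinear") return(init)

  d <- fit_data(records, trait)  # keep zero-yield records for nls
  start <- list(la = log(init$params$a), b = init$params$b, c = init$params$c)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ exp(la) * x^b * exp(-c * x), data = d,
                      start = start,
                      control = do.call(minpack.lm::nls.lm.control, control)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- new_wood_fit(init$params, trait, d,
                        sum((d$y - wood_eval(init$params, d$x))^2),
                        "nls", FALSE, init$n_excluded)
    warning("nonlinear refinement failed; returning log-linear initialiser",
            call. = FALSE)
    return(out)
  }
  cf <- stats::coef(fit)
  params <- wood_params(exp(cf[["la"]]), cf[["b"]], cf[["c"]], trait = trait)
  rss <- sum(stats::resid(fit)^2)
  init_rss <- sum((d$y - wood_eval(init$params, d$x))^2)
  if (rss > init_rss) {  # LM should never worsen its start; keep the better
    params <- init$params
    rss <- init_rss
  }
  conv <- isTRUE(fit$convInfo$isConv)
  new_wood_fit(params, trait, d, rss, "nls", conv, init$n_excluded)
}

#' Truncated-lactation fit with 305-day projection
#'
#' Fits the Wood model only to records up to \code{max_day} and extends the
#' fitted curve to the standard 305-day window: the in-window area
#' \eqn{\int_0^{max\_day}} is the modelled actual yield, the extrapolated
#' \eqn{\int_0^{305}} the predicted full-lactation yield. This is the
#' machinery behind projecting 305-day yields for cows culled early.
#'
#' @inheritParams fit_wood
#' @param max_day Truncation day: only records with \code{day <= max_day}
#'   enter the fit.
#' @param horizon Projection horizon in days (default 305).
#'
#' @return A \code{wood_fit} with extra elements \code{max_day},
#'   \code{area_window} (yield over \code{[0, max_day]}) and
#'   \code{predicted_305} (yield over \code{[0, horizon]}).
#' @export
fit_truncated <- function(records, trait = "milk", max_day,
                          method = c("nls", "loglinear"), horizon = 305) {
  if (!is.numeric(max_day) || length(max_day) != 1L || max_day <= 0)
    stop("'max_day' must be a single positive day", call. = FALSE)
  keep <- is.finite(records[["day"]]) & records[["day"]] <= max_day
  fit <- fit_wood(records[keep, , drop = FALSE], trait, method)
  fit$max_day <- max_day
  fit$area_window <- tryCatch(wood_cumulative(fit$params, 0, max_day),
                              error = function(e) NA_real_)
  fit$predicted_305 <- tryCatch(wood_cumulative(fit$params, 0, horizon),
                                error = function(e) NA_real_)
  if (!is.finite(fit$predicted_305))
    warning("fitted curve is not integrable from day 0 (b <= -1); ",
            "projection is NA", call. = FALSE)
  class(fit) <- c("wood_fit_truncated", class(fit))
  fit
}

#' @export
print.wood_fit_truncated <- function(x, ...) {
  NextMethod()
  cat(sprintf("  truncated at day %g: area 0-%g = %.2f, predicted 0-305 = %.2f\n",
              x$max_day, x$max_day, x$area_window, x$predicted_305))
  invisible(x)
}

#' Truncation series: projection accuracy by days in milk
#'
#' Refits the herd curve on successively longer windows (the truncation
#' days) and tabulates the fitted parameters, in-window area and projected
#' 305-day yield for each, mirroring the usual accuracy-versus-days-in-milk
#' accounting for a milk-recorded herd.
#'
#' @inheritParams fit_wood
#' @param truncation_days Vector of truncation days (default
#'   \code{c(30, 60, ..., 270, 305)}).
#' @param horizon Projection horizon (default 305).
#'
#' @return Data frame with one row per truncation day: \code{max_day},
#'   \code{a}, \code{b}, \code{c}, \code{n_obs}, \code{area_window},
#'   \code{predicted_305}, \code{converged}.
#' @export
truncation_series <- function(records, trait = "milk",
                              truncation_days = c(seq(30, 270, by = 30), 305),
                              method = c("nls", "loglinear"), horizon = 305) {
  method <- match.arg(method)
  rows <- lapply(truncation_days, function(td) {
    f <- tryCatch(fit_truncated(records, trait, td, method, horizon),
                  error = function(e) NULL)
    if (is.null(f))
      return(data.frame(max_day = td, a = NA_real_, b = NA_real_,
                        c = NA_real_, n_obs = 0L, area_window = NA_real_,
                        predicted_305 = NA_real_, converged = FALSE))
    data.frame(max_day = td, a = f$params$a, b = f$params$b, c = f$params$c,
               n_obs = f$n_obs, area_window = f$area_window,
               predicted_305 = f$predicted_305, converged = f$converged)
  })
  do.call(rbind, rows)
}
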