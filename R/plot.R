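#' Plot Wood lactation curves
#'
#' Draws one fitted curve per group over a day grid, optionally overlaying
#' the test-day records the fit was based on.
#'
#' @param fits Named list of \code{wood_fit} or \code{\link{wood_params}}
#'   objects (one curve per name), or a single such object.
#' @param days Day grid (default \code{1:305}).
#' @param records Optional test-day records to overlay as points (columns
#'   \code{day} and the trait).
#' @param trait Trait column for the overlay and the y-axis label.
#'
#' @return A ggplot object.
#'
#' @examples
#' p <- plot_wood_curves(list(T1 = wood_params(13.7833, 0.3056, 0.0029)))
#' @export
plot_wood_curves <- function(fits, days = 1:305, records = NULL,
                             trait = "milk") {
  if (inherits(fits, c("wood_fit", "wood_params")))
    fits <- stats::setNames(list(fits), "curve")
  s <- sample_curves(fits, days)
  df <- data.frame(day = rep(s$days, length(s$samples)),
                   value = unlist(s$samples, use.names = FALSE),
                   group = rep(s$labels, each = length(s$days)))
  unit <- switch(trait, milk = "kg/day", urea = "mg/L",
                 fat = , protein = , lactose = "%", "")
  g <- ggplot2::ggplot(df, ggplot2::aes(x = day, y = value, colour = group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "days in milk",
                  y = sprintf("%s%s", trait,
                              if (nzchar(unit)) paste0(" (", unit, ")") else ""),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(records) && all(c("day", trait) %in% names(records)))
    g <- g + ggplot2::geom_point(
      data = data.frame(day = records$day, value = records[[trait]]),
      mapping = ggplot2::aes(x = day, y = value),
      inherit.aes = FALSE, alpha = 0.25, size = 0.6)
  g
}

#' Plot a culling-impact report
#'
#' Shows each cohort's fitted curve extended to the horizon, in the spirit
#' of extending culled cows' shortened lactations by their projected
#' curves.
#'
#' @param report A \code{culling_report} built from records (its cohorts
#'   must carry predicted yields).
#' @param horizon Day horizon for the x-axis (default 305).
#'
#' @return A ggplot object (cohort predicted 305-day yields by final day).
#' @export
plot_culling_report <- function(report, horizon = 305) {
  stopifnot(inherits(report, "culling_report"))
  df <- as.data.frame(report$cohorts)
  ggplot2::ggplot(df, ggplot2::aes(x = final_day, y = predicted_305)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = report$herd_actual_305,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = report$herd_counterfactual_305,
                        linetype = "dotted") +
    ggplot2::labs(x = "cohort final milking day",
                  y = "projected 305-day yield (kg)",
                  caption = "dashed: realised herd average; dotted: no-culling counterfactual") +
    ggplot2::theme_minimal()
}
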