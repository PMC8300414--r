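#' Culling cohort table
#'
#' A cohort groups the cows that share a final milking period: cows with k
#' monthly tests form the 0-(30k) cohort, completers the 0-305 cohort. Each
#' row carries the cohort's record and cow counts, its mean realised yield
#' over the truncated window, and its mean projected 305-day yield.
#'
#' @param final_day Cohort upper bounds in days (e.g. 30, 60, ..., 305).
#' @param n_milkings Test-day records per cohort.
#' @param n_cows Cows per cohort; must be positive.
#' @param actual_yield Mean yield (kg) over \code{[0, final_day]}; \code{NA}
#'   allowed for skeletons awaiting fits.
#' @param predicted_305 Mean projected yield (kg) over \code{[0, 305]};
#'   \code{NA} allowed for skeletons.
#'
#' @return Data frame of class \code{culling_cohorts}.
#' @export
culling_cohorts <- function(final_day, n_milkings, n_cows,
                            actual_yield = NA_real_,
                            predicted_305 = NA_real_) {
  df <- data.frame(final_day = as.numeric(final_day),
                   n_milkings = as.integer(n_milkings),
                   n_cows = as.integer(n_cows),
                   actual_yield = as.numeric(actual_yield),
                   predicted_305 = as.numeric(predicted_305))
  if (any(df$n_cows <= 0))
    stop("every cohort must have n_cows > 0", call. = FALSE)
  if (any(df$final_day <= 0))
    stop("'final_day' must be positive", call. = FALSE)
  if (any(duplicated(df$final_day)))
    stop("duplicate cohort 'final_day' values", call. = FALSE)
  if (any(!is.na(df$actual_yield) & df$actual_yield < 0) ||
      any(!is.na(df$predicted_305) & df$predicted_305 < 0))
    stop("yields must be non-negative", call. = FALSE)
  class(df) <- c("culling_cohorts", "data.frame")
  df
}

#' Assign cows to culling cohorts by attended tests
#'
#' Membership follows the count of monthly tests a cow attended: a cow with
#' k tests lands in the 0-(k * period_length) cohort; cows with at least
#' \code{horizon / period_length} tests are completers (0-horizon). This
#' reproduces the bookkeeping in which a cohort's milkings/cows ratio is
#' exactly its test count.
#'
#' @param records Data frame of test-day records (columns \code{cow_id},
#'   \code{day}).
#' @param period_length Days per test period (default 30).
#' @param horizon Lactation horizon (default 305).
#'
#' @return A \code{\link{culling_cohorts}} skeleton (yields \code{NA}),
#'   ordered by \code{final_day}, with attribute \code{"assignment"}: a data
#'   frame of \code{cow_id}, \code{n_tests}, \code{final_day}.
#' @export
assign_cohorts <- function(records, period_length = 30, horizon = 305) {
  if (!all(c("cow_id", "day") %in% names(records)))
    stop("'records' needs columns cow_id and day", call. = FALSE)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (any(records$day < 1 | records$day > horizon))
    stop("records must lie within [1, horizon]", call. = FALSE)
  k <- as.integer(table(records$cow_id)[unique(records$cow_id)])
  assignment <- data.frame(cow_id = unique(records$cow_id), n_tests = k)
  full_k <- horizon %/% period_length
  assignment$final_day <- ifelse(assignment$n_tests >= full_k, horizon,
                                 assignment$n_tests * period_length)
  agg <- stats::aggregate(cbind(n_milkings = n_tests, n_cows = 1) ~ final_day,
                          data = assignment, FUN = sum)
  agg <- agg[order(agg$final_day), , drop = FALSE]
  out <- culling_cohorts(agg$final_day, agg$n_milkings, agg$n_cows)
  attr(out, "assignment") <- assignment
  out
}

#' Counterfactual herd yield without culling
#'
#' The 305-day herd-average yield that would have been realised had no cow
#' been culled: the cow-number-weighted mean of the cohorts' projected
#' 305-day yields.
#'
#' @param cohorts A \code{\link{culling_cohorts}} table with
#'   \code{predicted_305} filled in.
#'
#' @return A single numeric (kg per cow).
#'
#' @examples
#' coh <- herd_t1_cohorts()
#' herd_counterfactual(coh)  # 9798.13 kg
#' @export
herd_counterfactual <- function(cohorts) {
  if (!is.data.frame(cohorts) || nrow(cohorts) == 0L)
    stop("'cohorts' must be a non-empty cohort table", call. = FALSE)
  if (any(is.na(cohorts$predicted_305)))
    stop("all cohorts need a 'predicted_305' value", call. = FALSE)
  if (any(cohorts$n_cows <= 0))
    stop("cohort weights (n_cows) must be positive", call. = FALSE)
  sum(cohorts$n_cows * cohorts$predicted_305) / sum(cohorts$n_cows)
}

#' Per-cow yield gain attributable to culling
#'
#' Difference between the realised herd-average 305-day yield (with culling)
#' and the counterfactual average had culled cows completed their
#' lactations. Positive when culling removed below-average producers;
#' the sign is preserved, so a counterfactual above the realised average
#' yields a negative gain.
#'
#' @param herd_actual_305 Realised herd-average 305-day yield (kg), > 0.
#' @param cohorts A \code{\link{culling_cohorts}} table.
#'
#' @return Gain in kg per cow.
#'
#' @examples
#' culling_gain(11385, herd_t1_cohorts())  # 1586.87 kg
#' @export
culling_gain <- function(herd_actual_305, cohorts) {
  if (!is.numeric(herd_actual_305) || length(herd_actual_305) != 1L ||
      herd_actual_305 <= 0)
    stop("'herd_actual_305' must be a single positive yield", call. = FALSE)
  herd_actual_305 - herd_counterfactual(cohorts)
}

#' Culling decision for one test-day yield
#'
#' Strict "below threshold" rule: a cow is culled iff its observed milk
#' yield at the checked test is below the criterion (default 24 kg); a
#' yield exactly at the threshold is kept.
#'
#' @param milk_at_test Observed milk yield(s), kg; non-negative. Vectorised.
#' @param threshold Culling criterion in kg (default 24).
#'
#' @return Character vector, \code{"cull"} or \code{"keep"} per value.
#' @export
cull_decision <- function(milk_at_test, threshold = 24) {
  if (any(milk_at_test < 0)) stop("milk yield must be >= 0", call. = FALSE)
  ifelse(milk_at_test < threshold, "cull", "keep")
}

#' Build a culling-impact report from test-day records
#'
#' Assigns cows to cohorts, fits a Wood curve to each cohort's pooled
#' (truncated) records, integrates it over the truncated window (actual
#' yield) and over 0-305 (projected yield), and assembles the with/without
#' culling accounting. Cohorts whose data window ends before the curve's
#' identifiable region (all tests pre-peak) borrow the herd-level shape
#' (b, c) from the completer cohort and rescale the scale parameter to the
#' cohort's observed level ("shape-borrowing"); see \code{borrow_max_day}.
#'
#' @param records Test-day records (columns \code{cow_id}, \code{day}, and
#'   the trait column).
#' @param herd_actual_305 Realised herd-average 305-day yield (kg). When
#'   \code{NULL} (simulation use) the completer cohort's projected yield is
#'   used, i.e. the realised average of the cows actually milked to 305 days.
#' @param trait Trait column fitted (default \code{"milk"}).
#' @param period_length,horizon Cohort bookkeeping as in
#'   \code{\link{assign_cohorts}}.
#' @param borrow_max_day Cohorts with \code{final_day <= borrow_max_day}
#'   use shape-borrowing instead of a free fit (default 90: windows that end
#'   before a typical peak cannot identify the post-peak slope). Cohorts
#'   with fewer than 3 distinct test days always borrow.
#' @param method Fit method for free fits, see \code{\link{fit_wood}}.
#'
#' @return An object of class \code{culling_report}: list with
#'   \code{cohorts} (a \code{\link{culling_cohorts}} table with yields),
#'   \code{herd_actual_305}, \code{herd_counterfactual_305},
#'   \code{gain_per_cow} and \code{herd_fit} (the completer-cohort fit).
#'
#' @examples
#' herd <- simulate_herd(herd_sim_config(n_cows = 120, seed = 3))
#' build_culling_report(herd$records)
#' @export
build_culling_report <- function(records, herd_actual_305 = NULL,
                                 trait = "milk", period_length = 30,
                                 horizon = 305, borrow_max_day = 90,
                                 method = "nls") {
  skel <- assign_cohorts(records, period_length, horizon)
  assignment <- attr(skel, "assignment")
  rec_cohort <- assignment$final_day[match(records$cow_id, assignment$cow_id)]

  completer <- records[rec_cohort == horizon, , drop = FALSE]
  herd_pool <- if (nrow(completer) > 0L) completer else records
  herd_fit <- fit_wood(herd_pool, trait, method)

  fit_cohort <- function(final_day) {
    sub <- records[rec_cohort == final_day, , drop = FALSE]
    distinct <- length(unique(sub$day))
    if (final_day <= borrow_max_day || distinct < 3L) {
      # shape-borrowing: herd-level b, c; a rescaled to the cohort's level
      hp <- herd_fit$params
      ratio <- mean(sub[[trait]] / wood_eval(hp, sub$day))
      list(params = wood_params(hp$a * ratio, hp$b, hp$c, trait = trait),
           borrowed = TRUE)
    } else {
      f <- tryCatch(fit_truncated(sub, trait, final_day, method, horizon),
                    error = function(e) NULL)
      if (is.null(f)) {
        warning(sprintf("cohort 0-%g unfittable; excluded", final_day),
                call. = FALSE)
        return(NULL)
      }
      list(params = f$params, borrowed = FALSE)
    }
  }

  rows <- lapply(seq_len(nrow(skel)), function(i) {
    fd <- skel$final_day[i]
    f <- fit_cohort(fd)
    if (is.null(f)) return(NULL)
    data.frame(final_day = fd, n_milkings = skel$n_milkings[i],
               n_cows = skel$n_cows[i],
               actual_yield = wood_cumulative(f$params, 0, fd),
               predicted_305 = wood_cumulative(f$params, 0, horizon),
               borrowed_shape = f$borrowed)
  })
  tab <- do.call(rbind, rows)
  cohorts <- culling_cohorts(tab$final_day, tab$n_milkings, tab$n_cows,
                             tab$actual_yield, tab$predicted_305)
  cohorts$borrowed_shape <- tab$borrowed_shape

  if (is.null(herd_actual_305)) {
    comp <- cohorts[cohorts$final_day == horizon, , drop = FALSE]
    if (nrow(comp) == 0L)
      stop("no completer cohort; supply 'herd_actual_305' explicitly",
           call. = FALSE)
    herd_actual_305 <- comp$predicted_305[1L]
  }
  culling_report_from_cohorts(cohorts, herd_actual_305, herd_fit = herd_fit)
}

#' Assemble a culling report from a precomputed cohort table
#'
#' For cohort tables whose yields were computed elsewhere (e.g. published
#' herd-recording summaries): computes the counterfactual herd yield and
#' the per-cow culling gain without any fitting.
#'
#' @param cohorts A \code{\link{culling_cohorts}} table with yields.
#' @param herd_actual_305 Realised herd-average 305-day yield (kg).
#' @param herd_fit Optional \code{wood_fit} carried along for reference.
#'
#' @return A \code{culling_report}.
#'
#' @examples
#' culling_report_from_cohorts(herd_t1_cohorts(), 11385)
#' @export
culling_report_from_cohorts <- function(cohorts, herd_actual_305,
                                        herd_fit = NULL) {
  cf <- herd_counterfactual(cohorts)
  structure(list(cohorts = cohorts,
                 herd_actual_305 = herd_actual_305,
                 herd_counterfactual_305 = cf,
                 gain_per_cow = herd_actual_305 - cf,
                 herd_fit = herd_fit),
            class = "culling_report")
}

#' @export
print.culling_report <- function(x, ...) {
  cat("Culling-impact report\n")
  cat(sprintf("  cohorts: %d | cows: %d | milkings: %d\n",
              nrow(x$cohorts), sum(x$cohorts$n_cows),
              sum(x$cohorts$n_milkings)))
  cat(sprintf("  realised herd 305-d average (with culling): %10.2f kg\n",
              x$herd_actual_305))
  cat(sprintf("  counterfactual average (no culling):        %10.2f kg\n",
              x$herd_counterfactual_305))
  cat(sprintf("  gain per cow attributable to culling:       %10.2f kg\n",
              x$gain_per_cow))
  invisible(x)
}
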