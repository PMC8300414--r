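#' Configuration for the synthetic herd generator
#'
#' Describes a simulated milk-recorded herd of primiparous cows: a
#' herd-level Wood curve, per-cow heterogeneity around it, a monthly
#' test-day schedule, multiplicative measurement noise, and threshold-based
#' early culling. Defaults emulate a large high-yield herd (628 first
#' lactations, herd curve peaking near day 105 at about 42 kg/day, 24 kg
#' culling criterion applied at the first three monthly tests).
#'
#' @param n_cows Number of cows (default 628).
#' @param herd_params Herd-level \code{\link{wood_params}} for milk yield
#'   (default \code{wood_params(13.7833, 0.3056, 0.0029)}).
#' @param cow_cv Coefficient of variation of the per-cow lognormal
#'   multiplier on the scale parameter \code{a} (default 0.15).
#' @param shape_jitter_sd Relative standard deviation of the additive
#'   normal jitter on each cow's \code{b} and \code{c} (default 0.10, i.e.
#'   10\% of the herd value).
#' @param test_interval Nominal days between monthly tests (default 30).
#' @param interval_jitter Half-width of the uniform jitter on each interval,
#'   in days (default 3).
#' @param first_test Range (min, max) of the uniformly drawn first test day
#'   (default \code{c(5, 35)}).
#' @param noise_cv Multiplicative lognormal residual CV on every record
#'   (default 0.08).
#' @param cull_threshold Milk yield (kg) below which a cow is culled at a
#'   checked test; strict "below" (default 24).
#' @param cull_check_tests Test indices at which the culling rule is applied
#'   (default \code{1:3}, i.e. roughly days 30, 60, 90). Use
#'   \code{integer(0)} to disable culling.
#' @param horizon Lactation horizon in days (default 305).
#' @param trait_params Named list of \code{\link{wood_params}} for
#'   additional traits simulated with the same machinery (defaults sketch
#'   typical fat/protein/lactose percentages and milk urea in mg/L).
#' @param seed Integer seed; the generated herd is a pure function of the
#'   configuration, including the seed.
#'
#' @return A validated list of class \code{herd_sim_config}.
#' @export
herd_sim_config <- function(n_cows = 628,
                            herd_params = wood_params(13.7833, 0.3056, 0.0029),
                            cow_cv = 0.15,
                            shape_jitter_sd = 0.10,
                            test_interval = 30,
                            interval_jitter = 3,
                            first_test = c(5, 35),
                            noise_cv = 0.08,
                            cull_threshold = 24,
                            cull_check_tests = 1:3,
                            horizon = 305,
                            trait_params = list(
                              fat     = wood_params(4.80, -0.120, -0.0006, trait = "fat"),
                              protein = wood_params(3.90, -0.080, -0.0010, trait = "protein"),
                              lactose = wood_params(5.00, -0.010,  0.0001, trait = "lactose"),
                              urea    = wood_params(90.0,  0.250,  0.0025, trait = "urea")),
                            seed = 1L) {
  herd_params <- as_wood_params(herd_params)
  stopifnot(n_cows >= 1, cow_cv >= 0, shape_jitter_sd >= 0,
            test_interval >= 1, interval_jitter >= 0, noise_cv >= 0,
            cull_threshold >= 0, horizon >= 1,
            length(first_test) == 2L, first_test[1] >= 1,
            first_test[2] >= first_test[1])
  if (!is.list(trait_params) ||
      (length(trait_params) && is.null(names(trait_params))))
    stop("'trait_params' must be a named list of wood_params", call. = FALSE)
  trait_params <- lapply(trait_params, as_wood_params)
  structure(list(n_cows = as.integer(n_cows), herd_params = herd_params,
                 cow_cv = cow_cv, shape_jitter_sd = shape_jitter_sd,
                 test_interval = test_interval,
                 interval_jitter = interval_jitter,
                 first_test = first_test, noise_cv = noise_cv,
                 cull_threshold = cull_threshold,
                 cull_check_tests = as.integer(cull_check_tests),
                 horizon = horizon, trait_params = trait_params,
                 seed = as.integer(seed)),
            class = "herd_sim_config")
}

# lognormal multiplier with mean 1 and the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Simulate one cow's lactation records
#'
#' Draws cow-specific Wood parameters around the herd curve, walks the
#' monthly test schedule, applies multiplicative lognormal noise to every
#' record, and stops emitting records (recording the culling day) if the
#' observed milk yield at a checked test falls below the culling threshold.
#'
#' @param config A \code{\link{herd_sim_config}}.
#' @param cow_id Identifier used in the records.
#' @param cow_seed Integer seed for this cow's draws (derived from the
#'   config seed by \code{\link{simulate_herd}}).
#'
#' @return List with \code{records} (data frame: cow_id, herd_id, day, milk
#'   and any configured composition traits) and \code{truth} (one-row data
#'   frame: true parameters, true 0-horizon milk integral, culling status).
#' @export
simulate_cow <- function(config, cow_id = "cow1", cow_seed = config$seed) {
  stopifnot(inherits(config, "herd_sim_config"))
  set.seed(cow_seed)
  hp <- config$herd_params

  draw_cow_params <- function(p) {
    wood_params(p$a * rlnorm_cv(1, config$cow_cv),
                p$b + stats::rnorm(1, 0, config$shape_jitter_sd * abs(p$b)),
                p$c + stats::rnorm(1, 0, config$shape_jitter_sd * abs(p$c)),
                trait = attr(p, "trait"))
  }
  cp <- draw_cow_params(hp)
  tp <- lapply(config$trait_params, draw_cow_params)

  # monthly schedule with uniform jitter; an uninterrupted lactation
  # attends the full count of monthly tests within the horizon, as in
  # routine milk recording where each cohort's milkings/cows ratio is
  # exactly its test count
  n_full <- config$horizon %/% config$test_interval
  first <- max(1L, round(stats::runif(1, config$first_test[1],
                                      config$first_test[2])))
  days <- first
  if (n_full > 1L) {
    for (try in 1:1000) {
      ints <- round(stats::runif(n_full - 1L,
                                 config$test_interval - config$interval_jitter,
                                 config$test_interval + config$interval_jitter))
      if (first + sum(ints) <= config$horizon) break
    }
    days <- first + c(0L, cumsum(as.integer(ints)))
    days <- days[days <= config$horizon]
  }

  milk <- fat <- numeric(0)
  obs <- list()
  cull_day <- NA_integer_
  for (i in seq_along(days)) {
    rec <- c(milk = wood_eval(cp, days[i]) * rlnorm_cv(1, config$noise_cv),
             vapply(tp, function(p)
               wood_eval(p, days[i]) * rlnorm_cv(1, config$noise_cv),
               numeric(1)))
    obs[[i]] <- rec
    if (i %in% config$cull_check_tests &&
        rec[["milk"]] < config$cull_threshold) {
      cull_day <- days[i]
      break
    }
  }
  n_tests <- length(obs)
  records <- data.frame(cow_id = rep(cow_id, n_tests),
                        herd_id = rep("sim", n_tests),
                        day = days[seq_len(n_tests)],
                        do.call(rbind, obs),
                        check.names = FALSE)
  truth <- data.frame(cow_id = cow_id, a = cp$a, b = cp$b, c = cp$c,
                      true_305 = wood_cumulative(cp, 0, config$horizon),
                      culled = !is.na(cull_day), cull_day = cull_day,
                      n_tests = n_tests)
  list(records = records, truth = truth)
}

#' Simulate a milk-recorded herd
#'
#' Generates test-day records for a whole herd by running
#' \code{\link{simulate_cow}} over independent per-cow random streams
#' derived from the configuration seed. Identical configurations produce
#' identical datasets.
#'
#' @param config A \code{\link{herd_sim_config}}.
#'
#' @return An object of class \code{herd_sim}: a list with \code{records}
#'   (all cows' test-day records), \code{truth} (per-cow ground truth for
#'   oracle checks: true parameters, true 0-horizon milk integral, culling
#'   day) and \code{config}.
#'
#' @examples
#' herd <- simulate_herd(herd_sim_config(n_cows = 50, seed = 42))
#' head(herd$records)
#' mean(herd$truth$culled)
#' @export
simulate_herd <- function(config = herd_sim_config()) {
  stopifnot(inherits(config, "herd_sim_config"))
  set.seed(config$seed)
  cow_seeds <- sample.int(.Machine$integer.max, config$n_cows)
  ids <- sprintf("cow%04d", seq_len(config$n_cows))
  sims <- lapply(seq_len(config$n_cows), function(i)
    simulate_cow(config, ids[i], cow_seeds[i]))
  out <- structure(list(records = do.call(rbind, lapply(sims, `[[`, "records")),
                        truth = do.call(rbind, lapply(sims, `[[`, "truth")),
                        config = config),
                   class = "herd_sim")
  rownames(out$records) <- NULL
  rownames(out$truth) <- NULL
  out
}

#' @export
print.herd_sim <- function(x, ...) {
  k <- x$truth$n_tests
  fd <- ifelse(k >= x$config$horizon %/% x$config$test_interval,
               x$config$horizon, k * x$config$test_interval)
  tab <- table(fd)
  cat(sprintf("Simulated herd: %d cows, %d test-day records (seed %d)\n",
              nrow(x$truth), nrow(x$records), x$config$seed))
  cat(sprintf("  culled early: %d (%.1f%%)\n", sum(x$truth$culled),
              100 * mean(x$truth$culled)))
  cat("  cohort sizes (by final milking day):\n")
  for (nm in names(tab)) cat(sprintf("    0-%s: %d cows\n", nm, tab[[nm]]))
  invisible(x)
}
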