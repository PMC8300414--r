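#' Read a test-day record CSV
#'
#' Comma-delimited, UTF-8, "." decimal, with header columns \code{cow_id},
#' \code{herd_id}, \code{day}, \code{milk}; trailing trait columns
#' \code{fat}, \code{protein}, \code{lactose}, \code{urea} optional. Rows
#' violating the record invariants (day outside [1, 400], negative milk,
#' percentages outside [0, 15], urea outside [0, 1000]) are rejected with
#' row-numbered warnings; duplicate (cow_id, day) pairs are an error.
#'
#' @param path File path.
#'
#' @return Validated data frame of test-day records.
#' @export
read_testday_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  mandatory <- c("cow_id", "herd_id", "day", "milk")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)

  traits <- intersect(c("fat", "protein", "lactose", "urea"), names(df))
  num_cols <- c("day", "milk", traits)
  bad_parse <- rep(FALSE, nrow(df))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad_parse <- bad_parse | (is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "")
    df[[cl]] <- v
  }
  ok <- !bad_parse &
    is.finite(df$day) & df$day >= 1 & df$day <= 400 & df$day == round(df$day) &
    is.finite(df$milk) & df$milk >= 0
  for (tr in intersect(c("fat", "protein", "lactose"), traits))
    ok <- ok & (is.na(df[[tr]]) | (df[[tr]] >= 0 & df[[tr]] <= 15))
  if ("urea" %in% traits)
    ok <- ok & (is.na(df$urea) | (df$urea >= 0 & df$urea <= 1000))
  if (any(!ok))
    warning(sprintf("rejected %d invalid row(s): %s", sum(!ok),
                    paste(utils::head(which(!ok), 10L), collapse = ", ")),
            call. = FALSE)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop("no valid records in ", path, call. = FALSE)

  dup <- duplicated(df[c("cow_id", "day")])
  if (any(dup)) {
    d1 <- df[which(dup)[1L], ]
    stop(sprintf("duplicate (cow_id, day) record: (%s, %d)",
                 d1$cow_id, as.integer(d1$day)), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write test-day records as CSV
#'
#' Numeric fields keep full precision, so a write/read round trip
#' reproduces the records.
#'
#' @param records Test-day record data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_testday_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a culling-cohort table
#'
#' Delimited text with five columns: milking period, number of milkings,
#' number of cows, yield in the truncated period, and projected 305-day
#' yield. The period column accepts either a plain final-day integer
#' (e.g. \code{305}) or a range label (\code{"0-305"}, en-dash or hyphen).
#' Thousands separators in yields are tolerated. Rows with a non-positive
#' cow count are rejected.
#'
#' @param path File path.
#'
#' @return A \code{\link{culling_cohorts}} table.
#'
#' @examples
#' path <- system.file("extdata", "herd_t1_culling_cohorts.csv",
#'                     package = "lactwood")
#' read_cohort_table(path)
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(df) < 5L)
    stop("cohort table needs 5 columns (period, milkings, cows, ",
         "actual yield, predicted 305-day yield)", call. = FALSE)
  period <- as.character(df[[1L]])
  # "0-305" / "0–305" / "305" all denote final day 305
  final_day <- suppressWarnings(as.numeric(
    sub("^\\s*0\\s*[-–—]\\s*", "", period)))
  parse_num <- function(v)
    suppressWarnings(as.numeric(gsub("[ ,]", "", as.character(v))))
  n_milkings <- parse_num(df[[2L]])
  n_cows <- parse_num(df[[3L]])
  actual <- parse_num(df[[4L]])
  pred <- parse_num(df[[5L]])
  bad <- !is.finite(final_day) | !is.finite(n_milkings) | !is.finite(n_cows) |
    !is.finite(actual) | !is.finite(pred) | n_cows <= 0
  if (any(bad))
    warning(sprintf("rejected %d cohort row(s): %s", sum(bad),
                    paste(which(bad), collapse = ", ")), call. = FALSE)
  if (all(bad)) stop("no valid cohort rows in ", path, call. = FALSE)
  culling_cohorts(final_day[!bad], n_milkings[!bad], n_cows[!bad],
                  actual[!bad], pred[!bad])
}

#' Write a culling-cohort table as CSV
#'
#' @param cohorts A \code{\link{culling_cohorts}} table.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_table <- function(cohorts, path) {
  utils::write.csv(as.data.frame(cohorts), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Reference truncation fits for the T1 herd
#'
#' Published herd-level Wood fits for a high-yield primiparous Polish
#' Holstein-Friesian herd ("herd T1", 628 first lactations recorded
#' monthly): for each truncation day (30, 60, ..., 305) the fitted
#' parameters, the area under the curve over the truncated window (actual
#' yield, kg) and the projected 0-305-day yield (kg). The 305-day row is
#' the full-lactation fit (a = 13.7833, b = 0.3056, c = 0.0029), peaking
#' near day 105 at about 42.1 kg/day. Parameters are printed to four
#' decimals, so re-integrating them reproduces the yield columns only to
#' within a few percent.
#'
#' @return Data frame with columns \code{max_day}, \code{a}, \code{b},
#'   \code{c}, \code{area_window}, \code{predicted_305}.
#'
#' @examples
#' t1 <- herd_t1_wood_params()
#' wood_peak(wood_params(t1$a[t1$max_day == 305],
#'                       t1$b[t1$max_day == 305],
#'                       t1$c[t1$max_day == 305]))
#' @export
herd_t1_wood_params <- function() {
  utils::read.csv(system.file("extdata", "herd_t1_truncation_fits.csv",
                              package = "lactwood"),
                  stringsAsFactors = FALSE)
}

#' Reference culling cohorts for the T1 herd
#'
#' Published cohort accounting for the same herd as
#' \code{\link{herd_t1_wood_params}}: cows grouped by final milking period
#' (0-30, 0-60, ..., 0-305), with record and cow counts, realised yield
#' over the truncated period and projected 305-day yield. The realised
#' herd-average 305-day yield to compare against is 11,385 kg
#' (\code{\link{herd_t1_actual_yield}}).
#'
#' @return A \code{\link{culling_cohorts}} table (10 cohorts, 628 cows).
#'
#' @examples
#' coh <- herd_t1_cohorts()
#' sum(coh$n_cows)                          # 628
#' herd_counterfactual(coh)                 # 9798.13
#' culling_gain(herd_t1_actual_yield, coh)  # 1586.87
#' @export
herd_t1_cohorts <- function() {
  read_cohort_table(system.file("extdata", "herd_t1_culling_cohorts.csv",
                                package = "lactwood"))
}

#' Realised 305-day herd-average milk yield of the T1 herd (kg)
#'
#' The with-culling realised average used in the culling-gain accounting.
#'
#' @format Single numeric, 11385.
#' @export
herd_t1_actual_yield <- 11385
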