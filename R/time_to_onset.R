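# Time-to-onset: interval between therapy start and event onset, and its
# binned distribution.

TTO_BREAKS <- c(0, 30, 60, 90, 180, 360, Inf)
TTO_LABELS <- c("0-30", "31-60", "61-90", "91-180", "181-360", ">=360")

#' Onset interval in days
#'
#' Calendar-day difference between the event onset date and the therapy
#' start date. Either date missing (including partial dates, which carry no
#' day resolution) gives `NA`.
#'
#' @param event_dt,start_dt `Date` vectors or raw `YYYYMMDD` codes.
#' @return integer vector of day differences (may be negative).
#' @export
onset_days <- function(event_dt, start_dt) {
  if (!inherits(event_dt, "Date")) event_dt <- parse_faers_date(event_dt)
  if (!inherits(start_dt, "Date")) start_dt <- parse_faers_date(start_dt)
  as.integer(event_dt - start_dt)
}

#' Onset intervals for a target-drug cohort
#'
#' Per report: the earliest therapy start date among target drug entries
#' (rows flagged `is_target` by [build_cohort()], or all rows if the flag is
#' absent) against the report's event onset date.
#'
#' @param cohort a `case_data` object.
#' @return integer vector of day differences, one per report (`NA` where
#'   either date is unavailable).
#' @export
cohort_onset_days <- function(cohort) {
  dr <- cohort$drugs
  if (!is.null(dr$is_target)) dr <- dr[dr$is_target, , drop = FALSE]
  dr <- dr[!is.na(dr$start_dt), , drop = FALSE]
  # earliest start date per report
  o <- order(dr$primaryid, dr$start_dt)
  first <- !duplicated(dr$primaryid[o])
  start <- dr$start_dt[o][first]
  names(start) <- dr$primaryid[o][first]
  rep_start <- start[cohort$reports$primaryid]
  onset_days(cohort$reports$event_dt, as.Date(rep_start, origin = "1970-01-01"))
}

#' Binned time-to-onset distribution
#'
#' Bins known non-negative onset intervals into
#' `0-30, 31-60, 61-90, 91-180, 181-360, >=360` days (edges inclusive;
#' day 360 falls in `181-360`, the last bin starts at 361). Negative
#' intervals are data-entry artifacts: excluded from the distribution and
#' counted separately.
#'
#' @param days integer vector of onset intervals (with `NA` for unknown), or
#'   a `case_data` cohort (then [cohort_onset_days()] is applied).
#' @return an object of class `onset_distribution`: `n_known`, `n_missing`,
#'   `n_negative_excluded`, `bins` (data frame `bin`, `n`, `percent` of
#'   known), `mean_days`, `sd_days`.
#' @export
onset_distribution <- function(days) {
  if (inherits(days, "case_data")) days <- cohort_onset_days(days)
  days <- as.numeric(days)
  n_missing <- sum(is.na(days))
  known <- days[!is.na(days)]
  neg <- known < 0
  n_negative <- sum(neg)
  known <- known[!neg]
  n_known <- length(known)
  if (n_known > 0) {
    idx <- findInterval(known, c(TTO_BREAKS[-c(1, length(TTO_BREAKS))] + 0.5),
                        left.open = FALSE) + 1L
    counts <- tabulate(idx, nbins = length(TTO_LABELS))
    pct <- 100 * counts / n_known
  } else {
    counts <- rep(0L, length(TTO_LABELS))
    pct <- rep(0, length(TTO_LABELS))
  }
  structure(list(
    n_known = n_known, n_missing = n_missing,
    n_negative_excluded = n_negative,
    bins = data.frame(bin = TTO_LABELS, n = counts, percent = pct,
                      stringsAsFactors = FALSE),
    mean_days = if (n_known) mean(known) else NA_real_,
    sd_days = if (n_known > 1) stats::sd(known) else NA_real_
  ), class = "onset_distribution")
}

#' @export
print.onset_distribution <- function(x, ...) {
  cat(sprintf("Time to onset: %d known, %d missing, %d negative excluded\n",
              x$n_known, x$n_missing, x$n_negative_excluded))
  if (x$n_known)
    cat(sprintf("  mean %.2f days (SD %.2f)\n", x$mean_days, x$sd_days))
  b <- x$bins
  b$percent <- round_half_up(b$percent, 1)
  print(b, row.names = FALSE)
  invisible(x)
}

#' Export an onset distribution
#'
#' Tab-delimited text with columns `bin`, `n`, `percent`.
#'
#' @param x an `onset_distribution`.
#' @param path file path.
#' @export
write_onset_distribution <- function(x, path) {
  utils::write.table(x$bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
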