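# Descriptive summaries, annual trends and plot-ready exports.

#' Descriptive summary of a report cohort
#'
#' Tabulates counts and percentages per level of sex, age group, weight
#' group, reporting year, SOC, reporter occupation, continent and clinical
#' outcome. Percentages are computed over the full cohort including the
#' `NS` (not-specified) level, so the blocks for report-level variables sum
#' to the cohort size. SOC and outcome blocks count reports, which may
#' carry several SOCs/outcomes each. Level order is fixed for closed
#' vocabularies and count-descending for open ones.
#'
#' @param cohort a `case_data` object.
#' @return an object of class `cohort_summary`: a named list of data frames
#'   (`level`, `n`, `percent`) plus `n_reports` and onset `mean`/`sd` when
#'   onset intervals are computable.
#' @export
summarize_cases <- function(cohort) {
  rp <- cohort$reports
  n <- nrow(rp)
  pct <- function(x) if (n > 0) 100 * x / n else numeric(length(x))

  block <- function(values, levels = NULL) {
    if (is.null(levels)) {
      tb <- sort(table(values), decreasing = TRUE)
    } else {
      tb <- table(factor(values, levels = levels))
    }
    data.frame(level = as.character(if (length(tb)) names(tb) else character(0)),
               n = as.integer(tb),
               percent = pct(as.integer(tb)),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  soc_pairs <- unique(cohort$events[, c("primaryid", "soc")])
  out_pairs <- unique(cohort$outcomes[, c("primaryid", "code")])
  out_pairs$code[!(out_pairs$code %in%
                     c("DE", "DS", "HO", "LT", "CA", "RI", "OT"))] <- "NS"
  # reports with no outcome row at all count as NS
  no_outc <- setdiff(rp$primaryid, out_pairs$primaryid)
  if (length(no_outc))
    out_pairs <- rbind(out_pairs,
                       data.frame(primaryid = no_outc, code = "NS",
                                  stringsAsFactors = FALSE))

  yr <- rp$year
  yr_lab <- ifelse(is.na(yr), "NS", as.character(yr))

  res <- list(
    n_reports = n,
    sex = block(rp$sex, c("F", "M", "NS")),
    age_group = block(rp$age_group, c("<18", "18-44", "45-64", ">=65", "NS")),
    weight_group = block(rp$weight_group, c("<80", ">=80", "NS")),
    year = block(yr_lab, sort(unique(yr_lab))),
    soc = block(soc_pairs$soc),
    reporter = block(ifelse(rp$reporter_code == "", "NS", rp$reporter_code)),
    reporter_group = block(rp$reporter_group,
                           c("consumer-related", "healthcare-professional",
                             "NS")),
    continent = block(rp$continent),
    outcome = block(out_pairs$code, c("DE", "DS", "HO", "LT", "CA", "RI",
                                      "OT", "NS"))
  )
  tto <- tryCatch(cohort_onset_days(cohort), error = function(e) NULL)
  if (!is.null(tto)) {
    known <- tto[!is.na(tto) & tto >= 0]
    if (length(known)) {
      res$onset_mean <- mean(known)
      res$onset_sd <- if (length(known) > 1) stats::sd(known) else NA_real_
    }
  }
  structure(res, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d reports\n", x$n_reports))
  for (nm in c("sex", "age_group", "weight_group", "reporter_group",
               "outcome")) {
    b <- x[[nm]]
    b$percent <- round_half_up(b$percent, 1)
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s %d (%.1f%%)", b$level, b$n, b$percent),
                      collapse = ", ")))
  }
  if (!is.null(x$onset_mean))
    cat(sprintf("  time to onset: mean %.2f d (SD %.2f)\n",
                x$onset_mean, x$onset_sd))
  invisible(x)
}

#' Cumulative reporting trace of the most frequent terms
#'
#' For the `top_k` most frequently reported PTs, the cumulative percentage
#' of that term's reports received by the end of each reporting year. Each
#' trace is non-decreasing and ends at 100.
#'
#' @param cohort a `case_data` object.
#' @param top_k number of terms traced (by total report count).
#' @return data frame with columns `term`, `year`, `n`, `cum_n`,
#'   `cum_percent`.
#' @export
cumulative_trace <- function(cohort, top_k = 10) {
  ev <- cohort$events
  yr <- cohort$reports$year[match(ev$primaryid, cohort$reports$primaryid)]
  ev <- ev[!is.na(yr), , drop = FALSE]
  yr <- yr[!is.na(yr)]
  totals <- sort(table(ev$pt), decreasing = TRUE)
  terms <- names(utils::head(totals, top_k))
  years <- sort(unique(yr))
  rows <- lapply(terms, function(tm) {
    cnt <- table(factor(yr[ev$pt == tm], levels = years))
    cum <- cumsum(as.integer(cnt))
    data.frame(term = tm, year = years, n = as.integer(cnt), cum_n = cum,
               cum_percent = 100 * cum / cum[length(cum)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a descriptive summary as delimited text
#'
#' Long-format tab-delimited export: one row per (variable, level) with
#' count and percentage.
#'
#' @param x a `cohort_summary`.
#' @param path file path.
#' @export
write_cohort_summary <- function(x, path) {
  blocks <- x[vapply(x, is.data.frame, TRUE)]
  long <- do.call(rbind, lapply(names(blocks), function(nm) {
    cbind(variable = nm, blocks[[nm]], stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sensitivity re-analysis excluding an indication subset
#'
#' Re-runs cohort extraction after removing a user-supplied subset of
#' indication PTs from the indication list (e.g. atypical diagnoses), then
#' refits the disproportionality statistics; used to check that specific
#' indication populations do not drive the signals.
#'
#' @param cases the deduplicated `case_data` universe.
#' @param target_drug,role,indication_pts as in [build_cohort()].
#' @param exclude_pts indication PTs to drop.
#' @param level,priors,thresholds passed through to the fit.
#' @return a `disprop` fit on the reduced universe.
#' @export
sensitivity_refit <- function(cases, target_drug, exclude_pts,
                              role = "PS",
                              indication_pts = default_glioma_indication_pts(),
                              level = "PT",
                              priors = bcpnn_priors(),
                              thresholds = signal_thresholds()) {
  keep <- setdiff(toupper(trimws(indication_pts)),
                  toupper(trimws(exclude_pts)))
  if (length(keep) == 0)
    stop_config("excluding these PTs leaves an empty indication set")
  ch <- build_cohort(cases, target_drug, role = role, indication_pts = keep)
  disprop(contingency_tables(ch$cohort, ch$comparator, level = level),
          priors = priors, thresholds = thresholds)
}
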