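# Stratified signal detection and cross-stratum heterogeneity.
#
# Subgroup analyses re-run the disproportionality fit inside strata of a
# demographic variable, with comparator reports matched to the same stratum.
# Heterogeneity of the reporting odds ratio across strata is assessed on the
# 2x2xK array per term: the Mantel-Haenszel common OR (with the CMH test)
# and the Breslow-Day statistic with Tarone's correction on K-1 degrees of
# freedom as the p-interaction.

#' Breslow-Day test of odds-ratio homogeneity (with Tarone correction)
#'
#' Given K fourfold tables for one term, tests whether the stratum odds
#' ratios share a common value. Expected `a` cells under the Mantel-Haenszel
#' common OR are obtained from the usual quadratic; the Tarone term corrects
#' for the MH estimate not being the conditional MLE.
#'
#' @param a,b,c,d numeric vectors of length K (one stratum per element).
#' @return list with `statistic`, `df` (K-1), and `p_value`.
#' @export
breslow_day_test <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  k <- length(a)
  if (k < 2) stop_validation("Breslow-Day needs at least 2 strata")
  n <- a + b + c + d
  or_mh <- sum(a * d / n) / sum(b * c / n)
  if (!is.finite(or_mh) || or_mh <= 0)
    return(list(statistic = NA_real_, df = k - 1, p_value = NA_real_))

  m1 <- a + b   # row margins
  m2 <- c + d
  n1 <- a + c   # event column margin
  e <- numeric(k); v <- numeric(k)
  for (i in seq_len(k)) {
    if (abs(or_mh - 1) < 1e-12) {
      e[i] <- m1[i] * n1[i] / n[i]
    } else {
      A <- 1 - or_mh
      B <- (m1[i] + n1[i]) * or_mh + (m2[i] - n1[i])
      C <- -or_mh * m1[i] * n1[i]
      disc <- B^2 - 4 * A * C
      r1 <- (-B + sqrt(disc)) / (2 * A)
      r2 <- (-B - sqrt(disc)) / (2 * A)
      lo <- max(0, n1[i] - m2[i]); hi <- min(m1[i], n1[i])
      e[i] <- if (r1 >= lo && r1 <= hi) r1 else r2
    }
    v[i] <- 1 / (1 / e[i] + 1 / (m1[i] - e[i]) + 1 / (n1[i] - e[i]) +
                   1 / (m2[i] - n1[i] + e[i]))
  }
  x2 <- sum((a - e)^2 / v)
  x2t <- x2 - sum(a - e)^2 / sum(v)   # Tarone correction
  x2t <- max(x2t, 0)
  list(statistic = x2t, df = k - 1,
       p_value = stats::pchisq(x2t, df = k - 1, lower.tail = FALSE))
}

#' Heterogeneity test across stratum tables for one term
#'
#' Combines the Mantel-Haenszel common odds ratio and CMH association test
#' with the Breslow-Day-Tarone homogeneity p-value (the operational
#' "p-interaction"). Strata with an empty margin are dropped; fewer than two
#' evaluable strata make the test not evaluable.
#'
#' @param a,b,c,d numeric vectors of per-stratum fourfold cells.
#' @return list with `k` (evaluable strata), `cmh_common_or`, `p_cmh`,
#'   `bd_statistic`, `p_homogeneity`.
#' @export
heterogeneity_test <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  a <- a[ok]; b <- b[ok]; c <- c[ok]; d <- d[ok]
  k <- length(a)
  if (k < 2) {
    return(list(k = k, cmh_common_or = NA_real_, p_cmh = NA_real_,
                bd_statistic = NA_real_, p_homogeneity = NA_real_))
  }
  arr <- array(0, dim = c(2, 2, k))
  arr[1, 1, ] <- a; arr[1, 2, ] <- b
  arr[2, 1, ] <- c; arr[2, 2, ] <- d
  mh <- stats::mantelhaen.test(arr, correct = FALSE)
  bd <- breslow_day_test(a, b, c, d)
  list(k = k,
       cmh_common_or = unname(mh$estimate),
       p_cmh = mh$p.value,
       bd_statistic = bd$statistic,
       p_homogeneity = bd$p_value)
}

#' Stratified signal detection with heterogeneity testing
#'
#' Splits cohort and comparator by a stratification variable (comparators
#' are matched to the same stratum), fits [disprop()] within each stratum,
#' excludes unstable strata/terms by the minimum-report rule, and tests
#' cross-stratum heterogeneity per term. The `NS` (missing) stratum is
#' tabulated descriptively but never enters signal listing or heterogeneity
#' tests.
#'
#' @param cohort,comparator `case_data` objects.
#' @param variable one of `"sex"`, `"age_group"`, `"reporter_group"`,
#'   `"weight_group"`.
#' @param min_n minimum report count (default 30): with
#'   `min_n_on = "term"` a term needs at least `min_n` cohort reports of
#'   the event within the stratum to be listed; with
#'   `min_n_on = "stratum"` whole strata below `min_n` cohort reports are
#'   excluded.
#' @param min_n_on `"term"` (default) or `"stratum"`.
#' @param level `"PT"` or `"SOC"`.
#' @param priors,thresholds,zero_correction passed to [disprop()].
#' @return an object of class `stratified_signals`: list with `variable`,
#'   `strata` (per-stratum label, cohort/comparator sizes, status, and
#'   `disprop` fit for retained strata), and `heterogeneity` (data frame
#'   with per-term MH common OR, CMH p, Breslow-Day-Tarone p).
#' @export
stratify_and_detect <- function(cohort, comparator, variable,
                                min_n = 30, min_n_on = c("term", "stratum"),
                                level = "PT",
                                priors = bcpnn_priors(),
                                thresholds = signal_thresholds(),
                                zero_correction = FALSE) {
  min_n_on <- match.arg(min_n_on)
  valid <- c("sex", "age_group", "reporter_group", "weight_group")
  if (!variable %in% valid)
    stop_config("unknown stratification variable '%s' (use one of %s)",
                variable, paste(valid, collapse = ", "))

  g1 <- cohort$reports[[variable]]
  g0 <- comparator$reports[[variable]]
  labels <- sort(unique(c(g1, g0)))
  labels <- c(setdiff(labels, "NS"), intersect("NS", labels))

  strata <- list()
  for (lab in labels) {
    co <- subset_cases(cohort, cohort$reports$primaryid[g1 == lab])
    cp <- subset_cases(comparator, comparator$reports$primaryid[g0 == lab])
    entry <- list(label = lab, n_cohort = n_reports(co),
                  n_comparator = n_reports(cp))
    if (lab == "NS") {
      entry$status <- "descriptive"   # missing stratum: counts only
    } else if (min_n_on == "stratum" && entry$n_cohort < min_n) {
      entry$status <- "excluded"
    } else {
      tabs <- contingency_tables(co, cp, level = level)
      fit <- disprop(tabs, priors = priors, thresholds = thresholds,
                     zero_correction = zero_correction)
      if (min_n_on == "term") {
        drop <- fit$table$a < min_n
        fit$table$excluded <- drop
        fit$table$ror_pos[drop] <- FALSE
        fit$table$prr_pos[drop] <- FALSE
        fit$table$bcpnn_pos[drop] <- FALSE
        fit$table$core[drop] <- FALSE
      } else {
        fit$table$excluded <- FALSE
      }
      entry$status <- "analysed"
      entry$fit <- fit
    }
    strata[[lab]] <- entry
  }

  analysed <- Filter(function(s) identical(s$status, "analysed"), strata)
  het <- NULL
  if (length(analysed) >= 2) {
    terms <- sort(unique(unlist(lapply(analysed, function(s) s$fit$table$term))))
    rows <- lapply(terms, function(tm) {
      cells <- vapply(analysed, function(s) {
        i <- match(tm, s$fit$table$term)
        if (is.na(i)) c(0, s$n_cohort, 0, s$n_comparator) else
          unlist(s$fit$table[i, c("a", "b", "c", "d")], use.names = FALSE)
      }, numeric(4))
      h <- heterogeneity_test(cells[1, ], cells[2, ], cells[3, ], cells[4, ])
      data.frame(term = tm, k = h$k, cmh_common_or = h$cmh_common_or,
                 p_cmh = h$p_cmh, bd_statistic = h$bd_statistic,
                 p_homogeneity = h$p_homogeneity, stringsAsFactors = FALSE)
    })
    het <- do.call(rbind, rows)
    het$heterogeneous <- !is.na(het$p_homogeneity) & het$p_homogeneity < 0.05
  }

  structure(list(variable = variable, min_n = min_n, min_n_on = min_n_on,
                 strata = strata, heterogeneity = het),
            class = "stratified_signals")
}

#' @export
print.stratified_signals <- function(x, ...) {
  cat(sprintf("Stratified signal detection by %s (min_n = %d on %s)\n",
              x$variable, x$min_n, x$min_n_on))
  for (s in x$strata) {
    extra <- if (identical(s$status, "analysed"))
      sprintf(", %d core signals", sum(s$fit$table$core)) else ""
    cat(sprintf("  %-10s n=%6d vs %6d  [%s%s]\n", s$label, s$n_cohort,
                s$n_comparator, s$status, extra))
  }
  if (!is.null(x$heterogeneity))
    cat(sprintf("  heterogeneous terms (Breslow-Day-Tarone p < 0.05): %d/%d\n",
                sum(x$heterogeneity$heterogeneous),
                nrow(x$heterogeneity)))
  invisible(x)
}

#' Long-format export of a stratified analysis
#'
#' One row per (stratum, term) with cells, statistics, flags, exclusion
#' marker, and the per-term homogeneity p-value — direct input for forest
#' plots.
#'
#' @param x a `stratified_signals` object.
#' @param ... unused.
#' @return data frame in long format.
#' @export
as.data.frame.stratified_signals <- function(x, ...) {
  rows <- list()
  for (s in x$strata) {
    if (!identical(s$status, "analysed")) next
    tb <- s$fit$table
    tb <- cbind(variable = x$variable, stratum = s$label, tb,
                stringsAsFactors = FALSE)
    rows[[s$label]] <- tb
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(x$heterogeneity)) {
    i <- match(out$term, x$heterogeneity$term)
    out$cmh_common_or <- x$heterogeneity$cmh_common_or[i]
    out$p_cmh <- x$heterogeneity$p_cmh[i]
    out$p_homogeneity <- x$heterogeneity$p_homogeneity[i]
  }
  out
}

#' @rdname as.data.frame.stratified_signals
#' @param path file path for the tab-delimited export.
#' @export
write_stratified_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
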