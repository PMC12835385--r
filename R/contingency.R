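# 2x2 contingency tables for disproportionality analysis.
#
# For one (cohort, event term) pair the fourfold table is
#   a = cohort reports with the event        b = cohort reports without it
#   c = comparator reports with the event    d = comparator reports without it
# A report with k distinct terms contributes to k tables (the a+b margin is
# the cohort size for every term); repeated REAC rows for one PT within a
# report count once.

#' Construct contingency tables from explicit cells
#'
#' Vectorized constructor for fourfold tables given the `a`, `b`, `c`, `d`
#' cells directly (e.g. from a published signal table).
#'
#' @param a,b,c,d non-negative cell counts.
#' @param term term labels (recycled).
#' @param level `"PT"` or `"SOC"`.
#' @return a `contingency_tables` data frame with columns
#'   `term, level, a, b, c, d, n_total`.
#' @export
contingency_table <- function(a, b, c, d, term = NA_character_, level = "PT") {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE))
    stop_validation("contingency cells must be non-negative")
  out <- data.frame(term = as.character(term), level = level,
                    a = a, b = b, c = c, d = d,
                    n_total = a + b + c + d, stringsAsFactors = FALSE)
  class(out) <- c("contingency_tables", "data.frame")
  out
}

#' Build contingency tables from cohort and comparator report sets
#'
#' Tabulates one fourfold table per distinct term observed in the union of
#' the two report sets, at the preferred-term or system-organ-class level.
#' At SOC level a report counts once per SOC if at least one of its PTs maps
#' there; PTs absent from the map fall in an explicit `UNMAPPED` SOC.
#'
#' @param cohort,comparator `case_data` objects (disjoint report sets).
#' @param level `"PT"` (default) or `"SOC"`.
#' @param pt_to_soc PT-to-SOC map (columns `pt`, `soc`); only needed at SOC
#'   level when the `case_data` events lack a `soc` column.
#' @return a `contingency_tables` data frame, one row per term, ordered by
#'   decreasing `a` then term.
#' @export
contingency_tables <- function(cohort, comparator, level = c("PT", "SOC"),
                               pt_to_soc = NULL) {
  level <- match.arg(level)
  n1 <- n_reports(cohort)
  n0 <- n_reports(comparator)

  term_pairs <- function(cd) {
    ev <- cd$events
    if (level == "PT") {
      data.frame(primaryid = ev$primaryid, term = ev$pt,
                 stringsAsFactors = FALSE)
    } else {
      soc <- ev$soc
      if (is.null(soc)) {
        if (is.null(pt_to_soc))
          stop_config("SOC level requires a pt_to_soc map")
        soc <- pt_to_soc$soc[match(ev$pt, toupper(pt_to_soc$pt))]
        soc[is.na(soc)] <- "UNMAPPED"
      }
      unique(data.frame(primaryid = ev$primaryid, term = soc,
                        stringsAsFactors = FALSE))
    }
  }
  p1 <- term_pairs(cohort)
  p0 <- term_pairs(comparator)
  terms <- sort(unique(c(p1$term, p0$term)))
  a <- as.numeric(table(factor(p1$term, levels = terms)))
  cc <- as.numeric(table(factor(p0$term, levels = terms)))
  out <- contingency_table(a = a, b = n1 - a, c = cc, d = n0 - cc,
                           term = terms, level = level)
  out <- out[order(-out$a, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a contingency-table export
#'
#' Tab-delimited text with columns `term, level, a, b, c, d, n_total`.
#'
#' @param x a `contingency_tables` data frame.
#' @param path file path.
#' @return `read_contingency_tables()` returns the tables; the writer
#'   returns `path` invisibly.
#' @export
write_contingency_tables <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contingency_tables
#' @export
read_contingency_tables <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  contingency_table(df$a, df$b, df$c, df$d, term = df$term, level = df$level)
}
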