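# Disproportionality estimators and the central `disprop()` fit.
#
# Three classical signal-detection statistics are computed for every
# fourfold table:
#
#   ROR  = ad/bc, Wald 95% CI on the log scale with
#          SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)
#   PRR  = [a/(a+b)] / [c/(c+d)], assessed with the uncorrected 1-df
#          chi-square (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d))
#   IC   = log2[ (a/(a+b)) / ((a+c)/N) ], the information component, with a
#          lower credibility bound IC025 from the Bayesian confidence
#          propagation posterior (see `bcpnn_priors()`)
#
# Signal criteria: ROR-positive iff the CI lower bound > 1; PRR-positive iff
# PRR >= 2 and chi-square >= 4; BCPNN-positive iff IC025 > 0. A term positive
# under all three is a "core" signal.

#' BCPNN priors and credibility-interval mode
#'
#' Parameterizes the Bayesian confidence propagation (BCPNN) information
#' component. The point estimate is always the maximum-likelihood
#' `IC = log2[(a/(a+b)) / ((a+c)/N)]`. Two lower-bound modes are offered:
#'
#' * `"bate1998"` (default): the three-term posterior variance of the
#'   classic Bayesian confidence propagation formulation with Dirichlet/Beta
#'   priors `alpha1, alpha2, beta1, beta2, gamma11` (all 1 by default, so
#'   the marginal priors are `alpha = beta = 2` and the cell prior `gamma`
#'   is tied to the margins); `IC025 = IC - ci_multiplier * SD` with
#'   multiplier 2.
#' * `"table3"`: the simple closed form
#'   `IC025 = IC - 1.96 * sqrt(1/(a+b) + 1/(c+d))` sometimes printed in
#'   methods tables; retained for formula-faithful output.
#'
#' @param alpha1,alpha2,beta1,beta2,gamma11 strictly positive prior
#'   constants.
#' @param variance_mode `"bate1998"` or `"table3"`.
#' @param ci_multiplier multiplier on the posterior SD; defaults to 2 for
#'   `bate1998` and 1.96 for `table3`.
#' @return an object of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha1 = 1, alpha2 = 1, beta1 = 1, beta2 = 1,
                         gamma11 = 1,
                         variance_mode = c("bate1998", "table3"),
                         ci_multiplier = NULL) {
  variance_mode <- match.arg(variance_mode)
  vals <- c(alpha1, alpha2, beta1, beta2, gamma11)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_validation("BCPNN priors must be strictly positive")
  if (is.null(ci_multiplier))
    ci_multiplier <- if (variance_mode == "bate1998") 2 else 1.96
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1,
                 beta2 = beta2, gamma11 = gamma11,
                 variance_mode = variance_mode,
                 ci_multiplier = ci_multiplier),
            class = "bcpnn_priors")
}

#' Signal-classification thresholds
#'
#' @param ror_lower ROR criterion: CI lower bound must exceed this (1).
#' @param prr_min,chi2_min PRR criterion: `PRR >= prr_min` and
#'   `chi2 >= chi2_min` (inclusive by default; set `strict = TRUE` for
#'   strict inequalities).
#' @param ic025_min BCPNN criterion: `IC025 >` this (0).
#' @param min_count minimum `a` cell; terms with fewer cohort reports of the
#'   event are never flagged (default 3).
#' @param strict use strict `>` for the PRR/chi-square thresholds.
#' @return an object of class `signal_thresholds`.
#' @export
signal_thresholds <- function(ror_lower = 1, prr_min = 2, chi2_min = 4,
                              ic025_min = 0, min_count = 3, strict = FALSE) {
  structure(list(ror_lower = ror_lower, prr_min = prr_min,
                 chi2_min = chi2_min, ic025_min = ic025_min,
                 min_count = min_count, strict = strict),
            class = "signal_thresholds")
}

#' Reporting odds ratio with Wald confidence interval
#'
#' @param a,b,c,d fourfold-table cells (vectorized).
#' @param conf_level confidence level for the Wald interval.
#' @param zero_correction apply the Haldane-Anscombe +0.5 continuity
#'   correction to all four cells of tables containing a zero (off by
#'   default; without it such tables are not evaluable and return `NA`).
#' @return data frame with columns `ror`, `ror_l`, `ror_u`.
#' @export
ror_stat <- function(a, b, c, d, conf_level = 0.95, zero_correction = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_correction) {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    zero <- rep(FALSE, length(a))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ror <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  out <- data.frame(ror = ror,
                    ror_l = exp(log(ror) - z * se),
                    ror_u = exp(log(ror) + z * se))
  out[zero, ] <- NA_real_
  out
}

#' Proportional reporting ratio with uncorrected chi-square
#'
#' The chi-square has 1 degree of freedom and no Yates continuity
#' correction; the p-value is the upper tail.
#'
#' @inheritParams ror_stat
#' @return data frame with columns `prr`, `chi2`, `p_chi2`.
#' @export
prr_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  bad <- (a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  out <- data.frame(prr = prr, chi2 = chi2, p_chi2 = p)
  out[bad, ] <- NA_real_
  out
}

#' Information component and its lower credibility bound
#'
#' @inheritParams ror_stat
#' @param priors a [bcpnn_priors()] object selecting the variance mode.
#' @return data frame with columns `ic`, `ic025` (bits). Tables with
#'   `a = 0` (or an empty margin) are not evaluable in the default mode and
#'   return `NA`.
#' @export
bcpnn_stat <- function(a, b, c, d, priors = bcpnn_priors()) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n1 <- a + b   # drug margin
  m1 <- a + c   # event margin
  bad <- a == 0 | n1 == 0 | m1 == 0 | n == 0
  ic <- log2((a / n1) / (m1 / n))

  if (priors$variance_mode == "table3") {
    sd_ic <- sqrt(1 / n1 + 1 / (c + d))
  } else {
    al <- priors$alpha1 + priors$alpha2
    be <- priors$beta1 + priors$beta2
    g11 <- priors$gamma11
    g <- g11 * (n + al) * (n + be) / ((n1 + priors$alpha1) * (m1 + priors$beta1))
    v <- ((n - a + g - g11) / ((a + g11) * (1 + n + g)) +
            (n - n1 + al - priors$alpha1) / ((n1 + priors$alpha1) * (1 + n + al)) +
            (n - m1 + be - priors$beta1) / ((m1 + priors$beta1) * (1 + n + be))) /
      log(2)^2
    sd_ic <- sqrt(v)
  }
  out <- data.frame(ic = ic, ic025 = ic - priors$ci_multiplier * sd_ic)
  out[bad, ] <- NA_real_
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment over one family of p-values
#' (missing values are passed through).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_validation("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fit disproportionality statistics to a set of contingency tables
#'
#' The central estimator: computes ROR (Wald CI), PRR (uncorrected 1-df
#' chi-square), and the BCPNN information component with its lower
#' credibility bound for every table; adjusts the chi-square p-values over
#' the whole family by Benjamini-Hochberg; and classifies each term against
#' the signal thresholds. Terms whose statistics are not evaluable (zero
#' cells without correction, `a = 0`) carry `NA` statistics and all-false
#' flags; terms with `a` below `min_count` are never flagged.
#'
#' @param tables a `contingency_tables` data frame (see
#'   [contingency_tables()] or [contingency_table()]).
#' @param priors a [bcpnn_priors()] object.
#' @param thresholds a [signal_thresholds()] object.
#' @param zero_correction apply Haldane-Anscombe +0.5 to zero-cell tables.
#' @param conf_level confidence level for the ROR Wald interval.
#' @return an object of class `disprop` with a `$table` data frame in fixed
#'   column order `term, level, a, b, c, d, ror, ror_l, ror_u, prr, chi2,
#'   p, q, ic, ic025, ror_pos, prr_pos, bcpnn_pos, core`.
#' @seealso [summary.disprop()], [venn_counts()], [write_signal_table()]
#' @export
disprop <- function(tables, priors = bcpnn_priors(),
                    thresholds = signal_thresholds(),
                    zero_correction = FALSE, conf_level = 0.95) {
  stopifnot(is.data.frame(tables))
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c <- as.numeric(tables$c); d <- as.numeric(tables$d)

  r <- ror_stat(a, b, c, d, conf_level, zero_correction)
  p <- prr_stat(a, b, c, d)
  ic <- bcpnn_stat(a, b, c, d, priors)
  q <- bh_adjust(p$p_chi2)

  th <- thresholds
  ge <- if (th$strict) `>` else `>=`
  ror_pos <- !is.na(r$ror_l) & r$ror_l > th$ror_lower
  prr_pos <- !is.na(p$prr) & !is.na(p$chi2) &
    ge(p$prr, th$prr_min) & ge(p$chi2, th$chi2_min)
  bcpnn_pos <- !is.na(ic$ic025) & ic$ic025 > th$ic025_min
  low_n <- a < th$min_count
  ror_pos[low_n] <- FALSE
  prr_pos[low_n] <- FALSE
  bcpnn_pos[low_n] <- FALSE

  tab <- data.frame(
    term = as.character(tables$term),
    level = if (!is.null(tables$level)) as.character(tables$level) else "PT",
    a = a, b = b, c = c, d = d,
    ror = r$ror, ror_l = r$ror_l, ror_u = r$ror_u,
    prr = p$prr, chi2 = p$chi2, p = p$p_chi2, q = q,
    ic = ic$ic, ic025 = ic$ic025,
    ror_pos = ror_pos, prr_pos = prr_pos, bcpnn_pos = bcpnn_pos,
    core = ror_pos & prr_pos & bcpnn_pos,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, priors = priors, thresholds = thresholds,
                 conf_level = conf_level,
                 n_total = if (nrow(tab)) tab$a[1] + tab$b[1] + tab$c[1] + tab$d[1]
                           else 0),
            class = "disprop")
}

#' @export
print.disprop <- function(x, digits = 2, max_terms = 10, ...) {
  tab <- x$table
  cat(sprintf("Disproportionality fit: %d terms, N = %s reports\n",
              nrow(tab), format(x$n_total, big.mark = ",")))
  cat(sprintf("  ROR-positive %d | PRR-positive %d | BCPNN-positive %d | core %d\n",
              sum(tab$ror_pos), sum(tab$prr_pos), sum(tab$bcpnn_pos),
              sum(tab$core)))
  show <- utils::head(tab[order(-tab$a), ], max_terms)
  num <- c("ror", "ror_l", "ror_u", "prr", "chi2", "ic", "ic025")
  show[num] <- lapply(show[num], round_half_up, digits)
  print(show[, c("term", "a", "ror", "ror_l", "ror_u", "prr", "chi2",
                 "ic", "ic025", "core")], row.names = FALSE)
  if (nrow(tab) > max_terms)
    cat(sprintf("  ... %d more terms\n", nrow(tab) - max_terms))
  invisible(x)
}

#' Summarize a disproportionality fit
#'
#' Reports per-method positive counts, the Venn-region decomposition of the
#' three methods' flag sets, and the number of core signals surviving the
#' FDR threshold.
#'
#' @param object a `disprop` fit.
#' @param fdr q-value threshold reported alongside (0.05).
#' @param ... unused.
#' @return an object of class `summary.disprop`.
#' @export
summary.disprop <- function(object, fdr = 0.05, ...) {
  tab <- object$table
  flags <- list(ror = tab$term[tab$ror_pos],
                prr = tab$term[tab$prr_pos],
                bcpnn = tab$term[tab$bcpnn_pos])
  structure(list(n_terms = nrow(tab), venn = venn_counts(flags),
                 n_core = sum(tab$core),
                 n_core_fdr = sum(tab$core & !is.na(tab$q) & tab$q < fdr),
                 fdr = fdr),
            class = "summary.disprop")
}

#' @export
print.summary.disprop <- function(x, ...) {
  v <- x$venn
  cat(sprintf("%d terms analysed\n", x$n_terms))
  cat(sprintf("  positive: ROR %d, PRR %d, BCPNN %d\n",
              v[["ror"]], v[["prr"]], v[["bcpnn"]]))
  cat(sprintf("  all three methods (core): %d (%d with q < %.2f)\n",
              x$n_core, x$n_core_fdr, x$fdr))
  invisible(x)
}

#' @export
as.data.frame.disprop <- function(x, ...) x$table

#' @export
coef.disprop <- function(object, ...) {
  stats::setNames(object$table$ror, object$table$term)
}

#' @export
confint.disprop <- function(object, parm, level, ...) {
  m <- as.matrix(object$table[, c("ror_l", "ror_u")])
  rownames(m) <- object$table$term
  colnames(m) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Forest plot of a disproportionality fit
#'
#' Plots ROR point estimates with 95% CIs on a log axis for the most
#' frequently reported terms; core signals are filled.
#'
#' @param x a `disprop` fit.
#' @param max_terms number of terms shown (by decreasing `a`).
#' @param ... passed to `plot()`.
#' @export
plot.disprop <- function(x, max_terms = 20, ...) {
  tab <- x$table[!is.na(x$table$ror), ]
  tab <- utils::head(tab[order(-tab$a), ], max_terms)
  tab <- tab[rev(seq_len(nrow(tab))), ]
  k <- nrow(tab)
  if (k == 0) return(invisible(x))
  old <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(old))
  plot(tab$ror, seq_len(k), log = "x",
       xlim = range(c(tab$ror_l, tab$ror_u, 1), finite = TRUE),
       yaxt = "n", xlab = "Reporting odds ratio (log scale)", ylab = "",
       pch = ifelse(tab$core, 19, 1), ...)
  graphics::segments(tab$ror_l, seq_len(k), tab$ror_u, seq_len(k))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(k), labels = tab$term, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Venn-region counts for per-method flag sets
#'
#' @param flags named list of three character vectors: the terms flagged by
#'   each method.
#' @return named integer vector with per-method totals, exclusive regions,
#'   pairwise-only regions, and the triple intersection (`core`).
#' @export
venn_counts <- function(flags) {
  stopifnot(length(flags) == 3)
  s <- lapply(flags, unique)
  nm <- names(s)
  if (is.null(nm)) nm <- c("m1", "m2", "m3")
  triple <- intersect(intersect(s[[1]], s[[2]]), s[[3]])
  p12 <- setdiff(intersect(s[[1]], s[[2]]), s[[3]])
  p13 <- setdiff(intersect(s[[1]], s[[3]]), s[[2]])
  p23 <- setdiff(intersect(s[[2]], s[[3]]), s[[1]])
  o1 <- setdiff(s[[1]], union(s[[2]], s[[3]]))
  o2 <- setdiff(s[[2]], union(s[[1]], s[[3]]))
  o3 <- setdiff(s[[3]], union(s[[1]], s[[2]]))
  out <- c(length(s[[1]]), length(s[[2]]), length(s[[3]]),
           length(o1), length(o2), length(o3),
           length(p12), length(p13), length(p23), length(triple))
  names(out) <- c(nm,
                  paste0(nm, "_only"),
                  paste(nm[1], nm[2], sep = "&"),
                  paste(nm[1], nm[3], sep = "&"),
                  paste(nm[2], nm[3], sep = "&"),
                  "core")
  out
}

#' Write / read a signal-table export
#'
#' Tab-delimited text with the fixed column order
#' `term, level, a, b, c, d, ror, ror_l, ror_u, prr, chi2, p, q, ic, ic025,
#' ror_pos, prr_pos, bcpnn_pos, core`.
#'
#' @param x a `disprop` fit or its `$table`.
#' @param path file path.
#' @return the reader returns the table as a data frame; the writer returns
#'   `path` invisibly.
#' @export
write_signal_table <- function(x, path) {
  tab <- if (inherits(x, "disprop")) x$table else x
  cols <- c("term", "level", "a", "b", "c", "d", "ror", "ror_l", "ror_u",
            "prr", "chi2", "p", "q", "ic", "ic025",
            "ror_pos", "prr_pos", "bcpnn_pos", "core")
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_table
#' @export
read_signal_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "")
}
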