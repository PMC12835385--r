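# Bundled reference data.

#' Published reference signal set: bevacizumab in glioma, top-30 PTs
#'
#' The fourfold-table cells and published disproportionality statistics for
#' the 30 most frequently reported preferred terms in a deduplicated,
#' indication-restricted FAERS universe of bevacizumab-treated glioma
#' patients (cohort margin a+b = 14,095 primary-suspect reports against an
#' indication-matched comparator, N = 66,528). Used as the golden surface
#' for validating the estimators: re-deriving every statistic from the raw
#' cells must reproduce the published values at two decimal places.
#'
#' @return data frame with columns `soc`, `pt`, `a`, `b`, `c`, `d` and the
#'   published `ror`, `ror_l`, `ror_u`, `prr`, `chi2`, `ic`, `ic025`.
#' @export
bev_glioma_reference <- function() {
  path <- system.file("extdata", "bev_glioma_top30.csv",
                      package = "faersignal", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
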