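# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going away from zero, the convention
#' used in published pharmacovigilance tables (base `round()` rounds half to
#' even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Classed error constructors so callers can distinguish configuration
# problems from I/O and validation failures.
stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("faersignal_config_error", "error")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("faersignal_validation_error", "error")))
}

#' Parse FAERS date fields
#'
#' FAERS dates are integers or strings in `YYYYMMDD` form; truncated values
#' (`YYYYMM`, `YYYY`) occur in real extracts. Full dates are returned as
#' `Date`; partial dates are missing at day resolution (they remain usable
#' for year tabulation via [faers_year()]). Impossible dates (e.g. month 13,
#' Feb 30) are missing.
#'
#' @param x integer or character vector of raw date codes.
#' @return `Date` vector, `NA` where the input has no valid day resolution.
#' @export
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  # date codes repeat heavily in real extracts: parse unique values once
  ux <- unique(x)
  uout <- rep(as.Date(NA), length(ux))
  full <- grepl("^[0-9]{8}$", ux)
  if (any(full)) {
    uout[full] <- as.Date(ux[full], format = "%Y%m%d")  # invalid -> NA
  }
  uout[match(x, ux)]
}

#' Extract the calendar year of a FAERS date code
#'
#' Partial dates (`YYYYMM`, `YYYY`) are valid here even though they are
#' missing for day-resolution arithmetic.
#'
#' @param x integer or character vector of raw date codes.
#' @return integer vector of years, `NA` where no year can be read.
#' @export
faers_year <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x) & !is.na(x)
  yr <- rep(NA_integer_, length(x))
  yr[ok] <- as.integer(substr(x[ok], 1, 4))
  yr[!is.na(yr) & (yr < 1900 | yr > 2100)] <- NA_integer_
  yr
}

# Does a raw date code have full day resolution and parse as a real date?
is_full_date <- function(x) {
  !is.na(parse_faers_date(x))
}

num_or_na <- function(x) {
  suppressWarnings(as.numeric(x))
}
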