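# Assembling analysis-ready case reports: demographics categorization,
# drug-name standardization, and cohort/comparator extraction.

#' Convert a FAERS age value to years
#'
#' @param value numeric age values (raw text accepted).
#' @param unit FAERS age unit codes: `YR` (years), `DEC` (decades), `MON`
#'   (months), `WK` (weeks), `DY` (days). Unknown codes yield `NA` with a
#'   warning; a missing code with a present value is taken as years.
#' @return numeric vector of ages in years.
#' @export
age_to_years <- function(value, unit) {
  v <- num_or_na(value)
  u <- toupper(trimws(as.character(unit)))
  u[is.na(u) | u == ""] <- "YR"
  mult <- c(YR = 1, YEAR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
            DY = 1 / 365.25)
  m <- mult[u]
  unknown <- is.na(m) & !is.na(v)
  if (any(unknown)) {
    warning(sprintf("unknown age unit code(s) %s treated as missing",
                    paste(unique(u[unknown]), collapse = ", ")),
            call. = FALSE)
  }
  v * unname(m)
}

#' Age, weight and reporter categorization
#'
#' `age_group_of()` bins ages (years) into `<18`, `18-44`, `45-64`, `>=65`;
#' values outside the plausible range (below 0 or above 120 years) are
#' outliers and become missing. `weight_group_of()` bins weights (kg) into
#' `<80` and `>=80` (80 kg itself falls in `>=80`); weights above 400 kg are
#' outliers. `reporter_group_of()` maps occupation codes `MD`, `PH`, `RN`,
#' `OT` to `healthcare-professional` and `CN`, `LW`, `SALES` to
#' `consumer-related`. In each case anything missing or unrecognized is
#' `NS` (not specified), so categorization is total.
#'
#' @param age_years,weight_kg numeric vectors.
#' @param code character vector of reporter occupation codes.
#' @return character vector of group codes.
#' @export
age_group_of <- function(age_years) {
  a <- num_or_na(age_years)
  a[!is.na(a) & (a < 0 | a > 120)] <- NA  # outlier exclusion
  g <- rep("NS", length(a))
  g[!is.na(a) & a < 18] <- "<18"
  g[!is.na(a) & a >= 18 & a < 45] <- "18-44"
  g[!is.na(a) & a >= 45 & a < 65] <- "45-64"
  g[!is.na(a) & a >= 65] <- ">=65"
  g
}

#' @rdname age_group_of
#' @export
weight_group_of <- function(weight_kg) {
  w <- num_or_na(weight_kg)
  w[!is.na(w) & (w < 0 | w > 400)] <- NA  # outlier exclusion
  g <- rep("NS", length(w))
  g[!is.na(w) & w < 80] <- "<80"
  g[!is.na(w) & w >= 80] <- ">=80"
  g
}

#' @rdname age_group_of
#' @export
reporter_group_of <- function(code) {
  cd <- toupper(trimws(as.character(code)))
  g <- rep("NS", length(cd))
  g[cd %in% c("MD", "PH", "RN", "OT")] <- "healthcare-professional"
  g[cd %in% c("CN", "LW", "SALES")] <- "consumer-related"
  g
}

#' Standardize drug names against a synonym table
#'
#' Exact matching on trimmed, upper-cased names; unmatched names pass
#' through unchanged (already-normalized).
#'
#' @param x character vector of raw drug names.
#' @param synonyms data frame with columns `raw`, `canonical`.
#' @return character vector of canonical names.
#' @export
standardize_drug_name <- function(x, synonyms = default_drug_synonyms()) {
  nm <- toupper(trimws(as.character(x)))
  hit <- match(nm, toupper(trimws(synonyms$raw)))
  out <- ifelse(is.na(hit), nm, synonyms$canonical[hit])
  out
}

#' Assemble analysis-ready case reports
#'
#' Joins the seven raw tables into a relational case-report set keyed by
#' PRIMARYID: one demographics row per retained report plus long tables of
#' drug entries (with therapy start dates and per-drug indications folded
#' in), distinct event PTs, and outcome codes. Demographics are categorized
#' (see [age_group_of()]); outliers are stored as missing and coded `NS`.
#'
#' @param tables a `faers_tables` object.
#' @param kept PRIMARYIDs to retain (e.g. `faers_dedup(tables)$kept`);
#'   `NULL` keeps all.
#' @param synonyms drug synonym table, see [standardize_drug_name()].
#' @param pt_to_soc PT-to-SOC map (columns `pt`, `soc`) used to derive each
#'   report's SOC set.
#' @param continent_map country-to-continent map, see
#'   [default_continent_map()].
#' @return an object of class `case_data`: list of data frames `reports`,
#'   `drugs`, `events`, `outcomes`.
#' @export
build_case_reports <- function(tables, kept = NULL,
                               synonyms = default_drug_synonyms(),
                               pt_to_soc = default_pt_soc_map(),
                               continent_map = default_continent_map()) {
  demo <- tables$demo
  if (!is.null(kept)) demo <- demo[demo$PRIMARYID %in% kept, , drop = FALSE]
  pid <- as.character(demo$PRIMARYID)

  age_years <- age_to_years(demo$AGE, demo$AGE_COD)
  age_years[!is.na(age_years) & (age_years < 0 | age_years > 120)] <- NA
  weight_kg <- num_or_na(demo$WT)
  wt_cod <- toupper(trimws(as.character(demo$WT_COD)))
  weight_kg[wt_cod %in% c("LBS", "LB")] <-
    weight_kg[wt_cod %in% c("LBS", "LB")] * 0.45359237
  weight_kg[!is.na(weight_kg) & (weight_kg < 0 | weight_kg > 400)] <- NA

  sex <- toupper(trimws(as.character(demo$SEX)))
  sex[!(sex %in% c("F", "M"))] <- "NS"

  country <- toupper(trimws(as.character(demo$REPORTER_COUNTRY)))
  cont <- continent_map$continent[match(country, continent_map$country)]
  cont[is.na(cont)] <- "Others"

  reports <- data.frame(
    primaryid = pid,
    caseid = as.character(demo$CASEID),
    fda_dt = parse_faers_date(demo$FDA_DT),
    year = faers_year(demo$FDA_DT),
    sex = sex,
    age_years = age_years,
    age_group = age_group_of(age_years),
    weight_kg = weight_kg,
    weight_group = weight_group_of(weight_kg),
    reporter_code = toupper(trimws(as.character(demo$OCCP_COD))),
    reporter_group = reporter_group_of(demo$OCCP_COD),
    country = country,
    continent = cont,
    event_dt = parse_faers_date(demo$EVENT_DT),
    stringsAsFactors = FALSE
  )

  keep_row <- function(df) df[df$PRIMARYID %in% pid, , drop = FALSE]
  drug <- keep_row(tables$drug)
  ther <- keep_row(tables$ther)
  indi <- keep_row(tables$indi)

  dkey <- paste(drug$PRIMARYID, drug$DRUG_SEQ, sep = "\r")
  tkey <- paste(ther$PRIMARYID, ther$DSG_DRUG_SEQ, sep = "\r")
  # earliest full start date per drug entry
  tdate <- parse_faers_date(ther$START_DT)
  ord <- order(tkey, tdate)
  first <- !duplicated(tkey[ord])
  start_map <- data.frame(key = tkey[ord][first], start_dt = tdate[ord][first])
  indi_pt <- toupper(trimws(as.character(indi$INDI_PT)))

  drugs <- data.frame(
    primaryid = as.character(drug$PRIMARYID),
    drug_seq = as.character(drug$DRUG_SEQ),
    drug_name_raw = as.character(drug$DRUGNAME),
    drug_name_std = standardize_drug_name(drug$DRUGNAME, synonyms),
    role = toupper(trimws(as.character(drug$ROLE_COD))),
    start_dt = start_map$start_dt[match(dkey, start_map$key)],
    stringsAsFactors = FALSE
  )
  # per-drug indication PTs kept long-form alongside
  indications <- data.frame(
    primaryid = as.character(indi$PRIMARYID),
    drug_seq = as.character(indi$INDI_DRUG_SEQ),
    indi_pt = indi_pt,
    stringsAsFactors = FALSE
  )

  reac <- keep_row(tables$reac)
  ev_pt <- toupper(trimws(as.character(reac$PT)))
  events <- unique(data.frame(primaryid = as.character(reac$PRIMARYID),
                              pt = ev_pt, stringsAsFactors = FALSE))
  events$soc <- pt_to_soc$soc[match(events$pt, toupper(pt_to_soc$pt))]
  events$soc[is.na(events$soc)] <- "UNMAPPED"
  rownames(events) <- NULL

  outc <- keep_row(tables$outc)
  outcomes <- unique(data.frame(primaryid = as.character(outc$PRIMARYID),
                                code = toupper(trimws(as.character(outc$OUTC_COD))),
                                stringsAsFactors = FALSE))
  rownames(outcomes) <- NULL

  structure(list(reports = reports, drugs = drugs, indications = indications,
                 events = events, outcomes = outcomes),
            class = "case_data")
}

#' @export
print.case_data <- function(x, ...) {
  cat(sprintf(paste0("case_data: %d reports, %d drug entries, ",
                     "%d report-event pairs\n"),
              nrow(x$reports), nrow(x$drugs), nrow(x$events)))
  invisible(x)
}

# Subset a case_data object to a set of report identifiers.
subset_cases <- function(cd, primaryids) {
  out <- lapply(cd, function(df) {
    df <- df[df$primaryid %in% primaryids, , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  class(out) <- "case_data"
  out
}

#' Number of reports in a `case_data` set
#' @param cd a `case_data` object.
#' @return integer count of reports.
#' @export
n_reports <- function(cd) nrow(cd$reports)

#' Extract target-drug cohort and comparator universe
#'
#' The cohort consists of deduplicated reports having at least one drug
#' entry whose standardized name is in `target_drug`, whose role equals
#' `role` (default `PS`, primary suspect), and whose own indication PTs
#' intersect `indication_pts`. The comparator is, by default, the rest of
#' the indication-restricted universe: reports in the same indication whose
#' qualifying suspect drug is not the target (`background = "indication"`).
#' With `background = "full"` the comparator is every other deduplicated
#' report in the database. Cohort and comparator are always disjoint and,
#' in indication mode, partition the indication universe.
#'
#' @param cases a `case_data` object (already deduplicated).
#' @param target_drug character set of canonical target drug names.
#' @param role FAERS role code filter: one of `PS`, `SS`, `C`, `I`.
#' @param indication_pts character set of indication PTs (must be non-empty).
#' @param background `"indication"` (default) or `"full"`.
#' @return list with elements `cohort` and `comparator`, each a `case_data`;
#'   the cohort's `drugs` table gains a logical `is_target` column.
#' @export
build_cohort <- function(cases, target_drug, role = "PS",
                         indication_pts = default_glioma_indication_pts(),
                         background = c("indication", "full")) {
  background <- match.arg(background)
  if (length(indication_pts) == 0)
    stop_config("indication_pts must be a non-empty PT set")
  if (!role %in% c("PS", "SS", "C", "I"))
    stop_config("role must be one of PS, SS, C, I")
  target <- toupper(trimws(target_drug))
  ipts <- toupper(trimws(indication_pts))

  dr <- cases$drugs
  ind <- cases$indications
  dkey <- paste(dr$primaryid, dr$drug_seq, sep = "\r")
  ikey <- paste(ind$primaryid, ind$drug_seq, sep = "\r")
  drug_has_ind <- dkey %in% ikey[ind$indi_pt %in% ipts]

  is_target_row <- dr$drug_name_std %in% target & dr$role == role &
    drug_has_ind
  cohort_ids <- unique(dr$primaryid[is_target_row])

  if (background == "indication") {
    universe_ids <- unique(ind$primaryid[ind$indi_pt %in% ipts])
    comp_ids <- setdiff(universe_ids, cohort_ids)
  } else {
    comp_ids <- setdiff(cases$reports$primaryid, cohort_ids)
  }

  cohort <- subset_cases(cases, cohort_ids)
  cohort$drugs$is_target <- cohort$drugs$drug_name_std %in% target &
    cohort$drugs$role == role
  comparator <- subset_cases(cases, comp_ids)
  list(cohort = cohort, comparator = comparator)
}
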