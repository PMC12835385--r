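# Fixture builders and independent brute-force oracles used across tests.

# Minimal case_data constructor from plain vectors: one report per id, one
# event row per (id, pt) pair supplied.
make_case_data <- function(ids, events = NULL, sex = "NS", age_group = "NS",
                           reporter_group = "NS") {
  ids <- as.character(ids)
  k <- length(ids)
  reports <- data.frame(
    primaryid = ids, caseid = ids,
    fda_dt = rep(as.Date("2020-06-01"), k), year = rep(2020L, k),
    sex = rep_len(sex, k),
    age_years = rep(NA_real_, k),
    age_group = rep_len(age_group, k),
    weight_kg = rep(NA_real_, k), weight_group = rep("NS", k),
    reporter_code = rep("", k),
    reporter_group = rep_len(reporter_group, k),
    country = rep("US", k), continent = rep("North America", k),
    event_dt = rep(as.Date(NA), k),
    stringsAsFactors = FALSE
  )
  if (is.null(events))
    events <- data.frame(primaryid = character(0), pt = character(0))
  events$primaryid <- as.character(events$primaryid)
  events <- unique(events[, c("primaryid", "pt")])
  events$soc <- rep("SOC1", nrow(events))
  structure(list(
    reports = reports,
    drugs = data.frame(primaryid = character(0), drug_seq = character(0),
                       drug_name_raw = character(0),
                       drug_name_std = character(0), role = character(0),
                       start_dt = as.Date(character(0)),
                       stringsAsFactors = FALSE),
    indications = data.frame(primaryid = character(0),
                             drug_seq = character(0),
                             indi_pt = character(0), stringsAsFactors = FALSE),
    events = events,
    outcomes = data.frame(primaryid = character(0), code = character(0),
                          stringsAsFactors = FALSE)
  ), class = "case_data")
}

# Brute-force recount oracle: per-term cells from raw (report, term) pairs.
oracle_cells <- function(cohort_pairs, comparator_pairs, n1, n0) {
  cohort_pairs <- unique(cohort_pairs)
  comparator_pairs <- unique(comparator_pairs)
  terms <- sort(unique(c(cohort_pairs$pt, comparator_pairs$pt)))
  do.call(rbind, lapply(terms, function(tm) {
    a <- sum(cohort_pairs$pt == tm)
    cc <- sum(comparator_pairs$pt == tm)
    data.frame(term = tm, a = a, b = n1 - a, c = cc, d = n0 - cc,
               stringsAsFactors = FALSE)
  }))
}

# Brute-force deduplication: per case keep max FDA_DT then max PRIMARYID,
# enumerated row by row (independent of the package's sort-based path).
oracle_dedup <- function(pid, cid, fdt) {
  kept <- character(0)
  for (cs in unique(cid)) {
    i <- which(cid == cs)
    best <- i[1]
    for (j in i[-1]) {
      if (fdt[j] > fdt[best] ||
          (fdt[j] == fdt[best] &&
           as.numeric(pid[j]) > as.numeric(pid[best]))) best <- j
    }
    kept <- c(kept, pid[best])
  }
  sort(kept)
}

# Lean generator config for pipeline-scale tests.
lean_config <- function(seed, nt = 5000, nc = 20000,
                        injected = c(HYPERTENSION = 5.0)) {
  synthetic_config(
    n_target_reports = nt, n_comparator_reports = nc,
    pt_catalog = data.frame(
      pt = c("HYPERTENSION", "NAUSEA", "HEADACHE", "FATIGUE", "PROTEINURIA"),
      soc = c("VASCULAR DISORDERS", "GASTROINTESTINAL DISORDERS",
              "NERVOUS SYSTEM DISORDERS",
              "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS",
              "RENAL AND URINARY DISORDERS"),
      base_prob = c(0.010, 0.015, 0.012, 0.014, 0.004),
      stringsAsFactors = FALSE),
    injected_signals = injected,
    duplicate_rate = 0.05,
    seed = seed
  )
}

# Full pipeline on generated tables: dedup -> case reports -> cohorts.
run_pipeline <- function(tabs) {
  dd <- faers_dedup(tabs)
  cases <- build_case_reports(tabs, kept = dd$kept)
  build_cohort(cases, "BEVACIZUMAB")
}

ref30 <- function() bev_glioma_reference()
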