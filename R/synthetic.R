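# Synthetic FAERS-like report generator with known ground truth.
#
# Emulates the structure of a real spontaneous-report extract restricted to
# one indication: a target-drug cohort and an other-suspect-drug comparator
# sharing the indication, duplicate case versions, realistic missingness,
# demographic strata, and per-PT event probabilities. Signals are injected
# on the per-report odds scale, so the injected value is exactly the
# reporting odds ratio the pipeline estimates.

#' Default synthetic event catalog
#'
#' Preferred terms with their SOC and baseline (comparator) per-report event
#' probability. Baselines approximate the background reporting proportions
#' of common terms in an indication-restricted glioma universe.
#'
#' @return data frame with columns `pt`, `soc`, `base_prob`.
#' @export
default_pt_catalog <- function() {
  map <- default_pt_soc_map()
  pts <- c("DEATH" = 0.010, "DISEASE PROGRESSION" = 0.021,
           "OFF LABEL USE" = 0.018, "FATIGUE" = 0.012,
           "HYPERTENSION" = 0.0033, "HEADACHE" = 0.010,
           "NAUSEA" = 0.012, "THROMBOCYTOPENIA" = 0.019,
           "GLIOBLASTOMA" = 0.006, "PLATELET COUNT DECREASED" = 0.0075,
           "SEIZURE" = 0.010, "PULMONARY EMBOLISM" = 0.0086,
           "BLOOD PRESSURE INCREASED" = 0.0015, "PROTEINURIA" = 0.00065,
           "CONFUSIONAL STATE" = 0.0065, "VOMITING" = 0.0115,
           "DEEP VEIN THROMBOSIS" = 0.0054, "WEIGHT INCREASED" = 0.0024,
           "WEIGHT DECREASED" = 0.0036, "HEMIPARESIS" = 0.0052,
           "MUSCULAR WEAKNESS" = 0.0036, "NEUTROPENIA" = 0.0107,
           "COGNITIVE DISORDER" = 0.0030, "HAEMORRHAGE" = 0.0040)
  data.frame(pt = names(pts),
             soc = map$soc[match(names(pts), map$pt)],
             base_prob = unname(pts), stringsAsFactors = FALSE)
}

#' Default injected reporting odds ratios
#'
#' True per-report reporting odds ratios for the terms with established
#' disproportionality in bevacizumab-treated glioma (hypertension,
#' blood-pressure increase, proteinuria, death, thromboembolic terms), at
#' the published signal strengths; all other catalog terms are left at the
#' null.
#'
#' @return named numeric vector (PT -> odds ratio).
#' @export
default_injected_signals <- function() {
  c("HYPERTENSION" = 5.0, "BLOOD PRESSURE INCREASED" = 5.4,
    "PROTEINURIA" = 11.7, "DEATH" = 4.2, "OFF LABEL USE" = 1.7,
    "FATIGUE" = 1.8, "WEIGHT INCREASED" = 2.8,
    "THROMBOCYTOPENIA" = 0.6, "NEUTROPENIA" = 0.57)
}

#' Configuration of the synthetic report generator
#'
#' Defaults emulate the structure of the glioma/bevacizumab study universe:
#' sex missing in 19.6% of reports, age in 33.7%, weight in 50.3%, onset
#' dates in 73.2%; demographic mixes follow the published cohort
#' composition; onset intervals are log-normal with mean about 97 days.
#'
#' @param n_target_reports,n_comparator_reports unique case counts for the
#'   target-drug cohort and the same-indication comparator.
#' @param pt_catalog data frame `pt`, `soc`, `base_prob` (probabilities in
#'   (0,1)).
#' @param injected_signals named numeric vector of true reporting odds
#'   ratios for catalog PTs (others implicitly 1).
#' @param duplicate_rate fraction of cases emitted with a second, superseded
#'   version.
#' @param missingness named fractions for `sex`, `age`, `weight`, `onset`,
#'   `reporter`.
#' @param sex_mix,age_mix,reporter_mix distributions over the known strata
#'   (normalized internally).
#' @param stratum_effects optional per-stratum odds modifiers: a list with
#'   elements `variable` (e.g. `"sex"`) and `multipliers`, a named list
#'   mapping stratum label to a named numeric vector of per-PT odds
#'   multipliers applied to target reports in that stratum.
#' @param onset_meanlog,onset_sdlog log-normal parameters of the onset
#'   interval in days.
#' @param negative_onset_rate small fraction of reports with an event date
#'   before therapy start (data-entry artifacts).
#' @param date_window inclusive `YYYYMMDD` bounds for FDA receipt dates.
#' @param target_drug,comparator_drugs canonical drug names; raw spellings
#'   in the DRUG table are drawn from the synonym table to exercise
#'   standardization.
#' @param indication_pts indication PTs shared by the universe.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_target_reports = 2000,
                             n_comparator_reports = 8000,
                             pt_catalog = default_pt_catalog(),
                             injected_signals = default_injected_signals(),
                             duplicate_rate = 0.10,
                             missingness = c(sex = 0.196, age = 0.337,
                                             weight = 0.503, onset = 0.732,
                                             reporter = 0.018),
                             sex_mix = c(F = 0.403, M = 0.597),
                             age_mix = c("<18" = 0.047, "18-44" = 0.206,
                                         "45-64" = 0.560, ">=65" = 0.187),
                             reporter_mix = c("consumer-related" = 0.119,
                                              "healthcare-professional" = 0.881),
                             stratum_effects = NULL,
                             onset_meanlog = 3.75, onset_sdlog = 1.30,
                             negative_onset_rate = 0.005,
                             date_window = c(20040101, 20241231),
                             target_drug = "BEVACIZUMAB",
                             comparator_drugs = c("TEMOZOLOMIDE", "LOMUSTINE",
                                                  "CARMUSTINE", "NIVOLUMAB"),
                             indication_pts = default_glioma_indication_pts(),
                             seed = 20040101) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_target_reports < 0 || cfg$n_comparator_reports < 0)
    stop_validation("report counts must be non-negative")
  p <- cfg$pt_catalog$base_prob
  if (any(p <= 0 | p >= 1))
    stop_validation("baseline event probabilities must lie strictly in (0, 1)")
  if (any(cfg$injected_signals <= 0) || any(!is.finite(cfg$injected_signals)))
    stop_validation("injected odds ratios must be positive and finite")
  extra <- setdiff(names(cfg$injected_signals), cfg$pt_catalog$pt)
  if (length(extra))
    stop_validation("injected signal for PT(s) not in catalog: %s",
                    paste(extra, collapse = ", "))
  if (any(cfg$missingness < 0 | cfg$missingness > 1))
    stop_validation("missingness fractions must lie in [0, 1]")
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate >= 1)
    stop_validation("duplicate_rate must lie in [0, 1)")
  if (!is.null(cfg$stratum_effects)) {
    mult <- unlist(cfg$stratum_effects$multipliers)
    if (any(mult <= 0)) stop_validation("stratum odds multipliers must be > 0")
  }
  invisible(cfg)
}

# One shared stream, sub-streamed per generation phase so that adding a
# field does not reshuffle unrelated draws. Seeds stay below 2^31.
sub_seed <- function(seed, phase) {
  as.integer((as.numeric(seed) * 7919 + phase * 104729) %% 2147483629)
}

sample_mix <- function(n, mix, seed) {
  set.seed(seed)
  mix <- mix / sum(mix)
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Generate a synthetic FAERS-like quarter
#'
#' Produces the seven raw tables (in memory; optionally written to disk in
#' the dollar-delimited quarterly dialect). Target reports carry the target
#' drug as primary suspect with the shared indication; comparator reports
#' carry another suspect drug with the same indication. Event PTs are drawn
#' per-report Bernoulli with odds multiplied by the injected signal (and any
#' stratum modifier) for target reports. A `duplicate_rate` fraction of
#' cases is emitted twice (an earlier, superseded version sharing CASEID).
#' Deterministic under the config seed.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory for [write_faers_quarter()].
#' @return a `faers_tables` object with attribute `truth`: a list holding
#'   the per-report ground truth (`reports` data frame) and the config.
#' @export
synthetic_faers <- function(config = synthetic_config(), dir = NULL) {
  validate_synthetic_config(config)
  nt <- config$n_target_reports
  nc <- config$n_comparator_reports
  n <- nt + nc
  seed <- config$seed

  caseid <- 5000000 + seq_len(n)
  primaryid <- caseid * 10 + 1
  is_target <- c(rep(TRUE, nt), rep(FALSE, nc))

  ## phase 1: receipt dates ------------------------------------------------
  set.seed(sub_seed(seed, 1))
  d0 <- as.Date(as.character(config$date_window[1]), "%Y%m%d")
  d1 <- as.Date(as.character(config$date_window[2]), "%Y%m%d")
  fda_dt <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L

  ## phase 2: demographics -------------------------------------------------
  sex <- sample_mix(n, config$sex_mix, sub_seed(seed, 2))
  age_grp <- sample_mix(n, config$age_mix, sub_seed(seed, 3))
  set.seed(sub_seed(seed, 4))
  age <- numeric(n)
  rng <- list("<18" = c(1, 17), "18-44" = c(18, 44),
              "45-64" = c(45, 64), ">=65" = c(65, 90))
  for (g in names(rng)) {
    i <- age_grp == g
    age[i] <- round(stats::runif(sum(i), rng[[g]][1], rng[[g]][2]))
  }
  set.seed(sub_seed(seed, 5))
  weight <- round(pmin(pmax(stats::rnorm(n, 76, 16), 30), 180), 1)
  rep_grp <- sample_mix(n, config$reporter_mix, sub_seed(seed, 6))
  set.seed(sub_seed(seed, 7))
  occp <- character(n)
  hcp <- rep_grp == "healthcare-professional"
  occp[hcp] <- sample(c("MD", "OT", "PH", "RN"), sum(hcp), replace = TRUE,
                      prob = c(0.45, 0.47, 0.05, 0.03))
  occp[!hcp] <- sample(c("CN", "LW", "SALES"), sum(!hcp), replace = TRUE,
                       prob = c(0.97, 0.02, 0.01))
  set.seed(sub_seed(seed, 8))
  country <- sample(c("US", "CA", "GB", "DE", "FR", "JP", "CN", "AU", "BR",
                      "ZA"),
                    n, replace = TRUE,
                    prob = c(0.68, 0.05, 0.05, 0.04, 0.04, 0.05, 0.04, 0.02,
                             0.02, 0.01))

  ## phase 3: masking ------------------------------------------------------
  ms <- config$missingness
  set.seed(sub_seed(seed, 9))
  sex_out <- sex
  sex_out[stats::runif(n) < ms[["sex"]]] <- ""
  set.seed(sub_seed(seed, 10))
  age_miss <- stats::runif(n) < ms[["age"]]
  set.seed(sub_seed(seed, 11))
  wt_miss <- stats::runif(n) < ms[["weight"]]
  set.seed(sub_seed(seed, 12))
  occ_miss <- stats::runif(n) < ms[["reporter"]]
  occp[occ_miss] <- ""

  # a sprinkle of non-year age units to exercise conversion
  set.seed(sub_seed(seed, 13))
  age_cod <- rep("YR", n)
  dec <- !age_miss & stats::runif(n) < 0.02
  age_cod[dec] <- "DEC"
  age_val <- ifelse(age_cod == "DEC", age / 10, age)

  ## phase 4: events -------------------------------------------------------
  cat_pts <- config$pt_catalog$pt
  base_p <- config$pt_catalog$base_prob
  or_vec <- rep(1, length(cat_pts))
  names(or_vec) <- cat_pts
  or_vec[names(config$injected_signals)] <- config$injected_signals

  se <- config$stratum_effects
  ev_idx <- vector("list", length(cat_pts))
  set.seed(sub_seed(seed, 14))
  for (j in seq_along(cat_pts)) {
    o <- base_p[j] / (1 - base_p[j])
    odds <- rep(o, n)
    odds[is_target] <- odds[is_target] * or_vec[j]
    if (!is.null(se)) {
      gvar <- switch(se$variable, sex = sex, age_group = age_grp,
                     reporter_group = rep_grp,
                     stop_config("unknown stratum_effects variable '%s'",
                                 se$variable))
      for (lab in names(se$multipliers)) {
        m <- se$multipliers[[lab]]
        if (cat_pts[j] %in% names(m)) {
          i <- is_target & gvar == lab
          odds[i] <- odds[i] * m[[cat_pts[j]]]
        }
      }
    }
    pj <- odds / (1 + odds)
    ev_idx[[j]] <- which(stats::runif(n) < pj)
  }
  # every report carries at least one reaction row; reports drawing no
  # catalog event get a neutral filler term outside the analysis catalog
  hit_any <- logical(n)
  for (j in seq_along(ev_idx)) hit_any[ev_idx[[j]]] <- TRUE
  no_ev <- which(!hit_any)
  ev <- data.frame(
    idx = c(unlist(ev_idx), no_ev),
    pt = c(rep(cat_pts, lengths(ev_idx)),
           rep("UNEVALUABLE EVENT", length(no_ev))),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$idx, ev$pt), , drop = FALSE]

  ## phase 5: drugs, therapy and onset dates -------------------------------
  syn <- default_drug_synonyms()
  set.seed(sub_seed(seed, 15))
  target_raw <- sample(c("BEVACIZUMAB", "AVASTIN", " Avastin ", "MVASI"),
                       n, replace = TRUE, prob = c(0.55, 0.35, 0.05, 0.05))
  comp_raw <- sample(config$comparator_drugs, n, replace = TRUE)
  drugname <- ifelse(is_target, target_raw, comp_raw)
  set.seed(sub_seed(seed, 16))
  indi_pt <- sample(toupper(config$indication_pts), n, replace = TRUE)

  set.seed(sub_seed(seed, 17))
  start_dt <- fda_dt - sample.int(700L, n, replace = TRUE)
  onset <- round(stats::rlnorm(n, config$onset_meanlog, config$onset_sdlog))
  negpick <- stats::runif(n) < config$negative_onset_rate
  onset[negpick] <- -sample.int(30L, sum(negpick), replace = TRUE)
  event_dt <- start_dt + onset
  onset_miss <- stats::runif(n) < ms[["onset"]]

  ## phase 6: outcomes -----------------------------------------------------
  set.seed(sub_seed(seed, 18))
  outc_cod <- sample(c("DE", "HO", "OT", "LT", "DS", "RI", ""),
                     n, replace = TRUE,
                     prob = c(0.254, 0.275, 0.356, 0.032, 0.010, 0.001,
                              0.072))

  fmt_dt <- function(d) {  # format unique dates once
    ud <- unique(d)
    format(ud, "%Y%m%d")[match(d, ud)]
  }
  mask <- function(x, miss) { x[miss] <- ""; x }
  demo <- data.frame(
    PRIMARYID = as.character(primaryid),
    CASEID = as.character(caseid),
    FDA_DT = fmt_dt(fda_dt),
    EVENT_DT = mask(fmt_dt(event_dt), onset_miss),
    AGE = mask(as.character(age_val), age_miss),
    AGE_COD = mask(age_cod, age_miss),
    SEX = sex_out,
    WT = mask(as.character(weight), wt_miss),
    WT_COD = mask(rep("KG", n), wt_miss),
    OCCP_COD = occp,
    REPORTER_COUNTRY = country,
    stringsAsFactors = FALSE
  )
  drug <- data.frame(
    PRIMARYID = as.character(primaryid),
    DRUG_SEQ = "1",
    DRUGNAME = drugname,
    ROLE_COD = "PS",
    stringsAsFactors = FALSE
  )
  reac <- data.frame(
    PRIMARYID = as.character(primaryid[ev$idx]),
    PT = ev$pt,
    stringsAsFactors = FALSE
  )
  ther <- data.frame(
    PRIMARYID = as.character(primaryid),
    DSG_DRUG_SEQ = "1",
    START_DT = fmt_dt(start_dt),
    stringsAsFactors = FALSE
  )
  indi <- data.frame(
    PRIMARYID = as.character(primaryid),
    INDI_DRUG_SEQ = "1",
    INDI_PT = indi_pt,
    stringsAsFactors = FALSE
  )
  has_outc <- outc_cod != ""
  outc <- data.frame(
    PRIMARYID = as.character(primaryid[has_outc]),
    OUTC_COD = outc_cod[has_outc],
    stringsAsFactors = FALSE
  )
  rpsr <- data.frame(
    PRIMARYID = as.character(primaryid),
    RPSR_COD = ifelse(hcp, "HP", "CSM"),
    stringsAsFactors = FALSE
  )

  ## phase 7: duplicate case versions --------------------------------------
  ndup <- floor(config$duplicate_rate * n)
  if (ndup > 0) {
    set.seed(sub_seed(seed, 19))
    dup_i <- sort(sample.int(n, ndup))
    tie <- stats::runif(ndup) < 0.3   # same FDA_DT, lower PRIMARYID loses
    dup_pid <- as.character(caseid[dup_i] * 10)
    dup_fdt <- fmt_dt(fda_dt[dup_i] - sample.int(90L, ndup, replace = TRUE))
    dup_fdt[tie] <- fmt_dt(fda_dt[dup_i])[tie]
    ids <- as.character(primaryid[dup_i])
    d_demo <- demo[demo$PRIMARYID %in% ids, , drop = FALSE]
    d_demo$FDA_DT <- dup_fdt[match(d_demo$PRIMARYID, ids)]
    d_demo$PRIMARYID <- dup_pid[match(d_demo$PRIMARYID, ids)]
    demo <- rbind(demo, d_demo)
    for (nm in c("drug", "reac", "ther", "indi", "outc", "rpsr")) {
      df <- get(nm)
      rows <- df[df$PRIMARYID %in% ids, , drop = FALSE]
      rows$PRIMARYID <- dup_pid[match(rows$PRIMARYID, ids)]
      assign(nm, rbind(df, rows))
    }
  }

  tabs <- as_faers_tables(list(demo = demo, drug = drug, reac = reac,
                               ther = ther, indi = indi, outc = outc,
                               rpsr = rpsr),
                          quarter = "SYN1")
  attr(tabs, "truth") <- list(
    config = config,
    reports = data.frame(primaryid = as.character(primaryid),
                         caseid = as.character(caseid),
                         is_target = is_target, sex = sex,
                         age_group = age_grp, reporter_group = rep_grp,
                         onset = onset, onset_missing = onset_miss,
                         stringsAsFactors = FALSE)
  )
  if (!is.null(dir)) write_faers_quarter(tabs, dir)
  tabs
}
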