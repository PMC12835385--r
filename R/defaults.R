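# Default reference tables. MedDRA and the WHO Drug Dictionary are licensed,
# so every mapping here is a small user-replaceable placeholder covering the
# vocabulary of the bundled synthetic generator and examples.

#' FAERS quarterly ASCII dialect
#'
#' Describes the on-disk layout of one FAERS quarterly extract: the field
#' delimiter and, per table, the mandatory columns (with accepted legacy
#' aliases, since older quarters name some columns differently).
#'
#' @param delim field delimiter (FAERS uses `"$"`).
#' @return an object of class `faers_dialect`.
#' @export
faers_dialect <- function(delim = "$") {
  cols <- list(
    demo = list(PRIMARYID = c("PRIMARYID", "ISR"),
                CASEID    = c("CASEID", "CASE"),
                FDA_DT    = "FDA_DT",
                EVENT_DT  = "EVENT_DT",
                AGE       = "AGE",
                AGE_COD   = "AGE_COD",
                SEX       = c("SEX", "GNDR_COD"),
                WT        = "WT",
                WT_COD    = "WT_COD",
                OCCP_COD  = "OCCP_COD",
                REPORTER_COUNTRY = "REPORTER_COUNTRY"),
    drug = list(PRIMARYID = c("PRIMARYID", "ISR"),
                DRUG_SEQ  = c("DRUG_SEQ", "DSG_DRUG_SEQ"),
                DRUGNAME  = "DRUGNAME",
                ROLE_COD  = "ROLE_COD"),
    reac = list(PRIMARYID = c("PRIMARYID", "ISR"),
                PT        = "PT"),
    ther = list(PRIMARYID    = c("PRIMARYID", "ISR"),
                DSG_DRUG_SEQ = c("DSG_DRUG_SEQ", "DRUG_SEQ"),
                START_DT     = "START_DT"),
    indi = list(PRIMARYID     = c("PRIMARYID", "ISR"),
                INDI_DRUG_SEQ = c("INDI_DRUG_SEQ", "DRUG_SEQ"),
                INDI_PT       = "INDI_PT"),
    outc = list(PRIMARYID = c("PRIMARYID", "ISR"),
                OUTC_COD  = c("OUTC_COD", "OUTC_CODE")),
    rpsr = list(PRIMARYID = c("PRIMARYID", "ISR"),
                RPSR_COD  = "RPSR_COD")
  )
  structure(list(delim = delim, columns = cols), class = "faers_dialect")
}

#' Default preferred-term to system-organ-class map
#'
#' Covers the event vocabulary of the synthetic generator. Real analyses
#' should supply their own (licensed) MedDRA map via the `pt_to_soc`
#' arguments; the expected shape is a two-column data frame `pt`, `soc`.
#'
#' @return data frame with columns `pt` and `soc`.
#' @export
default_pt_soc_map <- function() {
  m <- matrix(c(
    "DEATH",                    "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS",
    "DISEASE PROGRESSION",      "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS",
    "FATIGUE",                  "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS",
    "ASTHENIA",                 "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS",
    "PYREXIA",                  "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS",
    "DRUG INEFFECTIVE",         "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS",
    "GENERAL PHYSICAL HEALTH DETERIORATION",
                                "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS",
    "UNEVALUABLE EVENT",        "GENERAL DISORDERS AND ADMINISTRATION SITE CONDITIONS",
    "OFF LABEL USE",            "INJURY, POISONING AND PROCEDURAL COMPLICATIONS",
    "FALL",                     "INJURY, POISONING AND PROCEDURAL COMPLICATIONS",
    "INTENTIONAL PRODUCT USE ISSUE",
                                "INJURY, POISONING AND PROCEDURAL COMPLICATIONS",
    "HYPERTENSION",             "VASCULAR DISORDERS",
    "DEEP VEIN THROMBOSIS",     "VASCULAR DISORDERS",
    "HAEMORRHAGE",              "VASCULAR DISORDERS",
    "HEADACHE",                 "NERVOUS SYSTEM DISORDERS",
    "SEIZURE",                  "NERVOUS SYSTEM DISORDERS",
    "HEMIPARESIS",              "NERVOUS SYSTEM DISORDERS",
    "COGNITIVE DISORDER",       "NERVOUS SYSTEM DISORDERS",
    "NAUSEA",                   "GASTROINTESTINAL DISORDERS",
    "VOMITING",                 "GASTROINTESTINAL DISORDERS",
    "DIARRHOEA",                "GASTROINTESTINAL DISORDERS",
    "THROMBOCYTOPENIA",         "BLOOD AND LYMPHATIC SYSTEM DISORDERS",
    "NEUTROPENIA",              "BLOOD AND LYMPHATIC SYSTEM DISORDERS",
    "GLIOBLASTOMA",             "NEOPLASMS BENIGN, MALIGNANT AND UNSPECIFIED (INCL CYSTS AND POLYPS)",
    "NEOPLASM PROGRESSION",     "NEOPLASMS BENIGN, MALIGNANT AND UNSPECIFIED (INCL CYSTS AND POLYPS)",
    "PLATELET COUNT DECREASED", "INVESTIGATIONS",
    "BLOOD PRESSURE INCREASED", "INVESTIGATIONS",
    "WEIGHT INCREASED",         "INVESTIGATIONS",
    "WEIGHT DECREASED",         "INVESTIGATIONS",
    "PROTEINURIA",              "RENAL AND URINARY DISORDERS",
    "PULMONARY EMBOLISM",       "RESPIRATORY, THORACIC AND MEDIASTINAL DISORDERS",
    "CONFUSIONAL STATE",        "PSYCHIATRIC DISORDERS",
    "MUSCULAR WEAKNESS",        "MUSCULOSKELETAL AND CONNECTIVE TISSUE DISORDERS"
  ), ncol = 2, byrow = TRUE)
  data.frame(pt = m[, 1], soc = m[, 2], stringsAsFactors = FALSE)
}

#' Default drug synonym table
#'
#' Two-column table mapping raw drug-name variants (after trimming and
#' upper-casing) to a canonical name; exact matching only.
#'
#' @return data frame with columns `raw` and `canonical`.
#' @export
default_drug_synonyms <- function() {
  data.frame(
    raw = c("BEVACIZUMAB", "AVASTIN", "MVASI", "ZIRABEV",
            "BEVACIZUMAB-AWWB", "TEMOZOLOMIDE", "TEMODAR",
            "LOMUSTINE", "CEENU", "CARMUSTINE", "NIVOLUMAB",
            "DEXAMETHASONE", "LEVETIRACETAM"),
    canonical = c("BEVACIZUMAB", "BEVACIZUMAB", "BEVACIZUMAB", "BEVACIZUMAB",
                  "BEVACIZUMAB", "TEMOZOLOMIDE", "TEMOZOLOMIDE",
                  "LOMUSTINE", "LOMUSTINE", "CARMUSTINE", "NIVOLUMAB",
                  "DEXAMETHASONE", "LEVETIRACETAM"),
    stringsAsFactors = FALSE
  )
}

#' Placeholder glioma indication preferred terms
#'
#' A configurable stand-in for a full MedDRA-derived indication list (the
#' complete licensed list has 28 diagnostic categories); supply your own
#' vector wherever an `indication_pts` argument appears.
#'
#' @return character vector of indication PTs.
#' @export
default_glioma_indication_pts <- function() {
  c("GLIOMA", "GLIOBLASTOMA", "GLIOBLASTOMA MULTIFORME", "ASTROCYTOMA",
    "ANAPLASTIC ASTROCYTOMA", "OLIGODENDROGLIOMA", "ANAPLASTIC OLIGODENDROGLIOMA",
    "BRAIN STEM GLIOMA", "MALIGNANT GLIOMA", "GLIOSARCOMA",
    "ASTROCYTOMA MALIGNANT", "MIXED GLIOMA")
}

#' Default country-to-continent map
#'
#' Small editable map from ISO-like FAERS reporter-country codes to
#' continents; unknown codes map to `"Others"`.
#'
#' @return data frame with columns `country` and `continent`.
#' @export
default_continent_map <- function() {
  data.frame(
    country = c("US", "CA", "MX", "GB", "DE", "FR", "IT", "ES", "NL", "PL",
                "JP", "CN", "KR", "IN", "AU", "NZ", "BR", "AR", "CO",
                "ZA", "EG", "NG"),
    continent = c(rep("North America", 3), rep("Europe", 7),
                  rep("Asia", 4), rep("Oceania", 2), rep("South America", 3),
                  rep("Africa", 3)),
    stringsAsFactors = FALSE
  )
}
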