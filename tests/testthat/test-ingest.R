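# Quarterly-table parsing, deduplication and cohort extraction.

test_that("a seven-table quarter round-trips through write and read", {
  cfg <- synthetic_config(n_target_reports = 300, n_comparator_reports = 700,
                          seed = 11)
  dir <- withr::local_tempdir()
  tabs <- synthetic_faers(cfg, dir = dir)
  back <- read_faers_quarter(dir, quarter = "SYN1")
  for (tb in c("demo", "drug", "reac", "ther", "indi", "outc", "rpsr")) {
    x <- tabs[[tb]][order(tabs[[tb]]$PRIMARYID), , drop = FALSE]
    y <- back[[tb]][order(back[[tb]]$PRIMARYID), , drop = FALSE]
    rownames(x) <- rownames(y) <- NULL
    expect_equal(x, y, info = tb)
  }
})

test_that("one-row fixture files load into one record per table", {
  dir <- withr::local_tempdir()
  rows <- list(
    demo = "PRIMARYID$CASEID$FDA_DT$EVENT_DT$AGE$AGE_COD$SEX$WT$WT_COD$OCCP_COD$REPORTER_COUNTRY\n101$10$20200101$20191230$55$YR$F$70$KG$MD$US",
    drug = "PRIMARYID$DRUG_SEQ$DRUGNAME$ROLE_COD\n101$1$AVASTIN$PS",
    reac = "PRIMARYID$PT\n101$HYPERTENSION",
    ther = "PRIMARYID$DSG_DRUG_SEQ$START_DT\n101$1$20191201",
    indi = "PRIMARYID$INDI_DRUG_SEQ$INDI_PT\n101$1$GLIOMA",
    outc = "PRIMARYID$OUTC_COD\n101$HO",
    rpsr = "PRIMARYID$RPSR_COD\n101$HP"
  )
  paths <- list()
  for (tb in names(rows)) {
    paths[[tb]] <- file.path(dir, paste0(tb, ".txt"))
    writeLines(rows[[tb]], paths[[tb]])
  }
  tabs <- read_faers_quarter(paths)
  for (tb in names(rows)) expect_identical(nrow(tabs[[tb]]), 1L)
  expect_identical(tabs$drug$DRUGNAME, "AVASTIN")
})

test_that("a DEMO file without PRIMARYID raises a configuration error", {
  dir <- withr::local_tempdir()
  tabs <- synthetic_faers(synthetic_config(n_target_reports = 5,
                                           n_comparator_reports = 5,
                                           seed = 2), dir = dir)
  demo_path <- file.path(dir, "demosyn1.txt")
  demo <- read.table(demo_path, sep = "$", header = TRUE, colClasses = "character")
  names(demo)[names(demo) == "PRIMARYID"] <- "SOMETHING_ELSE"
  write.table(demo, demo_path, sep = "$", quote = FALSE, row.names = FALSE)
  expect_error(read_faers_quarter(dir),
               class = "faersignal_config_error")
  expect_error(read_faers_quarter(dir), "PRIMARYID")
})

test_that("legacy column aliases resolve to canonical names", {
  dir <- withr::local_tempdir()
  writeLines(c("ISR$CASE$FDA_DT$EVENT_DT$AGE$AGE_COD$GNDR_COD$WT$WT_COD$OCCP_COD$REPORTER_COUNTRY",
               "101$10$20100101$$40$YR$M$$$OT$DE"),
             file.path(dir, "demo.txt"))
  for (tb in c("drug", "reac", "ther", "indi", "outc", "rpsr")) {
    hdr <- switch(tb,
                  drug = "ISR$DRUG_SEQ$DRUGNAME$ROLE_COD",
                  reac = "ISR$PT",
                  ther = "ISR$DSG_DRUG_SEQ$START_DT",
                  indi = "ISR$INDI_DRUG_SEQ$INDI_PT",
                  outc = "ISR$OUTC_COD",
                  rpsr = "ISR$RPSR_COD")
    writeLines(hdr, file.path(dir, paste0(tb, ".txt")))
  }
  tabs <- read_faers_quarter(dir)
  expect_true(all(c("PRIMARYID", "CASEID", "SEX") %in% names(tabs$demo)))
  expect_identical(tabs$demo$SEX, "M")
})

test_that("deduplication reproduces the published worked example", {
  demo <- data.frame(
    PRIMARYID = c("43682654", "43693684", "53651284", "54635428"),
    CASEID = c("5657190", "5657190", "5660307", "5660307"),
    FDA_DT = c("20061207", "20061225", "20080302", "20080302"),
    stringsAsFactors = FALSE
  )
  dd <- faers_dedup(demo)
  expect_setequal(dd$kept, c("43693684", "54635428"))
  expect_setequal(dd$dropped, c("43682654", "53651284"))
})

test_that("deduplication matches a brute-force enumeration oracle", {
  set.seed(31)
  n_cases <- 60
  cid <- as.character(sample(1000 + seq_len(n_cases), 150, replace = TRUE))
  pid <- as.character(sample(1e6, 150))
  fdt_num <- sample(seq(as.Date("2010-01-01"), as.Date("2015-12-31"), 1),
                    150, replace = TRUE)
  demo <- data.frame(PRIMARYID = pid, CASEID = cid,
                     FDA_DT = format(fdt_num, "%Y%m%d"),
                     stringsAsFactors = FALSE)
  dd <- faers_dedup(demo)
  expect_identical(sort(dd$kept), oracle_dedup(pid, cid, fdt_num))
  # one report per case, most recent receipt date wins
  expect_identical(length(dd$kept), length(unique(cid)))
})

test_that("deduplication is idempotent and order-invariant", {
  set.seed(7)
  demo <- data.frame(
    PRIMARYID = as.character(sample(1e6, 40)),
    CASEID = as.character(sample(1:12, 40, replace = TRUE)),
    FDA_DT = format(sample(seq(as.Date("2019-01-01"), by = 1, length.out = 400),
                           40, replace = TRUE), "%Y%m%d"),
    stringsAsFactors = FALSE
  )
  dd1 <- faers_dedup(demo)
  shuffled <- demo[sample(nrow(demo)), ]
  expect_identical(sort(faers_dedup(shuffled)$kept), sort(dd1$kept))
  # re-running on the already-kept records changes nothing
  dd2 <- faers_dedup(demo[demo$PRIMARYID %in% dd1$kept, ])
  expect_setequal(dd2$kept, dd1$kept)
  # three versions of one case keep the latest date
  tri <- data.frame(PRIMARYID = c("1", "2", "3"), CASEID = "9",
                    FDA_DT = c("20100101", "20100301", "20100201"))
  expect_identical(faers_dedup(tri)$kept, "2")
})

test_that("records with invalid FDA_DT are quarantined with a reason", {
  demo <- data.frame(PRIMARYID = c("1", "2", "3"), CASEID = c("9", "9", "8"),
                     FDA_DT = c("20100101", "20101340", "2010"),
                     stringsAsFactors = FALSE)
  dd <- faers_dedup(demo)
  expect_identical(dd$kept, "1")
  expect_identical(nrow(dd$quarantined), 2L)
  expect_true(all(dd$quarantined$reason == "invalid FDA_DT"))
})

test_that("multi-quarter PRIMARYID collisions keep the later quarter", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  t1 <- synthetic_faers(synthetic_config(n_target_reports = 10,
                                         n_comparator_reports = 10,
                                         duplicate_rate = 0, seed = 5),
                        dir = dir1)
  t2 <- synthetic_faers(synthetic_config(n_target_reports = 10,
                                         n_comparator_reports = 10,
                                         duplicate_rate = 0, seed = 6),
                        dir = dir2)
  # force a collision: replace one id in quarter 2 with an id from quarter 1
  clash <- t1$demo$PRIMARYID[1]
  old <- t2$demo$PRIMARYID[1]
  for (tb in c("demo", "drug", "reac", "ther", "indi", "outc", "rpsr"))
    t2[[tb]]$PRIMARYID[t2[[tb]]$PRIMARYID == old] <- clash
  t2$demo$SEX[t2$demo$PRIMARYID == clash] <- "F"
  merged <- combine_quarters(list(t1, t2))
  expect_identical(sum(merged$demo$PRIMARYID == clash), 1L)
  expect_identical(merged$demo$SEX[merged$demo$PRIMARYID == clash], "F")
})

test_that("cohort and comparator partition the indication universe", {
  cfg <- lean_config(21, nt = 400, nc = 1600)
  ch <- run_pipeline(synthetic_faers(cfg))
  expect_identical(n_reports(ch$cohort), 400L)
  expect_identical(n_reports(ch$comparator), 1600L)
  expect_length(intersect(ch$cohort$reports$primaryid,
                          ch$comparator$reports$primaryid), 0)
})

test_that("cohort filtering matches a brute-force row filter", {
  # 10 hand-built reports: 4 target-PS-glioma, 1 target-SS-glioma (excluded),
  # 5 other-drug glioma
  demo <- data.frame(
    PRIMARYID = as.character(1:10), CASEID = as.character(1:10),
    FDA_DT = "20200101", EVENT_DT = "", AGE = "", AGE_COD = "", SEX = "",
    WT = "", WT_COD = "", OCCP_COD = "", REPORTER_COUNTRY = "US",
    stringsAsFactors = FALSE
  )
  drug <- data.frame(
    PRIMARYID = as.character(1:10), DRUG_SEQ = "1",
    DRUGNAME = c(rep("Avastin", 4), "BEVACIZUMAB", rep("TEMODAR", 5)),
    ROLE_COD = c(rep("PS", 4), "SS", rep("PS", 5)),
    stringsAsFactors = FALSE
  )
  reac <- data.frame(PRIMARYID = as.character(1:10), PT = "HEADACHE")
  ther <- data.frame(PRIMARYID = character(0), DSG_DRUG_SEQ = character(0),
                     START_DT = character(0))
  indi <- data.frame(PRIMARYID = as.character(1:10), INDI_DRUG_SEQ = "1",
                     INDI_PT = "GLIOMA", stringsAsFactors = FALSE)
  outc <- data.frame(PRIMARYID = character(0), OUTC_COD = character(0))
  rpsr <- data.frame(PRIMARYID = character(0), RPSR_COD = character(0))
  tabs <- structure(list(demo = demo, drug = drug, reac = reac, ther = ther,
                         indi = indi, outc = outc, rpsr = rpsr),
                    quarter = NA, class = "faers_tables")
  cases <- build_case_reports(tabs)
  ch <- build_cohort(cases, "BEVACIZUMAB", role = "PS",
                     indication_pts = "GLIOMA")
  expect_setequal(ch$cohort$reports$primaryid, as.character(1:4))
  # SS-only report 5 is comparator, not cohort
  expect_true("5" %in% ch$comparator$reports$primaryid)
  expect_identical(n_reports(ch$comparator), 6L)
  # empty drug table: everything empty
  tabs$drug <- drug[0, ]; tabs$indi <- indi[0, ]
  ch0 <- build_cohort(build_case_reports(tabs), "BEVACIZUMAB",
                      indication_pts = "GLIOMA")
  expect_identical(n_reports(ch0$cohort), 0L)
  expect_identical(n_reports(ch0$comparator), 0L)
  # empty indication set is a configuration error
  expect_error(build_cohort(cases, "BEVACIZUMAB", indication_pts = character(0)),
               class = "faersignal_config_error")
})

test_that("full-database background uses all non-cohort reports", {
  cfg <- lean_config(22, nt = 200, nc = 800)
  tabs <- synthetic_faers(cfg)
  dd <- faers_dedup(tabs)
  cases <- build_case_reports(tabs, kept = dd$kept)
  ch <- build_cohort(cases, "BEVACIZUMAB", background = "full")
  expect_identical(n_reports(ch$cohort) + n_reports(ch$comparator),
                   length(dd$kept))
})

test_that("demographic categorization applies bins, outliers and units", {
  # age bins, including both edges of every interval
  expect_identical(age_group_of(c(0, 17.9, 18, 44, 45, 50, 64, 65, 120)),
                   c("<18", "<18", "18-44", "18-44", "45-64", "45-64",
                     "45-64", ">=65", ">=65"))
  # missing and outliers go to NS
  expect_identical(age_group_of(c(NA, -1, 130)), c("NS", "NS", "NS"))
  # weight boundary: 80 kg belongs to >=80; >400 kg is an outlier
  expect_identical(weight_group_of(c(79.9, 80, 80.1, 401, NA)),
                   c("<80", ">=80", ">=80", "NS", "NS"))
  # reporter occupation grouping
  expect_identical(reporter_group_of(c("MD", "PH", "RN", "OT", "CN", "LW",
                                       "SALES", "XX", NA)),
                   c(rep("healthcare-professional", 4),
                     rep("consumer-related", 3), "NS", "NS"))
  # unit conversion: decades, months, days; unknown unit warns and drops
  expect_equal(age_to_years(c(5, 24, 365.25), c("DEC", "MON", "DY")),
               c(50, 2, 1))
  expect_warning(out <- age_to_years(10, "QQ"), "unknown age unit")
  expect_true(is.na(out))
})

test_that("partial dates tabulate by year but not by day", {
  expect_identical(faers_year(c("20200615", "202006", "2020", "", "abc")),
                   c(2020L, 2020L, 2020L, NA, NA))
  expect_true(all(is.na(parse_faers_date(c("202006", "2020", "20201350")))))
  expect_identical(parse_faers_date("20200615"), as.Date("2020-06-15"))
})

test_that("categorization is total on generated reports", {
  tabs <- synthetic_faers(synthetic_config(n_target_reports = 300,
                                           n_comparator_reports = 300,
                                           seed = 13))
  cases <- build_case_reports(tabs, kept = faers_dedup(tabs)$kept)
  rp <- cases$reports
  expect_false(any(is.na(rp$sex)))
  expect_false(any(is.na(rp$age_group)))
  expect_false(any(is.na(rp$weight_group)))
  expect_false(any(is.na(rp$reporter_group)))
  expect_true(all(rp$age_group %in% c("<18", "18-44", "45-64", ">=65", "NS")))
})
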