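# Stratified detection, CMH common OR and Breslow-Day-Tarone homogeneity.

test_that("identical strata are perfectly homogeneous", {
  h <- heterogeneity_test(a = c(50, 50), b = c(150, 150),
                          c = c(20, 20), d = c(180, 180))
  expect_equal(h$bd_statistic, 0, tolerance = 1e-8)
  expect_equal(h$p_homogeneity, 1, tolerance = 1e-8)
  # common OR equals the shared stratum OR
  expect_equal(h$cmh_common_or, (50 * 180) / (150 * 20), tolerance = 1e-6)
})

test_that("strata with odds ratios 1 and 10 are detected as heterogeneous", {
  # stratum 1: OR = 1; stratum 2: OR = 10; all cells >= 200
  h <- heterogeneity_test(a = c(200, 400), b = c(200, 200),
                          c = c(200, 200), d = c(200, 1000))
  expect_lt(h$p_homogeneity, 0.05)
  # MH common OR lies between the stratum ORs
  or1 <- 1; or2 <- (400 * 1000) / (200 * 200)
  expect_gt(h$cmh_common_or, min(or1, or2))
  expect_lt(h$cmh_common_or, max(or1, or2))
})

test_that("the Breslow-Day statistic matches a hand computation", {
  # two strata, worked through the defining equations step by step with the
  # MH common OR: solve the quadratic for the expected a-cell, accumulate
  # (a - E)^2 / V, apply Tarone's correction
  a <- c(30, 60); b <- c(70, 40); c <- c(20, 30); d <- c(80, 70)
  n <- a + b + c + d
  psi <- sum(a * d / n) / sum(b * c / n)
  e <- v <- numeric(2)
  for (i in 1:2) {
    A <- 1 - psi
    B <- (a[i] + b[i] + a[i] + c[i]) * psi + (c[i] + d[i] - a[i] - c[i])
    C <- -psi * (a[i] + b[i]) * (a[i] + c[i])
    roots <- c((-B + sqrt(B^2 - 4 * A * C)) / (2 * A),
               (-B - sqrt(B^2 - 4 * A * C)) / (2 * A))
    lo <- max(0, (a[i] + c[i]) - (c[i] + d[i]))
    hi <- min(a[i] + b[i], a[i] + c[i])
    e[i] <- roots[roots >= lo & roots <= hi][1]
    v[i] <- 1 / (1 / e[i] + 1 / (a[i] + b[i] - e[i]) +
                   1 / (a[i] + c[i] - e[i]) +
                   1 / (c[i] + d[i] - a[i] - c[i] + e[i]))
  }
  x2 <- sum((a - e)^2 / v) - sum(a - e)^2 / sum(v)
  expected_p <- pchisq(x2, df = 1, lower.tail = FALSE)
  got <- breslow_day_test(a, b, c, d)
  expect_equal(got$statistic, x2, tolerance = 1e-10)
  expect_equal(got$p_value, expected_p, tolerance = 1e-10)
  expect_equal(got$df, 1)
})

test_that("fewer than two evaluable strata is not evaluable", {
  h <- heterogeneity_test(a = c(10, 0), b = c(90, 0),
                          c = c(5, 0), d = c(95, 0))
  expect_true(is.na(h$p_homogeneity))
  expect_error(breslow_day_test(10, 90, 5, 95),
               class = "faersignal_validation_error")
})

test_that("pooling strata reproduces the overall table exactly", {
  ch <- run_pipeline(synthetic_faers(lean_config(55, nt = 2000, nc = 8000)))
  overall <- contingency_tables(ch$cohort, ch$comparator)
  st <- stratify_and_detect(ch$cohort, ch$comparator, "sex", min_n = 1)
  # sum cells over every stratum (including NS, recounted directly)
  labs <- names(st$strata)
  for (tm in c("HYPERTENSION", "NAUSEA")) {
    tot <- c(a = 0, b = 0, c = 0, d = 0)
    for (lab in labs) {
      s <- st$strata[[lab]]
      if (identical(s$status, "analysed")) {
        i <- match(tm, s$fit$table$term)
        if (!is.na(i))
          tot <- tot + unlist(s$fit$table[i, c("a", "b", "c", "d")])
        else
          tot <- tot + c(a = 0, b = s$n_cohort, c = 0, d = s$n_comparator)
      } else {
        co <- subset(ch$cohort$reports, sex == lab)
        cp <- subset(ch$comparator$reports, sex == lab)
        a_ns <- length(unique(ch$cohort$events$primaryid[
          ch$cohort$events$pt == tm &
            ch$cohort$events$primaryid %in% co$primaryid]))
        c_ns <- length(unique(ch$comparator$events$primaryid[
          ch$comparator$events$pt == tm &
            ch$comparator$events$primaryid %in% cp$primaryid]))
        tot <- tot + c(a_ns, nrow(co) - a_ns, c_ns, nrow(cp) - c_ns)
      }
    }
    i <- match(tm, overall$term)
    expect_equal(unname(tot),
                 unlist(overall[i, c("a", "b", "c", "d")], use.names = FALSE),
                 info = tm)
  }
})

test_that("per-stratum cells equal a brute-force recount", {
  ch <- run_pipeline(synthetic_faers(lean_config(56, nt = 1000, nc = 4000)))
  st <- stratify_and_detect(ch$cohort, ch$comparator, "age_group", min_n = 1)
  for (lab in names(st$strata)) {
    s <- st$strata[[lab]]
    if (!identical(s$status, "analysed")) next
    co_ids <- ch$cohort$reports$primaryid[ch$cohort$reports$age_group == lab]
    cp_ids <- ch$comparator$reports$primaryid[
      ch$comparator$reports$age_group == lab]
    oc <- oracle_cells(
      ch$cohort$events[ch$cohort$events$primaryid %in% co_ids,
                       c("primaryid", "pt")],
      ch$comparator$events[ch$comparator$events$primaryid %in% cp_ids,
                           c("primaryid", "pt")],
      length(co_ids), length(cp_ids))
    m <- merge(s$fit$table, oc, by = "term", suffixes = c("", ".o"))
    expect_equal(m$a, m$a.o, info = lab)
    expect_equal(m$c, m$c.o, info = lab)
  }
})

test_that("the minimum-report rule excludes unstable strata inclusively", {
  # term-level rule: a = 29 excluded, a = 30 retained
  cohort <- make_case_data(
    1:200, data.frame(primaryid = c(1:29, 101:130),
                      pt = rep(c("RARE29", "COMMON30"), c(29, 30))),
    sex = rep(c("F", "M"), each = 100))
  comp <- make_case_data(
    1001:3000, data.frame(primaryid = 1001:1010,
                          pt = rep(c("RARE29", "COMMON30"), 5)),
    sex = rep(c("F", "M"), each = 1000))
  st <- stratify_and_detect(cohort, comp, "sex", min_n = 30)
  f <- st$strata[["F"]]$fit$table   # RARE29 lives in F stratum
  m <- st$strata[["M"]]$fit$table
  expect_true(f$excluded[f$term == "RARE29"])
  expect_false(any(f$ror_pos[f$term == "RARE29"]))
  expect_false(m$excluded[m$term == "COMMON30"])
  # stratum-level variant: a whole stratum of 29 reports is dropped
  small <- make_case_data(1:29, data.frame(primaryid = 1:5, pt = "X"),
                          sex = "F")
  big <- make_case_data(30:200, data.frame(primaryid = 30:40, pt = "X"),
                        sex = "M")
  both <- list(reports = rbind(small$reports, big$reports),
               drugs = small$drugs, indications = small$indications,
               events = rbind(small$events, big$events),
               outcomes = small$outcomes)
  class(both) <- "case_data"
  st2 <- stratify_and_detect(both, make_case_data(500:1000, sex = "M"),
                             "sex", min_n = 30, min_n_on = "stratum")
  expect_identical(st2$strata[["F"]]$status, "excluded")
  expect_identical(st2$strata[["M"]]$status, "analysed")
})

test_that("the NS stratum is descriptive only and unknown variables error", {
  ch <- run_pipeline(synthetic_faers(lean_config(57, nt = 300, nc = 1200)))
  st <- stratify_and_detect(ch$cohort, ch$comparator, "sex")
  expect_identical(st$strata[["NS"]]$status, "descriptive")
  expect_null(st$strata[["NS"]]$fit)
  expect_error(stratify_and_detect(ch$cohort, ch$comparator, "height"),
               class = "faersignal_config_error")
})

test_that("long-format export carries strata, flags and homogeneity p", {
  ch <- run_pipeline(synthetic_faers(lean_config(58, nt = 800, nc = 3200)))
  st <- stratify_and_detect(ch$cohort, ch$comparator, "sex", min_n = 5)
  long <- as.data.frame(st)
  expect_true(all(c("variable", "stratum", "term", "a", "ror",
                    "p_homogeneity") %in% names(long)))
  expect_setequal(unique(long$stratum), c("F", "M"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stratified_table(st, path)
  back <- read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(back), nrow(long))
})
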