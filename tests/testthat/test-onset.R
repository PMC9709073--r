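.onset_fixture <- function() {
  demo <- parse_table(c(
    demo_header,
    demo_line("1000000011", "100000001", event_dt = "20210119"),  # 18 days
    demo_line("1000000021", "100000002", event_dt = "20201231"),  # before start
    demo_line("1000000031", "100000003", event_dt = "20210301"),  # partial start
    demo_line("1000000041", "100000004", event_dt = "202103"),    # partial event
    demo_line("1000000051", "100000005", event_dt = ""),          # no event
    demo_line("1000000061", "100000006", event_dt = "20210401")), # no THER row
    "DEMO")
  drug <- parse_table(c(
    "primaryid$drug_seq$role_cod$drugname$prod_ai",
    paste0("10000000", 1:6, "1$1$PS$NIRAPARIB$NIRAPARIB")), "DRUG")
  ther <- parse_table(c(
    "primaryid$dsg_drug_seq$start_dt",
    "1000000011$1$20210101",
    "1000000021$1$20210101",
    "1000000031$1$202101",
    "1000000041$1$20210101",
    "1000000051$1$20210101"), "THER")
  list(demo = demo, drug = drug, ther = ther)
}

test_that("onset is event minus earliest PS start with reasoned exclusions", {
  f <- .onset_fixture()
  demo <- deduplicate(f$demo)
  cohort <- build_cohort(demo, f$drug, "niraparib")
  rec <- compute_onset(demo, f$ther, cohort)
  expect_equal(rec$onset_days, 18L)
  excl <- attr(rec, "exclusions")
  expect_equal(unname(excl["negative_onset"]), 1L)
  expect_equal(unname(excl["partial_start_date"]), 1L)
  expect_equal(unname(excl["partial_event_date"]), 1L)
  expect_equal(unname(excl["no_event_date"]), 1L)
  expect_equal(unname(excl["no_start_date"]), 1L)
  # every target report is either included or tallied under exactly one reason
  expect_equal(nrow(rec) + sum(excl), length(cohort$target_caseids))
})

test_that("multiple therapy rows use the earliest full-precision start", {
  demo <- parse_table(c(demo_header,
                        demo_line("1000000011", "100000001",
                                  event_dt = "20210301")), "DEMO")
  drug <- parse_table(c("primaryid$drug_seq$role_cod$drugname$prod_ai",
                        "1000000011$1$PS$NIRAPARIB$NIRAPARIB"), "DRUG")
  ther <- parse_table(c("primaryid$dsg_drug_seq$start_dt",
                        "1000000011$1$20210201",
                        "1000000011$1$20210110",
                        "1000000011$1$202012"), "THER")
  cohort <- build_cohort(demo, drug, "niraparib")
  rec <- compute_onset(demo, ther, cohort)
  expect_equal(rec$onset_days, as.integer(as.Date("2021-03-01") -
                                            as.Date("2021-01-10")))
})

test_that("summaries use interpolated quartiles and inclusive 30-day bins", {
  expect_equal(summarize_onset(data.frame(onset_days = c(10, 18, 100)))$median_days, 18)
  s <- summarize_onset(data.frame(onset_days = c(0, 30, 31, 360, 361, 500)))
  expect_equal(s$bins$count[s$bins$bin == "0-30"], 2L)    # 0 and 30 inclusive
  expect_equal(s$bins$count[s$bins$bin == "31-60"], 1L)
  expect_equal(s$bins$count[s$bins$bin == "331-360"], 1L)
  expect_equal(s$bins$count[s$bins$bin == ">360"], 2L)
  expect_equal(sum(s$bins$count), s$n_with_onset)
  expect_lt(abs(sum(s$bins$percent) - 100), 0.05)
  # quartiles follow the linear-interpolation convention
  x <- c(3, 7, 12, 40, 90)
  s2 <- summarize_onset(data.frame(onset_days = x))
  expect_equal(c(s2$q1, s2$median_days, s2$q3),
               unname(quantile(x, c(0.25, 0.5, 0.75), type = 7)))
})

test_that("the empty summary is an explicit marker", {
  s <- summarize_onset(data.frame(onset_days = integer(0)))
  expect_equal(s$n_with_onset, 0L)
  expect_true(is.na(s$median_days))
  expect_true(all(s$bins$count == 0L))
})

test_that("sampled onset medians track the generating exponential", {
  med <- withr::with_seed(77, median(round(rexp(10000, log(2) / 18))))
  s <- summarize_onset(data.frame(onset_days = withr::with_seed(
    77, round(rexp(10000, log(2) / 18)))))
  expect_equal(s$median_days, med)
  expect_lt(abs(s$median_days / 18 - 1), 0.05)
})
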