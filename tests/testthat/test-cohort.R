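test_that("target matching requires the PS role and a word-boundary name hit", {
  t <- tiny_tables()
  demo <- deduplicate(t$demo)
  cohort <- build_cohort(demo, t$drug, c("niraparib", "zejula"))
  # trade name and salt form match; the concomitant-only mention does not
  expect_setequal(cohort$target_caseids,
                  c("100000001", "100000002", "100000003"))
  expect_setequal(cohort$background_caseids, c("100000004", "100000005"))

  drug2 <- parse_table(c("primaryid$drug_seq$role_cod$drugname$prod_ai",
                         "1000000011$1$PS$NIRAPARIBX$NIRAPARIBX"), "DRUG")
  expect_equal(nrow(match_target(drug2, "niraparib")), 0L)
  expect_error(match_target(t$drug, character(0)), "non-empty")
})

test_that("target and background partition the deduplicated cases", {
  co <- simulate_corpus(sim_config(n_reports = 500L, seed = 3L))
  demo <- deduplicate(co$demo)
  cohort <- build_cohort(demo, co$drug, c("niraparib", "zejula"))
  expect_length(intersect(cohort$target_caseids, cohort$background_caseids), 0L)
  expect_setequal(c(cohort$target_caseids, cohort$background_caseids),
                  unique(demo$caseid))
  # generator bookkeeping: exactly the cases whose PS drug is the target
  truth <- names(co$ground_truth$ps_drug[co$ground_truth$ps_drug == "NIRAPARIB"])
  expect_setequal(cohort$target_caseids, truth)
})

test_that("characteristics recover the generator's tallies exactly", {
  co <- simulate_corpus(sim_config(
    n_reports = 10000L, seed = 21L,
    demographics = list(sex = c(F = 0.6, M = 0.4, UNK = 0))))
  demo <- deduplicate(co$demo)
  cohort <- build_cohort(demo, co$drug, "niraparib")
  chars <- summarize_characteristics(cohort, demo, co$outc, co$indi)
  n <- length(cohort$target_caseids)

  d <- demo[demo$caseid %in% cohort$target_caseids, ]
  sex_rows <- chars[chars$category == "sex", ]
  expect_equal(sex_rows$count[sex_rows$level == "Female"], sum(d$sex == "F", na.rm = TRUE))
  expect_equal(sex_rows$count[sex_rows$level == "Male"], sum(d$sex == "M", na.rm = TRUE))
  expect_equal(sum(sex_rows$count), n)
  expect_equal(sex_rows$percent,
               round(100 * sex_rows$count / n, 2))

  # partition categories sum to 100 within rounding slack
  for (cat in c("sex", "age", "reporting_year")) {
    expect_lt(abs(sum(chars$percent[chars$category == cat]) - 100), 0.05)
  }
})

test_that("an empty cohort yields an all-zero summary without errors", {
  t <- tiny_tables()
  demo <- deduplicate(t$demo)
  cohort <- build_cohort(demo, t$drug, "olaparib")
  expect_length(cohort$target_caseids, 0L)
  chars <- summarize_characteristics(cohort, demo)
  expect_true(all(chars$count == 0L))
  expect_true(all(chars$percent == 0))
})

test_that("consumer exclusion removes CN reports from both sets and is idempotent", {
  co <- simulate_corpus(sim_config(n_reports = 5000L, seed = 13L))
  demo <- deduplicate(co$demo)
  cohort <- build_cohort(demo, co$drug, c("niraparib", "zejula"))
  reduced <- exclude_consumers(cohort, demo)
  cn <- demo$caseid[!is.na(demo$occp_cod) & demo$occp_cod == "CN"]
  expect_length(intersect(reduced$target_caseids, cn), 0L)
  expect_length(intersect(reduced$background_caseids, cn), 0L)
  expect_equal(exclude_consumers(reduced, demo), reduced)

  # with the default 77.4% consumer mix roughly 23% of target reports survive
  frac <- length(reduced$target_caseids) / length(cohort$target_caseids)
  expect_lt(abs(frac - 0.226), 0.05)

  # no-op on a corpus without consumer reports
  co2 <- simulate_corpus(sim_config(
    n_reports = 300L, seed = 14L,
    demographics = list(occp = c(MD = 0.8, PH = 0.2, UNK = 0))))
  demo2 <- deduplicate(co2$demo)
  cohort2 <- build_cohort(demo2, co2$drug, "niraparib")
  expect_equal(exclude_consumers(cohort2, demo2), cohort2)
})

test_that("age normalization honours unit codes and plausibility bounds", {
  yrs <- faersignal:::.age_in_years(c("60", "7", "24", "730", "65", "150", "abc"),
                                    c("YR", "DEC", "MON", "DY", NA, NA, "YR"))
  expect_equal(yrs[1:4], c(60, 70, 2, 730 / 365.25))
  expect_equal(yrs[5], 65)       # plausible bare value treated as years
  expect_true(is.na(yrs[6]))     # 150 exceeds any verified human age
  expect_true(is.na(yrs[7]))
})
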