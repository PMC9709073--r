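test_that("parse_table reads well-formed rows and typed role codes", {
  demo <- parse_table(c(demo_header,
                        demo_line("1000000011", "100000001"),
                        demo_line("1000000021", "100000002", sex = "M")),
                      "DEMO")
  expect_equal(nrow(demo), 2L)
  expect_equal(demo$sex, c("F", "M"))
  expect_equal(attr(demo, "parse_log")$n_skipped, 0L)

  drug <- parse_table(c("primaryid$drug_seq$role_cod$drugname$prod_ai",
                        "1000000011$1$PS$NIRAPARIB$NIRAPARIB",
                        "1000000011$2$XX$ASPIRIN$ASPIRIN"), "DRUG")
  expect_equal(drug$role_cod[1L], "PS")
  expect_equal(drug$role_valid, c(TRUE, FALSE))
})

test_that("parse_table tolerates a missing trailing field and accounts for bad rows", {
  lines <- c(demo_header,
             # trailing country dropped entirely (8 fields instead of 9)
             "1000000011$100000001$20210101$$60$YR$F$MD",
             demo_line("1000000021", "100000002"),
             "too$few$fields")
  demo <- parse_table(lines, "DEMO")
  log <- attr(demo, "parse_log")
  expect_equal(nrow(demo), 2L)
  expect_true(is.na(demo$occr_country[1L]))
  expect_equal(log$n_rows, 3L)
  expect_equal(log$n_skipped, 1L)
  expect_equal(log$n_parsed + log$n_skipped, log$n_rows)
})

test_that("parse_table fails fast on an unusable header", {
  expect_error(parse_table("primaryid$caseid", "DEMO"), "unreadable header")
  expect_error(parse_table(character(0), "REAC"), "unreadable header")
})

test_that("parse_date classifies precision and rejects invalid calendars", {
  res <- parse_date(c("20210115", "202101", "2021", "", "20211332",
                      "20210230", "202113", "abc", NA))
  expect_equal(res$precision,
               c("full", "year-month", "year", "absent", "absent", "absent",
                 "absent", "absent", "absent"))
  expect_equal(res$date[1L], as.Date("2021-01-15"))
  expect_equal(res$year[2L], 2021L)
  expect_equal(res$month[2L], 1L)
  # total and idempotent on its own full-date rendering
  rendered <- format(res$date[1L], "%Y%m%d")
  expect_equal(parse_date(rendered)$date, res$date[1L])
})

test_that("deduplicate keeps the latest version per case", {
  demo <- parse_table(c(demo_header,
                        demo_line("1000000011", "100000001", "20200101"),
                        demo_line("1000000012", "100000001", "20210101"),
                        demo_line("1000000021", "100000002", "20200601")),
                      "DEMO")
  kept <- deduplicate(demo)
  expect_equal(sort(kept$primaryid), c("1000000012", "1000000021"))
  expect_false(anyDuplicated(kept$caseid) > 0)
})

test_that("deduplicate breaks receipt-date ties by the larger primaryid", {
  demo <- parse_table(c(demo_header,
                        demo_line("1000000013", "100000001", "20210101"),
                        demo_line("1000000011", "100000001", "20210101")),
                      "DEMO")
  expect_equal(deduplicate(demo)$primaryid, "1000000013")
})

test_that("deduplicate is idempotent and never invents records", {
  co <- simulate_corpus(sim_config(n_reports = 300L, duplicate_rate = 0.2,
                                   seed = 11L))
  once <- deduplicate(co$demo)
  twice <- deduplicate(once)
  expect_equal(twice, once, ignore_attr = TRUE)
  expect_true(all(once$primaryid %in% co$demo$primaryid))
  expect_equal(nrow(once), length(unique(co$demo$caseid)))
  expect_equal(nrow(once), co$ground_truth$n_cases)
  expect_equal(nrow(co$demo) - nrow(once), co$ground_truth$n_injected_duplicates)
})

test_that("tables round-trip through the '$' dialect unchanged", {
  co <- simulate_corpus(sim_config(n_reports = 120L, seed = 7L))
  for (kind in c("demo", "drug", "reac", "ther")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_table(co[[kind]], path)
    back <- parse_table(path, toupper(kind))
    back$role_valid <- NULL  # derived column added at parse time
    expect_equal(back, co[[kind]], ignore_attr = TRUE)
  }
})
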