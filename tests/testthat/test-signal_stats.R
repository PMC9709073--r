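test_that("estimators reproduce hand-computed closed-form values", {
  # symmetric table: all nulls
  expect_equal(compute_ror(10, 10, 10, 10)$ror, 1)
  r <- compute_ror(10, 10, 10, 10)
  expect_equal(log(r$ror_high) + log(r$ror_low), 0)  # symmetric on log scale

  expect_equal(compute_ror(20, 80, 100, 800)$ror, 2)
  expect_equal(compute_prr(20, 80, 100, 800)$prr, 1.8)

  # proportional table: prr 1, chi2 0
  p <- compute_prr(10, 90, 100, 900)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)

  # independence: ic 0, simplified ebgm 1
  expect_equal(compute_ic(10, 90, 90, 810)$ic, 0)
  expect_equal(compute_ebgm(10, 90, 90, 810)$ebgm, 1)

  # N = 10000, a = 10, margins 100: ic = log2(10), ebgm = 10
  expect_equal(compute_ic(10, 90, 90, 9810)$ic, log2(10))
  expect_equal(compute_ebgm(10, 90, 90, 9810)$ebgm, 10)
})

test_that("every statistic matches the independent oracle to 12 significant digits", {
  tabs <- random_tables(250, seed = 99)
  est <- cbind(compute_ror(tabs$a, tabs$b, tabs$c, tabs$d),
               compute_prr(tabs$a, tabs$b, tabs$c, tabs$d),
               compute_ic(tabs$a, tabs$b, tabs$c, tabs$d),
               compute_ebgm(tabs$a, tabs$b, tabs$c, tabs$d))
  for (i in seq_len(nrow(tabs))) {
    o <- oracle_stats(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    for (s in names(o)) {
      # tolerance on the statistic's own scale: near-zero log-scale values
      # (IC of a near-independent table) are compared absolutely
      expect_lt(abs(est[[s]][i] - o[[s]]) / max(abs(o[[s]]), 1), 1e-12)
    }
  }
})

test_that("zero cells yield undefined markers, or finite values under Haldane", {
  expect_true(is.na(compute_ror(0, 100, 50, 1000)$ror))
  expect_true(is.na(compute_prr(5, 100, 0, 1000)$prr))
  h <- compute_ror(0, 100, 50, 1000, haldane = TRUE)
  expect_true(is.finite(h$ror))
  expect_equal(h$ror, (0.5 * 1000.5) / (100.5 * 50.5))
})

test_that("simplified EBGM equals 2^IC for all tables", {
  tabs <- random_tables(200, seed = 4)
  expect_equal(compute_ebgm(tabs$a, tabs$b, tabs$c, tabs$d)$ebgm,
               2^compute_ic(tabs$a, tabs$b, tabs$c, tabs$d)$ic,
               tolerance = 1e-12)
})

test_that("all four statistics increase in a with fixed margins", {
  # margins fixed: a+b, c+d, a+c, b+d constant while a grows
  a <- 10:40; m1 <- 100; m2 <- 10000; mc <- 500
  b <- m1 - a; c <- mc - a; d <- m2 - mc - b
  expect_true(all(diff(compute_ror(a, b, c, d)$ror) > 0))
  expect_true(all(diff(compute_prr(a, b, c, d)$prr) > 0))
  expect_true(all(diff(compute_ic(a, b, c, d)$ic) > 0))
  expect_true(all(diff(compute_ebgm(a, b, c, d)$ebgm) > 0))
})

test_that("PRR and ROR converge as event rates shrink", {
  rates <- 10^seq(-1, -4, length.out = 8)
  gap <- vapply(rates, function(r) {
    a <- 1000 * r * 2; b <- 1000 - a       # target rate 2r
    c <- 100000 * r; d <- 100000 - c       # background rate r
    abs(compute_prr(a, b, c, d)$prr - compute_ror(a, b, c, d)$ror)
  }, 0)
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[length(gap)], 1e-3)
})

test_that("gamma-Poisson shrinkage pulls toward 1 on a null corpus and refuses tiny collections", {
  tabs <- withr::with_seed(42, {
    E <- runif(400, 0.5, 80)
    data.frame(a = rpois(400, E), E = E)
  })
  N <- 5e6
  # embed (a, E) in full tables: margins chosen so (a+b)(a+c)/N = E
  ab <- rep(20000, 400)
  ac <- round(tabs$E * N / ab)
  b <- ab - tabs$a; c <- ac - tabs$a; d <- N - ab - c
  ok <- tabs$a >= 1 & c >= 1
  eb <- compute_ebgm(tabs$a[ok], b[ok], c[ok], d[ok], mode = "shrinkage")
  raw <- compute_ebgm(tabs$a[ok], b[ok], c[ok], d[ok], mode = "simplified")
  # shrinkage: estimates concentrate near 1, never exceeding the raw maximum
  expect_lt(abs(median(eb$ebgm) - 1), 0.15)
  expect_lt(max(eb$ebgm), max(raw$ebgm))
  expect_true(all(eb$ebgm05 <= eb$ebgm))
  # spread of shrunken estimates is tighter than the raw ratios
  expect_lt(stats::sd(log(eb$ebgm)), stats::sd(log(raw$ebgm)))

  expect_error(compute_ebgm(3:12, 100, 50, 1000, mode = "shrinkage"),
               "at least 50")
})

test_that("significance criteria follow each algorithm's rule", {
  th <- default_thresholds()
  est <- data.frame(term = c("Eye disorders", "boundary", "strong", "tiny"),
                    a = c(551, 100, 500, 2),
                    ror_low = c(1.02, 1.0, 5, 9),
                    prr = c(1.10, 2.5, 8, 9),
                    chi2 = c(5.53, 10, 900, 50),
                    ic025 = c(0.01, -0.1, 2, 3),
                    ebgm05 = c(1.01, 1.5, 6, 9))
  fl <- apply_criteria(est, th, label_terms = "eye disorders")
  # published SOC-style row: ROR and IC flag, PRR and EBGM do not
  expect_equal(unlist(fl[1, c("ror_sig", "prr_sig", "ic_sig", "ebgm_sig")]),
               c(ror_sig = TRUE, prr_sig = FALSE, ic_sig = TRUE,
                 ebgm_sig = FALSE))
  expect_true(fl$expected[1])
  # lower bound exactly 1 is not a signal (strict inequality)
  expect_false(fl$ror_sig[2])
  expect_true(fl$all_four[3])
  # a below min_a blocks ROR/PRR but not IC/EBGM
  expect_false(fl$ror_sig[4])
  expect_false(fl$prr_sig[4])
  expect_true(fl$ic_sig[4])
  expect_equal(fl$all_four, with(fl, ror_sig & prr_sig & ic_sig & ebgm_sig))
})

test_that("thresholds round-trip through the YAML config", {
  th <- read_thresholds(system.file("extdata", "demo_thresholds.yaml",
                                    package = "faersignal"))
  expect_equal(th, default_thresholds())
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("nonsense: 1", bad)
  expect_error(read_thresholds(bad), "unknown threshold key")
})
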