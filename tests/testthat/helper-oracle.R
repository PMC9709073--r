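# Independently coded evaluation of the four estimators, used as the oracle
# against the package implementation. Deliberately written via a different
# route: odds computed cell-wise, chi-squared delegated to
# stats::chisq.test, logs accumulated term by term.
oracle_stats <- function(a, b, c, d, ebgm_z = 1.645) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  odds_target <- a / b
  odds_background <- c / d
  ror <- odds_target / odds_background
  se <- sqrt(sum(1 / c(a, b, c, d)))
  ror_low <- exp(log(ror) - stats::qnorm(0.975) * se)
  ror_high <- exp(log(ror) + stats::qnorm(0.975) * se)
  rate_target <- a / (a + b)
  rate_background <- c / (c + d)
  prr <- rate_target / rate_background
  chi2 <- unname(suppressWarnings(stats::chisq.test(
    matrix(c(a, c, b, d), nrow = 2), correct = FALSE)$statistic))
  ic <- (log(a) + log(N) - log(a + b) - log(a + c)) / log(2)
  v <- 1 / a - 1 / (a + b) - 1 / (a + c) + 1 / N
  ic025 <- ic - 1.96 * sqrt(max(v, 0)) / log(2)
  ebgm <- 2^ic
  ebgm05 <- ebgm * exp(-ebgm_z * se)
  list(ror = ror, ror_low = ror_low, ror_high = ror_high, prr = prr,
       chi2 = chi2, ic = ic, ic025 = ic025, ebgm = ebgm, ebgm05 = ebgm05)
}

# random strictly positive 2x2 tables for property tests
random_tables <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    a = sample(1:500, n, replace = TRUE),
    b = sample(1:20000, n, replace = TRUE),
    c = sample(1:5000, n, replace = TRUE),
    d = sample(1:2000000, n, replace = TRUE)))
}

# minimal hand-written DEMO lines in the FAERS dialect
demo_header <- "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$occr_country"
demo_line <- function(primaryid, caseid, fda_dt = "20210101",
                      event_dt = "", age = "60", age_cod = "YR", sex = "F",
                      occp_cod = "MD", country = "US") {
  paste(primaryid, caseid, fda_dt, event_dt, age, age_cod, sex, occp_cod,
        country, sep = "$")
}

# small in-memory table set for cohort/contingency unit tests: three target
# reports (one via trade name, one salt form), two background
tiny_tables <- function() {
  demo <- parse_table(c(
    demo_header,
    demo_line("1000000011", "100000001", "20200101", "20200120"),
    demo_line("1000000021", "100000002", "20200201", occp_cod = "CN"),
    demo_line("1000000031", "100000003", "20200301"),
    demo_line("1000000041", "100000004", "20200401", occp_cod = "CN"),
    demo_line("1000000051", "100000005", "20200501")), "DEMO")
  drug <- parse_table(c(
    "primaryid$drug_seq$role_cod$drugname$prod_ai",
    "1000000011$1$PS$NIRAPARIB$NIRAPARIB",
    "1000000021$1$PS$ZEJULA$NIRAPARIB",
    "1000000031$1$PS$NIRAPARIB TOSYLATE MONOHYDRATE$NIRAPARIB",
    "1000000031$2$C$ASPIRIN$ASPIRIN",
    "1000000041$1$PS$METFORMIN$METFORMIN",
    "1000000041$2$C$NIRAPARIB$NIRAPARIB",
    "1000000051$1$PS$IBUPROFEN$IBUPROFEN"), "DRUG")
  reac <- parse_table(c(
    "primaryid$pt",
    "1000000011$Nausea",
    "1000000011$Nausea",
    "1000000011$Vomiting",
    "1000000021$Nausea",
    "1000000031$Anaemia",
    "1000000041$Nausea",
    "1000000051$Headache"), "REAC")
  list(demo = demo, drug = drug, reac = reac)
}
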