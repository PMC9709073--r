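# Default preferred-term vocabulary for simulated corpora: background
# mention probability per report and SOC assignment. Rates span the range
# seen for common and rare terms in spontaneous-report corpora.
.default_pt_vocabulary <- function() {
  v <- rbind(
    c("Anaemia",                  "Blood and lymphatic system disorders", 0.060),
    c("Thrombocytopenia",         "Blood and lymphatic system disorders", 0.032),
    c("Neutropenia",              "Blood and lymphatic system disorders", 0.024),
    c("Nausea",                   "Gastrointestinal disorders",           0.320),
    c("Vomiting",                 "Gastrointestinal disorders",           0.160),
    c("Constipation",             "Gastrointestinal disorders",           0.080),
    c("Diarrhoea",                "Gastrointestinal disorders",           0.200),
    c("Abdominal pain",           "Gastrointestinal disorders",           0.120),
    c("Fatigue",                  "General disorders and administration site conditions", 0.280),
    c("Asthenia",                 "General disorders and administration site conditions", 0.120),
    c("Malaise",                  "General disorders and administration site conditions", 0.080),
    c("Drug ineffective",         "General disorders and administration site conditions", 0.350),
    c("Headache",                 "Nervous system disorders",             0.200),
    c("Dizziness",                "Nervous system disorders",             0.160),
    c("Neuropathy peripheral",    "Nervous system disorders",             0.032),
    c("Memory impairment",        "Nervous system disorders",             0.020),
    c("Platelet count decreased", "Investigations",                       0.024),
    c("Blood pressure increased", "Investigations",                       0.040),
    c("Weight decreased",         "Investigations",                       0.048),
    c("Heart rate increased",     "Investigations",                       0.028),
    c("Insomnia",                 "Psychiatric disorders",                0.080),
    c("Anxiety",                  "Psychiatric disorders",                0.072),
    c("Emotional distress",       "Psychiatric disorders",                0.024),
    c("Rash",                     "Skin and subcutaneous tissue disorders", 0.120),
    c("Pruritus",                 "Skin and subcutaneous tissue disorders", 0.080),
    c("Photosensitivity reaction","Skin and subcutaneous tissue disorders", 0.012),
    c("Hypertension",             "Vascular disorders",                   0.060),
    c("Hot flush",                "Vascular disorders",                   0.028),
    c("Dyspnoea",                 "Respiratory, thoracic and mediastinal disorders", 0.100),
    c("Cough",                    "Respiratory, thoracic and mediastinal disorders", 0.080),
    c("Arthralgia",               "Musculoskeletal and connective tissue disorders", 0.080),
    c("Back pain",                "Musculoskeletal and connective tissue disorders", 0.060),
    c("Renal impairment",         "Renal and urinary disorders",          0.020),
    c("Palpitations",             "Cardiac disorders",                    0.032),
    c("Tachycardia",              "Cardiac disorders",                    0.024)
  )
  data.frame(pt = v[, 1L], soc = v[, 2L],
             base_rate = as.numeric(v[, 3L]), stringsAsFactors = FALSE)
}

.default_drugs <- function() {
  data.frame(
    name = c("NIRAPARIB", "CARBOPLATIN", "PACLITAXEL", "BEVACIZUMAB",
             "METFORMIN", "LISINOPRIL", "ATORVASTATIN", "IBUPROFEN"),
    prob = c(0.15, 0.20, 0.18, 0.12, 0.25, 0.22, 0.25, 0.30),
    stringsAsFactors = FALSE)
}

#' Configure a synthetic spontaneous-report corpus
#'
#' Defines the generative model behind [simulate_corpus()]: each report
#' includes each drug independently with its marginal probability (an empty
#' draw is backfilled with one weighted sample); the designated target drug
#' takes role PS when present, otherwise the first included drug does;
#' preferred terms are then drawn independently per PT with probability
#' `base_rate * rr(PS drug, PT)`, capped at 1 — the implicit null model of
#' 2x2 disproportionality, with no PT-PT correlation. Demographics default
#' to the mix typical of an oncology spontaneous-report cohort: mostly
#' female, largely consumer-reported (77%), mostly US. Onset times are
#' exponential with a median of 18 days, observed at day precision for
#' roughly 37% of reports.
#'
#' @param n_reports number of deduplicated cases to emit.
#' @param drugs data frame `name`, `prob` (marginal inclusion probability).
#' @param target name of the target drug (must appear in `drugs`).
#' @param pt_vocabulary data frame `pt`, `soc`, `base_rate`.
#' @param rr data frame `drug`, `pt`, `rr` of true relative risks; pairs not
#'   listed have RR 1.
#' @param demographics list overriding any of `sex`, `occp`, `country`
#'   (named probability vectors; the name `UNK` denotes a missing field),
#'   `age_meanlog`, `age_sdlog`, `age_missing`, `outcomes`.
#' @param duplicate_rate fraction of cases also emitted as a stale earlier
#'   version (exercises deduplication).
#' @param onset_median_days median of the exponential onset model.
#' @param onset_obs_frac fraction of target-style reports with full-precision
#'   event and start dates.
#' @param date_error_rate fraction of dated reports whose event date is an
#'   input error (precedes the start date).
#' @param trade_name_frac fraction of target mentions written under the
#'   trade name; a further tenth use a salt-form suffix.
#' @param date_range character vector of two dates bounding receipt dates.
#' @param seed integer RNG seed; one stream drives the whole corpus, so a
#'   given config is byte-reproducible.
#' @return A `faers_sim_config` list.
#' @export
sim_config <- function(n_reports = 2000L,
                       drugs = .default_drugs(),
                       target = "NIRAPARIB",
                       pt_vocabulary = .default_pt_vocabulary(),
                       rr = NULL,
                       demographics = list(),
                       duplicate_rate = 0.05,
                       onset_median_days = 18,
                       onset_obs_frac = 0.37,
                       date_error_rate = 0.01,
                       trade_name_frac = 0.30,
                       date_range = c("2017-01-01", "2021-12-31"),
                       seed = 1L) {
  stopifnot(n_reports >= 1, target %in% drugs$name, nrow(pt_vocabulary) >= 1,
            all(drugs$prob >= 0 & drugs$prob <= 1),
            all(pt_vocabulary$base_rate >= 0 & pt_vocabulary$base_rate <= 1),
            duplicate_rate >= 0, duplicate_rate <= 1)
  demo_defaults <- list(
    sex = c(F = 0.785, M = 0.018, UNK = 0.197),
    occp = c(CN = 0.774, MD = 0.140, OT = 0.038, HP = 0.016, PH = 0.010,
             LW = 0.001, UNK = 0.021),
    country = c(US = 0.873, JP = 0.024, CA = 0.018, FR = 0.016, GB = 0.014,
                DE = 0.055),
    age_meanlog = log(60), age_sdlog = 0.18, age_missing = 0.638,
    outcomes = c(DE = 0.066, DS = 0.003, HO = 0.223, LT = 0.051, OT = 0.467)
  )
  dm <- utils::modifyList(demo_defaults, demographics)
  if (!is.null(rr)) {
    stopifnot(all(c("drug", "pt", "rr") %in% names(rr)), all(rr$rr >= 0),
              all(rr$drug %in% drugs$name), all(rr$pt %in% pt_vocabulary$pt))
  }
  structure(list(
    n_reports = as.integer(n_reports), drugs = drugs, target = target,
    pt_vocabulary = pt_vocabulary, rr = rr, demographics = dm,
    duplicate_rate = duplicate_rate, onset_median_days = onset_median_days,
    onset_obs_frac = onset_obs_frac, date_error_rate = date_error_rate,
    trade_name_frac = trade_name_frac, date_range = as.Date(date_range),
    seed = as.integer(seed)
  ), class = "faers_sim_config")
}

.sample_mix <- function(n, mix) {
  lv <- sample(names(mix), n, replace = TRUE, prob = mix)
  ifelse(lv == "UNK", NA_character_, lv)
}

#' Generate a FAERS-dialect corpus with known ground truth
#'
#' Draws `n_reports` deduplicated cases under the model of [sim_config()],
#' then injects stale case versions at the configured duplicate rate so the
#' emitted DEMO table contains more rows than cases. All six FAERS tables
#' are produced in memory as data frames parseable/writable by the I/O
#' layer ([write_corpus()] emits the '$'-delimited files). A single seeded
#' RNG stream drives every draw, so the same config always yields the same
#' corpus.
#'
#' @param config a `faers_sim_config`.
#' @return A `faers_corpus`: list of data frames `demo`, `drug`, `reac`,
#'   `outc`, `indi`, `ther`, plus `ground_truth` (true RR matrix, base
#'   rates, duplicate caseids, demographic and onset parameters, probability
#'   cap violations) and the `config`.
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  drugs <- config$drugs
  vocab <- config$pt_vocabulary
  K <- nrow(drugs); P <- nrow(vocab)
  tgt <- match(config$target, drugs$name)

  # --- true relative-risk matrix (drug x PT), default 1
  R <- matrix(1, K, P, dimnames = list(drugs$name, vocab$pt))
  if (!is.null(config$rr)) {
    R[cbind(match(config$rr$drug, drugs$name),
            match(config$rr$pt, vocab$pt))] <- config$rr$rr
  }

  # --- drug sets and the primary-suspect drug
  inc <- matrix(runif(n * K), n, K) < rep(drugs$prob, each = n)
  empty <- !rowSums(inc)
  if (any(empty)) {
    inc[cbind(which(empty),
              sample(K, sum(empty), replace = TRUE, prob = drugs$prob))] <- TRUE
  }
  ps <- ifelse(inc[, tgt], tgt, apply(inc, 1L, which.max))

  # --- PT mentions: Bernoulli(base * rr[ps]) per term, >=1 term per report
  p_raw <- matrix(vocab$base_rate, n, P, byrow = TRUE) * R[ps, , drop = FALSE]
  cap_violations <- sum(p_raw > 1)
  mention <- matrix(runif(n * P), n, P) < pmin(p_raw, 1)
  none <- !rowSums(mention)
  if (any(none)) {
    mention[cbind(which(none),
                  sample(P, sum(none), replace = TRUE,
                         prob = vocab$base_rate))] <- TRUE
  }

  # --- identifiers: caseid, with the kept version numbered 2 for cases that
  # also get a stale version 1
  caseid <- sprintf("%08d", 10000000L + seq_len(n))
  dup <- runif(n) < config$duplicate_rate
  version <- ifelse(dup, 2L, 1L)
  primaryid <- paste0(caseid, version)

  # --- demographics and dates
  dm <- config$demographics
  sex <- .sample_mix(n, dm$sex)
  occp <- .sample_mix(n, dm$occp)
  country <- .sample_mix(n, dm$country)
  age <- round(stats::rlnorm(n, dm$age_meanlog, dm$age_sdlog))
  age_missing <- runif(n) < dm$age_missing
  age_chr <- ifelse(age_missing, NA_character_, as.character(age))
  age_cod <- ifelse(age_missing, NA_character_, "YR")

  span <- as.integer(config$date_range[2L] - config$date_range[1L])
  fda <- config$date_range[1L] + floor(runif(n) * (span + 1L))
  start <- fda - floor(runif(n) * 90)
  onset_rate <- log(2) / config$onset_median_days
  onset_days <- round(rexp(n, onset_rate))
  event <- start + onset_days
  err <- runif(n) < config$date_error_rate
  event[err] <- start[err] - (1L + floor(runif(sum(err)) * 30))

  fmt <- function(d) format(d, "%Y%m%d")
  # degrade dates outside the observed fraction: event absent or partial,
  # or start absent (no THER row) or partial
  u <- runif(n)
  obs <- u < config$onset_obs_frac
  deg <- findInterval((u - config$onset_obs_frac) / (1 - config$onset_obs_frac),
                      c(0, 0.5, 0.7, 0.85)) * !obs
  event_chr <- fmt(event)
  event_chr[deg == 1L] <- NA_character_
  event_chr[deg == 2L] <- format(event[deg == 2L], "%Y%m")
  start_chr <- fmt(start)
  start_chr[deg == 4L] <- format(start[deg == 4L], "%Y%m")
  has_ther <- deg != 3L

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, fda_dt = fmt(fda),
    event_dt = event_chr, age = age_chr, age_cod = age_cod, sex = sex,
    occp_cod = occp, occr_country = country, stringsAsFactors = FALSE)

  # --- DRUG rows: PS drug first (seq 1), other included drugs after
  drug_rows <- function(pid) {
    ord <- lapply(seq_len(n), function(i) {
      others <- setdiff(which(inc[i, ]), ps[i])
      c(ps[i], others)
    })
    k <- lengths(ord)
    i_rep <- rep(seq_len(n), k)
    di <- unlist(ord, use.names = FALSE)
    seq_in <- sequence(k)
    role <- ifelse(seq_in == 1L, "PS",
                   sample(c("SS", "C", "I"), length(di), replace = TRUE,
                          prob = c(0.2, 0.75, 0.05)))
    name <- drugs$name[di]
    is_t <- di == tgt
    u2 <- runif(length(di))
    name[is_t & u2 < config$trade_name_frac] <- "ZEJULA"
    name[is_t & u2 >= 0.9] <- "NIRAPARIB TOSYLATE MONOHYDRATE"
    data.frame(primaryid = pid[i_rep], drug_seq = as.character(seq_in),
               role_cod = role, drugname = name,
               prod_ai = drugs$name[di], stringsAsFactors = FALSE)
  }
  drug_tab <- drug_rows(primaryid)

  # --- REAC rows
  hit <- which(mention, arr.ind = TRUE)
  reac <- data.frame(primaryid = primaryid[hit[, 1L]],
                     pt = vocab$pt[hit[, 2L]], stringsAsFactors = FALSE)
  reac <- reac[order(match(reac$primaryid, primaryid), reac$pt), ]
  rownames(reac) <- NULL

  # --- OUTC rows (independent per code; a report may have several)
  oc <- names(dm$outcomes)
  om <- matrix(runif(n * length(oc)), n) < rep(dm$outcomes, each = n)
  ohit <- which(om, arr.ind = TRUE)
  outc <- data.frame(primaryid = primaryid[ohit[, 1L]],
                     outc_cod = oc[ohit[, 2L]], stringsAsFactors = FALSE)
  outc <- outc[order(match(outc$primaryid, primaryid), outc$outc_cod), ]
  rownames(outc) <- NULL

  # --- INDI rows for the PS drug
  onc_ind <- c("Ovarian cancer" = 0.62, "Fallopian tube cancer" = 0.05,
               "Malignant peritoneal neoplasm" = 0.05,
               "Uterine cancer" = 0.02, "Breast cancer" = 0.06,
               "Product used for unknown indication" = 0.20)
  gen_ind <- c("Hypertension" = 0.25, "Diabetes mellitus" = 0.25,
               "Pain" = 0.25, "Product used for unknown indication" = 0.25)
  ind <- character(n)
  is_tgt_rep <- ps == tgt
  ind[is_tgt_rep] <- sample(names(onc_ind), sum(is_tgt_rep), replace = TRUE,
                            prob = onc_ind)
  ind[!is_tgt_rep] <- sample(names(gen_ind), sum(!is_tgt_rep), replace = TRUE,
                             prob = gen_ind)
  indi <- data.frame(primaryid = primaryid, indi_drug_seq = "1",
                     indi_pt = ind, stringsAsFactors = FALSE)

  # --- THER rows for the PS drug
  ther <- data.frame(primaryid = primaryid[has_ther], dsg_drug_seq = "1",
                     start_dt = start_chr[has_ther], stringsAsFactors = FALSE)

  # --- stale duplicate versions: same case, version 1, earlier receipt date
  if (any(dup)) {
    di <- which(dup)
    stale_pid <- paste0(caseid[di], 1L)
    stale_demo <- demo[di, , drop = FALSE]
    stale_demo$primaryid <- stale_pid
    stale_demo$fda_dt <- fmt(fda[di] - (30L + floor(runif(length(di)) * 120)))
    demo <- rbind(demo, stale_demo)
    stale_drug <- drug_tab[drug_tab$primaryid %in% primaryid[di], , drop = FALSE]
    stale_drug$primaryid <- paste0(substr(stale_drug$primaryid, 1L, 8L), 1L)
    drug_tab <- rbind(drug_tab, stale_drug)
    stale_reac <- reac[reac$primaryid %in% primaryid[di], , drop = FALSE]
    stale_reac$primaryid <- paste0(substr(stale_reac$primaryid, 1L, 8L), 1L)
    reac <- rbind(reac, stale_reac)
  }
  rownames(demo) <- rownames(drug_tab) <- rownames(reac) <- NULL

  truth <- list(
    rr = R, base_rates = setNames(vocab$base_rate, vocab$pt),
    soc = setNames(vocab$soc, vocab$pt),
    target = config$target, n_cases = n,
    n_injected_duplicates = sum(dup), duplicate_caseids = caseid[dup],
    ps_drug = setNames(drugs$name[ps], caseid),
    true_onset_days = setNames(onset_days, caseid),
    onset_rate = onset_rate, demographics = dm,
    cap_violations = cap_violations)

  structure(list(demo = demo, drug = drug_tab, reac = reac, outc = outc,
                 indi = indi, ther = ther, ground_truth = truth,
                 config = config),
            class = "faers_corpus")
}

#' @export
print.faers_corpus <- function(x, ...) {
  cat("Synthetic FAERS corpus:", x$ground_truth$n_cases, "cases (",
      nrow(x$demo), "DEMO rows incl.", x$ground_truth$n_injected_duplicates,
      "stale versions )\n")
  invisible(x)
}

#' Write a corpus as FAERS-dialect files
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `OUTC.txt`, `INDI.txt`,
#' `THER.txt` in the '$'-delimited dialect consumed by [parse_table()] /
#' [read_faers_dir()]. Output is byte-deterministic for a given corpus.
#'
#' @param corpus a `faers_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in c("demo", "drug", "reac", "outc", "indi", "ther")) {
    write_table(corpus[[kind]], file.path(dir, paste0(toupper(kind), ".txt")))
  }
  invisible(dir)
}

#' Write the PT-to-SOC mapping of a simulated corpus
#'
#' @param corpus a `faers_corpus`.
#' @param path CSV output path (columns `pt`, `soc`).
#' @return the mapping data frame, invisibly written to `path` when given.
#' @export
corpus_soc_map <- function(corpus, path = NULL) {
  m <- data.frame(pt = corpus$config$pt_vocabulary$pt,
                  soc = corpus$config$pt_vocabulary$soc,
                  stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(m, path, row.names = FALSE)
  invisible(m)
}

#' Deterministic ~200-report regression corpus
#'
#' A small fixed corpus with two planted signals on the target drug
#' (Thrombocytopenia RR 12, Nausea RR 6), a 10% stale-version rate and a
#' fixed seed, used for golden-file and hand-audited counting tests. The
#' same call always regenerates byte-identical tables.
#'
#' @return A `faers_corpus`.
#' @export
regression_fixture <- function() {
  cfg <- sim_config(
    n_reports = 200L,
    rr = data.frame(drug = "NIRAPARIB",
                    pt = c("Thrombocytopenia", "Nausea"),
                    rr = c(12, 6), stringsAsFactors = FALSE),
    duplicate_rate = 0.10,
    seed = 8675309L)
  simulate_corpus(cfg)
}
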