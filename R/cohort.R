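#' Normalize a drug or event term for matching
#'
#' Trims, case-folds to lower case, and collapses internal whitespace runs to
#' a single space. All name and label matching in the package goes through
#' this normalization, so `"  ZEJULA  "` and `"zejula"` compare equal.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Match target-drug primary-suspect mentions
#'
#' A drug row matches when its role code is PS (primary suspect) and its
#' normalized `drugname` or `prod_ai` contains one of the normalized target
#' names as a word-boundary substring — so the salt form
#' `"NIRAPARIB TOSYLATE MONOHYDRATE"` matches the name `"niraparib"`, but
#' `"niraparibx"` does not.
#'
#' @param drug a DRUG data frame from [parse_table()].
#' @param names non-empty character vector of target names (generic and
#'   trade names).
#' @return The matching rows of `drug` (columns `primaryid`, `drug_seq`,
#'   `role_cod`, `drugname`, `prod_ai`).
#' @export
match_target <- function(drug, names) {
  if (length(names) == 0L || all(!nzchar(trimws(names)))) {
    stop("target name list must be non-empty")
  }
  pats <- paste0("\\b",
                 gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", normalize_term(names)),
                 "\\b")
  nm1 <- normalize_term(drug$drugname)
  nm2 <- if ("prod_ai" %in% base::names(drug)) normalize_term(drug$prod_ai) else NA_character_
  hit <- rep(FALSE, nrow(drug))
  for (p in pats) {
    hit <- hit | grepl(p, nm1, perl = TRUE) |
      (!is.na(nm2) & grepl(p, nm2, perl = TRUE))
  }
  hit <- hit & !is.na(drug$role_cod) & drug$role_cod == "PS"
  keep <- c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai")
  out <- drug[hit, intersect(keep, base::names(drug)), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the target-drug cohort and background set
#'
#' Partitions the deduplicated case set into target reports (at least one
#' primary-suspect mention of a target name) and background reports (all
#' other deduplicated cases). Every deduplicated case lands in exactly one
#' of the two sets.
#'
#' @param demo deduplicated DEMO data frame (see [deduplicate()]).
#' @param drug DRUG data frame.
#' @param target_names character vector of generic/trade names.
#' @return An object of class `faers_cohort`: a list with `target_caseids`,
#'   `background_caseids`, `name_list`, and `matches` (data frame
#'   `primaryid`, `caseid`, `drug_seq` of the matched PS mentions of kept
#'   case versions, used to link INDI/THER rows).
#' @export
build_cohort <- function(demo, drug, target_names) {
  matched <- match_target(drug, target_names)
  # restrict to kept case versions
  matched <- matched[matched$primaryid %in% demo$primaryid, , drop = FALSE]
  caseid_of <- setNames(demo$caseid, demo$primaryid)
  matched$caseid <- unname(caseid_of[matched$primaryid])
  target <- unique(matched$caseid)
  background <- setdiff(unique(demo$caseid), target)
  structure(list(
    target_caseids = target,
    background_caseids = background,
    name_list = target_names,
    matches = matched[, c("primaryid", "caseid", "drug_seq")]
  ), class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("FAERS cohort:", length(x$target_caseids), "target /",
      length(x$background_caseids), "background reports\n")
  cat("  target names:", paste(x$name_list, collapse = ", "), "\n")
  invisible(x)
}

#' Remove consumer-submitted reports (sensitivity variant)
#'
#' Drops reports whose reporter occupation code is CN (consumer) from both
#' the target and the background set, so every downstream statistic can be
#' recomputed on the professional-report subset. Idempotent.
#'
#' @param cohort a `faers_cohort`.
#' @param demo the deduplicated DEMO table the cohort was built on.
#' @return A reduced `faers_cohort`.
#' @export
exclude_consumers <- function(cohort, demo) {
  cn <- demo$caseid[!is.na(demo$occp_cod) & demo$occp_cod == "CN"]
  cohort$target_caseids <- setdiff(cohort$target_caseids, cn)
  cohort$background_caseids <- setdiff(cohort$background_caseids, cn)
  cohort$matches <- cohort$matches[cohort$matches$caseid %in%
                                     cohort$target_caseids, , drop = FALSE]
  cohort
}

# Convert reported age to years using the FAERS unit code. A missing unit
# with a humanly plausible value (0-122, bounded by the oldest verified
# human age) is taken as years.
.age_in_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  u <- toupper(ifelse(is.na(age_cod), "", age_cod))
  yrs <- rep(NA_real_, length(a))
  yrs[u == "YR"] <- a[u == "YR"]
  yrs[u == "DEC"] <- a[u == "DEC"] * 10
  yrs[u == "MON"] <- a[u == "MON"] / 12
  yrs[u == "WK"] <- a[u == "WK"] / 52.14
  yrs[u == "DY"] <- a[u == "DY"] / 365.25
  plausible <- u == "" & !is.na(a) & a >= 0 & a <= 122
  yrs[plausible] <- a[plausible]
  yrs
}

.char_row <- function(category, level, count, n) {
  data.frame(category = category, level = level, count = as.integer(count),
             percent = if (n > 0) round(100 * count / n, 2) else 0,
             stringsAsFactors = FALSE)
}

#' Descriptive characteristics of a report cohort
#'
#' Tabulates the target cohort the way pharmacovigilance papers present
#' their first table: sex, age bands, top indications, serious outcomes,
#' top reporter countries, reporter occupation, and reporting year. Counts
#' are per report; a report with several outcome codes contributes to each
#' outcome row, so outcome rows need not sum to the cohort size, while sex,
#' age and year partition the cohort exactly.
#'
#' @param cohort a `faers_cohort`.
#' @param demo deduplicated DEMO table.
#' @param outc OUTC table (may be `NULL`).
#' @param indi INDI table (may be `NULL`); indications are read only from
#'   rows linked to a matched primary-suspect drug sequence.
#' @param top_k_indications,top_k_countries how many leading levels to list.
#' @return A data frame `category`, `level`, `count`, `percent` (percent of
#'   cohort size, 2 decimals).
#' @export
summarize_characteristics <- function(cohort, demo, outc = NULL, indi = NULL,
                                      top_k_indications = 4L,
                                      top_k_countries = 5L) {
  d <- demo[demo$caseid %in% cohort$target_caseids, , drop = FALSE]
  n <- nrow(d)
  out <- list()

  sex <- ifelse(is.na(d$sex), "Unknown",
                ifelse(d$sex == "F", "Female",
                       ifelse(d$sex == "M", "Male", "Unknown")))
  for (lv in c("Female", "Male", "Unknown")) {
    out[[length(out) + 1L]] <- .char_row("sex", lv, sum(sex == lv), n)
  }

  yrs <- .age_in_years(d$age, d$age_cod)
  band <- ifelse(is.na(yrs), "Unknown or missing",
                 ifelse(yrs < 40, "<40",
                        ifelse(yrs <= 50, "40-50", ">50")))
  for (lv in c("<40", "40-50", ">50", "Unknown or missing")) {
    out[[length(out) + 1L]] <- .char_row("age", lv, sum(band == lv), n)
  }

  if (!is.null(indi) && nrow(cohort$matches) > 0L && nrow(indi) > 0L) {
    key <- paste(cohort$matches$primaryid, cohort$matches$drug_seq)
    link <- paste(indi$primaryid, indi$indi_drug_seq)
    ipt <- indi$indi_pt[link %in% key & !is.na(indi$indi_pt)]
    # one indication count per report and term
    ipt_case <- unique(data.frame(
      caseid = setNames(demo$caseid, demo$primaryid)[indi$primaryid[link %in% key & !is.na(indi$indi_pt)]],
      term = ipt, stringsAsFactors = FALSE))
    tab <- sort(table(ipt_case$term), decreasing = TRUE)
    for (lv in names(head(tab, top_k_indications))) {
      out[[length(out) + 1L]] <- .char_row("indication", lv, tab[[lv]], n)
    }
  }

  if (!is.null(outc) && nrow(outc) > 0L) {
    oc <- outc[outc$primaryid %in% d$primaryid, , drop = FALSE]
    per_case <- unique(data.frame(primaryid = oc$primaryid, code = oc$outc_cod,
                                  stringsAsFactors = FALSE))
    cnt <- function(codes) sum(per_case$code %in% codes)
    # Five outcome rows; congenital anomaly (CA) and required intervention
    # (RI) are folded into the catch-all serious row.
    rows <- list(c("Death", "DE"), c("Disability", "DS"),
                 c("Hospitalization-initial or prolonged", "HO"),
                 c("Life-threatening", "LT"))
    for (r in rows) {
      out[[length(out) + 1L]] <- .char_row("serious_outcome", r[1L], cnt(r[2L]), n)
    }
    out[[length(out) + 1L]] <- .char_row("serious_outcome",
                                         "Other serious medical events",
                                         cnt(c("OT", "CA", "RI")), n)
  }

  ctry <- ifelse(is.na(d$occr_country), "Unknown", d$occr_country)
  ctab <- sort(table(ctry), decreasing = TRUE)
  for (lv in names(head(ctab, top_k_countries))) {
    out[[length(out) + 1L]] <- .char_row("country", lv, ctab[[lv]], n)
  }

  occ_labels <- c(CN = "Consumer", HP = "Health professional", LW = "Lawyer",
                  MD = "Physician", OT = "Other health-professional",
                  PH = "Pharmacist")
  occ <- ifelse(is.na(d$occp_cod), "Unknown",
                ifelse(d$occp_cod %in% names(occ_labels),
                       occ_labels[d$occp_cod], "Unknown"))
  for (lv in c(unname(occ_labels), "Unknown")) {
    k <- sum(occ == lv)
    if (k > 0L || lv != "Unknown") {
      out[[length(out) + 1L]] <- .char_row("reporter", lv, k, n)
    }
  }

  yr <- parse_date(d$fda_dt)$year
  yr_lab <- ifelse(is.na(yr), "Unknown", as.character(yr))
  for (lv in sort(unique(yr_lab))) {
    out[[length(out) + 1L]] <- .char_row("reporting_year", lv, sum(yr_lab == lv), n)
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "cohort_size") <- n
  res
}
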