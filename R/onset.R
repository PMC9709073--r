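#' Time to onset of target-drug adverse events
#'
#' For each target report, onset is the event date minus the earliest
#' full-precision therapy start date of the matched primary-suspect drug
#' (linked through `dsg_drug_seq`). Only day-resolution arithmetic is
#' performed: reports with missing or partial dates are excluded, as are
#' input errors where the event predates the drug start. Every excluded
#' report is tallied under exactly one reason, in the priority order
#' `no_event_date`, `partial_event_date`, `no_start_date`,
#' `partial_start_date`, `negative_onset`.
#'
#' @param demo deduplicated DEMO table.
#' @param ther THER table (`primaryid`, `dsg_drug_seq`, `start_dt`).
#' @param cohort a `faers_cohort`.
#' @return data frame `caseid`, `onset_days` (integer >= 0), with attribute
#'   `exclusions` (named integer vector of per-reason tallies; reasons plus
#'   rows sum to the target cohort size).
#' @export
compute_onset <- function(demo, ther, cohort) {
  d <- demo[demo$caseid %in% cohort$target_caseids, , drop = FALSE]
  ev <- parse_date(d$event_dt)

  # earliest full-precision start date among THER rows of the matched PS
  # drug sequence(s) of the kept case version
  key <- paste(cohort$matches$primaryid, cohort$matches$drug_seq)
  th <- ther[paste(ther$primaryid, ther$dsg_drug_seq) %in% key, , drop = FALSE]
  st <- parse_date(th$start_dt)
  th_full <- th[st$precision == "full", , drop = FALSE]
  st_full <- st$date[st$precision == "full"]
  start_by_pid <- tapply(st_full, th_full$primaryid, min)
  has_any_start <- d$primaryid %in% th$primaryid
  start_date <- as.Date(start_by_pid[d$primaryid],
                        origin = "1970-01-01")

  reason <- rep(NA_character_, nrow(d))
  reason[ev$precision == "absent"] <- "no_event_date"
  miss <- is.na(reason) & ev$precision != "full"
  reason[miss] <- "partial_event_date"
  miss <- is.na(reason) & !has_any_start
  reason[miss] <- "no_start_date"
  miss <- is.na(reason) & is.na(start_date)
  reason[miss] <- "partial_start_date"
  onset <- as.integer(ev$date - start_date)
  miss <- is.na(reason) & onset < 0
  reason[miss] <- "negative_onset"

  keep <- is.na(reason)
  out <- data.frame(caseid = d$caseid[keep], onset_days = onset[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  reasons <- c("no_event_date", "partial_event_date", "no_start_date",
               "partial_start_date", "negative_onset")
  attr(out, "exclusions") <- setNames(
    as.integer(table(factor(reason, levels = reasons))), reasons)
  out
}

.onset_bin_labels <- c(paste(seq(0, 330, 30) + c(0, rep(1, 11)),
                             seq(30, 360, 30), sep = "-"), ">360")

#' Summarize time-to-onset
#'
#' Median and interquartile range (linear-interpolation quartiles, R type
#' 7), plus 30-day bins `0-30`, `31-60`, ..., `331-360`, `>360` with
#' per-bin percentages. Both 0 and 30 days fall in the first bin; each
#' subsequent bin is right-closed at its multiple of 30.
#'
#' @param records data frame from [compute_onset()].
#' @return list with `n_with_onset`, `median_days`, `q1`, `q3`, and `bins`
#'   (data frame `bin`, `count`, `percent`). An empty input returns the
#'   marker `n_with_onset = 0` with `NA` summaries and zero counts.
#' @export
summarize_onset <- function(records) {
  x <- records$onset_days
  labels <- .onset_bin_labels
  if (length(x) == 0L) {
    bins <- data.frame(bin = labels, count = 0L, percent = 0,
                       stringsAsFactors = FALSE)
    return(list(n_with_onset = 0L, median_days = NA_real_, q1 = NA_real_,
                q3 = NA_real_, bins = bins))
  }
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  idx <- pmin(pmax(ceiling(x / 30), 1L), 13L)  # day 0 -> first bin, >360 -> 13
  cnt <- as.integer(table(factor(idx, levels = 1:13)))
  bins <- data.frame(bin = labels, count = cnt,
                     percent = round(100 * cnt / length(x), 2),
                     stringsAsFactors = FALSE)
  list(n_with_onset = length(x), median_days = q[2L], q1 = q[1L], q3 = q[3L],
       bins = bins)
}
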