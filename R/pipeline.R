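#' Run the full signal-detection pipeline
#'
#' End-to-end orchestration: parse (or accept in-memory) FAERS tables,
#' deduplicate case versions, build the target primary-suspect cohort
#' (optionally excluding consumer reports), tabulate descriptive
#' characteristics, build PT- and SOC-level contingency tables, compute the
#' four disproportionality statistics with significance flags and label
#' classification, and summarize time to onset. When `out_dir` is given the
#' standard report bundle is written: `characteristics.csv`,
#' `soc_signals.csv`, `pt_signals.csv`, `pt_signals_all_four.csv`,
#' `onset_summary.csv`, `onset_bins.csv`, a `run_log.txt` with the filter
#' funnel, full-precision companions (`*_full.csv`), and the effective
#' configuration (`config.yaml`). Report CSVs round statistics to 2
#' decimals; the companions keep full precision.
#'
#' @param input a directory of FAERS-dialect files (see [read_faers_dir()])
#'   or a `faers_corpus` / named list of parsed tables.
#' @param target_names character vector of generic/trade names.
#' @param soc_map data frame `pt`, `soc`, or path to such a CSV.
#' @param label_terms character vector of label terms, or path to a plain
#'   text file with one term per line.
#' @param thresholds list from [default_thresholds()] or path to a YAML file.
#' @param level `"pt"`, `"soc"` or `"both"`.
#' @param exclude_consumers drop CN-reported cases before all statistics.
#' @param ebgm_mode,ic_variant,ebgm_z,haldane passed to [signal_table()].
#' @param out_dir optional output directory for the report bundle.
#' @return Invisibly, a list with `cohort`, `characteristics`, `pt_signals`,
#'   `soc_signals`, `pt_signals_all_four`, `onset_records`, `onset_summary`,
#'   and `log` (named funnel counts).
#' @export
run_pipeline <- function(input, target_names, soc_map = NULL,
                         label_terms = character(0),
                         thresholds = default_thresholds(),
                         level = c("both", "pt", "soc"),
                         exclude_consumers = FALSE,
                         ebgm_mode = "simplified", ic_variant = "delta",
                         ebgm_z = 1.645, haldane = FALSE, out_dir = NULL) {
  level <- match.arg(level)
  tabs <- if (is.character(input)) read_faers_dir(input) else input
  for (req in c("demo", "drug", "reac")) {
    if (is.null(tabs[[req]])) stop("pipeline aborted at stage 'ingest': ",
                                   toupper(req), " table missing")
  }
  if (is.character(soc_map)) {
    soc_map <- utils::read.csv(soc_map, stringsAsFactors = FALSE)
  }
  if (is.character(label_terms) && length(label_terms) == 1L &&
      file.exists(label_terms)) {
    label_terms <- readLines(label_terms, warn = FALSE)
    label_terms <- label_terms[nzchar(trimws(label_terms))]
  }
  if (is.character(thresholds)) thresholds <- read_thresholds(thresholds)

  log <- c(reports_read = nrow(tabs$demo))
  demo <- deduplicate(tabs$demo)
  log["deduplicated_cases"] <- nrow(demo)

  cohort <- build_cohort(demo, tabs$drug, target_names)
  if (exclude_consumers) {
    cohort <- exclude_consumers(cohort, demo)
    demo <- demo[demo$caseid %in% c(cohort$target_caseids,
                                    cohort$background_caseids), , drop = FALSE]
    log["after_consumer_exclusion"] <- nrow(demo)
  }
  log["target_cohort"] <- length(cohort$target_caseids)
  if (length(cohort$target_caseids) == 0L) {
    warning("no reports match the target names; signal tables are empty")
  }

  characteristics <- summarize_characteristics(cohort, demo, tabs$outc,
                                               tabs$indi)

  pt_sig <- soc_sig <- NULL
  if (level %in% c("both", "pt")) {
    pt_tables <- build_tables(cohort, demo, tabs$reac, level = "pt")
    log["pt_terms"] <- nrow(pt_tables)
    pt_sig <- signal_table(pt_tables, thresholds, label_terms,
                           ebgm_mode = ebgm_mode, ic_variant = ic_variant,
                           ebgm_z = ebgm_z, haldane = haldane)
    log["pt_all_four"] <- sum(pt_sig$all_four, na.rm = TRUE)
  }
  if (level %in% c("both", "soc")) {
    if (is.null(soc_map)) stop("pipeline aborted at stage 'contingency': ",
                               "SOC level requested without soc_map")
    soc_tables <- build_tables(cohort, demo, tabs$reac, level = "soc",
                               soc_map = soc_map)
    log["soc_terms"] <- nrow(soc_tables)
    soc_sig <- signal_table(soc_tables, thresholds, label_terms,
                            ebgm_mode = ebgm_mode, ic_variant = ic_variant,
                            ebgm_z = ebgm_z, haldane = haldane)
  }

  onset_records <- NULL
  onset_summary <- NULL
  if (!is.null(tabs$ther)) {
    onset_records <- compute_onset(demo, tabs$ther, cohort)
    log["onset_records"] <- nrow(onset_records)
    onset_summary <- summarize_onset(onset_records)
  }

  all_four <- if (!is.null(pt_sig)) {
    pt_sig[pt_sig$all_four, , drop = FALSE]
  }

  res <- list(cohort = cohort, characteristics = characteristics,
              pt_signals = pt_sig, soc_signals = soc_sig,
              pt_signals_all_four = all_four,
              onset_records = onset_records, onset_summary = onset_summary,
              log = log)
  if (!is.null(out_dir)) {
    .write_bundle(res, out_dir,
                  config = list(target_names = target_names,
                                exclude_consumers = exclude_consumers,
                                ebgm_mode = ebgm_mode, ic_variant = ic_variant,
                                ebgm_z = ebgm_z, haldane = haldane,
                                thresholds = thresholds,
                                label_terms = label_terms, level = level))
  }
  invisible(res)
}

.round_stats <- function(df) {
  num <- vapply(df, is.numeric, TRUE) &
    !names(df) %in% c("a", "b", "c", "d", "count")
  df[num] <- lapply(df[num], round, digits = 2)
  df
}

.write_bundle <- function(res, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name, full = FALSE) {
    if (is.null(df)) return(invisible())
    utils::write.csv(if (full) df else .round_stats(df),
                     file.path(out_dir, name), row.names = FALSE, na = "")
  }
  wcsv(res$characteristics, "characteristics.csv")
  wcsv(res$soc_signals, "soc_signals.csv")
  wcsv(res$pt_signals, "pt_signals.csv")
  wcsv(res$pt_signals_all_four, "pt_signals_all_four.csv")
  wcsv(res$soc_signals, "soc_signals_full.csv", full = TRUE)
  wcsv(res$pt_signals, "pt_signals_full.csv", full = TRUE)
  if (!is.null(res$onset_summary)) {
    s <- res$onset_summary
    utils::write.csv(data.frame(
      statistic = c("n_with_onset", "median_days", "q1_days", "q3_days"),
      value = c(s$n_with_onset, s$median_days, s$q1, s$q3)),
      file.path(out_dir, "onset_summary.csv"), row.names = FALSE, na = "")
    utils::write.csv(s$bins, file.path(out_dir, "onset_bins.csv"),
                     row.names = FALSE)
  }
  writeLines(c("filter funnel:",
               sprintf("  %-26s %d", names(res$log), res$log)),
             file.path(out_dir, "run_log.txt"))
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
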