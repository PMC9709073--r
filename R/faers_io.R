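# Required columns per FAERS quarterly ASCII table kind. Extra columns in a
# file are preserved; missing required columns are fatal.
.faers_required_cols <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "occr_country"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  REAC = c("primaryid", "pt"),
  OUTC = c("primaryid", "outc_cod"),
  INDI = c("primaryid", "indi_drug_seq", "indi_pt"),
  THER = c("primaryid", "dsg_drug_seq", "start_dt")
)

.faers_role_codes <- c("PS", "SS", "C", "I")

#' Parse one FAERS-dialect quarterly ASCII table
#'
#' FAERS quarterly extracts are '$'-delimited text files with a single header
#' row and one table per file. `parse_table()` reads one such file (or
#' connection, or character vector of lines) into a data frame with one row
#' per record. Fields left empty in the file become `NA`. Rows whose field
#' count cannot be reconciled with the header (a single missing trailing
#' field is tolerated, as FAERS writers drop the final empty field) are
#' skipped and counted in the parse log.
#'
#' @param x path to a file, a connection, or a character vector of raw lines.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"INDI"`,
#'   `"THER"`.
#' @return A data frame of character columns named as in the header
#'   (lower-cased), with attributes `parse_log` (list with `n_rows`,
#'   `n_parsed`, `n_skipped`, `skipped_lines`) and `table_kind`. `DRUG`
#'   tables gain a logical `role_valid` column flagging rows whose
#'   `role_cod` is one of PS/SS/C/I.
#' @examples
#' lines <- c("primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$occr_country",
#'            "100000011$10000001$20210315$20210301$63$YR$F$CN$US")
#' demo <- parse_table(lines, "DEMO")
#' demo$sex
#' @export
parse_table <- function(x, table_kind = c("DEMO", "DRUG", "REAC", "OUTC",
                                          "INDI", "THER")) {
  table_kind <- match.arg(table_kind)
  lines <- if (is.character(x) && length(x) > 1L) {
    x
  } else if (is.character(x) && length(x) == 1L && !grepl("\\$", x)) {
    readLines(x, encoding = "UTF-8", warn = FALSE)
  } else if (inherits(x, "connection")) {
    readLines(x, encoding = "UTF-8", warn = FALSE)
  } else {
    x
  }
  # FAERS archives are inconsistently encoded; recode to valid UTF-8 with
  # replacement so downstream string ops never fail.
  lines <- iconv(lines, from = "UTF-8", to = "UTF-8", sub = "�")
  if (length(lines) == 0L || !nzchar(lines[1L])) {
    stop("unreadable header: '", table_kind, "' input has no header row")
  }
  header <- tolower(trimws(strsplit(lines[1L], "$", fixed = TRUE)[[1L]]))
  required <- .faers_required_cols[[table_kind]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0L) {
    stop("unreadable header: ", table_kind, " table lacks column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  ncol <- length(header)
  fields <- strsplit(body, "$", fixed = TRUE)
  lens <- lengths(fields)
  # A row whose final field is empty splits one short; pad it back.
  pad <- lens == ncol - 1L
  fields[pad] <- lapply(fields[pad], function(f) c(f, NA_character_))
  lens[pad] <- ncol
  bad <- lens != ncol
  skipped <- which(bad)
  fields <- fields[!bad]
  mat <- if (length(fields)) {
    matrix(unlist(fields, use.names = FALSE), ncol = ncol, byrow = TRUE)
  } else {
    matrix(character(0), ncol = ncol)
  }
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  for (j in seq_along(df)) {
    v <- trimws(df[[j]])
    v[v == ""] <- NA_character_
    df[[j]] <- v
  }
  if (table_kind == "DRUG") {
    df$role_cod <- toupper(df$role_cod)
    df$role_valid <- !is.na(df$role_cod) & df$role_cod %in% .faers_role_codes
  }
  attr(df, "table_kind") <- table_kind
  attr(df, "parse_log") <- list(
    table_kind = table_kind,
    n_rows = length(body),
    n_parsed = nrow(df),
    n_skipped = length(skipped),
    skipped_lines = skipped + 1L  # 1-based file line numbers
  )
  df
}

#' Parse FAERS date strings with explicit precision
#'
#' FAERS date fields hold 8-digit (YYYYMMDD), 6-digit (YYYYMM) or 4-digit
#' (YYYY) values, or are empty. Partial dates are kept for year-level
#' tabulation but only full, calendar-valid dates receive a `Date`; invalid
#' calendars (month 13, day 32) are treated as absent. The function is total:
#' any input maps to a row, never an error.
#'
#' @param raw character vector of raw date fields.
#' @return A data frame with columns `raw`, `precision` (one of `"full"`,
#'   `"year-month"`, `"year"`, `"absent"`), `year`, `month`, `day`
#'   (integer, `NA` where not determined) and `date` (`Date`, non-`NA` only
#'   for `"full"`).
#' @examples
#' parse_date(c("20210115", "202101", "2021", "", "20211332"))
#' @export
parse_date <- function(raw) {
  raw <- as.character(raw)
  n <- length(raw)
  clean <- trimws(raw)
  clean[is.na(clean)] <- ""
  digits <- grepl("^[0-9]+$", clean)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep("absent", n)

  is8 <- digits & nchar(clean) == 8L
  is6 <- digits & nchar(clean) == 6L
  is4 <- digits & nchar(clean) == 4L

  year[is8 | is6 | is4] <- as.integer(substr(clean[is8 | is6 | is4], 1L, 4L))
  month[is8 | is6] <- as.integer(substr(clean[is8 | is6], 5L, 6L))
  day[is8] <- as.integer(substr(clean[is8], 7L, 8L))

  date <- rep(as.Date(NA), n)
  if (any(is8)) {
    cand <- as.Date(clean[is8], format = "%Y%m%d")  # NA for month 13, day 32
    date[is8] <- cand
    full_ok <- is8
    full_ok[is8] <- !is.na(cand)
    precision[full_ok] <- "full"
    bad8 <- is8 & !full_ok
    year[bad8] <- NA_integer_; month[bad8] <- NA_integer_; day[bad8] <- NA_integer_
  }
  ym_ok <- is6 & !is.na(month) & month >= 1L & month <= 12L
  precision[ym_ok] <- "year-month"
  bad6 <- is6 & !ym_ok
  year[bad6] <- NA_integer_; month[bad6] <- NA_integer_
  precision[is4] <- "year"

  data.frame(raw = raw, precision = precision, year = year, month = month,
             day = day, date = date, stringsAsFactors = FALSE)
}

#' Deduplicate FAERS case versions
#'
#' Quarterly FAERS files re-publish earlier versions of the same safety
#' report under new `primaryid`s that share a `caseid`. Before any
#' statistics, each case is collapsed to its latest version: the record with
#' the largest `fda_dt`, ties broken by the larger numeric `primaryid`
#' (version numbers increase). The operation is deterministic and
#' idempotent, and never invents records.
#'
#' @param demo a DEMO data frame from [parse_table()].
#' @return The surviving rows of `demo`, one per `caseid`, with an attribute
#'   `dedup_log` (list with `n_in`, `n_out`, `n_removed`).
#' @export
deduplicate <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (nrow(demo) == 0L) {
    out <- demo
    attr(out, "dedup_log") <- list(n_in = 0L, n_out = 0L, n_removed = 0L)
    return(out)
  }
  fda <- suppressWarnings(as.numeric(demo$fda_dt))
  fda[is.na(fda)] <- -Inf
  pid <- suppressWarnings(as.numeric(demo$primaryid))
  pid[is.na(pid)] <- -Inf
  ord <- order(demo$caseid, fda, pid)  # within caseid, latest version last
  demo_o <- demo[ord, , drop = FALSE]
  keep <- !duplicated(demo_o$caseid, fromLast = TRUE)
  out <- demo_o[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "table_kind") <- attr(demo, "table_kind")
  attr(out, "dedup_log") <- list(n_in = nrow(demo), n_out = nrow(out),
                                 n_removed = nrow(demo) - nrow(out))
  out
}

#' Write a data frame back in the FAERS '$'-delimited dialect
#'
#' Inverse of [parse_table()]: one header row, '$'-separated fields, `NA`
#' rendered as the empty field. Round-tripping a parsed table through
#' `write_table()` and [parse_table()] reproduces the records exactly.
#'
#' @param df data frame of character columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  df <- df[, setdiff(names(df), "role_valid"), drop = FALSE]
  mat <- vapply(df, function(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  }, character(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L)
  lines <- c(paste(names(df), collapse = "$"),
             if (nrow(df)) apply(mat, 1L, paste, collapse = "$"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a directory of FAERS-dialect tables
#'
#' Looks for files named `DEMO*`, `DRUG*`, `REAC*`, `OUTC*`, `INDI*`,
#' `THER*` (case-insensitive, any extension) and parses each with
#' [parse_table()]. Multiple files of one kind (e.g. several quarters) are
#' row-bound in filename order.
#'
#' @param dir directory path.
#' @return Named list with elements `demo`, `drug`, `reac`, `outc`, `indi`,
#'   `ther` (missing kinds are `NULL`) and `parse_logs`.
#' @export
read_faers_dir <- function(dir) {
  stopifnot(dir.exists(dir))
  kinds <- names(.faers_required_cols)
  out <- list()
  logs <- list()
  for (kind in kinds) {
    files <- sort(list.files(dir, pattern = paste0("^", kind), full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) {
      out[[tolower(kind)]] <- NULL
      next
    }
    parts <- lapply(files, parse_table, table_kind = kind)
    logs[[kind]] <- lapply(parts, attr, "parse_log")
    tab <- do.call(rbind, parts)
    attr(tab, "table_kind") <- kind
    out[[tolower(kind)]] <- tab
  }
  out$parse_logs <- logs
  out
}
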