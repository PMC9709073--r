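#' Build report-level 2x2 contingency tables
#'
#' For every preferred term (or, at SOC level, every system organ class)
#' observed in the corpus, counts the classic disproportionality cells:
#' `a` target reports mentioning the term, `b` target reports not mentioning
#' it, `c` background reports mentioning it, `d` background reports not
#' mentioning it. The counting unit is the deduplicated report: a report
#' listing the same PT twice counts once, and at SOC level a report counts
#' once per SOC no matter how many of its PTs map there. PTs missing from
#' the SOC map are routed to an explicit `"(unmapped)"` class rather than
#' dropped.
#'
#' @param cohort a `faers_cohort`.
#' @param demo the deduplicated DEMO table (maps `primaryid` to `caseid`;
#'   only events of kept case versions are counted).
#' @param reac REAC data frame (`primaryid`, `pt`).
#' @param level `"pt"` or `"soc"`.
#' @param soc_map data frame with columns `pt`, `soc` (required for
#'   `level = "soc"`); each PT maps to exactly one SOC.
#' @return A data frame `level`, `term`, `a`, `b`, `c`, `d` with one row per
#'   term, plus attributes `n_target`, `n_background`, and (at SOC level)
#'   `unmapped_pts`.
#' @export
build_tables <- function(cohort, demo, reac, level = c("pt", "soc"),
                         soc_map = NULL) {
  level <- match.arg(level)
  n_target <- length(cohort$target_caseids)
  n_background <- length(cohort$background_caseids)

  ev <- reac[reac$primaryid %in% demo$primaryid & !is.na(reac$pt), , drop = FALSE]
  caseid_of <- setNames(demo$caseid, demo$primaryid)
  term <- gsub("[[:space:]]+", " ", trimws(ev$pt))
  ev <- data.frame(caseid = unname(caseid_of[ev$primaryid]), term = term,
                   stringsAsFactors = FALSE)
  ev <- ev[nzchar(ev$term), , drop = FALSE]

  unmapped <- character(0)
  if (level == "soc") {
    if (is.null(soc_map)) stop("soc_map is required at SOC level")
    stopifnot(all(c("pt", "soc") %in% names(soc_map)))
    key <- normalize_term(soc_map$pt)
    if (anyDuplicated(key)) {
      dup <- unique(soc_map$pt[duplicated(key)])
      stop("soc_map maps PT(s) to more than one SOC: ",
           paste(head(dup, 5L), collapse = ", "))
    }
    soc_of <- setNames(soc_map$soc, key)
    mapped <- soc_of[normalize_term(ev$term)]
    unmapped <- sort(unique(ev$term[is.na(mapped)]))
    ev$term <- ifelse(is.na(mapped), "(unmapped)", unname(mapped))
  }

  ev <- unique(ev)  # report-level counting
  is_target <- ev$caseid %in% cohort$target_caseids
  terms <- sort(unique(ev$term))
  a <- as.integer(table(factor(ev$term[is_target], levels = terms)))
  c_ <- as.integer(table(factor(ev$term[!is_target], levels = terms)))
  out <- data.frame(level = toupper(level), term = terms, a = a,
                    b = n_target - a, c = c_, d = n_background - c_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_target") <- n_target
  attr(out, "n_background") <- n_background
  if (level == "soc") attr(out, "unmapped_pts") <- unmapped
  out
}

#' Back-solve comparator cells from published ROR and its CI
#'
#' Disproportionality tables in publications print, per term, the target
#' case count `a`, the cohort size `n`, and the reporting odds ratio with
#' its Wald 95% interval — but not the comparator cells `c` and `d`. Those
#' two cells are exactly identified by the two printed relations: on the
#' log scale the interval half-width is `1.96 * sqrt(1/a + 1/b + 1/c + 1/d)`
#' and the point estimate is `(a*d)/(b*c)`. Writing
#' `r = (ln(hi/lo) / (2*1.96))^2 - 1/a - 1/b` for the residual comparator
#' variance, the closed-form solution is
#' `d = (1 + b*ror/a) / r`, `c = a*d / (b*ror)`.
#'
#' Because the printed values are rounded to 2 decimals, the recovered cells
#' are positive reals, not integers; a nearest-integer rendering is returned
#' alongside. When the rounded interval is narrower than the `1/a + 1/b`
#' floor the system has no positive solution and the function signals an
#' infeasibility error (condition class `faersignal_infeasible`).
#'
#' @param a target reports with the term (>= 1).
#' @param n_target target cohort size (> a).
#' @param ror printed reporting odds ratio.
#' @param ci_low,ci_high printed 95% interval bounds, `ci_low < ror < ci_high`.
#' @param z normal quantile used for the printed interval (default 1.96).
#' @return A list with `a`, `b`, `c`, `d` (reals), `c_int`, `d_int`
#'   (nearest integers), and `residual` (the solved `1/c + 1/d`).
#' @examples
#' tab <- reconstruct_comparator(772, 11701, 8.52, 7.91, 9.17)
#' round(compute_prr(tab$a, tab$b, tab$c, tab$d)$prr, 2)  # 8.02
#' @export
reconstruct_comparator <- function(a, n_target, ror, ci_low, ci_high,
                                   z = 1.96) {
  stopifnot(a >= 1, n_target > a, ci_low < ror, ror < ci_high)
  b <- n_target - a
  se <- log(ci_high / ci_low) / (2 * z)
  r <- se^2 - 1 / a - 1 / b
  if (r <= 0) {
    stop(structure(class = c("faersignal_infeasible", "error", "condition"),
                   list(message = sprintf(
                     paste0("printed CI width is below the 1/a + 1/b floor ",
                            "(residual %.3g <= 0); comparator cells cannot ",
                            "be reconstructed at this rounding"), r),
                     call = sys.call(-1))))
  }
  d <- (1 + b * ror / a) / r
  c_ <- a * d / (b * ror)
  list(a = a, b = b, c = c_, d = d,
       c_int = round(c_), d_int = round(d), residual = r)
}
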