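#' Event rows for contingency construction
#'
#' Expands a deduplicated corpus to one row per (case, distinct term):
#' the counting unit of the disproportionality analysis. The same PT
#' repeated within one report counts once. At SOC level, terms are the
#' distinct (case, SOC) pairs after PT-to-SOC rollup.
#'
#' @param tables Deduplicated `faers_tables` covering the whole corpus.
#' @param target_ids `primaryid`s of the target-drug (primary-suspect)
#'   cases, e.g. `demo$primaryid` of [select_target_reports()] output.
#' @param level `"pt"` or `"soc"`.
#' @param map PT/SOC dictionary, required for `level = "soc"`.
#' @return A tibble with columns `primaryid`, `is_target`, `term`.
#' @export
event_rows <- function(tables, target_ids, level = c("pt", "soc"),
                       map = NULL) {
  level <- match.arg(level)
  reac <- tibble::as_tibble(tables$reac)
  rows <- tibble::tibble(
    primaryid = reac$primaryid,
    is_target = reac$primaryid %in% target_ids,
    term = toupper(trimws(reac$pt))
  )
  if (level == "soc") {
    if (is.null(map)) stop("SOC level requires a PT/SOC dictionary",
                           call. = FALSE)
    rows$term <- map_pt_to_soc(rows$term, map)
  }
  dplyr::distinct(rows[!is.na(rows$term), ])
}

#' Build 2x2 contingency tables for every term
#'
#' For each term t over the event rows: `a` target-drug rows with t, `b`
#' target-drug rows without t, `c` and `d` the same for the comparator
#' (all non-target rows in the corpus), so `a + b` is the target drug's
#' event margin and `a + b + c + d = N` for every term.
#'
#' @param rows Output of [event_rows()].
#' @return A tibble with columns `term`, `a`, `b`, `c`, `d`, `n_total`,
#'   one row per term, sorted by decreasing `a`.
#' @export
build_contingency <- function(rows) {
  margin_target <- sum(rows$is_target)
  margin_other <- sum(!rows$is_target)
  counts <- rows |>
    dplyr::count(.data$term, .data$is_target) |>
    tidyr::pivot_wider(names_from = "is_target", values_from = "n",
                       values_fill = 0L)
  a <- if ("TRUE" %in% names(counts)) counts[["TRUE"]] else rep(0L, nrow(counts))
  c <- if ("FALSE" %in% names(counts)) counts[["FALSE"]] else rep(0L, nrow(counts))
  out <- tibble::tibble(
    term = counts$term,
    a = a,
    b = margin_target - a,
    c = c,
    d = margin_other - c,
    n_total = margin_target + margin_other
  )
  out[order(-out$a, out$term), ]
}
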