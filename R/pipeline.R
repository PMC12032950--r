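#' Run the full disproportionality pipeline
#'
#' Orchestrates the end-to-end analysis for one target drug: read the
#' quarterly files, keep the latest version of each case, select the cases
#' with the target drug as primary suspect, roll reactions up to SOC,
#' apply the minimum-report filter at PT level, build 2x2 tables against
#' all other drugs in the corpus, compute the four disproportionality
#' statistics with screening flags, and write descriptive summaries. All
#' steps are deterministic: identical inputs and configuration give
#' byte-identical outputs.
#'
#' @param input_dir Directory of FAERS-style quarterly files, or `NULL` if
#'   `tables` is given.
#' @param tables Pre-loaded `faers_tables` (alternative to `input_dir`).
#' @param target Canonical target drug name.
#' @param synonyms Synonym table (data frame or TSV path), optional.
#' @param pt_soc PT/SOC dictionary (data frame or TSV path).
#' @param out_dir Output directory; created if needed.
#' @param min_pt_reports Minimum target-drug report count for a PT to enter
#'   the PT-level signal table (default 3).
#' @param criteria A [screen_criteria()] object.
#' @param zero_cell,ic_variance Passed to [signal_scores()].
#' @return Invisibly, a list with the deduplicated case table, the
#'   descriptive summary, quarterly counts, and the screened PT- and
#'   SOC-level score tables. Side effect: TSV outputs and a `run_log.txt`
#'   configuration echo under `out_dir`.
#' @export
run_pipeline <- function(input_dir = NULL, tables = NULL, target,
                         synonyms = NULL, pt_soc, out_dir,
                         min_pt_reports = 3,
                         criteria = screen_criteria(),
                         zero_cell = c("undefined", "haldane"),
                         ic_variance = c("plus1", "plain")) {
  zero_cell <- match.arg(zero_cell)
  ic_variance <- match.arg(ic_variance)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- "configuration"
  result <- tryCatch({
    if (is.character(synonyms)) synonyms <- load_synonyms(synonyms)
    if (is.character(pt_soc)) pt_soc <- load_pt_soc(pt_soc)

    stage <- "parse"
    if (is.null(tables)) tables <- read_faers(input_dir)

    stage <- "deduplicate"
    dedup <- deduplicate_cases(tables)

    stage <- "target selection"
    target_tabs <- select_target_reports(dedup, target, synonyms)
    target_ids <- target_tabs$demo$primaryid
    cases <- case_table(target_tabs)

    stage <- "descriptives"
    descr <- summarize_cases(cases, target_tabs$outc)
    quarters <- quarterly_counts(cases$fda_date)

    stage <- "contingency"
    pt_rows <- event_rows(dedup, target_ids, level = "pt")
    soc_rows <- suppressWarnings(
      event_rows(dedup, target_ids, level = "soc", map = pt_soc))
    pt_tables <- build_contingency(pt_rows)
    soc_tables <- build_contingency(soc_rows)
    target_pt <- pt_tables[pt_tables$a > 0, ]
    keep <- filter_min_reports(setNames(target_pt$a, target_pt$term),
                               min_n = min_pt_reports)
    pt_tables <- pt_tables[pt_tables$term %in% keep, ]
    soc_tables <- soc_tables[soc_tables$a > 0, ]

    stage <- "signals"
    pt_scores <- screen_signals(
      signal_scores(pt_tables, zero_cell, ic_variance), criteria)
    soc_scores <- screen_signals(
      signal_scores(soc_tables, zero_cell, ic_variance), criteria)

    stage <- "write outputs"
    out <- function(name) {
      path <- file.path(out_dir, name)
      written <<- c(written, path)
      path
    }
    write.table(cases, out("cases.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(descr, out("descriptives.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(quarters, out("quarterly_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_signal_table(pt_scores, out("pt_signals.tsv"))
    write_signal_table(soc_scores, out("soc_signals.tsv"))
    writeLines(c(
      sprintf("faersdpa %s", as.character(utils::packageVersion("faersdpa"))),
      sprintf("target: %s", target),
      sprintf("input: %s", if (is.null(input_dir)) "<in-memory tables>"
              else normalizePath(input_dir)),
      sprintf("cases after deduplication: %d", nrow(dedup$demo)),
      sprintf("target primary-suspect cases: %d", length(target_ids)),
      sprintf("min_pt_reports: %d", min_pt_reports),
      sprintf("criteria: ROR lower>%s & a>=%s; PRR>=%s & chi2>=%s & a>=%s; IC025>%s; EBGM05>%s; combine=%s",
              criteria$ror_lo_gt, criteria$min_a, criteria$prr_min,
              criteria$chi2_min, criteria$min_a, criteria$ic025_gt,
              criteria$ebgm05_gt, criteria$combine),
      sprintf("zero_cell: %s; ic_variance: %s", zero_cell, ic_variance)
    ), out("run_log.txt"))

    list(cases = cases, descriptives = descr, quarterly = quarters,
         pt_signals = pt_scores, soc_signals = soc_scores)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
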