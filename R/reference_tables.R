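#' Path to a packaged example or reference file
#'
#' @param file File name under the package's `extdata` directory; empty to
#'   list the available files.
#' @return A file path (or file listing).
#' @export
faersdpa_extdata <- function(file = "") {
  if (!nzchar(file)) {
    return(list.files(system.file("extdata", package = "faersdpa")))
  }
  path <- system.file("extdata", file, package = "faersdpa")
  if (!nzchar(path)) stop("no packaged file named ", file, call. = FALSE)
  path
}

#' Published avelumab reference tables
#'
#' Reference values from a published FAERS avelumab disproportionality
#' analysis (reporting period Q3 2015 to Q1 2024), shipped as plain TSV:
#'
#' * `"pt"`: the 30-row preferred-term signal table (report count, ROR
#'   with 95% CI, PRR with 95% CI, chi-square, IC with IC025, EBGM with
#'   EBGM05).
#' * `"soc"`: the 22-row system-organ-class signal table, whose report
#'   counts sum to the avelumab event margin of 3,845.
#' * `"descriptives"`: the report-demographics table (category counts with
#'   printed percentages; factors have their own denominators).
#'
#' These tables serve as cross-check fixtures: [reconstruct_from_printed()]
#' inverts each printed PRR back to a full 2x2 table (corpus size
#' N = 32,732,219 reaction events), and the recomputed statistics are
#' compared against the printed ones.
#'
#' @param table Which table to load.
#' @return A tibble.
#' @export
avelumab_reference <- function(table = c("pt", "soc", "descriptives")) {
  table <- match.arg(table)
  file <- switch(table,
    pt = "avelumab_pt_reference.tsv",
    soc = "avelumab_soc_reference.tsv",
    descriptives = "avelumab_descriptives_reference.tsv"
  )
  tibble::as_tibble(read.delim(faersdpa_extdata(file),
                               check.names = FALSE))
}

#' Margins of the published avelumab analysis
#'
#' The constants needed to reconstruct 2x2 tables from the published
#' signal tables: the avelumab event-level margin (3,845, the sum of the
#' 22 SOC report counts) and the total number of reaction events in the
#' corpus (32,732,219).
#'
#' @return Named list with `drug_margin` and `n_total`.
#' @export
avelumab_margins <- function() {
  list(drug_margin = 3845, n_total = 32732219)
}
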