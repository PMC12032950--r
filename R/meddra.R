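#' Load a PT-to-SOC dictionary
#'
#' The package takes any two-column tab-separated dictionary mapping each
#' preferred term (PT) to its primary system organ class (SOC). A small
#' hand-assembled example dictionary covering the avelumab reference
#' tables ships in `inst/extdata/pt_soc_synthetic.tsv`; it is a synthetic
#' stand-in, not an excerpt of the licensed MedDRA distribution.
#'
#' @param path TSV with columns `pt` and `soc` (header required).
#' @return A tibble of class `pt_soc_map`; PT names must be unique after
#'   case-folding.
#' @export
load_pt_soc <- function(path) {
  tbl <- tibble::as_tibble(read.delim(path, colClasses = "character"))
  if (!all(c("pt", "soc") %in% names(tbl))) {
    stop("PT/SOC dictionary must have columns 'pt' and 'soc'", call. = FALSE)
  }
  key <- toupper(trimws(tbl$pt))
  if (anyDuplicated(key)) {
    stop("PT/SOC dictionary maps the same PT more than once: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  structure(tbl, class = c("pt_soc_map", class(tbl)))
}

#' Map preferred terms to system organ classes
#'
#' Case-insensitive lookup of each PT's primary SOC. Unmapped PTs return
#' the sentinel `"UNMAPPED"`; one warning reports how many distinct PTs
#' were unmapped.
#'
#' @param pt Character vector of PT names.
#' @param map Dictionary from [load_pt_soc()] (or any data frame with
#'   columns `pt` and `soc`).
#' @return Character vector of SOC names.
#' @export
map_pt_to_soc <- function(pt, map) {
  stopifnot(all(c("pt", "soc") %in% colnames(map)))
  lookup <- setNames(map$soc, toupper(trimws(map$pt)))
  key <- toupper(trimws(pt))
  soc <- unname(lookup[key])
  missing <- is.na(soc) & !is.na(pt)
  soc[missing] <- "UNMAPPED"
  if (any(missing)) {
    warning(sprintf("%d distinct PT(s) not in the dictionary",
                    length(unique(key[missing]))), call. = FALSE)
  }
  soc
}

#' Minimum-report filter for preferred terms
#'
#' Signal screening starts from the PTs reported at least `min_n` times
#' (three by default).
#'
#' @param pt_counts Named integer vector, or data frame with columns
#'   `term`/`pt` and `n`, of report counts per PT.
#' @param min_n Minimum report count.
#' @return Character vector of PT names passing the filter, sorted.
#' @export
filter_min_reports <- function(pt_counts, min_n = 3) {
  if (is.data.frame(pt_counts)) {
    term_col <- intersect(c("term", "pt"), names(pt_counts))[1]
    counts <- setNames(pt_counts$n, pt_counts[[term_col]])
  } else {
    counts <- pt_counts
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  nm <- names(counts)
  if (is.null(nm)) nm <- character(length(counts))
  sort(nm[counts >= min_n])
}
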