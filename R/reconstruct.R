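#' Reconstruct a 2x2 contingency table from published signal-table values
#'
#' Published disproportionality tables usually print, per term, the report
#' count `a` and the PRR, together with the drug's total event margin and
#' the corpus size N. Because
#' `PRR = (a/(a+b)) / (c/(c+d))`, those four numbers determine the
#' remaining cells:
#' `b = drug_margin - a`,
#' `c = round((n_total - drug_margin) / (prr_printed * drug_margin / a))`,
#' `d = n_total - drug_margin - c`.
#' `c` is rounded to the nearest integer since cells are counts; the
#' rounding error is far below the two-decimal precision of the printed
#' PRR, so recomputing the PRR from the reconstructed table reproduces the
#' printed value well within 0.5%.
#'
#' @param a Number of reports for the term under the target drug (>= 1).
#' @param prr_printed The printed proportional reporting ratio (> 0).
#' @param drug_margin Total event rows for the target drug (`a + b`).
#' @param n_total Total event rows in the corpus (N).
#' @return A tibble with columns `a`, `b`, `c`, `d`, `n_total`. Vectorised
#'   over all arguments.
#' @examples
#' reconstruct_from_printed(35, 4.95, 3845, 32732219)
#' @export
reconstruct_from_printed <- function(a, prr_printed, drug_margin, n_total) {
  n <- max(length(a), length(prr_printed), length(drug_margin), length(n_total))
  a <- rep_len(as.numeric(a), n)
  prr_printed <- rep_len(as.numeric(prr_printed), n)
  drug_margin <- rep_len(as.numeric(drug_margin), n)
  n_total <- rep_len(as.numeric(n_total), n)

  if (any(a < 1)) stop("a must be >= 1", call. = FALSE)
  if (any(drug_margin <= a)) {
    stop("drug_margin must exceed a", call. = FALSE)
  }
  if (any(n_total <= drug_margin)) {
    stop("n_total must exceed drug_margin", call. = FALSE)
  }
  if (any(prr_printed <= 0)) stop("prr_printed must be positive", call. = FALSE)

  b <- drug_margin - a
  c <- round((n_total - drug_margin) / (prr_printed * drug_margin / a))
  d <- n_total - drug_margin - c
  if (any(c < 1)) {
    stop("infeasible reconstruction: derived c < 1 (printed PRR too large ",
         "for the stated margins)", call. = FALSE)
  }
  tibble::tibble(a = a, b = b, c = c, d = d, n_total = n_total)
}
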