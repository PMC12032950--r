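#' Disproportionality statistics for 2x2 pharmacovigilance tables
#'
#' The four classical signal-detection statistics computed from the cells of
#' a drug-by-event 2x2 contingency table: `a` reports with both the target
#' drug and the target event, `b` target-drug reports with other events,
#' `c` target-event reports for other drugs, `d` everything else
#' (N = a + b + c + d).
#'
#' All functions are vectorised over the four cells and return one row per
#' table. Tables with `a = 0` or an empty `b` or `c` cell yield an
#' undefined-signal row (all statistics `NA`, `defined = FALSE`) unless
#' `zero_cell = "haldane"`, which adds 0.5 to every cell first.
#'
#' * `ror_with_ci()`: reporting odds ratio `a*d/(b*c)` with the Woolf 95%
#'   interval `exp(log(ROR) +/- 1.96*s)`, `s = sqrt(1/a+1/b+1/c+1/d)`.
#' * `prr_with_chi2()`: proportional reporting ratio
#'   `(a/(a+b)) / (c/(c+d))` with a 95% interval on the log scale using the
#'   same `s` as the ROR, plus the Pearson chi-square
#'   `(ad-bc)^2 * N / ((a+b)(c+d)(a+c)(b+d))` without continuity correction.
#' * `ic_with_bound()`: Bayesian confidence propagation information
#'   component `IC = log2(a*N / ((a+c)(a+b)))`, the log2 observed-to-expected
#'   reporting ratio, with lower bound
#'   `IC025 = IC - 1.96 * s_ic / ln(2)`. The default variance term uses
#'   `s_ic = sqrt(1/(a+1)+1/b+1/c+1/d)` (`ic_variance = "plus1"`), which is
#'   the convention published avelumab signal tables follow; set
#'   `ic_variance = "plain"` for the `1/a` form.
#' * `ebgm_with_bound()`: empirical Bayes geometric mean
#'   `EBGM = a*N / ((a+c)(a+b))` (the unshrunk relative reporting ratio, so
#'   `IC = log2(EBGM)` holds exactly) with one-sided 5th percentile
#'   `EBGM05 = EBGM * exp(-1.645*s)`.
#'
#' @param a,b,c,d Non-negative cell counts (vectors of equal length are
#'   recycled by the usual rules).
#' @param zero_cell How to treat tables where `a`, `b` or `c` is zero:
#'   `"undefined"` (default) marks the row undefined, `"haldane"` applies
#'   the +0.5 correction to all four cells.
#' @param ic_variance Variance convention for the IC lower bound, see above.
#' @return A tibble with one row per table. Columns `defined` (logical) plus
#'   the statistic and its bounds.
#' @examples
#' ror_with_ci(35, 3810, 60185, 32668189)
#' prr_with_chi2(1, 1, 1, 1)
#' @name disproportionality
NULL

norm_q95 <- 1.959963984540054
norm_q90_onesided <- 1.644853626951472

check_cells <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  d <- rep_len(as.numeric(d), n)
  if (anyNA(c(a, b, c, d)) || any(c(a, b, c, d) < 0)) {
    stop("contingency cells must be non-negative and non-missing", call. = FALSE)
  }
  list(a = a, b = b, c = c, d = d)
}

apply_zero_cell <- function(cells, zero_cell) {
  zero_cell <- match.arg(zero_cell, c("undefined", "haldane"))
  undef <- cells$a == 0 | cells$b == 0 | cells$c == 0 | cells$d == 0
  if (zero_cell == "haldane") {
    corrected <- undef
    cells$a[corrected] <- cells$a[corrected] + 0.5
    cells$b[corrected] <- cells$b[corrected] + 0.5
    cells$c[corrected] <- cells$c[corrected] + 0.5
    cells$d[corrected] <- cells$d[corrected] + 0.5
    undef <- rep_len(FALSE, length(undef))
  }
  cells$defined <- !undef
  cells
}

log_se <- function(cells) {
  sqrt(1 / cells$a + 1 / cells$b + 1 / cells$c + 1 / cells$d)
}

#' @rdname disproportionality
#' @export
ror_with_ci <- function(a, b, c, d, zero_cell = c("undefined", "haldane")) {
  cells <- apply_zero_cell(check_cells(a, b, c, d), zero_cell)
  ror <- with(cells, a * d / (b * c))
  s <- log_se(cells)
  out <- tibble::tibble(
    defined = cells$defined,
    ror = ror,
    ror_lo95 = ror * exp(-norm_q95 * s),
    ror_hi95 = ror * exp(norm_q95 * s)
  )
  out[!out$defined, c("ror", "ror_lo95", "ror_hi95")] <- NA_real_
  out
}

#' @rdname disproportionality
#' @export
prr_with_chi2 <- function(a, b, c, d, zero_cell = c("undefined", "haldane")) {
  cells <- apply_zero_cell(check_cells(a, b, c, d), zero_cell)
  n <- with(cells, a + b + c + d)
  prr <- with(cells, (a / (a + b)) / (c / (c + d)))
  chi2 <- with(cells,
    (a * d - b * c)^2 * n / ((a + b) * (c + d) * (a + c) * (b + d)))
  s <- log_se(cells)
  out <- tibble::tibble(
    defined = cells$defined,
    prr = prr,
    prr_lo95 = prr * exp(-norm_q95 * s),
    prr_hi95 = prr * exp(norm_q95 * s),
    chi2 = chi2
  )
  out[!out$defined, c("prr", "prr_lo95", "prr_hi95", "chi2")] <- NA_real_
  out
}

#' @rdname disproportionality
#' @export
ic_with_bound <- function(a, b, c, d, zero_cell = c("undefined", "haldane"),
                          ic_variance = c("plus1", "plain")) {
  ic_variance <- match.arg(ic_variance)
  cells <- apply_zero_cell(check_cells(a, b, c, d), zero_cell)
  n <- with(cells, a + b + c + d)
  ic <- with(cells, log2(a * n / ((a + c) * (a + b))))
  a_var <- if (ic_variance == "plus1") cells$a + 1 else cells$a
  s_ic <- sqrt(1 / a_var + 1 / cells$b + 1 / cells$c + 1 / cells$d)
  out <- tibble::tibble(
    defined = cells$defined,
    ic = ic,
    ic025 = ic - norm_q95 * s_ic / log(2)
  )
  out[!out$defined, c("ic", "ic025")] <- NA_real_
  out
}

#' @rdname disproportionality
#' @export
ebgm_with_bound <- function(a, b, c, d, zero_cell = c("undefined", "haldane")) {
  cells <- apply_zero_cell(check_cells(a, b, c, d), zero_cell)
  n <- with(cells, a + b + c + d)
  ebgm <- with(cells, a * n / ((a + c) * (a + b)))
  s <- log_se(cells)
  out <- tibble::tibble(
    defined = cells$defined,
    ebgm = ebgm,
    ebgm05 = ebgm * exp(-norm_q90_onesided * s)
  )
  out[!out$defined, c("ebgm", "ebgm05")] <- NA_real_
  out
}

#' Compute all four signal statistics for a set of contingency tables
#'
#' Convenience wrapper combining [ror_with_ci()], [prr_with_chi2()],
#' [ic_with_bound()] and [ebgm_with_bound()] over a table of 2x2 cells,
#' such as the output of [build_contingency()].
#'
#' @param tables A data frame with columns `a`, `b`, `c`, `d`; any other
#'   columns (e.g. `term`) are carried through.
#' @inheritParams disproportionality
#' @return `tables` with the statistic columns appended.
#' @export
signal_scores <- function(tables, zero_cell = c("undefined", "haldane"),
                          ic_variance = c("plus1", "plain")) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
  zero_cell <- match.arg(zero_cell)
  ror <- ror_with_ci(tables$a, tables$b, tables$c, tables$d, zero_cell)
  prr <- prr_with_chi2(tables$a, tables$b, tables$c, tables$d, zero_cell)
  ic <- ic_with_bound(tables$a, tables$b, tables$c, tables$d, zero_cell,
                      ic_variance)
  ebgm <- ebgm_with_bound(tables$a, tables$b, tables$c, tables$d, zero_cell)
  dplyr::bind_cols(
    tibble::as_tibble(tables),
    ror[, c("ror", "ror_lo95", "ror_hi95")],
    prr[, c("prr", "prr_lo95", "prr_hi95", "chi2")],
    ic[, c("ic", "ic025")],
    ebgm[, c("ebgm", "ebgm05")],
    tibble::tibble(defined = ror$defined)
  )
}

#' Screening criteria for disproportionality signals
#'
#' Threshold set applied by [screen_signals()]: the ROR rule (lower 95%
#' bound above `ror_lo_gt` with at least `min_a` reports), the PRR rule
#' (`PRR >= prr_min`, `chi2 >= chi2_min`, at least `min_a` reports), the
#' BCPNN rule (`IC025 > ic025_gt`) and the MGPS rule
#' (`EBGM05 > ebgm05_gt`).
#'
#' @param ror_lo_gt,min_a,prr_min,chi2_min,ic025_gt,ebgm05_gt Thresholds;
#'   defaults are the conventional screening values.
#' @param combine `"all"` (a signal must satisfy all four rules) or `"any"`.
#' @return A list of class `screen_criteria`.
#' @export
screen_criteria <- function(ror_lo_gt = 1, min_a = 3, prr_min = 2,
                            chi2_min = 4, ic025_gt = 0, ebgm05_gt = 2,
                            combine = c("all", "any")) {
  thresholds <- c(ror_lo_gt = ror_lo_gt, min_a = min_a, prr_min = prr_min,
                  chi2_min = chi2_min, ebgm05_gt = ebgm05_gt)
  if (any(!is.finite(thresholds)) || any(thresholds <= 0)) {
    stop("screening thresholds must be positive", call. = FALSE)
  }
  structure(
    list(ror_lo_gt = ror_lo_gt, min_a = min_a, prr_min = prr_min,
         chi2_min = chi2_min, ic025_gt = ic025_gt, ebgm05_gt = ebgm05_gt,
         combine = match.arg(combine)),
    class = "screen_criteria"
  )
}

#' Apply screening criteria to computed signal scores
#'
#' Adds the four per-rule flags and the overall `signal` decision to a score
#' table produced by [signal_scores()]. Undefined rows (`defined = FALSE`)
#' fail every rule.
#'
#' @param scores Output of [signal_scores()] (must retain column `a`).
#' @param criteria A [screen_criteria()] object.
#' @return `scores` with logical columns `ror_flag`, `prr_flag`, `ic_flag`,
#'   `ebgm_flag` and `signal` appended.
#' @export
screen_signals <- function(scores, criteria = screen_criteria()) {
  stopifnot(inherits(criteria, "screen_criteria"))
  ok <- scores$defined
  flag <- function(x) !is.na(x) & ok & x
  scores$ror_flag <- flag(scores$ror_lo95 > criteria$ror_lo_gt &
                            scores$a >= criteria$min_a)
  scores$prr_flag <- flag(scores$prr >= criteria$prr_min &
                            scores$chi2 >= criteria$chi2_min &
                            scores$a >= criteria$min_a)
  scores$ic_flag <- flag(scores$ic025 > criteria$ic025_gt)
  scores$ebgm_flag <- flag(scores$ebgm05 > criteria$ebgm05_gt)
  rules <- cbind(scores$ror_flag, scores$prr_flag, scores$ic_flag,
                 scores$ebgm_flag)
  scores$signal <- if (criteria$combine == "all") {
    rowSums(rules) == 4L
  } else {
    rowSums(rules) > 0L
  }
  scores
}

#' Write a signal table to a delimited file
#'
#' Formats a screened score table in the conventional published layout
#' (term, case reports, ROR (95% CI), PRR (95% CI), chi-square, IC (IC025),
#' EBGM (EBGM05), signal flag), rounding displayed values to 2 decimals.
#'
#' @param scores Output of [screen_signals()], with a `term` column.
#' @param path File path; tab-separated.
#' @return The formatted tibble, invisibly.
#' @export
write_signal_table <- function(scores, path) {
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  out <- tibble::tibble(
    term = scores$term,
    case_reports = scores$a,
    ror_ci = paste0(fmt(scores$ror), " (", fmt(scores$ror_lo95), ", ",
                    fmt(scores$ror_hi95), ")"),
    prr_ci = paste0(fmt(scores$prr), " (", fmt(scores$prr_lo95), ", ",
                    fmt(scores$prr_hi95), ")"),
    chi_square = fmt(scores$chi2),
    ic_ic025 = paste0(fmt(scores$ic), " (", fmt(scores$ic025), ")"),
    ebgm_ebgm05 = paste0(fmt(scores$ebgm), " (", fmt(scores$ebgm05), ")"),
    signal = scores$signal
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
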