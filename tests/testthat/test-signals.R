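test_that("chi-square and ROR match independent oracles on all small tables", {
  tabs <- all_small_tables()
  got <- signal_scores(tabs)
  # cross-product ratio, computed directly
  expect_identical(got$ror, with(tabs, a * d / (b * c)))
  # textbook Pearson statistic without continuity correction
  chi_oracle <- vapply(seq_len(nrow(tabs)), function(i) {
    m <- matrix(unlist(tabs[i, c("a", "b", "c", "d")]), 2, byrow = TRUE)
    unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic)
  }, numeric(1))
  expect_equal(got$chi2, chi_oracle, tolerance = 1e-12)
})

test_that("IC equals log2(EBGM) exactly for random tables", {
  tabs <- random_tables(500)
  got <- signal_scores(tabs)
  expect_equal(got$ic, log2(got$ebgm), tolerance = 1e-12)
})

test_that("interval bounds bracket the point estimates", {
  tabs <- random_tables(200, seed = 99)
  got <- signal_scores(tabs)
  expect_true(all(got$ror_lo95 <= got$ror & got$ror <= got$ror_hi95))
  expect_true(all(got$prr_lo95 <= got$prr & got$prr <= got$prr_hi95))
  expect_true(all(got$ic025 <= got$ic))
  expect_true(all(got$ebgm05 <= got$ebgm))
  expect_true(all(got$chi2 >= 0))
})

test_that("independence table gives null statistics", {
  got <- signal_scores(data.frame(a = 1, b = 1, c = 1, d = 1))
  expect_equal(got$ror, 1)
  expect_equal(got$prr, 1)
  expect_equal(got$chi2, 0)
  expect_equal(got$ic, 0)
  expect_equal(got$ebgm, 1)
  expect_true(got$ror_lo95 < 1 && got$ror_hi95 > 1)
})

test_that("cell swaps and scaling behave as the formulas require", {
  tabs <- random_tables(100, seed = 5)
  base <- signal_scores(tabs)
  # transposing the 2x2 table leaves chi-square unchanged
  swapped <- signal_scores(data.frame(a = tabs$a, b = tabs$c, c = tabs$b,
                                      d = tabs$d))
  expect_equal(swapped$chi2, base$chi2, tolerance = 1e-9)
  # scaling all cells leaves point estimates unchanged, shrinks intervals
  k <- 7
  scaled <- signal_scores(tabs * k)
  expect_equal(scaled$ror, base$ror, tolerance = 1e-12)
  expect_equal(scaled$prr, base$prr, tolerance = 1e-12)
  expect_equal(scaled$ic, base$ic, tolerance = 1e-12)
  expect_equal(scaled$ebgm, base$ebgm, tolerance = 1e-12)
  expect_true(all(scaled$ror_lo95 > base$ror_lo95))
  expect_true(all(scaled$ror_hi95 < base$ror_hi95))
})

test_that("ROR dominates PRR exactly when d/(c+d) >= b/(a+b)", {
  tabs <- random_tables(300, seed = 17)
  got <- signal_scores(tabs)
  dominates <- with(tabs, d / (c + d) >= b / (a + b))
  expect_true(all((got$ror >= got$prr - 1e-12) == dominates |
                    abs(got$ror - got$prr) < 1e-12))
  # equality iff the two fractions agree
  eq <- with(tabs, abs(b / (a + b) - d / (c + d)) < 1e-12)
  expect_equal(abs(got$ror - got$prr) < 1e-9, eq)
})

test_that("zero cells yield undefined rows unless the Haldane mode is on", {
  got <- signal_scores(data.frame(a = c(0, 5), b = c(3, 0), c = c(4, 4),
                                  d = c(10, 10)))
  expect_equal(got$defined, c(FALSE, FALSE))
  expect_true(all(is.na(got$ror)))
  hald <- signal_scores(data.frame(a = 0, b = 3, c = 4, d = 10),
                        zero_cell = "haldane")
  expect_true(hald$defined)
  expect_equal(hald$ror, 0.5 * 10.5 / (3.5 * 4.5))
})

test_that("screening rules apply their thresholds and the count gate", {
  null_scores <- screen_signals(signal_scores(data.frame(a = 1, b = 1,
                                                         c = 1, d = 1)))
  expect_false(any(unlist(null_scores[, c("ror_flag", "prr_flag", "ic_flag",
                                          "ebgm_flag", "signal")])))
  # huge disproportionality but only 2 reports: ROR rule fails its N >= 3 gate
  rare <- screen_signals(signal_scores(data.frame(a = 2, b = 10, c = 5,
                                                  d = 100000)))
  expect_false(rare$ror_flag)
  expect_false(rare$prr_flag)
  expect_error(screen_criteria(prr_min = -1), "positive")
})

test_that("reconstructed thrombocytopenia row passes all four screens", {
  t <- reconstruct_from_printed(35, 4.95, 3845, 32732219)
  sc <- screen_signals(signal_scores(t))
  expect_true(sc$ror_flag && sc$prr_flag && sc$ic_flag && sc$ebgm_flag)
  expect_true(sc$signal)
})

test_that("reconstructed tables reproduce the published signal statistics", {
  rec <- reconstruct_reference()
  got <- signal_scores(rec[, c("a", "b", "c", "d")])

  # PRR round-trip: inversion recovers the printed PRR well within 0.5%
  expect_true(all(abs(got$prr - rec$prr) / rec$prr < 0.005))
  # chi-square within 1% relative
  expect_true(all(abs(got$chi2 - rec$chi2) / rec$chi2 < 0.01))
  # ratio-scale statistics at printed precision: two-decimal printing of
  # values up to ~91 carries rounding noise above a flat 0.02, so check
  # 0.02 absolute or 0.2% relative, whichever is larger
  near <- function(est, printed) {
    abs(est - printed) <= pmax(0.02, 0.002 * abs(printed))
  }
  expect_true(all(near(got$ror, rec$ror)))
  expect_true(all(near(got$ror_lo95, rec$ror_lo95)))
  expect_true(all(near(got$ror_hi95, rec$ror_hi95)))
  expect_true(all(near(got$ic, rec$ic)))
  expect_true(all(near(got$ic025, rec$ic025)))
  expect_true(all(near(got$ebgm, rec$ebgm)))
  expect_true(all(near(got$ebgm05, rec$ebgm05)))
  # the published PRR intervals for the largest ratios deviate from the
  # log-scale variance by up to ~1%; check at 1.5% relative
  expect_true(all(abs(got$prr_lo95 - rec$prr_lo95) / rec$prr_lo95 < 0.015))
  expect_true(all(abs(got$prr_hi95 - rec$prr_hi95) / rec$prr_hi95 < 0.015))
})

test_that("published SOC-level rows reconstruct the same way", {
  ref <- avelumab_reference("soc")
  m <- avelumab_margins()
  expect_equal(sum(ref$n), m$drug_margin)
  rec <- reconstruct_from_printed(ref$n, ref$prr, m$drug_margin, m$n_total)
  got <- signal_scores(rec)
  expect_true(all(abs(got$ic - ref$ic) <= 0.02))
  expect_true(all(abs(got$ic025 - ref$ic025) <= 0.02))
  expect_true(all(abs(got$ror - ref$ror) <= pmax(0.02, 0.002 * ref$ror)))
  expect_true(all(abs(got$ebgm - ref$ebgm) <= 0.02))
  # chi-square for near-null SOCs is quadratically sensitive to the
  # 2-decimal rounding of the printed PRR used in the inversion
  expect_true(all(abs(got$chi2 - ref$chi2) / ref$chi2 < 0.1))
})
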