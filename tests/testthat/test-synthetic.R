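test_that("invalid configurations are rejected naming the field", {
  expect_error(synthetic_config(n_cases = 0), "n_cases")
  expect_error(synthetic_config(target_drug_share = 1.2),
               "target_drug_share")
  expect_error(synthetic_config(duplicate_rate = 1), "duplicate_rate")
  expect_error(synthetic_config(events_per_case = 0.5), "events_per_case")
  expect_error(
    synthetic_config(n_events = 10,
                     background_event_weights = rep(0.2, 10)),
    "background_event_weights")
  expect_error(
    synthetic_config(n_events = 10,
                     planted_signals = data.frame(pt_id = 11,
                                                  relative_risk = 2)),
    "planted_signals")
  expect_error(
    synthetic_config(demographic_marginals = list(gender = c(F = 0.5))),
    "demographic_marginals")
})

test_that("no duplicates means one caseid per case, and plants are recorded", {
  cfg <- synthetic_config(n_cases = 500, duplicate_rate = 0, seed = 3,
                          planted_signals = data.frame(
                            pt_id = c(2, 9), relative_risk = c(4, 0.5)))
  g <- generate_reports(cfg)
  expect_equal(length(unique(g$tables$demo$caseid)), 500)
  expect_equal(nrow(g$tables$demo), 500)
  gt <- g$ground_truth
  expect_equal(gt$pt$relative_risk[c(2, 9)], c(4, 0.5))
  expect_true(all(gt$pt$relative_risk[-c(2, 9)] == 1))
  # exactly one latest version per caseid
  expect_equal(sum(gt$cases$is_latest), length(unique(gt$cases$caseid)))
})

test_that("the same configuration emits byte-identical files", {
  cfg <- synthetic_config(n_cases = 400, duplicate_rate = 0.15, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- generate_reports(cfg, dir = d1)$files
  f2 <- generate_reports(cfg, dir = d2)$files
  expect_equal(basename(f1), basename(f2))
  h1 <- unname(tools::md5sum(sort(unlist(f1))))
  h2 <- unname(tools::md5sum(sort(unlist(f2))))
  expect_identical(h1, h2)
})

test_that("row conservation holds and all child rows join to DEMO", {
  cfg <- synthetic_config(n_cases = 1000, duplicate_rate = 0.2, seed = 5,
                          events_per_case = 2.5)
  g <- generate_reports(cfg)
  demo_ids <- g$tables$demo$primaryid
  for (tab in c("drug", "reac", "outc", "ther")) {
    expect_true(all(g$tables[[tab]]$primaryid %in% demo_ids))
  }
  # every report version has at least one reaction row
  expect_true(all(demo_ids %in% g$tables$reac$primaryid))
  # duplicated versions replicate their case's reaction rows
  reac_per_id <- table(g$tables$reac$primaryid)
  gt <- g$ground_truth$cases
  v1 <- gt$primaryid[gt$version == 1]
  v2 <- gt$primaryid[gt$version == 2]
  matched_v1 <- gt$caseid[gt$version == 2] * 10 + 1
  expect_equal(as.integer(reac_per_id[as.character(v2)]),
               as.integer(reac_per_id[as.character(matched_v1)]))
})

test_that("a planted fivefold risk shows up in the emitted corpus", {
  cfg <- synthetic_config(n_cases = 200000, target_drug_share = 0.02,
                          n_events = 200, duplicate_rate = 0,
                          planted_signals = data.frame(pt_id = 7,
                                                       relative_risk = 5),
                          seed = 42)
  g <- generate_reports(cfg)
  # independent recount straight from the emitted tables with base R
  ps <- g$tables$drug
  target_ids <- ps$primaryid[ps$drugname %in% c("AVELUMAB", "BAVENCIO") &
                               ps$role_cod == "PS"]
  reac <- g$tables$reac
  is_t <- reac$primaryid %in% target_ids
  rate_t <- mean(reac$pt[is_t] == "PT_007")
  rate_o <- mean(reac$pt[!is_t] == "PT_007")
  expect_gt(rate_t / rate_o, 3.5)
  expect_lt(rate_t / rate_o, 6.5)

  # and the full signal pipeline recovers it: EBGM within [3.5, 6.5]
  rows <- event_rows(g$tables, target_ids, level = "pt")
  tabs <- build_contingency(rows)
  sc <- signal_scores(tabs)
  row7 <- sc[sc$term == "PT_007", ]
  expect_gte(row7$a, 30)
  expect_gt(row7$ebgm, 3.5)
  expect_lt(row7$ebgm, 6.5)
})

test_that("generator helpers match the corpus naming", {
  cfg <- synthetic_config(n_cases = 10, n_events = 25)
  syn <- synthetic_synonyms(cfg)
  expect_equal(syn$canonical, "AVELUMAB")
  dict <- synthetic_pt_soc(cfg)
  expect_equal(nrow(dict), 25)
  expect_equal(length(unique(dict$soc)), 10)
})
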