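test_that("an empty table with a valid header parses to zero rows", {
  dir <- write_quarter_fixture(
    withr::local_tempdir(),
    demo = "11$1$20220101$$55$YR$M$MD$US",
    drug = "11$1$1$PS$AVELUMAB$INTRAVENOUS",
    reac = character()  # header only
  )
  tabs <- read_faers(dir)
  expect_equal(nrow(tabs$reac), 0)
  expect_equal(nrow(tabs$demo), 1)
})

test_that("short rows are counted as malformed, not silently dropped", {
  dir <- write_quarter_fixture(
    withr::local_tempdir(),
    demo = "11$1$20220101$$55$YR$M$MD$US",
    drug = "11$1$1$PS$AVELUMAB$INTRAVENOUS",
    reac = c("11$1$Chills", "11$1")  # second row one field short
  )
  expect_warning(tabs <- read_faers(dir), "malformed")
  expect_equal(nrow(tabs$reac), 1)
  expect_equal(unname(attr(tabs, "malformed")["reac"]), 1L)
})

test_that("a missing mandatory column is a format error naming it", {
  dir <- withr::local_tempdir()
  write_quarter_fixture(dir,
    demo = "11$1$20220101$$55$YR$M$MD$US",
    drug = "11$1$1$PS$AVELUMAB$INTRAVENOUS")
  # overwrite REAC with a header lacking 'pt'
  writeLines("primaryid$caseid", file.path(dir, "REAC2022Q1.txt"))
  expect_error(read_faers(dir), "pt")
})

test_that("a synthetic quarter round-trips through write and parse", {
  cfg <- synthetic_config(n_cases = 300, duplicate_rate = 0.1, seed = 21)
  dir <- withr::local_tempdir()
  g <- generate_reports(cfg, dir = dir)
  tabs <- read_faers(dir)
  for (tab in c("demo", "drug", "reac", "outc", "ther")) {
    expect_equal(nrow(tabs[[tab]]), nrow(g$tables[[tab]]))
  }
  # re-serialise and re-parse: typed rows identical
  dir2 <- withr::local_tempdir()
  write_faers_files(tabs, dir2)
  tabs2 <- read_faers(dir2)
  for (tab in c("demo", "drug", "reac", "outc", "ther")) {
    o1 <- tabs[[tab]][do.call(order, unname(as.list(tabs[[tab]]))), ]
    o2 <- tabs2[[tab]][do.call(order, unname(as.list(tabs2[[tab]]))), ]
    expect_equal(as.data.frame(o1), as.data.frame(o2),
                 ignore_attr = TRUE)
  }
})

test_that("deduplication keeps the latest version and is order-invariant", {
  demo <- tibble::tibble(
    primaryid = c("71", "72", "81"),
    caseid = c("7", "7", "8"),
    fda_dt = c("20230101", "20230301", "20220601"),
    event_dt = NA, age = NA, age_cod = NA, sex = c("M", "F", "M"),
    occp_cod = "MD", reporter_country = "US"
  )
  tabs <- list(demo = demo,
               drug = tibble::tibble(primaryid = character(),
                                     caseid = character()),
               reac = tibble::tibble(primaryid = character(),
                                     caseid = character()),
               outc = tibble::tibble(primaryid = character(),
                                     caseid = character()),
               ther = tibble::tibble(primaryid = character(),
                                     caseid = character()))
  dd <- deduplicate_cases(tabs)
  expect_equal(sort(dd$demo$primaryid), c("72", "81"))
  # the 2023-03-01 version wins for case 7
  expect_equal(dd$demo$sex[dd$demo$caseid == "7"], "F")
  # idempotence
  expect_equal(as.data.frame(deduplicate_cases(dd)$demo),
               as.data.frame(dd$demo))
  # shuffling input rows changes nothing
  tabs_shuffled <- tabs
  tabs_shuffled$demo <- demo[c(3, 1, 2), ]
  expect_equal(as.data.frame(deduplicate_cases(tabs_shuffled)$demo),
               as.data.frame(dd$demo))
  # tie on the date: highest primaryid wins
  tabs$demo$fda_dt <- c("20230101", "20230101", "20220601")
  expect_equal(sort(deduplicate_cases(tabs)$demo$primaryid), c("72", "81"))
})

test_that("deduplication agrees with the generator's ground truth", {
  cfg <- synthetic_config(n_cases = 2000, duplicate_rate = 0.2, seed = 8)
  g <- generate_reports(cfg)
  dd <- deduplicate_cases(g$tables)
  gt <- g$ground_truth$cases
  expect_setequal(as.character(dd$demo$primaryid),
                  as.character(gt$primaryid[gt$is_latest]))
})

test_that("drug-name normalisation folds case and applies synonyms", {
  syn <- tibble::tibble(raw = "Bavencio", canonical = "AVELUMAB")
  got <- normalize_drug_names(c("Bavencio", "  avelumab ", "XYZ-123"), syn)
  expect_equal(as.character(got), c("AVELUMAB", "AVELUMAB", "XYZ-123"))
  expect_equal(attr(got, "remainder"), c("AVELUMAB", "XYZ-123"))
  conflicting <- tibble::tibble(raw = c("bavencio", "BAVENCIO"),
                                canonical = c("AVELUMAB", "OTHER"))
  expect_error(normalize_drug_names("x", conflicting), "conflicting")
})

test_that("target selection requires the primary-suspect role", {
  demo <- tibble::tibble(
    primaryid = c("1", "2"), caseid = c("1", "2"),
    fda_dt = "20230101", event_dt = NA, age = NA, age_cod = NA,
    sex = "M", occp_cod = "MD", reporter_country = "US")
  drug <- tibble::tibble(
    primaryid = c("1", "2", "2"), caseid = c("1", "2", "2"),
    drug_seq = c("1", "1", "2"),
    role_cod = c("C", "PS", "C"),
    drugname = c("AVELUMAB", "AVELUMAB", "OTHERDRUG"),
    route = "OTHER")
  reac <- tibble::tibble(primaryid = c("1", "2", "2", "2"),
                         caseid = c("1", "2", "2", "2"),
                         pt = c("Chills", "Chills", "Colitis", "Myositis"))
  empty <- tibble::tibble(primaryid = character(), caseid = character())
  tabs <- list(demo = demo, drug = drug, reac = reac,
               outc = empty, ther = empty)
  sel <- select_target_reports(tabs, "AVELUMAB")
  # concomitant-only case 1 excluded; case 2 in once despite 3 reactions
  expect_equal(sel$demo$primaryid, "2")
})

test_that("target selection matches the generator tally", {
  cfg <- synthetic_config(n_cases = 3000, target_drug_share = 0.1,
                          duplicate_rate = 0.1, seed = 13)
  g <- generate_reports(cfg)
  dd <- deduplicate_cases(g$tables)
  sel <- select_target_reports(dd, "AVELUMAB", synthetic_synonyms(cfg))
  gt <- g$ground_truth$cases
  expect_equal(nrow(sel$demo), sum(gt$is_target & gt$is_latest))
})

test_that("age conversion handles the unit codes and implausible values", {
  expect_equal(age_in_years(c("6", "55", "18", "26", "730"),
                            c("DEC", "YR", "MON", "WK", "DY")),
               c(60, 55, 1.5, 0.5, 730 / 365.25))
  expect_true(is.na(age_in_years("130", "YR")))  # > 122 years
  expect_true(is.na(age_in_years("", "YR")))
  expect_true(is.na(age_in_years("50", "XX")))   # unknown unit
})

test_that("partial dates floor to the period start and flag imprecision", {
  got <- parse_faers_date(c("20230315", "202303", "2023", "", "99"))
  expect_equal(got$date[1:3],
               as.Date(c("2023-03-15", "2023-03-01", "2023-01-01")))
  expect_equal(got$imprecise, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_true(all(is.na(got$date[4:5])))
})
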