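#' Configuration for the synthetic spontaneous-report generator
#'
#' Parameters controlling [generate_reports()]. Defaults emulate the mix
#' observed in post-marketing avelumab reports: demographic marginals match
#' the published report-level distributions (gender, reporter occupation,
#' country, administration route, serious outcomes), 23% of reports lack
#' age and 31% lack an event date.
#'
#' @param n_cases Number of distinct cases to simulate.
#' @param n_drugs Number of distinct non-target drugs in the corpus.
#' @param n_events Number of distinct preferred terms (PTs).
#' @param target_drug_share Fraction in (0,1) of cases whose primary-suspect
#'   drug is the target drug.
#' @param background_event_weights Probability vector of length `n_events`
#'   giving the PT distribution for non-target cases (default uniform).
#' @param planted_signals Data frame with columns `pt_id` (1-based index
#'   into the PT list) and `relative_risk` (>= 0): for target-drug cases the
#'   background weight of each planted PT is multiplied by its relative
#'   risk and the vector renormalised.
#' @param events_per_case Mean reactions per case; drawn as
#'   `1 + Poisson(events_per_case - 1)` so every case has at least one.
#' @param duplicate_rate Fraction in \[0,1) of cases additionally emitted as
#'   a second, later report version (same caseid, incremented primaryid,
#'   later receipt date, gender perturbed).
#' @param missing_age_rate,missing_date_rate Fractions in \[0,1) of reports
#'   with missing age / missing event date.
#' @param demographic_marginals Named list of named probability vectors for
#'   `gender`, `reporter`, `country`, `route` and `outcome`.
#' @param n_quarters Number of consecutive calendar quarters to simulate.
#' @param start_year,start_quarter First simulated quarter.
#' @param target_drug Canonical target drug name.
#' @param target_brand Brand name emitted verbatim for a share of
#'   target-drug entries (exercises synonym normalisation).
#' @param seed Integer RNG seed; the same configuration always produces
#'   byte-identical output files.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 20000,
                             n_drugs = 50,
                             n_events = 200,
                             target_drug_share = 0.02,
                             background_event_weights = NULL,
                             planted_signals = NULL,
                             events_per_case = 2,
                             duplicate_rate = 0.05,
                             missing_age_rate = 0.23,
                             missing_date_rate = 0.31,
                             demographic_marginals = NULL,
                             n_quarters = 4,
                             start_year = 2022,
                             start_quarter = 1,
                             target_drug = "AVELUMAB",
                             target_brand = "BAVENCIO",
                             seed = 1L) {
  check_count <- function(x, name) {
    if (length(x) != 1 || is.na(x) || x < 1 || x != as.integer(x)) {
      stop(sprintf("invalid config field '%s': must be a positive count", name),
           call. = FALSE)
    }
  }
  check_rate <- function(x, name, lo = 0, hi = 1, open_hi = TRUE) {
    bad <- length(x) != 1 || is.na(x) || x < lo ||
      (if (open_hi) x >= hi else x > hi)
    if (bad) {
      stop(sprintf("invalid config field '%s': must be in [%s, %s%s", lo,
                   name, hi, if (open_hi) ")" else "]"), call. = FALSE)
    }
  }
  check_count(n_cases, "n_cases")
  check_count(n_drugs, "n_drugs")
  check_count(n_events, "n_events")
  check_count(n_quarters, "n_quarters")
  if (length(target_drug_share) != 1 || is.na(target_drug_share) ||
      target_drug_share <= 0 || target_drug_share >= 1) {
    stop("invalid config field 'target_drug_share': must be in (0, 1)",
         call. = FALSE)
  }
  check_rate(duplicate_rate, "duplicate_rate")
  check_rate(missing_age_rate, "missing_age_rate")
  check_rate(missing_date_rate, "missing_date_rate")
  if (length(events_per_case) != 1 || is.na(events_per_case) ||
      events_per_case < 1) {
    stop("invalid config field 'events_per_case': mean must be >= 1",
         call. = FALSE)
  }

  if (is.null(background_event_weights)) {
    background_event_weights <- rep(1 / n_events, n_events)
  }
  if (length(background_event_weights) != n_events ||
      any(background_event_weights < 0) ||
      abs(sum(background_event_weights) - 1) > 1e-9) {
    stop("invalid config field 'background_event_weights': must be a ",
         "probability vector of length n_events summing to 1", call. = FALSE)
  }

  if (is.null(planted_signals)) {
    planted_signals <- data.frame(pt_id = integer(), relative_risk = numeric())
  }
  planted_signals <- as.data.frame(planted_signals)
  if (!all(c("pt_id", "relative_risk") %in% names(planted_signals))) {
    stop("invalid config field 'planted_signals': needs columns pt_id and ",
         "relative_risk", call. = FALSE)
  }
  if (nrow(planted_signals) > 0 &&
      (any(planted_signals$pt_id < 1) ||
       any(planted_signals$pt_id > n_events) ||
       any(duplicated(planted_signals$pt_id)) ||
       any(planted_signals$relative_risk < 0))) {
    stop("invalid config field 'planted_signals': pt_id must be distinct ",
         "indices in 1..n_events and relative_risk >= 0", call. = FALSE)
  }

  marginals <- default_marginals()
  if (!is.null(demographic_marginals)) {
    for (nm in names(demographic_marginals)) {
      if (!nm %in% names(marginals)) {
        stop(sprintf("invalid config field 'demographic_marginals': unknown factor '%s'", nm),
             call. = FALSE)
      }
      marginals[[nm]] <- demographic_marginals[[nm]]
    }
  }
  for (nm in names(marginals)) {
    p <- marginals[[nm]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("invalid config field 'demographic_marginals': '%s' must be a named probability vector summing to 1", nm),
           call. = FALSE)
    }
  }
  if (!start_quarter %in% 1:4) {
    stop("invalid config field 'start_quarter': must be 1..4", call. = FALSE)
  }

  structure(
    list(n_cases = as.integer(n_cases), n_drugs = as.integer(n_drugs),
         n_events = as.integer(n_events),
         target_drug_share = target_drug_share,
         background_event_weights = background_event_weights,
         planted_signals = planted_signals,
         events_per_case = events_per_case,
         duplicate_rate = duplicate_rate,
         missing_age_rate = missing_age_rate,
         missing_date_rate = missing_date_rate,
         demographic_marginals = marginals,
         n_quarters = as.integer(n_quarters),
         start_year = as.integer(start_year),
         start_quarter = as.integer(start_quarter),
         target_drug = toupper(target_drug),
         target_brand = toupper(target_brand),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Report-level demographic mix observed for post-marketing avelumab reports.
default_marginals <- function() {
  list(
    gender = c(F = 0.2624, M = 0.6359, UNK = 0.1017),
    reporter = c(MD = 0.7040, PH = 0.1393, CN = 0.1006, OT = 0.0503,
                 UNK = 0.0058),
    country = c(OTHER = 0.4044, US = 0.2881, JP = 0.1430, FR = 0.0948,
                GB = 0.0697),
    route = c("INTRAVENOUS" = 0.4484, "OTHER" = 0.4039,
              "INTRAVENOUS DRIP" = 0.1477),
    outcome = c(HO = 0.3481, OT = 0.3302, DE = 0.2511, LT = 0.0552,
                DS = 0.0134, RI = 0.0020)
  )
}

sample_marginal <- function(n, p) {
  names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
}

quarter_label <- function(date) {
  paste0(format(date, "%Y"), "Q", (as.integer(format(date, "%m")) - 1) %/% 3 + 1)
}

#' Generate a synthetic FAERS-style quarterly report corpus
#'
#' Simulates case-linked DEMO/DRUG/REAC/OUTC/THER tables with known ground
#' truth: a configurable share of cases has the target drug as primary
#' suspect, and for those cases the reaction distribution is the background
#' PT distribution reweighted by the planted relative risks. A fraction of
#' cases is emitted twice (same caseid, later report version) to exercise
#' deduplication. Output is deterministic: the same configuration (including
#' seed) yields byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory for the quarterly `$`-delimited files and
#'   ground-truth TSVs; `NULL` (default) keeps everything in memory.
#' @return A list with elements
#'   `tables` (list of tibbles `demo`, `drug`, `reac`, `outc`, `ther`),
#'   `ground_truth` (list with `pt` -- per-PT true relative risk for the
#'   target drug -- and `cases` -- one row per emitted report version with
#'   its `is_latest` flag), and `files` (paths written, or `NULL`).
#' @export
generate_reports <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  sim <- withr::with_seed(config$seed, simulate_corpus(config))
  files <- NULL
  if (!is.null(dir)) {
    files <- write_faers_files(sim$tables, dir)
    gt_files <- c(
      pt = file.path(dir, "ground_truth_pt.tsv"),
      cases = file.path(dir, "ground_truth_cases.tsv")
    )
    write.table(sim$ground_truth$pt, gt_files["pt"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$ground_truth$cases, gt_files["cases"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, gt_files)
  }
  list(tables = sim$tables, ground_truth = sim$ground_truth, files = files)
}

simulate_corpus <- function(config) {
  n <- config$n_cases
  caseid <- 10000000L + seq_len(n)
  primaryid <- caseid * 10L + 1L

  q_start <- as.Date(sprintf("%d-%02d-01", config$start_year,
                             (config$start_quarter - 1) * 3 + 1))
  q_index <- sample.int(config$n_quarters, n, replace = TRUE)
  q_first <- seq(q_start, by = "3 months", length.out = config$n_quarters + 1)
  q_len <- as.integer(q_first[-1] - q_first[-length(q_first)])
  fda_date <- q_first[q_index] + floor(runif(n) * q_len[q_index])

  is_target <- runif(n) < config$target_drug_share
  other_drugs <- sprintf("DRUG_%03d", seq_len(config$n_drugs))
  ps_drug <- ifelse(is_target, config$target_drug,
                    other_drugs[sample.int(config$n_drugs, n, replace = TRUE)])
  # brand-name spelling for a share of target entries
  use_brand <- is_target & runif(n) < 0.2
  ps_raw <- ifelse(use_brand, config$target_brand, ps_drug)

  m <- config$demographic_marginals
  gender <- sample_marginal(n, m$gender)
  reporter <- sample_marginal(n, m$reporter)
  country <- sample_marginal(n, m$country)
  route <- sample_marginal(n, m$route)

  age_years <- pmin(pmax(round(rnorm(n, 66, 12)), 19), 98)
  age_unit <- ifelse(runif(n) < 0.9, "YR", "DEC")
  age_value <- ifelse(age_unit == "YR", age_years, round(age_years / 10))
  age_missing <- runif(n) < config$missing_age_rate
  age_value[age_missing] <- NA
  age_unit[age_missing] <- NA

  ther_start <- fda_date - sample(30:210, n, replace = TRUE)
  onset_days <- floor(rexp(n, 1 / 40))
  event_date <- pmin(ther_start + onset_days, fda_date)
  event_date[runif(n) < config$missing_date_rate] <- NA

  # reactions: >= 1 per case; target cases use reweighted PT distribution
  k <- 1L + rpois(n, config$events_per_case - 1)
  w_bg <- config$background_event_weights
  w_target <- w_bg
  if (nrow(config$planted_signals) > 0) {
    w_target[config$planted_signals$pt_id] <-
      w_target[config$planted_signals$pt_id] *
      config$planted_signals$relative_risk
    w_target <- w_target / sum(w_target)
  }
  case_of_row <- rep.int(seq_len(n), k)
  target_row <- is_target[case_of_row]
  pt_id <- integer(length(case_of_row))
  pt_id[!target_row] <- sample.int(config$n_events, sum(!target_row),
                                   replace = TRUE, prob = w_bg)
  if (any(target_row)) {
    pt_id[target_row] <- sample.int(config$n_events, sum(target_row),
                                    replace = TRUE, prob = w_target)
  }

  # concomitant / secondary-suspect drugs
  n_con <- rpois(n, 0.7)
  con_case <- rep.int(seq_len(n), n_con)
  con_drug <- other_drugs[sample.int(config$n_drugs, length(con_case),
                                     replace = TRUE)]
  con_role <- sample(c("C", "SS", "I"), length(con_case), replace = TRUE,
                     prob = c(0.7, 0.2, 0.1))

  # serious outcomes: one per case for most, occasionally a second
  has_out <- runif(n) < 0.85
  out_case1 <- which(has_out)
  out_code1 <- sample_marginal(length(out_case1), m$outcome)
  out_case2 <- which(has_out & runif(n) < 0.15)
  out_code2 <- sample_marginal(length(out_case2), m$outcome)
  outc <- tibble::tibble(case = c(out_case1, out_case2),
                         outc_cod = c(out_code1, out_code2))
  outc <- dplyr::distinct(outc, .data$case, .data$outc_cod)
  outc <- outc[order(outc$case, outc$outc_cod), ]

  # duplicate versions: same caseid, later primaryid and receipt date,
  # gender perturbed
  dup <- which(runif(n) < config$duplicate_rate)
  dup_fda <- fda_date[dup] + sample(30:120, length(dup), replace = TRUE)
  dup_primaryid <- caseid[dup] * 10L + 2L
  dup_gender <- ifelse(gender[dup] == "M", "F", "M")

  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))

  demo <- tibble::tibble(
    primaryid = c(primaryid, dup_primaryid),
    caseid = c(caseid, caseid[dup]),
    fda_dt = c(fmt_date(fda_date), fmt_date(dup_fda)),
    event_dt = c(fmt_date(event_date), fmt_date(event_date[dup])),
    age = as.character(c(age_value, age_value[dup])),
    age_cod = c(age_unit, age_unit[dup]),
    sex = c(gender, dup_gender),
    occp_cod = c(reporter, reporter[dup]),
    reporter_country = c(country, country[dup])
  )
  demo$age[is.na(demo$age)] <- ""
  demo$age_cod[is.na(demo$age_cod)] <- ""

  drug_one <- tibble::tibble(
    case = c(seq_len(n), con_case),
    drug_seq = c(rep(1L, n), unlist_seq(n_con)),
    role_cod = c(rep("PS", n), con_role),
    drugname = c(ps_raw, con_drug),
    route = c(route, rep("OTHER", length(con_case)))
  )
  drug <- expand_versions(drug_one, caseid, dup)
  reac_one <- tibble::tibble(
    case = case_of_row,
    pt = sprintf("PT_%03d", pt_id)
  )
  reac <- expand_versions(reac_one, caseid, dup)
  outc_tbl <- expand_versions(outc, caseid, dup)
  ther_one <- tibble::tibble(
    case = seq_len(n),
    dsg_drug_seq = 1L,
    start_dt = fmt_date(ther_start)
  )
  ther <- expand_versions(ther_one, caseid, dup)

  rr <- rep(1, config$n_events)
  if (nrow(config$planted_signals) > 0) {
    rr[config$planted_signals$pt_id] <- config$planted_signals$relative_risk
  }
  gt_pt <- tibble::tibble(pt = sprintf("PT_%03d", seq_len(config$n_events)),
                          relative_risk = rr)
  gt_cases <- tibble::tibble(
    caseid = c(caseid, caseid[dup]),
    primaryid = c(primaryid, dup_primaryid),
    version = c(rep(1L, n), rep(2L, length(dup))),
    is_latest = c(!seq_len(n) %in% dup, rep(TRUE, length(dup))),
    is_target = c(is_target, is_target[dup])
  )
  gt_cases <- gt_cases[order(gt_cases$caseid, gt_cases$version), ]

  tables <- list(demo = demo, drug = drug, reac = reac, outc = outc_tbl,
                 ther = ther)
  list(tables = tables, ground_truth = list(pt = gt_pt, cases = gt_cases))
}

# per-case running sequence 2, 3, ... for concomitant drug entries
unlist_seq <- function(counts) {
  if (sum(counts) == 0) return(integer())
  unlist(lapply(counts[counts > 0], seq_len), use.names = FALSE) + 1L
}

# replicate per-case child rows for duplicate report versions and attach ids
expand_versions <- function(tbl, caseid, dup) {
  v1 <- tbl
  v1$primaryid <- caseid[v1$case] * 10L + 1L
  v1$caseid <- caseid[v1$case]
  v2 <- tbl[tbl$case %in% dup, , drop = FALSE]
  v2$primaryid <- caseid[v2$case] * 10L + 2L
  v2$caseid <- caseid[v2$case]
  out <- rbind(v1, v2)
  out <- out[order(out$primaryid), setdiff(names(out), "case"), drop = FALSE]
  cols <- c("primaryid", "caseid", setdiff(names(out), c("primaryid", "caseid")))
  tibble::as_tibble(out[, cols])
}

#' Write in-memory FAERS-style tables as quarterly $-delimited files
#'
#' One file per table per calendar quarter (`DEMO2022Q1.txt`, ...), first
#' line a `$`-separated header, dates as YYYYMMDD integers. Report versions
#' are assigned to the quarter of their own receipt date.
#'
#' @param tables List of tibbles `demo`, `drug`, `reac`, `outc`, `ther`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths written.
#' @export
write_faers_files <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  quarter_of <- setNames(
    quarter_label(as.Date(tables$demo$fda_dt, format = "%Y%m%d")),
    tables$demo$primaryid
  )
  paths <- character()
  for (tab in names(tables)) {
    tbl <- tables[[tab]]
    q <- quarter_of[as.character(tbl$primaryid)]
    for (lab in sort(unique(q))) {
      part <- tbl[q == lab, , drop = FALSE]
      part[] <- lapply(part, function(col) {
        col <- as.character(col)
        col[is.na(col)] <- ""
        col
      })
      path <- file.path(dir, paste0(toupper(tab), lab, ".txt"))
      lines <- c(paste(names(part), collapse = "$"),
                 do.call(paste, c(unname(as.list(part)), sep = "$")))
      writeLines(lines, path)
      paths <- c(paths, path)
    }
  }
  paths
}

#' Synonym table matching the synthetic corpus
#'
#' Two-column tibble mapping the brand-name spelling emitted by
#' [generate_reports()] to the canonical target drug name.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `raw` and `canonical`.
#' @export
synthetic_synonyms <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tibble::tibble(raw = config$target_brand, canonical = config$target_drug)
}

#' PT-to-SOC dictionary matching the synthetic corpus
#'
#' Assigns the `n_events` synthetic preferred terms round-robin to ten
#' synthetic system organ classes.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `pt` and `soc`.
#' @export
synthetic_pt_soc <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- seq_len(config$n_events)
  tibble::tibble(
    pt = sprintf("PT_%03d", ids),
    soc = sprintf("SOC_%02d", (ids - 1L) %% 10L + 1L)
  )
}
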