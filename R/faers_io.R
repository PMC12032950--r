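#' @name faers_io
#' @title Reading and linking FAERS-style quarterly files
#'
#' @description
#' FAERS quarterly extracts ship one ASCII file per table, `$`-delimited,
#' with a header line. Reports are keyed by `primaryid` (one id per report
#' version) and grouped into cases by `caseid`; the DEMO table carries the
#' receipt date (`fda_dt`) used to pick the most recent version of each
#' case.
NULL

faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "reporter_country"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "route"),
  reac = c("primaryid", "caseid", "pt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt")
)

parse_dollar_file <- function(path, table) {
  required <- faers_schema[[table]]
  lines <- readLines(path)
  if (length(lines) == 0) {
    stop(sprintf("format error in %s: empty file, no header", path),
         call. = FALSE)
  }
  header <- strsplit(lines[[1]], "$", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    stop(sprintf("format error in %s: missing mandatory column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "$", fixed = TRUE)
  # trailing empty field is dropped by strsplit; pad rows one short whose
  # line ends in the delimiter
  nf <- lengths(fields)
  ends_delim <- endsWith(body, "$")
  fields[nf == length(header) - 1 & ends_delim] <-
    lapply(fields[nf == length(header) - 1 & ends_delim], c, "")
  nf <- lengths(fields)
  ok <- nf == length(header)
  cols <- lapply(seq_along(header), function(i) {
    vapply(fields[ok], `[[`, character(1), i)
  })
  out <- tibble::as_tibble(setNames(cols, header))
  out[] <- lapply(out, function(col) {
    col[col == ""] <- NA
    col
  })
  attr(out, "n_malformed") <- sum(!ok)
  out
}

#' Parse a set of FAERS-style quarterly files
#'
#' Reads all `DEMO*/DRUG*/REAC*/OUTC*/THER*` `.txt` files found in `dir`
#' (any number of quarters) into one tibble per table. Rows whose field
#' count disagrees with the header are counted as malformed and excluded;
#' the per-table tallies are kept in the `malformed` attribute and a
#' warning is raised if the malformed fraction of any table exceeds
#' `max_malformed`.
#'
#' @param dir Directory containing the quarterly files.
#' @param max_malformed Tolerated malformed-row fraction per table before a
#'   warning is raised.
#' @return A list of class `faers_tables` with tibbles `demo`, `drug`,
#'   `reac`, `outc`, `ther` (all columns character; empty fields `NA`) and
#'   attribute `malformed` (named integer vector).
#' @export
read_faers <- function(dir, max_malformed = 0.01) {
  stopifnot(dir.exists(dir))
  tables <- list()
  malformed <- setNames(integer(length(faers_schema)), names(faers_schema))
  for (tab in names(faers_schema)) {
    paths <- list.files(dir, pattern = paste0("^", toupper(tab), ".*\\.txt$"),
                        full.names = TRUE)
    if (length(paths) == 0) {
      stop(sprintf("no %s files found in %s", toupper(tab), dir),
           call. = FALSE)
    }
    parts <- lapply(sort(paths), parse_dollar_file, table = tab)
    malformed[[tab]] <- sum(vapply(parts, attr, integer(1), "n_malformed"))
    tables[[tab]] <- dplyr::bind_rows(parts)[, faers_schema[[tab]]]
    n_rows <- nrow(tables[[tab]]) + malformed[[tab]]
    if (n_rows > 0 && malformed[[tab]] / n_rows > max_malformed) {
      warning(sprintf("%s: %d of %d rows malformed", toupper(tab),
                      malformed[[tab]], n_rows), call. = FALSE)
    }
  }
  structure(tables, class = "faers_tables", malformed = malformed)
}

#' Parse FAERS-style dates, tolerating partial values
#'
#' Full dates are `YYYYMMDD`; partial dates (`YYYYMM`, `YYYY`) are floored
#' to the first day of the month / year so they still order correctly, and
#' flagged imprecise so interval computations can exclude them.
#'
#' @param x Character vector of date fields.
#' @return A data frame with columns `date` (Date) and `imprecise`
#'   (logical; `NA` dates are imprecise).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(ifelse(is.na(x), "", x))
  date <- rep(as.Date(NA), length(x))
  full <- grepl("^\\d{8}$", x)
  ym <- grepl("^\\d{6}$", x)
  y <- grepl("^\\d{4}$", x)
  date[full] <- as.Date(x[full], format = "%Y%m%d")
  date[ym] <- as.Date(paste0(x[ym], "01"), format = "%Y%m%d")
  date[y] <- as.Date(paste0(x[y], "0101"), format = "%Y%m%d")
  data.frame(date = date, imprecise = !full | is.na(date))
}

#' Convert FAERS age value/unit pairs to years
#'
#' Unit codes: `DEC` decades, `YR` years, `MON` months, `WK` weeks, `DY`
#' days. Values converting to more than 122 years are treated as recording
#' errors and set missing.
#'
#' @param value Character or numeric age values.
#' @param unit Character unit codes (missing unit defaults to years).
#' @return Numeric vector of ages in years (NA when missing or implausible).
#' @export
age_in_years <- function(value, unit) {
  v <- suppressWarnings(as.numeric(value))
  u <- toupper(ifelse(is.na(unit) | unit == "", "YR", unit))
  factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365.25)
  years <- v * unname(factor[u])
  years[!u %in% names(factor)] <- NA
  years[!is.na(years) & (years < 0 | years > 122)] <- NA
  years
}

#' Keep only the most recent report version of each case
#'
#' FAERS cases accumulate report versions; analyses keep, per unique case
#' ID, the version with the latest receipt date (`fda_dt`). Ties on the
#' date are broken towards the highest `primaryid`, since later versions
#' receive later sequence numbers. All five tables are filtered to the kept
#' `primaryid`s; output rows are ordered by caseid, so the result is
#' independent of input order and idempotent.
#'
#' @param tables A `faers_tables` list from [read_faers()] (or the
#'   in-memory tables from [generate_reports()]).
#' @return The filtered `faers_tables` list.
#' @export
deduplicate_cases <- function(tables) {
  demo <- tibble::as_tibble(tables$demo)
  fda <- parse_faers_date(as.character(demo$fda_dt))$date
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  ord <- order(demo$caseid, fda, pid_num)
  demo <- demo[ord, ]
  keep <- !duplicated(demo$caseid, fromLast = TRUE)
  kept_demo <- demo[keep, ]
  kept_demo <- kept_demo[order(kept_demo$caseid), ]
  kept_ids <- kept_demo$primaryid
  out <- list(demo = kept_demo)
  for (tab in c("drug", "reac", "outc", "ther")) {
    tbl <- tibble::as_tibble(tables[[tab]])
    tbl <- tbl[tbl$primaryid %in% kept_ids, ]
    out[[tab]] <- tbl[order(tbl$caseid), ]
  }
  structure(out, class = "faers_tables",
            malformed = attr(tables, "malformed"))
}

#' Normalise drug names against a synonym table
#'
#' Matching is case- and surrounding-whitespace-insensitive (internal runs
#' of whitespace collapse to one space). Names without a synonym row pass
#' through upper-cased; the distinct unmatched names are returned in the
#' `remainder` attribute.
#'
#' @param names Character vector of raw drug names.
#' @param synonyms Data frame with columns `raw` and `canonical`, e.g. from
#'   [load_synonyms()] or [synthetic_synonyms()].
#' @return Character vector of normalised names with attribute `remainder`.
#' @export
normalize_drug_names <- function(names, synonyms) {
  stopifnot(all(c("raw", "canonical") %in% colnames(synonyms)))
  fold <- function(x) toupper(gsub("\\s+", " ", trimws(x)))
  key <- fold(synonyms$raw)
  if (anyDuplicated(key)) {
    conflict <- tapply(synonyms$canonical, key, function(x) length(unique(x)))
    if (any(conflict > 1)) {
      stop("configuration error: conflicting synonym rows for ",
           paste(names(conflict)[conflict > 1], collapse = ", "),
           call. = FALSE)
    }
  }
  lookup <- setNames(toupper(synonyms$canonical), key)
  folded <- fold(names)
  hit <- folded %in% names(lookup)
  out <- folded
  out[hit] <- unname(lookup[folded[hit]])
  structure(out, remainder = sort(unique(folded[!hit & !is.na(folded)])))
}

#' Load a two-column drug synonym table
#'
#' @param path TSV with columns `raw` and `canonical` (header required).
#' @return A tibble.
#' @export
load_synonyms <- function(path) {
  tbl <- tibble::as_tibble(read.delim(path, colClasses = "character"))
  if (!all(c("raw", "canonical") %in% names(tbl))) {
    stop("synonym table must have columns 'raw' and 'canonical'",
         call. = FALSE)
  }
  tbl
}

#' Select cases reporting the target drug as primary suspect
#'
#' Keeps the cases that contain at least one drug entry whose normalised
#' name equals `target` with role code `PS`. Selection is case-level: a
#' case with several target entries is returned once.
#'
#' @param tables Deduplicated `faers_tables`.
#' @param target Canonical target drug name.
#' @param synonyms Optional synonym table applied to `drugname` first.
#' @return The `faers_tables` list filtered to target cases, with the
#'   normalised name stored in `drug$drugname_norm`.
#' @export
select_target_reports <- function(tables, target, synonyms = NULL) {
  drug <- tibble::as_tibble(tables$drug)
  if (is.null(synonyms)) {
    synonyms <- tibble::tibble(raw = character(), canonical = character())
  }
  drug$drugname_norm <- as.character(normalize_drug_names(drug$drugname,
                                                          synonyms))
  target_ids <- unique(drug$primaryid[
    drug$drugname_norm == toupper(target) & drug$role_cod == "PS"
  ])
  out <- list(demo = tables$demo[tables$demo$primaryid %in% target_ids, ])
  for (tab in c("reac", "outc", "ther")) {
    tbl <- tibble::as_tibble(tables[[tab]])
    out[[tab]] <- tbl[tbl$primaryid %in% target_ids, ]
  }
  out$drug <- drug[drug$primaryid %in% target_ids, ]
  structure(out, class = "faers_tables",
            malformed = attr(tables, "malformed"))
}

#' Case-level view of a report table set
#'
#' Builds one row per report with the typed fields descriptive analyses
#' need: receipt/event dates, age in years, gender, reporter, country, the
#' administration route of the primary-suspect entry, and the therapy start
#' date of that entry (for time to onset).
#'
#' @param tables `faers_tables`, typically deduplicated and target-selected.
#' @return A tibble with one row per `primaryid`.
#' @export
case_table <- function(tables) {
  demo <- tibble::as_tibble(tables$demo)
  fda <- parse_faers_date(as.character(demo$fda_dt))
  event <- parse_faers_date(as.character(demo$event_dt))
  drug <- tibble::as_tibble(tables$drug)
  ps <- drug[drug$role_cod == "PS", c("primaryid", "drug_seq", "route")]
  ps <- ps[!duplicated(ps$primaryid), ]
  ther <- tibble::as_tibble(tables$ther)
  ps_ther <- dplyr::inner_join(
    ps, ther,
    by = c("primaryid", "drug_seq" = "dsg_drug_seq")
  )
  start <- parse_faers_date(as.character(ps_ther$start_dt))
  ps_ther$therapy_start <- start$date
  ps_ther$therapy_start_imprecise <- start$imprecise

  out <- tibble::tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_date = fda$date,
    event_date = event$date,
    event_date_imprecise = event$imprecise,
    age_years = age_in_years(demo$age, demo$age_cod),
    gender = dplyr::case_match(demo$sex, "F" ~ "female", "M" ~ "male",
                               .default = "unknown"),
    reporter = dplyr::case_match(demo$occp_cod,
      "MD" ~ "physician", "PH" ~ "pharmacist", "CN" ~ "consumer",
      "OT" ~ "other health professional", .default = "unknown"),
    country = ifelse(is.na(demo$reporter_country), "OTHER",
                     toupper(demo$reporter_country))
  )
  out <- dplyr::left_join(
    out,
    ps_ther[, c("primaryid", "route", "therapy_start",
                "therapy_start_imprecise")],
    by = "primaryid"
  )
  out$route <- collapse_route(out$route)
  out
}

#' Collapse free-text administration routes to three categories
#'
#' Any route mentioning "drip" maps to `intravenous drip`, other
#' intravenous variants to `intravenous`, everything else (including
#' missing) to `other`.
#'
#' @param route Character vector.
#' @return Character vector with levels `intravenous`, `intravenous drip`,
#'   `other`.
#' @export
collapse_route <- function(route) {
  r <- tolower(ifelse(is.na(route), "", route))
  dplyr::case_when(
    grepl("drip", r) ~ "intravenous drip",
    grepl("intraven|\\biv\\b", r) ~ "intravenous",
    .default = "other"
  )
}
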