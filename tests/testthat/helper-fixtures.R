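# Shared fixtures built in code.

# all 1,296 2x2 tables with cells in 1..6
all_small_tables <- function() {
  expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
}

# random strictly positive tables for property loops
random_tables <- function(n, seed = 421) {
  withr::with_seed(seed, {
    data.frame(
      a = sample(1:500, n, replace = TRUE),
      b = sample(1:5000, n, replace = TRUE),
      c = sample(1:50000, n, replace = TRUE),
      d = sample(1:1000000, n, replace = TRUE)
    )
  })
}

# write a hand-crafted $-delimited quarter into a temp dir
write_quarter_fixture <- function(dir, demo = NULL, drug = NULL, reac = NULL,
                                  outc = NULL, ther = NULL,
                                  quarter = "2022Q1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  defaults <- list(
    demo = c("primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$reporter_country"),
    drug = c("primaryid$caseid$drug_seq$role_cod$drugname$route"),
    reac = c("primaryid$caseid$pt"),
    outc = c("primaryid$caseid$outc_cod"),
    ther = c("primaryid$caseid$dsg_drug_seq$start_dt")
  )
  bodies <- list(demo = demo, drug = drug, reac = reac, outc = outc,
                 ther = ther)
  for (tab in names(defaults)) {
    writeLines(c(defaults[[tab]], bodies[[tab]]),
               file.path(dir, paste0(toupper(tab), quarter, ".txt")))
  }
  dir
}

# reconstruct every row of the published avelumab PT reference table
reconstruct_reference <- function(ref = avelumab_reference("pt")) {
  m <- avelumab_margins()
  cbind(ref,
        reconstruct_from_printed(ref$n, ref$prr, m$drug_margin, m$n_total))
}
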