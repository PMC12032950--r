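#!/usr/bin/env Rscript
# Simulate a FAERS-like spontaneous-report corpus with known ground truth.
#
# The corpus mirrors the structure of the real avelumab analysis: a small
# share of cases carries the target drug as primary suspect, duplicate
# report versions exist, demographics follow the published report mix, and
# three preferred terms carry planted elevated reporting rates (RR 5, 3
# and 2) against a uniform background.

library(faersdpa)

corpus_dir <- "scratch/synthetic_corpus"
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(
  n_cases = 50000,
  target_drug_share = 0.05,
  n_events = 200,
  events_per_case = 2,
  duplicate_rate = 0.1,
  planted_signals = data.frame(pt_id = c(7, 21, 60),
                               relative_risk = c(5, 3, 2)),
  seed = 20240901
)

g <- generate_reports(cfg, dir = corpus_dir)

cat(sprintf("wrote %d quarterly files to %s\n", length(g$files), corpus_dir))
cat(sprintf("cases: %d (%d report versions), target-drug share %.1f%%\n",
            cfg$n_cases, nrow(g$tables$demo), 100 * cfg$target_drug_share))
cat(sprintf("reaction rows: %d across %d distinct PTs\n",
            nrow(g$tables$reac), cfg$n_events))

planted <- g$ground_truth$pt[g$ground_truth$pt$relative_risk != 1, ]
write.table(planted, "results/simulation_ground_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("planted signals:\n")
print(as.data.frame(planted), row.names = FALSE)
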