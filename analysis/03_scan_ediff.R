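#!/usr/bin/env Rscript
## Scan every variant's +/- 30 bp REF and ALT flanking sequences
## against each dataset's motifs (log-odds best hits with exact DP null
## p-values, both strands), then compute the E_diff allelic-difference
## statistic per dataset and the one-row-per-variant results table.
## Reads results/run (02) and writes scan.tsv / ediff_pairs.tsv /
## results_table.tsv there; prints detections against the truth table.

suppressMessages(library(thymotif))

cfg <- pipeline_config("results/bundle", "results/run",
                       nmotifs = 3, wmax = 16, subsample = 200,
                       n_null = 20, run_affinity = FALSE, seed = 1)
run <- run_pipeline(cfg)   # earlier stages are served from the manifest

truth <- read.table("results/bundle/truth.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
ed <- run$ediff
cat("eligible variant-motif pairs:", nrow(ed),
    "| pass on score:", sum(ed$pass_sc),
    "| pass on p-value:", sum(ed$pass_p), "\n\n")
cat("top of the results table (one row per variant):\n")
print(head(run$results[, c("variant_id", "ref", "alt", "p_ref", "p_alt",
                           "sc_ref", "sc_alt", "e_diff_p", "e_diff_sc",
                           "pass_sc")], 10), digits = 3)

agg <- aggregate(cbind(pass_sc, pass_p) ~ variant_id, ed, any)
tr <- merge(truth, agg, by.x = "id", by.y = "variant_id", all.x = TRUE)
tr[is.na(tr)] <- FALSE
cat("\ndetection by truth class (score-based E_diff pass):\n")
print(aggregate(pass_sc ~ is_disruptive + type, tr, mean))
cat("\nNote the indel bias: deletions and creator insertions shift the\n",
    "best-hit score by 10-20 bits and pass, while single-column SNV\n",
    "disruptions (~5 bits at 1.5 bits/column) rarely clear the\n",
    "0.01/n_datasets bound.\n", sep = "")
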