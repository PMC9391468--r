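#!/usr/bin/env Rscript
## Generate the synthetic study bundle: a 2 x 200 kb genome with exons,
## 200 enhancers carrying a planted 12-bp motif in 70% of them, two
## replicate peak samples for H3K4me3 and H3K27ac in one cell type, RNA
## coverage elevated in enhancers, and 100 credible-set-style variants
## (10% disruptive: site-destroying SNVs and deletions, site-creating
## insertions). Everything is written as plain text under
## results/bundle/ together with a machine-readable truth table.

suppressMessages(library(thymotif))

cfg <- sim_config(seed = 1)
bundle <- simulate_bundle(cfg, "results/bundle")

cat("chromosomes:", length(bundle$genome), "x",
    cfg$chrom_length, "bp\n")
cat("enhancers:", length(bundle$enhancers),
    "| planted sites:", nrow(bundle$sites), "\n")
cat("peak calls:", nrow(bundle$peaks), "over",
    length(unique(bundle$peaks$sample_id)), "samples\n")
cat("variants:", nrow(bundle$variants), "\n")
print(table(bundle$truth$type))
cat("expected pooled peak counts after filters:\n")
print(bundle$truth_n_peaks)
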