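#!/usr/bin/env Rscript
## Detection benchmark: five independent bundles at the default study
## conditions, full pipeline on each, sensitivity and false-positive
## rate of the score-based E_diff pass set against the truth tables.
## Writes results/benchmark.tsv.

suppressMessages(library(thymotif))

rows <- list()
for (k in 1:5) {
  bdir <- file.path("results/benchmark", sprintf("bundle%d", k))
  odir <- file.path("results/benchmark", sprintf("run%d", k))
  b <- suppressWarnings(simulate_bundle(sim_config(seed = 3000 + k),
                                        bdir))
  cfg <- pipeline_config(bdir, odir, nmotifs = 2, wmax = 14,
                         subsample = 120, n_null = 0,
                         run_affinity = FALSE, seed = k)
  r <- suppressMessages(suppressWarnings(run_pipeline(cfg)))
  agg <- aggregate(pass_sc ~ variant_id, r$ediff, any)
  tr <- merge(b$truth, agg, by.x = "id", by.y = "variant_id", all.x = TRUE)
  tr$pass_sc[is.na(tr$pass_sc)] <- FALSE
  rows[[k]] <- data.frame(
    seed = 3000 + k,
    sensitivity = mean(tr$pass_sc[tr$is_disruptive]),
    fpr = mean(tr$pass_sc[!tr$is_disruptive]),
    sens_indel = mean(tr$pass_sc[tr$is_disruptive &
                                   tr$type != "snv"]),
    sens_snv = mean(tr$pass_sc[tr$is_disruptive & tr$type == "snv"]))
  cat(sprintf("seed %d: sensitivity %.2f (indel %.2f, snv %.2f), fpr %.3f\n",
              3000 + k, rows[[k]]$sensitivity, rows[[k]]$sens_indel,
              rows[[k]]$sens_snv, rows[[k]]$fpr))
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/benchmark.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nmedians: sensitivity %.2f, fpr %.3f\n",
            median(tab$sensitivity), median(tab$fpr)))
cat("The score-based statistic detects indel disruptions reliably but\n",
    "has little power for single-base substitutions; see the methods\n",
    "vignette for the analysis.\n", sep = "")
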