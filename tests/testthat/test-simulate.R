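small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chroms = 1, chrom_length = 60000,
             n_enhancers = 30, n_variants = 20, exon_fraction = 0.05,
             ...)
}

test_that("simulated genome matches GC target, exon bounds and seed", {
  cfg <- sim_config(seed = 4, n_chroms = 1, chrom_length = 100000)
  sim <- simulate_genome(cfg)
  s <- strsplit(as.character(sim$genome[[1]]), "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
  ## determinism: identical bytes
  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))
  ## exons within bounds and non-overlapping
  ex <- interval_frame(sim$exons)
  expect_true(all(ex$start >= 0 & ex$end <= 100000))
  expect_true(all(diff(ex$start) >= ex$end[-nrow(ex)] - ex$start[-nrow(ex)]
                  | diff(ex$start) > 0))
  expect_equal(length(sim$exons),
               length(merge_intervals(sim$exons)))
})

test_that("planted sites follow the plant rate and live in enhancers", {
  cfg <- small_config(seed = 6)
  sim <- simulate_genome(cfg)
  pl <- plant_and_peak(cfg, sim)
  n_expected <- round(0.7 * 30)
  expect_equal(nrow(pl$sites), n_expected)
  ## every site inside an enhancer, written into the genome
  ef <- interval_frame(pl$enhancers)
  for (i in seq_len(nrow(pl$sites))) {
    s <- pl$sites[i, ]
    inside <- any(ef$chrom == s$chrom & ef$start <= s$start &
                    ef$end >= s$end)
    expect_true(inside)
    written <- as.character(Biostrings::subseq(
      pl$genome[[s$chrom]], s$start + 1, s$end))
    expect_identical(written, s$site_seq)
  }
  ## enhancers avoid exons
  expect_equal(length(GenomicRanges::intersect(pl$enhancers, sim$exons)), 0)
})

test_that("drawn q-values control filter survival as configured", {
  ## all q-values failing: zero peaks survive the q < 1e-4 filter
  cfg <- small_config(seed = 7, q_fail_rate = 1)
  sim <- simulate_genome(cfg)
  pl <- plant_and_peak(cfg, sim)
  expect_equal(nrow(filter_peaks(pl$peaks)), 0)
  expect_true(all(pl$truth_n_peaks == 0))
  ## with coverage_out = 0 the RNA gate keeps only enhancer overlap
  cfg2 <- small_config(seed = 8, coverage_out = 0)
  sim2 <- simulate_genome(cfg2)
  pl2 <- plant_and_peak(cfg2, sim2)
  away <- data.frame(chrom = "chr1", start = 100, end = 200,
                     fold_change = 10, q_value = 1e-9,
                     sample_id = "sX", cell_type = "CD4ab",
                     hist_mod = "H3K4me3", stringsAsFactors = FALSE)
  expect_equal(nrow(suppressMessages(
    rna_active_filter(away, pl2$coverage))), 0)
  near <- interval_frame(pl2$enhancers)[1, ]
  inp <- away
  inp$start <- near$start; inp$end <- near$end
  expect_equal(nrow(rna_active_filter(inp, pl2$coverage)), 1)
})

test_that("pipeline peak counts equal the generator's own truth counts", {
  cfg <- small_config(seed = 9)
  sim <- simulate_genome(cfg)
  pl <- plant_and_peak(cfg, sim)
  for (ds in names(pl$truth_n_peaks)) {
    parts <- strsplit(ds, ".", fixed = TRUE)[[1]]
    sel <- pl$peaks$cell_type == parts[1] & pl$peaks$hist_mod == parts[2]
    kept <- rna_active_filter(filter_peaks(pl$peaks[sel, ]), pl$coverage)
    d <- pool_and_clean(kept, sim$exons, sim$chrom_sizes)
    expect_equal(length(d$regions), unname(pl$truth_n_peaks[[ds]]))
  }
})

test_that("disruptive variants change best-hit scores in the labeled direction", {
  cfg <- small_config(seed = 10)
  sim <- simulate_genome(cfg)
  pl <- plant_and_peak(cfg, sim)
  vs <- simulate_variants(cfg, pl, sim)
  bg <- uniform_bg()
  m <- cfg$planted_pwms[[1]]
  tbl <- score_pvalue_table(m, bg)
  truth <- vs$truth
  for (i in seq_len(nrow(vs$variants))) {
    v <- vs$variants[i, ]
    t <- truth[truth$id == v$id, ]
    pr <- extract_allele_sequences(v, vs$genome, flank = 30)
    hr <- best_hit(m, pr$seq_ref, bg, table = tbl)
    ha <- best_hit(m, pr$seq_alt, bg, table = tbl)
    if (t$is_disruptive && t$direction == "ref") {
      ## REF carries the intact site: rescoring drops on ALT
      expect_gt(hr$score, ha$score)
      expect_lt(hr$p, ha$p)
    } else if (t$is_disruptive && t$direction == "alt") {
      ## creator insertion: ALT match better than REF
      expect_lt(ha$p, hr$p)
    } else if (t$type == "neutral_snv") {
      ## background neutral SNVs sit far from planted sites; a best hit
      ## in the shared flank leaves both alleles identical
      if (hr$offset == ha$offset && hr$offset + m$width <= 30)
        expect_equal(hr$p, ha$p)
    }
  }
  expect_equal(nrow(vs$variants), 20)
  expect_equal(sum(truth$is_disruptive), 2)
})

test_that("the full bundle writes plain-text files that read back", {
  d <- withr::local_tempdir()
  cfg <- small_config(seed = 12)
  b <- suppressWarnings(simulate_bundle(cfg, d))
  expect_true(all(file.exists(file.path(d, c(
    "genome.fa", "exons.gff3", "chrom.sizes", "coverage.bedGraph",
    "variants.vcf", "truth.tsv", "sites.tsv", "config.json",
    "planted_motifs.meme")))))
  g <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_equal(unname(Biostrings::width(g)), 60000)
  expect_identical(as.character(g[[1]]), as.character(b$genome[[1]]))
  vv <- read_variants_vcf(file.path(d, "variants.vcf"))
  expect_equal(vv$pos, b$variants$pos)
  expect_equal(vv$ref, b$variants$ref)
  expect_equal(vv$alt, b$variants$alt)
  ex <- read_exons_gff3(file.path(d, "exons.gff3"))
  expect_setequal(bases_of(ex), bases_of(b$exons))
  pk <- list.files(d, "^peaks_.*\\.bed$")
  expect_equal(length(pk),
               2 * length(unlist(cfg$cell_types)))
  ## determinism at the byte level
  d2 <- withr::local_tempdir()
  suppressWarnings(simulate_bundle(small_config(seed = 12), d2))
  for (f in c("genome.fa", "variants.vcf", "truth.tsv",
              "coverage.bedGraph"))
    expect_identical(readLines(file.path(d, f)),
                     readLines(file.path(d2, f)))
})
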