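make_peaks <- function(chrom = "chr1", start = 0, end = 100,
                       fc = 5, q = 1e-6, sample = "s1",
                       ct = "CT", hm = "H3K27ac") {
  data.frame(chrom = chrom, start = start, end = end, fold_change = fc,
             q_value = q, sample_id = sample, cell_type = ct,
             hist_mod = hm, stringsAsFactors = FALSE)
}

test_that("peak filter boundaries are >= on fold change and < on q", {
  p <- rbind(make_peaks(fc = 3.0, q = 9e-5),
             make_peaks(start = 200, end = 300, fc = 2.99, q = 1e-9),
             make_peaks(start = 400, end = 500, fc = 10, q = 1e-4))
  out <- filter_peaks(p)
  expect_equal(nrow(out), 1)
  expect_equal(out$fold_change, 3.0)
  ## every retained peak satisfies its thresholds, exhaustively
  set.seed(3)
  big <- make_peaks(start = seq(0, 990, 10), end = seq(10, 1000, 10),
                    fc = stats::runif(100, 0, 6),
                    q = 10^stats::runif(100, -8, 0))
  kept <- filter_peaks(big, min_fc = 2, max_q = 1e-3)
  expect_true(all(kept$fold_change >= 2 & kept$q_value < 1e-3))
  expect_true(all(big$fold_change < 2 | big$q_value >= 1e-3 |
                    big$start %in% kept$start))
})

test_that("RNA activity gate keeps mean depth >= threshold inclusive", {
  ## total depth 0.1 over a 100 bp peak -> mean exactly 0.001
  tr <- coverage_track(interval_set("chr1", 0, 10, score = 0.01),
                       c(chr1 = 1000))
  p <- rbind(make_peaks(start = 0, end = 100),
             make_peaks(start = 500, end = 600))
  out <- rna_active_filter(p, tr, min_mean = 0.001)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 0)
  ## missing chromosome -> depth 0, dropped with a message
  p2 <- make_peaks(chrom = "chrX")
  expect_message(out2 <- rna_active_filter(p2, tr), "absent")
  expect_equal(nrow(out2), 0)
  ## brute-force agreement on a random track
  set.seed(21)
  starts <- seq(0, 990, 10)
  vals <- round(stats::runif(100, 0, 0.01), 4)
  keep <- vals > 0
  tr2 <- coverage_track(interval_set("chr1", starts[keep],
                                     starts[keep] + 10,
                                     score = vals[keep]), c(chr1 = 1000))
  per_base <- rep(vals, each = 10)
  pk <- make_peaks(start = 0, end = 1000)
  kept <- rna_active_filter(pk, tr2, min_mean = mean(per_base))
  expect_equal(nrow(kept), 1)  # mean equals threshold -> inclusive
  kept2 <- rna_active_filter(pk, tr2,
                             min_mean = mean(per_base) + 1e-9)
  expect_equal(nrow(kept2), 0)
})

test_that("pooling applies length filter, flanks and exon exclusion in order", {
  sizes <- c(chr1 = 10000)
  no_exons <- interval_set("chr1", 9000, 9001)
  ## identical peaks from two samples merge to one region
  p <- rbind(make_peaks(start = 100, end = 200, sample = "s1"),
             make_peaks(start = 100, end = 200, sample = "s2"))
  d <- pool_and_clean(p, no_exons, sizes, flank = 0)
  expect_s3_class(d, "peak_dataset")
  expect_equal(length(d$regions), 1)
  expect_equal(d$n_samples, 2)

  ## 5 bp dropped, 6 bp kept (length filter precedes flanking)
  p2 <- rbind(make_peaks(start = 100, end = 105),
              make_peaks(start = 300, end = 306))
  d2 <- pool_and_clean(p2, no_exons, sizes, min_len = 6, flank = 0)
  expect_equal(interval_frame(d2$regions)$start, 300)

  ## a 5 bp peak plus 20 bp flank would pass a post-flank filter;
  ## the order must drop it first
  d2b <- pool_and_clean(make_peaks(start = 100, end = 105),
                        no_exons, sizes, min_len = 6, flank = 20)
  expect_equal(length(d2b$regions), 0)

  ## exon exclusion splits and is applied last (fragments kept)
  d3 <- pool_and_clean(make_peaks(start = 100, end = 130),
                       interval_set("chr1", 110, 120), sizes,
                       min_len = 6, flank = 0)
  expect_equal(interval_frame(d3$regions)$start, c(100, 120))
  expect_equal(interval_frame(d3$regions)$end, c(110, 130))

  ## output bases subset of padded input minus exons
  set.seed(5)
  exons <- random_interval_set(10, chroms = "chr1")
  pr <- make_peaks(start = seq(500, 5000, 500), end = seq(560, 5060, 500))
  d4 <- pool_and_clean(pr, merge_intervals(exons), sizes, flank = 20)
  allowed <- setdiff(bases_of(pad_intervals(
    interval_set(pr$chrom, pr$start, pr$end), 20, sizes)),
    bases_of(merge_intervals(exons)))
  expect_true(all(bases_of(d4$regions) %in% allowed))

  expect_error(pool_and_clean(rbind(make_peaks(hm = "H3K4me3"),
                                    make_peaks(hm = "H3K27ac")),
                              no_exons, sizes), "one \\(cell_type")
})

test_that("pseudostates intersect available member marks per cell type", {
  sizes <- c(chr1 = 10000)
  mk <- function(hm, s, e) structure(
    list(cell_type = "CT", hist_mod = hm,
         regions = merge_intervals(interval_set("chr1", s, e)),
         n_samples = 1L), class = "peak_dataset")
  ds <- list(mk("H3K4me3", c(0, 300), c(100, 400)),
             mk("H3K27Ac", c(50, 350), c(120, 380)))
  ps <- suppressMessages(build_pseudostates(ds))
  ## only pseudostate 12 has both members (case-insensitive match)
  expect_length(ps, 1)
  expect_equal(ps[[1]]$hist_mod, "pseudostate12")
  expect_setequal(bases_of(ps[[1]]$regions),
                  intersect(bases_of(ds[[1]]$regions),
                            bases_of(ds[[2]]$regions)))
  ## three-way intersection against the per-base oracle
  ds3 <- list(mk("H3K4me3", 0, 200), mk("H3K27ac", 100, 300),
              mk("H3K4me1", c(0, 150), c(120, 260)))
  ps3 <- suppressMessages(build_pseudostates(ds3))
  p10 <- ps3[[which(vapply(ps3, function(d) d$hist_mod, "") ==
                      "pseudostate10")]]
  expect_setequal(bases_of(p10$regions),
                  Reduce(intersect, lapply(ds3, function(d)
                    bases_of(d$regions))))
  ## disjoint members -> empty set
  dsd <- list(mk("H3K4me3", 0, 100), mk("H3K27ac", 200, 300))
  psd <- suppressMessages(build_pseudostates(dsd))
  expect_equal(length(psd[[1]]$regions), 0)
  expect_error(build_pseudostates(ds, list(`8` = c("a", "b"))),
               "7, 9, 10, 11, 12")
})

test_that("sequence extraction is uppercase, named, length-preserving", {
  g <- toy_genome(chr1 = "acgtacgt")
  s <- extract_sequences(interval_set("chr1", 0, 4), g)
  expect_equal(as.character(s), c("chr1:0-4" = "ACGT"))
  expect_error(extract_sequences(interval_set("chr1", 4, 12), g),
               "chr1:4-12")
  set.seed(8)
  g2 <- toy_genome(chr1 = random_dna(5000))
  iv <- random_interval_set(100, chroms = "chr1", max_pos = 4000)
  out <- extract_sequences(iv, g2)
  expect_equal(Biostrings::width(out),
               interval_frame(iv)$end - interval_frame(iv)$start)
})

test_that("narrowPeak-style reading converts -log10 q-values", {
  d <- withr::local_tempdir()
  f <- file.path(d, "p.narrowPeak")
  writeLines(paste(c("chr1", 10, 60, "pk1", 0, ".", 4.5, 10, 6.2, 25),
                   collapse = "\t"), f)
  p <- read_peak_calls(f, "s1", "CT", "H3K27ac")
  expect_equal(p$fold_change, 4.5)
  expect_equal(p$q_value, 10^-6.2)
  ## reading the -log10 column as a raw probability must fail validation
  expect_error(read_peak_calls(f, "s1", "CT", "H3K27ac",
                               q_scale = "identity"), "q_value")
  expect_error(read_peak_calls(f, "s", "c", "h", q_col = 30), "fewer")
})
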