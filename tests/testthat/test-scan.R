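test_that("log-odds closed forms hold", {
  bg <- uniform_bg()
  ## a column equal to the background scores zero
  m <- pwm(matrix(0.25, 4, 2))
  expect_true(all(log_odds(m, bg) == 0))
  ## doubling a probability raises that cell by exactly one bit
  p1 <- c(0.4, 0.2, 0.2, 0.2)
  p2 <- c(0.8, 0.1, 0.05, 0.05)
  lo1 <- log_odds(pwm(matrix(p1, 4, 1)), bg)
  lo2 <- log_odds(pwm(matrix(p2, 4, 1)), bg)
  expect_equal(unname(lo2[1, 1] - lo1[1, 1]), 1)
  ## strongly peaked column ~ log2(p/0.25)
  p3 <- c(0.97, 0.01, 0.01, 0.01)
  expect_equal(unname(log_odds(pwm(matrix(p3, 4, 1)), bg)[1, 1]),
               log2(0.97 / 0.25), tolerance = 1e-12)
  bad <- uniform_bg()
  bad$freq[1] <- 0
  expect_error(log_odds(m, bad), "> 0")
})

test_that("DP p-values equal exhaustive enumeration for small widths", {
  set.seed(51)
  bg <- structure(list(order = 0,
                       freq = stats::setNames(c(0.3, 0.2, 0.2, 0.3),
                                              c("A", "C", "G", "T"))),
                  class = "bg_model")
  for (w in c(3, 5)) {
    m <- make_planted_pwm(w, 1.3, seed = w, id = "m")
    tbl <- score_pvalue_table(m, bg, resolution = 1000)
    ## enumerate all 4^w windows on the same integer grid
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    int_scores <- rowSums(matrix(tbl$ints[cbind(as.vector(grid),
                                                rep(seq_len(w),
                                                    each = nrow(grid)))],
                                 nrow(grid), w))
    probs <- apply(matrix(bg$freq[as.vector(grid)], nrow(grid), w), 1, prod)
    for (s in sort(unique(int_scores))) {
      brute <- sum(probs[int_scores >= s])
      expect_equal(tbl$tail[s + 1], brute, tolerance = 1e-12)
    }
    ## max achievable score: p = product of max-base background probs
    max_real <- sum(apply(tbl$lom, 2, max))
    expect_equal(score_pvalue(tbl, max_real),
                 prod(bg$freq[apply(m$probs, 2, which.max)]),
                 tolerance = 1e-12)
  }
  ## degenerate: uniform PWM vs uniform bg -> p = 1 everywhere
  tbl0 <- score_pvalue_table(pwm(matrix(0.25, 4, 2)), uniform_bg())
  expect_equal(score_pvalue(tbl0, 0), 1)
  expect_error(score_pvalue_table(make_planted_pwm(6, 1, seed = 1),
                                  uniform_bg(), resolution = 10),
               ">= 100")
})

test_that("grid discretization error is bounded by the bin width", {
  set.seed(52)
  bg <- uniform_bg()
  m <- make_planted_pwm(6, 1.5, seed = 3)
  tbl <- score_pvalue_table(m, bg, resolution = 1000)
  ## real score vs reconstructed grid score for random windows
  for (i in 1:50) {
    win <- sample.int(4, 6, replace = TRUE)
    real <- sum(tbl$lom[cbind(win, 1:6)])
    gridded <- sum(tbl$ints[cbind(win, 1:6)]) * tbl$delta + tbl$offset
    expect_lt(abs(real - gridded), 6 * tbl$delta / 2 + 1e-12)
  }
})

test_that("window p-values are conservative under the null", {
  set.seed(53)
  bg <- uniform_bg()
  m <- make_planted_pwm(8, 1.5, seed = 9)
  tbl <- score_pvalue_table(m, bg)
  wins <- matrix(sample.int(4, 10000 * 8, replace = TRUE), 10000, 8)
  scores <- rowSums(matrix(tbl$lom[cbind(as.vector(wins),
                                         rep(1:8, each = 10000))],
                           10000, 8))
  p <- vapply(scores, function(s) score_pvalue(tbl, s), numeric(1))
  for (thr in c(0.05, 0.01, 0.001))
    expect_lte(mean(p < thr), thr * 1.15 + 2 / 10000)
})

test_that("best hit finds plants, is strand-symmetric and skips N windows", {
  set.seed(54)
  bg <- uniform_bg()
  m <- make_planted_pwm(10, 1.7, seed = 2)
  cons <- consensus_string(m)
  seq <- random_dna(80)
  substr(seq, 31, 40) <- cons
  tbl <- score_pvalue_table(m, bg)
  h <- best_hit(m, seq, bg, table = tbl)
  expect_equal(h$offset, 30)
  expect_equal(h$score, sum(apply(tbl$lom, 2, max)), tolerance = 1e-9)
  ## reverse complement of the sequence: same best score
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  h2 <- best_hit(m, rc, bg, table = tbl)
  expect_equal(h2$score, h$score, tolerance = 1e-9)
  ## N masks windows: poison the plant, best hit moves elsewhere
  seqN <- seq
  substr(seqN, 35, 35) <- "N"
  h3 <- best_hit(m, seqN, bg, table = tbl)
  expect_lt(h3$score, h$score)
  expect_false(h3$offset %in% 26:34)
  ## shorter than the motif: -Inf sentinel and p = 1
  expect_message(h4 <- best_hit(m, "ACGT", bg, table = tbl), "shorter")
  expect_equal(h4$score, -Inf)
  expect_equal(h4$p, 1)
})

test_that("variant scanning yields one row per variant x motif and flags overlap", {
  set.seed(55)
  g <- toy_genome(chr1 = random_dna(2000))
  gs <- as.character(g[[1]])
  vs <- do.call(rbind, lapply(1:4, function(i) {
    p <- 200 * i
    rb <- substr(gs, p + 1, p + 1)
    normalize_variant("chr1", p, rb,
                      setdiff(c("A", "C", "G", "T"), rb)[1],
                      id = sprintf("v%d", i), coords = "zero")
  }))
  pairs <- lapply(seq_len(nrow(vs)), function(i)
    extract_allele_sequences(vs[i, ], g, flank = 30))
  motifs <- list(ds1 = list(make_planted_pwm(8, 1.5, seed = 1, id = "m1"),
                            make_planted_pwm(9, 1.5, seed = 2, id = "m2")),
                 ds2 = list(make_planted_pwm(7, 1.4, seed = 3, id = "m3")))
  res <- scan_variants(pairs, motifs, uniform_bg())
  expect_equal(nrow(res), 4 * 3)
  expect_equal(attr(res, "overlap_threshold"),
               significance_threshold(0.01, c(3, 4)))
  expect_true(all(res$p_ref > 0 & res$p_ref <= 1))
  expect_identical(res$significant_overlap,
                   pmin(res$p_ref, res$p_alt) <
                     attr(res, "overlap_threshold"))
})

test_that("a variant far from any match leaves both alleles identical", {
  ## construct: plant in the shared flank only
  set.seed(56)
  m <- make_planted_pwm(8, 1.6, seed = 4, id = "m")
  g <- toy_genome(chr1 = random_dna(500))
  gs <- as.character(g[[1]])
  ## plant inside the upstream shared flank (0-based 205..212)
  substr(gs, 206, 213) <- consensus_string(m)
  g <- toy_genome(chr1 = gs)
  rb <- substr(gs, 231, 231)
  v <- normalize_variant("chr1", 230, rb,
                         setdiff(c("A", "C", "G", "T"), rb)[1],
                         id = "far", coords = "zero")
  pr <- extract_allele_sequences(v, g, flank = 30)
  res <- scan_variants(list(pr), list(ds = list(m)), uniform_bg())
  expect_equal(res$p_ref, res$p_alt)
  expect_equal(res$sc_ref, res$sc_alt)
  expect_equal(res$offset_ref, res$offset_alt)
})
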