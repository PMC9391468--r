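test_that("TRAP affinity has the closed-form consensus energy and bounds", {
  set.seed(81)
  m <- make_planted_pwm(10, 1.6, seed = 7, id = "tf")
  prm <- trap_params()
  ## consensus window has energy 0 -> occupancy R0/(1+R0)
  cons <- consensus_string(m)
  r0 <- exp(prm$r0_slope * 10 + prm$r0_intercept)
  a_cons <- trap_affinity(m, cons, prm)
  ## both strands scanned; the revcomp window contributes a little too
  expect_gte(a_cons, r0 / (1 + r0))
  expect_lte(a_cons, 2)
  ## planting the consensus raises affinity over the same background
  bgseq <- random_dna(120)
  planted <- bgseq
  substr(planted, 51, 60) <- cons
  expect_gt(trap_affinity(m, planted, prm), trap_affinity(m, bgseq, prm))
  ## affinity within [0, 2 * n_windows]
  a <- trap_affinity(m, bgseq, prm)
  expect_gte(a, 0)
  expect_lte(a, 2 * (120 - 10 + 1))
  ## shorter than the motif
  expect_message(a0 <- trap_affinity(m, "ACGT", prm), "affinity 0")
  expect_equal(a0, 0)
  expect_error(trap_params(lambda = 0), "> 0")
})

test_that("TRAP affinity equals a brute-force window summation", {
  set.seed(82)
  m <- make_planted_pwm(7, 1.4, seed = 17, id = "tf")
  prm <- trap_params()
  seq <- random_dna(60)
  brute <- 0
  r0 <- exp(prm$r0_slope * 7 + prm$r0_intercept)
  for (s in c(seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))))) {
    ch <- strsplit(s, "")[[1]]
    for (i in 1:(60 - 7 + 1)) {
      e <- 0
      for (j in 1:7) {
        p <- m$probs[ch[i + j - 1], j]
        e <- e + log(max(m$probs[, j]) / p) / prm$lambda
      }
      brute <- brute + r0 * exp(-e) / (1 + r0 * exp(-e))
    }
  }
  expect_equal(trap_affinity(m, seq, prm), unname(brute),
               tolerance = 1e-9)
})

test_that("TRAP affinity is strand-symmetric and monotone in site count", {
  set.seed(83)
  m <- make_planted_pwm(9, 1.5, seed = 27, id = "tf")
  seq <- random_dna(150)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
  expect_equal(trap_affinity(m, seq), trap_affinity(m, rc),
               tolerance = 1e-9)
  cons <- consensus_string(m)
  s1 <- seq; substr(s1, 11, 19) <- cons
  s2 <- s1; substr(s2, 61, 69) <- cons
  s3 <- s2; substr(s3, 111, 119) <- cons
  a <- vapply(c(seq, s1, s2, s3), trap_affinity, numeric(1), pwm = m)
  expect_true(all(diff(a) > 0))
})

test_that("affinity p-values are floored, uniform-ish and reproducible", {
  set.seed(84)
  m <- make_planted_pwm(8, 1.5, seed = 37, id = "tf")
  bg <- uniform_bg()
  ## observed far above any null -> exactly the floor
  strong <- paste(rep(consensus_string(m), 8), collapse = "")
  a <- trap_affinity(m, strong)
  p <- affinity_pvalue(a, m, bg, len = nchar(strong), n_null = 100,
                       seed = 5)
  expect_equal(p, 1 / 101)
  expect_identical(p, affinity_pvalue(a, m, bg, len = nchar(strong),
                                      n_null = 100, seed = 5))
  ## null-drawn observations give roughly uniform p (moments check)
  nulls <- sample_background(bg, 60, 60)
  ps <- vapply(nulls, function(s)
    affinity_pvalue(trap_affinity(m, s), m, bg, len = 60, n_null = 100,
                    seed = 6), numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
  expect_error(affinity_pvalue(1, m, bg, len = 60, n_null = 10), ">= 100")
})

test_that("log10 p-value differences match the worked example", {
  expect_equal(round(log10_pvalue_difference(0.0025, 0.52), 2), 2.32)
  expect_equal(log10_pvalue_difference(0.3, 0.3), 0)
  expect_equal(log10_pvalue_difference(0.001, 0.1), 2.00)
  ## symmetry: order of alleles does not matter
  expect_equal(log10_pvalue_difference(0.52, 0.0025),
               log10_pvalue_difference(0.0025, 0.52))
  expect_error(log10_pvalue_difference(0, 0.5), "\\(0, 1\\]")
})

test_that("ranking orders by allelic difference with stable ties", {
  res <- data.frame(variant_id = c("b", "a", "c"), tf = "t",
                    affinity_ref = 1, affinity_alt = 1,
                    p_ref = c(0.001, 0.01, 0.01),
                    p_alt = c(0.5, 0.01, 0.1),
                    stringsAsFactors = FALSE)
  res$log10_diff <- mapply(log10_pvalue_difference, res$p_ref, res$p_alt)
  rk <- rank_allelic_differences(res)
  expect_equal(rk$variant_id, c("b", "c", "a"))
  expect_equal(rk$percentile, c(1, 2, 3) / 3 * 100)
  single <- rank_allelic_differences(res[1, , drop = FALSE])
  expect_equal(single$percentile, 100)
  ## tie stability by variant id
  res2 <- res
  res2$p_ref <- 0.01; res2$p_alt <- 0.1
  res2$log10_diff <- 1
  expect_equal(rank_allelic_differences(res2)$variant_id,
               c("a", "b", "c"))
  expect_error(rank_allelic_differences(res[0, ]), "no results")
})

test_that("a disruptive variant tops the TF ranking and BH is consistent", {
  set.seed(86)
  m <- make_planted_pwm(10, 1.7, seed = 47, id = "tf1")
  g <- toy_genome(chr1 = random_dna(1200))
  gs <- as.character(g[[1]])
  ## REF carries a consensus site; ALT deletes its core
  substr(gs, 401, 410) <- consensus_string(m)
  g <- toy_genome(chr1 = gs)
  disr <- normalize_variant("chr1", 403, substr(gs, 404, 409), "-",
                            id = "hit", coords = "zero")
  neut <- lapply(c(100, 700, 1000), function(p) {
    rb <- substr(gs, p + 1, p + 1)
    normalize_variant("chr1", p, rb,
                      setdiff(c("A", "C", "G", "T"), rb)[1],
                      id = paste0("n", p), coords = "zero")
  })
  pairs <- lapply(c(list(disr), neut), function(v)
    extract_allele_sequences(v, g, flank = 30))
  out <- trap_scan(pairs, list(m), uniform_bg(), n_null = 200, seed = 3)
  rk <- rank_allelic_differences(out)
  expect_equal(rk$variant_id[1], "hit")
  expect_gt(rk$affinity_ref[1], rk$affinity_alt[1])
  expect_true(all(out$q_ref >= out$p_ref - 1e-12))
  expect_true(all(out$q_alt >= out$p_alt - 1e-12))
})
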