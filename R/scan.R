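## Motif scanning with log-odds scores and exact null p-values
## (dynamic-programming convolution over an order-0 background).

#' Log-odds score matrix of a PWM against an order-0 background
#'
#' @param pwm a \code{pwm} (pseudocounts already applied).
#' @param bg a \code{bg_model}; its marginal letter frequencies are used.
#' @return 4 x width matrix, entry = log2(prob / bg frequency), in bits.
#' @export
log_odds <- function(pwm, bg) {
  f <- bg$freq
  if (any(f <= 0)) stop("background frequencies must all be > 0")
  log2(pwm$probs / f)
}

#' Exact score-to-p-value table for a PWM
#'
#' The log-odds matrix is discretized to an integer grid with
#' \code{resolution} bins over the total score range; the null
#' distribution of the window score under the order-0 background is then
#' the exact convolution of the per-position score distributions, giving
#' P(window score >= s) on the grid.
#'
#' @param pwm a \code{pwm}.
#' @param bg a \code{bg_model} (order-0 marginal used).
#' @param resolution number of grid bins over the score range
#'   (default 1000, minimum 100).
#' @return object of class \code{score_table}: \code{delta} (bin width in
#'   bits), \code{offset} (real score of grid 0), \code{ints} (integer
#'   cell scores), \code{tail} (P(score >= grid value)), \code{lom}
#'   (the real log-odds matrix).
#' @export
score_pvalue_table <- function(pwm, bg, resolution = 1000) {
  if (resolution < 100) stop("resolution must be >= 100")
  lom <- log_odds(pwm, bg)
  w <- ncol(lom)
  col_min <- apply(lom, 2, min)
  col_max <- apply(lom, 2, max)
  rng <- sum(col_max) - sum(col_min)
  if (rng < 1e-12) {
    ## degenerate: every window scores the same; p = 1 everywhere
    return(structure(list(delta = 0, offset = sum(col_min),
                          ints = matrix(0L, 4, w), tail = 1,
                          max_int = 0L, lom = lom),
                     class = "score_table"))
  }
  delta <- rng / resolution
  ints <- round(sweep(lom, 2, col_min, "-") / delta)
  storage.mode(ints) <- "integer"
  M <- sum(apply(ints, 2, max))
  dist <- numeric(M + 1)
  dist[1] <- 1
  f <- bg$freq
  for (p in seq_len(w)) {
    nd <- numeric(M + 1)
    for (b in 1:4) {
      s <- ints[b, p]
      nd[(1 + s):(M + 1)] <- nd[(1 + s):(M + 1)] + f[b] * dist[1:(M + 1 - s)]
    }
    dist <- nd
  }
  tail <- rev(cumsum(rev(dist)))
  tail <- pmin(pmax(tail, 0), 1)
  structure(list(delta = delta, offset = sum(col_min), ints = ints,
                 tail = tail, max_int = M, lom = lom),
            class = "score_table")
}

#' Look up the p-value of a real-valued window score
#' @param table a \code{score_table}.
#' @param score log-odds score in bits.
#' @return P(window score >= score) under the null, on the grid.
#' @export
score_pvalue <- function(table, score) {
  if (table$delta == 0) return(1)
  i <- round((score - table$offset) / table$delta)
  i <- max(0L, min(as.integer(i), table$max_int))
  table$tail[i + 1L]
}

## all window scores of an encoded sequence against a log-odds matrix;
## windows containing N are NA
window_scores <- function(enc, lom) {
  w <- ncol(lom)
  L <- length(enc)
  if (L < w) return(numeric(0))
  nwin <- L - w + 1L
  s <- numeric(nwin)
  for (p in seq_len(w)) {
    v <- lom[cbind(enc[p:(p + nwin - 1L)], p)]
    s <- s + v
  }
  s
}

#' Best motif hit in a sequence
#'
#' Maximal log-odds score over all windows and (optionally) both strands;
#' the p-value comes from the exact null table at that score. Ties are
#' broken in favor of the forward strand, then the smallest offset.
#' Windows containing N are skipped. A sequence shorter than the motif
#' yields score \code{-Inf} and p = 1.
#'
#' @param pwm a \code{pwm}.
#' @param seq DNA string.
#' @param bg order-0 \code{bg_model}.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param table optional precomputed \code{score_table}.
#' @return list: score (bits), p, strand ("+"/"-"), offset (0-based
#'   forward-strand window start).
#' @export
best_hit <- function(pwm, seq, bg, both_strands = TRUE, table = NULL) {
  if (is.null(table)) table <- score_pvalue_table(pwm, bg)
  lom <- table$lom
  enc <- encode_seq(seq)
  w <- ncol(lom)
  if (length(enc) < w) {
    message("sequence shorter than motif width; no hit")
    return(list(score = -Inf, p = 1, strand = NA_character_,
                offset = NA_integer_))
  }
  sf <- window_scores(enc, lom)
  best_s <- -Inf; best_strand <- NA_character_; best_off <- NA_integer_
  if (any(!is.na(sf))) {
    i <- which.max(sf)
    best_s <- sf[i]; best_strand <- "+"; best_off <- i - 1L
  }
  if (both_strands) {
    er <- revcomp_int(enc)
    sr <- window_scores(er, lom)
    if (any(!is.na(sr))) {
      j <- which.max(sr)
      if (sr[j] > best_s) {
        best_s <- sr[j]; best_strand <- "-"
        best_off <- length(enc) - w - (j - 1L)  # forward-strand start
      }
    }
  }
  if (!is.finite(best_s))
    return(list(score = -Inf, p = 1, strand = NA_character_,
                offset = NA_integer_))
  list(score = best_s, p = score_pvalue(table, best_s),
       strand = best_strand, offset = best_off)
}

#' Scan variant allele pairs against per-dataset motifs
#'
#' One result row per (variant x motif x dataset): best-hit p-values and
#' scores of the REF and ALT flanking sequences. A pair is flagged as a
#' significant overlap when \code{min(p_ref, p_alt)} is below the
#' Bonferroni bound \code{alpha / n_motifs / n_variants} (the total motif
#' and variant counts across the scan).
#'
#' @param pairs list of \code{allele_pair}.
#' @param motifs named list: dataset id -> list of \code{pwm}.
#' @param bg named list: dataset id -> order-0 \code{bg_model} (a single
#'   \code{bg_model} is recycled).
#' @param alpha significance level for the overlap flag (default 0.01).
#' @param overlap_threshold optional explicit threshold overriding the
#'   Bonferroni derivation.
#' @return data.frame: variant_id, ref, alt, dataset_id, motif_id,
#'   p_ref, p_alt, sc_ref, sc_alt, strand_ref, strand_alt, offset_ref,
#'   offset_alt, significant_overlap.
#' @export
scan_variants <- function(pairs, motifs, bg, alpha = 0.01,
                          overlap_threshold = NULL) {
  if (is(bg, "bg_model"))
    bg <- stats::setNames(rep(list(bg), length(motifs)), names(motifs))
  n_motifs <- sum(lengths(motifs))
  n_variants <- length(pairs)
  if (is.null(overlap_threshold))
    overlap_threshold <- significance_threshold(
      alpha, c(max(n_motifs, 1), max(n_variants, 1)))
  rows <- list()
  for (ds in names(motifs)) {
    tables <- lapply(motifs[[ds]], score_pvalue_table, bg = bg[[ds]])
    for (k in seq_along(motifs[[ds]])) {
      m <- motifs[[ds]][[k]]
      tbl <- tables[[k]]
      for (pr in pairs) {
        hr <- best_hit(m, pr$seq_ref, bg[[ds]], table = tbl)
        ha <- best_hit(m, pr$seq_alt, bg[[ds]], table = tbl)
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = pr$variant$id,
          ref = pr$variant$ref, alt = pr$variant$alt,
          dataset_id = ds, motif_id = m$id,
          p_ref = hr$p, p_alt = ha$p,
          sc_ref = hr$score, sc_alt = ha$score,
          strand_ref = hr$strand, strand_alt = ha$strand,
          offset_ref = hr$offset, offset_alt = ha$offset,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(0), ref = character(0),
               alt = character(0), dataset_id = character(0),
               motif_id = character(0), p_ref = numeric(0),
               p_alt = numeric(0), sc_ref = numeric(0),
               sc_alt = numeric(0), strand_ref = character(0),
               strand_alt = character(0), offset_ref = integer(0),
               offset_alt = integer(0), stringsAsFactors = FALSE)
  out$significant_overlap <-
    pmin(out$p_ref, out$p_alt) < overlap_threshold
  attr(out, "overlap_threshold") <- overlap_threshold
  out
}
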