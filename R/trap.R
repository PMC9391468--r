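## Biophysical TF-affinity arm: TRAP-style expected occupancy under a
## mismatch-energy model, with empirical-null p-values and the log10
## p-value-difference comparison between REF and ALT alleles.

#' TRAP model parameters
#'
#' \code{lambda} scales the mismatch energy; the width-dependent
#' prefactor is \code{ln R0 = r0_slope * width + r0_intercept}. Defaults
#' are the published TRAP values.
#'
#' @param lambda mismatch-energy scale (> 0, default 0.7).
#' @param r0_slope,r0_intercept prefactor coefficients (defaults 0.584
#'   and -5.66).
#' @return list of class \code{trap_params}.
#' @export
trap_params <- function(lambda = 0.7, r0_slope = 0.584,
                        r0_intercept = -5.66) {
  if (lambda <= 0) stop("lambda must be > 0")
  structure(list(lambda = lambda, r0_slope = r0_slope,
                 r0_intercept = r0_intercept), class = "trap_params")
}

## per-window mismatch energies for an encoded sequence:
## E = (1/lambda) * sum_i ln(p_max_i / p_base_i); NA windows -> NA
trap_energies <- function(enc, pwm, params) {
  w <- pwm$width
  pen <- log(matrix(apply(pwm$probs, 2, max), 4, w, byrow = TRUE) /
               pwm$probs) / params$lambda
  window_scores(enc, pen)
}

#' TRAP expected occupancy of a sequence for one TF motif
#'
#' Each window's mismatch energy is
#' E = (1/lambda) * sum_i ln(p_max,i / p_base_i,i) (0 for the consensus
#' window); its occupancy is R0 e^-E / (1 + R0 e^-E) with
#' ln R0 = slope * width + intercept. The affinity is the sum of
#' occupancies over all windows on both strands. Windows containing N
#' are skipped; a sequence shorter than the motif has affinity 0.
#'
#' @param pwm a \code{pwm}.
#' @param seq DNA string.
#' @param params \code{trap_params}.
#' @return numeric affinity in [0, 2 * (length - width + 1)].
#' @export
trap_affinity <- function(pwm, seq, params = trap_params()) {
  enc <- encode_seq(seq)
  if (length(enc) < pwm$width) {
    message("sequence shorter than motif width; affinity 0")
    return(0)
  }
  r0 <- exp(params$r0_slope * pwm$width + params$r0_intercept)
  occ <- function(e) {
    x <- r0 * exp(-e)
    x / (1 + x)
  }
  ef <- trap_energies(enc, pwm, params)
  er <- trap_energies(revcomp_int(enc), pwm, params)
  sum(occ(ef), na.rm = TRUE) + sum(occ(er), na.rm = TRUE)
}

#' Empirical p-value of an affinity against a background null
#'
#' Scores \code{n_null} background-model sequences of the given length
#' and returns \code{(1 + #(null >= observed)) / (n_null + 1)}.
#'
#' @param affinity observed affinity.
#' @param pwm the \code{pwm} it was computed with.
#' @param bg a \code{bg_model} generating the null sequences.
#' @param len null sequence length (bases) — use the scored sequence's
#'   length.
#' @param n_null number of null sequences (>= 100, default 1000).
#' @param seed RNG seed.
#' @param params \code{trap_params}.
#' @return p-value in [1/(n_null + 1), 1].
#' @export
affinity_pvalue <- function(affinity, pwm, bg, len, n_null = 1000,
                            seed = 1, params = trap_params()) {
  if (n_null < 100) stop("n_null must be >= 100")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old))
  set.seed(seed)
  nulls <- vapply(sample_background(bg, len, n_null), trap_affinity,
                  numeric(1), pwm = pwm, params = params)
  (1 + sum(nulls >= affinity)) / (n_null + 1)
}

#' Absolute log10 difference of two p-values
#'
#' @param p_ref,p_alt p-values in (0, 1].
#' @return |log10(p_ref) - log10(p_alt)|.
#' @export
log10_pvalue_difference <- function(p_ref, p_alt) {
  if (any(c(p_ref, p_alt) <= 0) || any(c(p_ref, p_alt) > 1))
    stop("p-values must be in (0, 1]")
  abs(log10(p_ref) - log10(p_alt))
}

#' Score variant allele pairs for TF affinity differences
#'
#' For each (variant x TF motif): TRAP affinities of the REF and ALT
#' flanking sequences, empirical-null p-values, and the absolute log10
#' p-value difference, with Benjamini-Hochberg adjustment of each
#' allele's p-values across TFs within a variant.
#'
#' @param pairs list of \code{allele_pair}.
#' @param tf_motifs list of \code{pwm} (e.g. from \code{\link{read_meme}}
#'   or \code{\link{read_jaspar}}).
#' @param bg \code{bg_model} for the null.
#' @param n_null null sequences per p-value (default 1000).
#' @param seed RNG seed.
#' @param params \code{trap_params}.
#' @return data.frame: variant_id, tf, affinity_ref, affinity_alt,
#'   p_ref, p_alt, q_ref, q_alt, log10_diff.
#' @export
trap_scan <- function(pairs, tf_motifs, bg, n_null = 1000, seed = 1,
                      params = trap_params()) {
  rows <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    for (k in seq_along(tf_motifs)) {
      m <- tf_motifs[[k]]
      a_ref <- trap_affinity(m, pr$seq_ref, params)
      a_alt <- trap_affinity(m, pr$seq_alt, params)
      p_ref <- affinity_pvalue(a_ref, m, bg, nchar(pr$seq_ref),
                               n_null = n_null, seed = seed + 13 * k,
                               params = params)
      p_alt <- affinity_pvalue(a_alt, m, bg, nchar(pr$seq_alt),
                               n_null = n_null, seed = seed + 13 * k + 7,
                               params = params)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = pr$variant$id, tf = m$id,
        affinity_ref = a_ref, affinity_alt = a_alt,
        p_ref = p_ref, p_alt = p_alt,
        log10_diff = log10_pvalue_difference(p_ref, p_alt),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_ref <- stats::ave(out$p_ref, out$variant_id,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  out$q_alt <- stats::ave(out$p_alt, out$variant_id,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  out
}

#' Rank variant-TF pairs by allelic affinity difference
#'
#' Descending by \code{log10_diff} (ties broken by variant id, then TF
#' id); the percentile of a row is rank / total * 100, so the strongest
#' difference is in the smallest percentile.
#'
#' @param results data.frame from \code{\link{trap_scan}}.
#' @return the same rows with \code{rank} and \code{percentile} added,
#'   sorted by rank.
#' @export
rank_allelic_differences <- function(results) {
  if (nrow(results) < 1) stop("no results to rank")
  ord <- order(-results$log10_diff, results$variant_id, results$tf)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$percentile <- out$rank / nrow(out) * 100
  rownames(out) <- NULL
  out
}
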