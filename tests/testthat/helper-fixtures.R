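## shared fixtures, all built in code

uniform_bg <- function() {
  structure(list(order = 0,
                 freq = stats::setNames(rep(0.25, 4),
                                        c("A", "C", "G", "T"))),
            class = "bg_model")
}

## random DNA string(s) under uniform base frequencies
random_dna <- function(len, n = 1) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

## sample one site string from a PWM
sample_site <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$probs, 2, function(p)
    sample.int(4, 1, prob = p))], collapse = "")
}

## sequence set with a PWM planted in a fraction of the sequences
planted_fixture <- function(pwm, n_seqs = 200, seq_len = 100,
                            plant_frac = 0.7, seed = 1) {
  set.seed(seed)
  seqs <- random_dna(seq_len, n_seqs)
  idx <- sample(n_seqs, round(plant_frac * n_seqs))
  w <- pwm$width
  for (i in idx) {
    pos <- sample(seq_len - w + 1, 1)
    substr(seqs[i], pos, pos + w - 1) <- sample_site(pwm)
  }
  list(seqs = seqs, planted_in = idx)
}

## best per-column correlation between a discovered and a reference PWM
## over all offsets and both orientations (mean per aligned column)
aligned_column_cor <- function(query, ref, min_overlap = 4) {
  best <- -Inf
  for (tgt in list(ref, reverse_complement_pwm(ref))) {
    wq <- query$width; wt <- tgt$width
    for (off in seq(-(wq - min_overlap), wt - min_overlap)) {
      qi <- max(1, 1 - off):min(wq, wt - off)
      if (length(qi) < min_overlap) next
      ti <- qi + off
      cors <- vapply(seq_along(qi), function(k)
        stats::cor(query$probs[, qi[k]], tgt$probs[, ti[k]]), numeric(1))
      best <- max(best, mean(cors))
    }
  }
  best
}

## per-base membership oracle for interval algebra (0-based positions)
bases_of <- function(gr) {
  df <- interval_frame(gr)
  if (!nrow(df)) return(character(0))
  unlist(lapply(seq_len(nrow(df)), function(i)
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1))))
}

random_interval_set <- function(n, chroms = c("chr1", "chr2"),
                                max_pos = 1000) {
  s <- sample(max_pos - 20, n, replace = TRUE)
  interval_set(sample(chroms, n, replace = TRUE), s,
               s + sample(1:20, n, replace = TRUE))
}

## tiny genome as a DNAStringSet
toy_genome <- function(...) {
  g <- Biostrings::DNAStringSet(c(...))
  g
}
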