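## Synthetic input bundle: genome, exons, enhancers with planted motif
## sites, per-sample histone peak calls (fold change + q-value), RNA
## coverage, and credible-set-style variants with known allelic effects.
## The generator's role is statistical structure (peak sizes, gamma fold
## changes, elevated coverage in active regions, planted PWMs, variants
## that create or destroy sites), not read-level realism.

#' Build a planted PWM with a target per-column information content
#'
#' Each column has one dominant base at probability p (the other three
#' sharing 1 - p), with p solved so the column's information content
#' (uniform reference) equals \code{ic_per_col} bits.
#'
#' @param width motif width (default 12).
#' @param ic_per_col bits per column (default 1.5).
#' @param seed RNG seed choosing the dominant bases.
#' @param id motif id.
#' @return a \code{pwm}.
#' @export
make_planted_pwm <- function(width = 12, ic_per_col = 1.5, seed = 1,
                             id = "planted_1") {
  stopifnot(ic_per_col > 0, ic_per_col < 2)
  f <- function(p) 2 + p * log2(p) + (1 - p) * log2((1 - p) / 3) - ic_per_col
  p <- stats::uniroot(f, c(0.2501, 1 - 1e-9))$root
  old <- .Random.seed_exists()
  set.seed(seed)
  dom <- sample.int(4, width, replace = TRUE)
  restore_seed(old)
  probs <- matrix((1 - p) / 3, 4, width)
  probs[cbind(dom, seq_len(width))] <- p
  pwm(probs, id = id)
}

#' Simulation configuration
#'
#' Defaults define the study conditions of the synthetic bundle: two
#' 200 kb chromosomes, 200 enhancers of a few hundred bp, one planted
#' 12-bp PWM at about 1.5 bits per column carried by 70\% of enhancers,
#' two replicate samples for each of two histone marks in one cell type,
#' gamma-distributed peak fold changes, coverage elevated inside
#' enhancers, and 100 variants of which 10\% disrupt (or create) planted
#' sites.
#'
#' @param seed master RNG seed.
#' @param n_chroms,chrom_length genome shape (bases).
#' @param gc_content genome GC fraction.
#' @param exon_fraction,exon_mean_len exon annotation density.
#' @param n_enhancers total enhancers across chromosomes.
#' @param enhancer_mean_len,enhancer_sd_len,enhancer_min_len,enhancer_max_len
#'   enhancer length distribution (bases, truncated normal).
#' @param planted_pwms list of \code{pwm} to plant (default: one 12-bp,
#'   1.5 bits/column motif derived from \code{seed}).
#' @param plant_rate fraction of enhancers carrying a site.
#' @param cell_types named list: cell type -> character vector of
#'   histone marks measured for it.
#' @param n_samples biological replicates per (cell type x mark).
#' @param peak_jitter per-sample peak boundary jitter (bases).
#' @param fc_shape,fc_scale gamma parameters of peak fold changes.
#' @param q_fail_rate fraction of per-sample peaks drawn with a failing
#'   q-value (>= 1e-4).
#' @param coverage_in,coverage_out mean RNA depth inside / outside
#'   enhancers.
#' @param n_variants,fraction_disruptive variant counts.
#' @param indel_range length range of disruptive deletions.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_length = 200000,
                       gc_content = 0.5, exon_fraction = 0.1,
                       exon_mean_len = 150, n_enhancers = 200,
                       enhancer_mean_len = 400, enhancer_sd_len = 150,
                       enhancer_min_len = 100, enhancer_max_len = 1000,
                       planted_pwms = NULL, plant_rate = 0.7,
                       cell_types = list(CD4ab = c("H3K4me3", "H3K27ac")),
                       n_samples = 2, peak_jitter = 20,
                       fc_shape = 2, fc_scale = 3, q_fail_rate = 0.15,
                       coverage_in = 2, coverage_out = 0,
                       n_variants = 100, fraction_disruptive = 0.1,
                       indel_range = c(1, 12)) {
  if (is.null(planted_pwms))
    planted_pwms <- list(make_planted_pwm(12, 1.5, seed = seed))
  cfg <- as.list(environment())
  stopifnot(plant_rate >= 0, plant_rate <= 1,
            fraction_disruptive >= 0, fraction_disruptive <= 1,
            q_fail_rate >= 0, q_fail_rate <= 1,
            chrom_length > 0, n_enhancers > 0)
  structure(cfg, class = "sim_config")
}

## sample n non-overlapping intervals avoiding a forbidden set, with a
## minimum gap between intervals and a margin from chromosome ends;
## plain-arithmetic overlap checks (0-based half-open throughout)
place_intervals <- function(n, lens, chrom_sizes, avoid = NULL,
                            gap = 100, margin = 200, max_tries = 1000) {
  blocked <- if (is.null(avoid) || length(avoid) == 0)
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  else interval_frame(merge_intervals(avoid))[, c("chrom", "start", "end")]
  by_chr <- split(blocked[, c("start", "end")], blocked$chrom)
  out_chr <- character(n); out_s <- numeric(n)
  lens <- rep_len(lens, n)
  chroms <- names(chrom_sizes)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      chr <- chroms[sample.int(length(chroms), 1)]
      len <- lens[i]
      hi <- chrom_sizes[[chr]] - margin - len
      if (hi <= margin) next
      s <- sample.int(hi - margin, 1) + margin
      e <- s + len
      bl <- by_chr[[chr]]
      if (!is.null(bl) && any(bl$start < e + gap & bl$end > s - gap)) next
      by_chr[[chr]] <- rbind(bl, data.frame(start = s, end = e))
      out_chr[i] <- chr; out_s[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place interval ", i,
                  " after ", max_tries, " tries")
  }
  sort(interval_set(out_chr, out_s, out_s + lens))
}

#' Simulate a genome and exon annotation
#'
#' I.i.d. background sequence at the configured GC content, with
#' non-overlapping exon features covering about \code{exon_fraction} of
#' each chromosome.
#'
#' @param config a \code{sim_config}.
#' @return list: genome (\code{DNAStringSet}), exons (\code{GRanges}),
#'   chrom_sizes (named integer).
#' @export
simulate_genome <- function(config) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old))
  set.seed(config$seed)
  gc <- config$gc_content
  pr <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(sample(DNA_BASES, config$chrom_length, TRUE, pr), collapse = ""),
    character(1)))
  names(genome) <- chroms
  chrom_sizes <- stats::setNames(rep(config$chrom_length, length(chroms)),
                                 chroms)
  n_ex <- max(1L, floor(config$chrom_length * config$exon_fraction /
                          config$exon_mean_len))
  exons <- GRanges()
  for (ch in chroms) {
    step <- config$chrom_length %/% (n_ex + 1L)
    starts <- step * seq_len(n_ex) +
      sample.int(max(step %/% 4, 2), n_ex, replace = TRUE)
    lens <- pmax(30, round(stats::rnorm(n_ex, config$exon_mean_len, 40)))
    ends <- pmin(starts + lens, config$chrom_length)
    exons <- c(exons, interval_set(ch, starts, ends))
  }
  exons <- merge_intervals(exons)
  list(genome = genome, exons = exons, chrom_sizes = chrom_sizes)
}

#' Plant motif sites and simulate peaks and coverage
#'
#' Enhancer intervals (avoiding exons) receive planted PWM sites at
#' \code{plant_rate}; per-sample peak calls are the enhancers with
#' jittered borders, gamma fold changes, and q-values of which about
#' \code{q_fail_rate} fail the q < 1e-4 filter; RNA coverage is
#' \code{coverage_in} inside enhancers and \code{coverage_out} outside.
#'
#' @param config a \code{sim_config}.
#' @param sim output of \code{\link{simulate_genome}}.
#' @return list: genome (with sites written in), enhancers, sites
#'   (data.frame), peaks (peak-call data.frame over all samples),
#'   coverage (\code{coverage_track}), truth_n_peaks (named expected
#'   per-dataset pooled peak counts after the standard filters).
#' @export
plant_and_peak <- function(config, sim) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old))
  set.seed(config$seed + 1L)
  genome <- sim$genome
  chrom_sizes <- sim$chrom_sizes
  lens <- pmin(config$enhancer_max_len,
               pmax(config$enhancer_min_len,
                    round(stats::rnorm(config$n_enhancers,
                                       config$enhancer_mean_len,
                                       config$enhancer_sd_len))))
  enhancers <- place_intervals(config$n_enhancers, lens, chrom_sizes,
                               avoid = sim$exons, gap = 100, margin = 300)
  ## plant sites
  n_plant <- round(config$plant_rate * length(enhancers))
  which_pl <- sort(sample.int(length(enhancers), n_plant))
  sites <- list()
  for (k in seq_along(which_pl)) {
    e <- enhancers[which_pl[k]]
    m <- config$planted_pwms[[(k - 1L) %% length(config$planted_pwms) + 1L]]
    w <- m$width
    s0 <- start(e) - 1L          # 0-based enhancer start
    room <- width(e) - w - 50L
    if (room < 1) next
    off <- sample.int(room, 1) + 25L
    site_seq <- paste(DNA_BASES[apply(m$probs, 2, function(p)
      sample.int(4, 1, prob = p))], collapse = "")
    pos0 <- s0 + off
    chr <- as.character(seqnames(e))
    genome[[chr]] <- Biostrings::replaceAt(
      genome[[chr]], IRanges(pos0 + 1L, pos0 + w),
      Biostrings::DNAString(site_seq))
    sites[[length(sites) + 1L]] <- data.frame(
      chrom = chr, start = pos0, end = pos0 + w, pwm_id = m$id,
      site_seq = site_seq, enhancer = which_pl[k],
      stringsAsFactors = FALSE)
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               pwm_id = character(0), site_seq = character(0),
               enhancer = integer(0), stringsAsFactors = FALSE)
  ## per-sample peaks
  ef <- interval_frame(enhancers)
  peaks <- list()
  pass_any <- list()
  for (ct in names(config$cell_types)) {
    for (hm in config$cell_types[[ct]]) {
      pass <- rep(FALSE, nrow(ef))
      for (sm in seq_len(config$n_samples)) {
        jl <- sample.int(config$peak_jitter + 1L, nrow(ef), TRUE) - 1L
        jr <- sample.int(config$peak_jitter + 1L, nrow(ef), TRUE) - 1L
        st <- pmax(ef$start - jl, 0)
        en <- ef$end + jr
        fc <- stats::rgamma(nrow(ef), shape = config$fc_shape,
                            scale = config$fc_scale)
        fail_q <- stats::runif(nrow(ef)) < config$q_fail_rate
        q <- ifelse(fail_q,
                    10^stats::runif(nrow(ef), -3.5, -2),
                    10^stats::runif(nrow(ef), -9, -5))
        peaks[[length(peaks) + 1L]] <- data.frame(
          chrom = ef$chrom, start = st, end = en,
          fold_change = fc, q_value = q,
          sample_id = sprintf("%s_%s_s%d", ct, hm, sm),
          cell_type = ct, hist_mod = hm, stringsAsFactors = FALSE)
        ## the generator's own account of the filters: fc/q gates plus
        ## the RNA gate (mean depth over the jittered peak)
        enh_w <- ef$end - ef$start
        peak_w <- en - st
        mdepth <- (config$coverage_in * enh_w +
                     config$coverage_out * (peak_w - enh_w)) / peak_w
        pass <- pass | (fc >= 3 & q < 1e-4 & mdepth >= 0.001)
      }
      pass_any[[paste(ct, hm, sep = ".")]] <- sum(pass)
    }
  }
  peaks <- do.call(rbind, peaks)
  ## coverage: enhancers at coverage_in, the rest at coverage_out
  cov_gr <- enhancers
  cov_gr$score <- config$coverage_in
  if (config$coverage_out > 0) {
    rest <- subtract_intervals(
      interval_set(names(chrom_sizes), rep(0, length(chrom_sizes)),
                   chrom_sizes), enhancers)
    rest$score <- config$coverage_out
    cov_gr <- sort(c(cov_gr, rest))
  }
  coverage <- coverage_track(cov_gr, chrom_sizes)
  list(genome = genome, enhancers = enhancers, sites = sites,
       peaks = peaks, coverage = coverage,
       truth_n_peaks = unlist(pass_any))
}

#' Simulate variants with known allelic effects
#'
#' A \code{fraction_disruptive} share of variants hit planted sites:
#' SNVs at the motif's most informative column, deletions overlapping
#' the site, and creator insertions — a broken (one base deleted) copy
#' of the motif consensus is written into background sequence and the
#' variant's insertion allele restores it, so the ALT allele carries the
#' intact site. The remainder are background variants at least 60 bp
#' from any site. Every variant gets a truth record.
#'
#' @param config a \code{sim_config}.
#' @param planted output of \code{\link{plant_and_peak}}.
#' @param sim output of \code{\link{simulate_genome}}.
#' @return list: genome (possibly edited for creators), variants
#'   (normalized data.frame), truth (data.frame: id, is_disruptive,
#'   affected_motif, direction, type).
#' @export
simulate_variants <- function(config, planted, sim) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old))
  set.seed(config$seed + 2L)
  genome <- planted$genome
  chrom_sizes <- sim$chrom_sizes
  sites <- planted$sites
  n_d <- round(config$n_variants * config$fraction_disruptive)
  if (n_d > nrow(sites) && n_d > 0)
    stop("not enough planted sites for the requested disruptive variants")
  types <- if (n_d > 0)
    rep(c("snv", "del", "ins_creator"), length.out = n_d) else character(0)
  hit <- if (n_d > 0) sample.int(nrow(sites), n_d) else integer(0)
  pwm_by_id <- stats::setNames(config$planted_pwms,
                               vapply(config$planted_pwms, `[[`, "", "id"))
  base_at <- function(chr, pos0)
    toupper(as.character(Biostrings::subseq(genome[[chr]],
                                            pos0 + 1, pos0 + 1)))
  ## indels adjacent to an identical base have several equivalent
  ## representations; iterate anchored re-normalization to the fixed
  ## point so the stored record matches what a VCF round trip yields
  canonical <- function(v) {
    if (nchar(v$ref) && nchar(v$alt)) return(v)
    repeat {
      anchor <- base_at(v$chrom, v$pos - 1)
      v2 <- normalize_variant(v$chrom, v$pos - 1,
                              paste0(anchor, v$ref),
                              paste0(anchor, v$alt),
                              id = v$id, coords = "zero")
      if (v2$pos == v$pos) return(v)
      v <- v2
    }
  }
  ## occupied: sites, enhancers and previously placed variants
  combine <- function(...) suppressWarnings(merge_intervals(c(...)))
  occupied <- combine(
    planted$enhancers,
    if (nrow(sites)) interval_set(sites$chrom, sites$start, sites$end)
    else GRanges())
  vrows <- list(); trows <- list()
  vid <- function(i) sprintf("var%03d", i)
  i <- 0L
  for (k in seq_len(n_d)) {
    i <- i + 1L
    s <- sites[hit[k], ]
    m <- pwm_by_id[[s$pwm_id]]
    w <- m$width
    if (types[k] == "snv") {
      col <- which.max(pwm_information(m))
      pos0 <- s$start + col - 1L
      ref <- base_at(s$chrom, pos0)
      worst <- DNA_BASES[which.min(m$probs[, col])]
      alt <- if (worst != ref) worst else
        DNA_BASES[order(m$probs[, col])][2]
      v <- normalize_variant(s$chrom, pos0, ref, alt, id = vid(i),
                             coords = "zero")
      dirn <- "ref"
    } else if (types[k] == "del") {
      kmax <- min(config$indel_range[2], w - 2L)
      klen <- sample(seq(max(config$indel_range[1], 1L), kmax), 1)
      pos0 <- s$start + (w - klen) %/% 2L
      ref <- toupper(as.character(Biostrings::subseq(
        genome[[s$chrom]], pos0 + 1, pos0 + klen)))
      v <- canonical(normalize_variant(s$chrom, pos0, ref, "-",
                                       id = vid(i), coords = "zero"))
      dirn <- "ref"
    } else {  # creator insertion: broken consensus in background
      cons <- consensus_string(m)
      j <- as.integer(ceiling(w / 2))  # central: maximal frameshift on REF
      broken <- paste0(substr(cons, 1, j - 1), substr(cons, j + 1, w))
      spot <- place_intervals(1, w - 1L, chrom_sizes,
                              avoid = combine(occupied, sim$exons),
                              gap = 80, margin = 300)
      chr <- as.character(seqnames(spot))
      p0 <- start(spot) - 1L
      genome[[chr]] <- Biostrings::replaceAt(
        genome[[chr]], IRanges(p0 + 1L, p0 + w - 1L),
        Biostrings::DNAString(broken))
      occupied <- combine(occupied, spot)
      v <- canonical(normalize_variant(chr, p0 + j - 1L, "-",
                                       substr(cons, j, j),
                                       id = vid(i), coords = "zero"))
      dirn <- "alt"
    }
    vrows[[i]] <- v
    trows[[i]] <- data.frame(id = v$id, is_disruptive = TRUE,
                             affected_motif = s$pwm_id,
                             direction = dirn, type = types[k],
                             stringsAsFactors = FALSE)
  }
  ## neutral background variants, >= 60 bp from anything planted
  n_n <- config$n_variants - n_d
  if (n_n > 0) {
    spots <- place_intervals(n_n, rep(1L, n_n), chrom_sizes,
                             avoid = combine(occupied, sim$exons),
                             gap = 60, margin = 300)
    for (k in seq_len(n_n)) {
      i <- i + 1L
      chr <- as.character(seqnames(spots[k]))
      p0 <- start(spots[k]) - 1L
      if (k %% 5 == 0) {           # occasional neutral indel
        ins <- paste(sample(DNA_BASES, sample(1:3, 1), TRUE),
                     collapse = "")
        v <- canonical(normalize_variant(chr, p0, "-", ins,
                                         id = vid(i), coords = "zero"))
        type <- "neutral_ins"
      } else {
        ref <- base_at(chr, p0)
        alt <- sample(setdiff(DNA_BASES, ref), 1)
        v <- normalize_variant(chr, p0, ref, alt, id = vid(i),
                               coords = "zero")
        type <- "neutral_snv"
      }
      vrows[[i]] <- v
      trows[[i]] <- data.frame(id = v$id, is_disruptive = FALSE,
                               affected_motif = "", direction = "",
                               type = type, stringsAsFactors = FALSE)
    }
  }
  list(genome = genome,
       variants = do.call(rbind, vrows),
       truth = do.call(rbind, trows))
}

#' Simulate the full input bundle
#'
#' Runs \code{\link{simulate_genome}}, \code{\link{plant_and_peak}} and
#' \code{\link{simulate_variants}} under the configuration's seed, and
#' optionally writes every input as a plain-text file.
#'
#' @param config a \code{sim_config}.
#' @param dir optional output directory (created if needed).
#' @return list of class \code{sim_bundle}: genome, exons, chrom_sizes,
#'   enhancers, sites, peaks, coverage, variants, truth, truth_n_peaks,
#'   config; plus \code{dir} when written.
#' @export
simulate_bundle <- function(config = sim_config(), dir = NULL) {
  sim <- simulate_genome(config)
  pl <- plant_and_peak(config, sim)
  vs <- simulate_variants(config, pl, sim)
  bundle <- structure(list(
    genome = vs$genome, exons = sim$exons, chrom_sizes = sim$chrom_sizes,
    enhancers = pl$enhancers, sites = pl$sites, peaks = pl$peaks,
    coverage = pl$coverage, variants = vs$variants, truth = vs$truth,
    truth_n_peaks = pl$truth_n_peaks, config = config),
    class = "sim_bundle")
  if (!is.null(dir)) {
    write_bundle(bundle, dir)
    bundle$dir <- dir
  }
  bundle
}

#' Write a simulated bundle as plain-text files
#'
#' Writes genome.fa, exons.gff3, chrom.sizes, one
#' \code{peaks_<cell>_<mark>_<sample>.bed} per sample (columns chrom,
#' start, end, name, fold_change, q_value), coverage.bedGraph,
#' variants.vcf, truth.tsv, sites.tsv and config.json.
#'
#' @param bundle a \code{sim_bundle}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(bundle$genome, fp("genome.fa"))
  ex <- bundle$exons
  ex$source <- "sim"
  ex$type <- "exon"
  ex$ID <- sprintf("exon%04d", seq_along(ex))
  rtracklayer::export(ex, fp("exons.gff3"), format = "gff3")
  utils::write.table(
    data.frame(names(bundle$chrom_sizes), bundle$chrom_sizes),
    fp("chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (sm in unique(bundle$peaks$sample_id)) {
    p <- bundle$peaks[bundle$peaks$sample_id == sm, ]
    utils::write.table(
      data.frame(p$chrom, p$start, p$end,
                 sprintf("peak%04d", seq_len(nrow(p))),
                 p$fold_change, p$q_value),
      fp(sprintf("peaks_%s.bed", sm)), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  cov_runs <- lapply(names(bundle$coverage$depth), function(ch) {
    r <- bundle$coverage$depth[[ch]]
    en <- cumsum(runLength(r))
    st <- c(0, en[-length(en)])
    keep <- runValue(r) > 0
    data.frame(chrom = ch, start = st[keep], end = en[keep],
               score = runValue(r)[keep])
  })
  cov_runs <- do.call(rbind, cov_runs)
  utils::write.table(cov_runs, fp("coverage.bedGraph"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_variants_vcf(bundle$variants, bundle$genome, fp("variants.vcf"))
  utils::write.table(bundle$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$sites, fp("sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  cfg$planted_pwms <- lapply(cfg$planted_pwms, function(m)
    list(id = m$id, width = m$width, probs = as.vector(m$probs)))
  cfg$cell_types <- as.list(cfg$cell_types)
  jsonlite::write_json(unclass(cfg), fp("config.json"), auto_unbox = TRUE,
                       digits = NA)
  write_meme(bundle$config$planted_pwms, fp("planted_motifs.meme"))
  invisible(dir)
}
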