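## Stage orchestration over a written input bundle: peaks ->
## pseudostates -> discovery -> scan -> ediff -> affinity -> report.
## Each stage writes its outputs plus a manifest of input file hashes;
## unchanged stages are skipped on rerun unless forced.

#' Pipeline configuration
#'
#' Collects every tunable of the workflow with its conventional default:
#' peak filters (fold change >= 3, q < 1e-4), the RNA activity gate
#' (mean depth >= 0.001), the 6 bp minimum peak length, 20 bp peak
#' flanks, 30 bp variant flanks, 6-30 bp motif widths, 20 motifs per
#' dataset, 600-sequence subsampling, alpha 0.01 and the p < 0.05
#' eligibility bound of the allelic-difference statistic.
#'
#' @param input_dir directory holding the input bundle (as written by
#'   \code{\link{write_bundle}}: genome.fa, exons.gff3, chrom.sizes,
#'   peaks_*.bed, coverage.bedGraph, variants.vcf).
#' @param out_dir output directory (stage subfolders are created).
#' @param min_fc,max_q peak filter thresholds.
#' @param min_mean_depth RNA activity gate.
#' @param min_len,flank_peaks peak cleaning parameters (bases).
#' @param flank_variant variant flank (bases).
#' @param wmin,wmax,nmotifs,subsample,n_null discovery parameters;
#'   \code{n_null = 0} skips E-value assignment.
#' @param alpha,eligibility_p significance parameters.
#' @param pseudostates pseudostate ids to build (subset of 7,9,10,11,12).
#' @param tf_library optional path to a MEME or JASPAR motif file for
#'   the affinity arm; defaults to the bundle's planted_motifs.meme if
#'   present, else the affinity stage is skipped.
#' @param affinity_n_null null sequences per affinity p-value.
#' @param run_affinity set FALSE to skip the affinity stage entirely.
#' @param seed master seed for all stochastic stages.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            min_fc = 3, max_q = 1e-4,
                            min_mean_depth = 0.001, min_len = 6,
                            flank_peaks = 20, flank_variant = 30,
                            wmin = 6, wmax = 30, nmotifs = 20,
                            subsample = 600, n_null = 50,
                            alpha = 0.01, eligibility_p = 0.05,
                            pseudostates = c(7, 9, 10, 11, 12),
                            tf_library = NULL, affinity_n_null = 200,
                            run_affinity = TRUE, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(min_fc > 0, max_q > 0, min_mean_depth > 0, min_len > 0,
            flank_peaks >= 0, flank_variant > 0, wmin >= 2,
            wmax >= wmin, nmotifs >= 1, subsample >= 1,
            alpha > 0, eligibility_p > 0)
  structure(cfg, class = "pipeline_config")
}

stage_manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- stage_manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

stage_fresh <- function(manifest, stage, inputs, outputs, force) {
  if (force) return(FALSE)
  rec <- manifest[[stage]]
  if (is.null(rec)) return(FALSE)
  if (!all(file.exists(unlist(rec$outputs)))) return(FALSE)
  cur <- hash_files(inputs)
  identical(lapply(rec$inputs, as.character)[sort(names(rec$inputs))],
            lapply(cur, as.character)[sort(names(cur))])
}

#' Run the full workflow over an input bundle
#'
#' Executes the stages in order, writing each stage's outputs under
#' \code{out_dir} and recording input hashes in a manifest; on rerun,
#' stages whose inputs (and recorded outputs) are unchanged are skipped
#' unless \code{force = TRUE}. Progress is reported with messages.
#'
#' @param config a \code{pipeline_config}.
#' @param force recompute every stage.
#' @return invisible list: datasets, motifs, scan, ediff, results,
#'   affinity (NULL when skipped), and \code{skipped} (character vector
#'   of stages served from the manifest).
#' @export
run_pipeline <- function(config, force = FALSE) {
  ind <- config$input_dir
  outd <- config$out_dir
  dir.create(outd, showWarnings = FALSE, recursive = TRUE)
  manifest <- read_manifest(outd)
  skipped <- character(0)
  fp_in <- function(f) file.path(ind, f)
  fp_out <- function(f) file.path(outd, f)
  peak_files <- sort(list.files(ind, "^peaks_.*\\.bed$", full.names = TRUE))
  if (!length(peak_files)) stop("peaks stage: no peaks_*.bed in ", ind)
  for (f in c("genome.fa", "exons.gff3", "chrom.sizes",
              "coverage.bedGraph", "variants.vcf"))
    if (!file.exists(fp_in(f))) stop("missing input: ", fp_in(f))
  genome <- Biostrings::readDNAStringSet(fp_in("genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  chrom_sizes <- read_chrom_sizes(fp_in("chrom.sizes"))
  save_stage <- function(stage, inputs, outputs) {
    manifest[[stage]] <<- list(inputs = hash_files(inputs),
                               outputs = as.list(outputs))
    jsonlite::write_json(manifest, stage_manifest_path(outd),
                         auto_unbox = TRUE)
  }

  ## ---- peaks stage ----
  peak_inputs <- c(peak_files, fp_in("coverage.bedGraph"),
                   fp_in("exons.gff3"), fp_in("chrom.sizes"),
                   fp_in("genome.fa"))
  summary_path <- fp_out("dataset_summary.tsv")
  if (stage_fresh(manifest, "peaks", peak_inputs, summary_path, force)) {
    message("peaks: unchanged, skipped")
    skipped <- c(skipped, "peaks")
    datasets <- readRDS(fp_out("datasets.rds"))
  } else {
    message("peaks: filtering and pooling ", length(peak_files), " file(s)")
    exons <- read_exons_gff3(fp_in("exons.gff3"))
    track <- read_bedgraph(fp_in("coverage.bedGraph"), chrom_sizes)
    calls <- lapply(peak_files, function(f) {
      nm <- sub("^peaks_(.*)\\.bed$", "\\1", basename(f))
      parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
      read_peak_calls(f, sample_id = nm, cell_type = parts[1],
                      hist_mod = parts[2], fc_col = 5, q_col = 6,
                      q_scale = "identity")
    })
    calls <- do.call(rbind, calls)
    kept <- filter_peaks(calls, config$min_fc, config$max_q)
    message("peaks: fold-change/q filter removed ",
            nrow(calls) - nrow(kept), " of ", nrow(calls), " calls")
    n0 <- nrow(kept)
    kept <- rna_active_filter(kept, track, config$min_mean_depth)
    message("peaks: RNA gate removed ", n0 - nrow(kept), " calls")
    combos <- unique(kept[, c("cell_type", "hist_mod")])
    datasets <- lapply(seq_len(nrow(combos)), function(i) {
      sel <- kept$cell_type == combos$cell_type[i] &
        kept$hist_mod == combos$hist_mod[i]
      pool_and_clean(kept[sel, ], exons, chrom_sizes,
                     min_len = config$min_len, flank = config$flank_peaks)
    })
    saveRDS(datasets, fp_out("datasets.rds"))
    for (d in datasets)
      write_bed(d$regions, fp_out(sprintf("regions_%s.bed", dataset_id(d))))
    utils::write.table(dataset_summary(datasets), summary_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    save_stage("peaks", peak_inputs, summary_path)
  }

  ## ---- pseudostates stage ----
  ps_path <- fp_out("dataset_summary_all.tsv")
  if (stage_fresh(manifest, "pseudostates", peak_inputs, ps_path, force)) {
    message("pseudostates: unchanged, skipped")
    skipped <- c(skipped, "pseudostates")
    datasets <- readRDS(fp_out("datasets_all.rds"))
  } else {
    ps <- build_pseudostates(
      datasets, pseudostate_definitions(config$pseudostates))
    ps <- Filter(function(d) length(d$regions) > 0, ps)
    message("pseudostates: ", length(ps), " built")
    datasets <- c(datasets, ps)
    saveRDS(datasets, fp_out("datasets_all.rds"))
    utils::write.table(dataset_summary(datasets), ps_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    save_stage("pseudostates", peak_inputs, ps_path)
  }

  ## ---- discovery stage ----
  motifs_path <- fp_out("motifs.meme")
  if (stage_fresh(manifest, "discover", peak_inputs, motifs_path, force)) {
    message("discover: unchanged, skipped")
    skipped <- c(skipped, "discover")
    motifs <- readRDS(fp_out("motifs.rds"))
    bgs <- readRDS(fp_out("backgrounds.rds"))
  } else {
    motifs <- list(); bgs <- list()
    for (d in datasets) {
      id <- dataset_id(d)
      seqs <- extract_sequences(d, genome)
      if (length(seqs) < 10 || sum(Biostrings::width(seqs)) < 200) {
        message("discover: ", id, " has too little sequence, skipped")
        next
      }
      sub <- subsample_sequences(as.character(seqs), config$subsample,
                                 seed = config$seed)
      bg1 <- fit_background(sub, order = 1)
      found <- discover_motifs(sub, bg1, wmin = config$wmin,
                               wmax = config$wmax,
                               nmotifs = config$nmotifs,
                               seed = config$seed, n_null = config$n_null,
                               source_dataset = id)
      for (k in seq_along(found))
        found[[k]]$id <- sprintf("%s.m%d", id, k)
      message("discover: ", id, ": ", length(found), " motif(s)")
      motifs[[id]] <- found
      bgs[[id]] <- fit_background(sub, order = 0)
    }
    saveRDS(motifs, fp_out("motifs.rds"))
    saveRDS(bgs, fp_out("backgrounds.rds"))
    write_meme(unlist(motifs, recursive = FALSE), motifs_path)
    rep <- do.call(rbind, lapply(names(motifs), function(id)
      data.frame(dataset = id,
                 motif = vapply(motifs[[id]], `[[`, "", "id"),
                 width = vapply(motifs[[id]], `[[`, 1L, "width"),
                 nsites = vapply(motifs[[id]], `[[`, 1, "nsites"),
                 evalue = vapply(motifs[[id]], `[[`, 1, "evalue"))))
    utils::write.table(rep, fp_out("motif_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    save_stage("discover", peak_inputs, motifs_path)
  }

  ## ---- scan stage ----
  scan_inputs <- c(peak_inputs, fp_in("variants.vcf"))
  scan_path <- fp_out("scan.tsv")
  if (stage_fresh(manifest, "scan", scan_inputs, scan_path, force)) {
    message("scan: unchanged, skipped")
    skipped <- c(skipped, "scan")
    scan <- utils::read.table(scan_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  } else {
    variants <- read_variants_vcf(fp_in("variants.vcf"))
    pairs <- lapply(seq_len(nrow(variants)), function(i)
      extract_allele_sequences(variants[i, ], genome,
                               flank = config$flank_variant))
    scan <- scan_variants(pairs, motifs, bgs, alpha = config$alpha)
    message("scan: ", nrow(scan), " variant x motif pairs")
    utils::write.table(scan, scan_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    save_stage("scan", scan_inputs, scan_path)
  }

  ## ---- ediff stage ----
  ediff_path <- fp_out("ediff_pairs.tsv")
  table_path <- fp_out("results_table.tsv")
  if (stage_fresh(manifest, "ediff", scan_inputs,
                  c(ediff_path, table_path), force)) {
    message("ediff: unchanged, skipped")
    skipped <- c(skipped, "ediff")
    ed <- utils::read.table(ediff_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    res <- utils::read.table(table_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  } else {
    ed <- suppressWarnings(
      ediff_by_dataset(scan, alpha = config$alpha,
                       eligibility_p = config$eligibility_p))
    res <- results_table(ed)
    message("ediff: ", sum(ed$pass_sc), " pair(s) pass on score, ",
            sum(ed$pass_p), " on p-value")
    utils::write.table(ed, ediff_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_results(res, table_path)
    save_stage("ediff", scan_inputs, c(ediff_path, table_path))
  }

  ## ---- affinity stage ----
  tf_lib <- config$tf_library
  if (is.null(tf_lib) && file.exists(fp_in("planted_motifs.meme")))
    tf_lib <- fp_in("planted_motifs.meme")
  affinity <- NULL
  if (isFALSE(config$run_affinity)) tf_lib <- NULL
  if (!is.null(tf_lib)) {
    aff_inputs <- c(tf_lib, fp_in("variants.vcf"), fp_in("genome.fa"))
    aff_path <- fp_out("affinity.tsv")
    if (stage_fresh(manifest, "affinity", aff_inputs, aff_path, force)) {
      message("affinity: unchanged, skipped")
      skipped <- c(skipped, "affinity")
      affinity <- utils::read.table(aff_path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
    } else {
      tf_motifs <- if (grepl("\\.meme$", tf_lib)) read_meme(tf_lib)
      else read_jaspar(tf_lib)
      variants <- read_variants_vcf(fp_in("variants.vcf"))
      pairs <- lapply(seq_len(nrow(variants)), function(i)
        extract_allele_sequences(variants[i, ], genome,
                                 flank = config$flank_variant))
      bg0 <- fit_background(as.character(genome), order = 0)
      affinity <- trap_scan(pairs, tf_motifs, bg0,
                            n_null = config$affinity_n_null,
                            seed = config$seed)
      affinity <- rank_allelic_differences(affinity)
      message("affinity: ", nrow(affinity), " variant x TF pairs")
      utils::write.table(affinity, aff_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      save_stage("affinity", aff_inputs, aff_path)
    }
  } else message("affinity: no TF library, stage skipped")

  invisible(list(datasets = datasets, motifs = motifs, scan = scan,
                 ediff = ed, results = res, affinity = affinity,
                 skipped = skipped))
}
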