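## Peak processing: per-sample histone peak calls -> per-dataset active
## region sets and pseudostates. A "dataset" is one cell type x histone
## mark (or pseudostate) combination, peaks pooled over individuals.

#' Validate a peak-call table
#'
#' Peak calls are plain data.frames with columns \code{chrom},
#' \code{start}, \code{end} (0-based half-open), \code{fold_change},
#' \code{q_value}, \code{sample_id}, \code{cell_type}, \code{hist_mod}.
#'
#' @param peaks data.frame of peak calls.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_peaks <- function(peaks) {
  need <- c("chrom", "start", "end", "fold_change", "q_value",
            "sample_id", "cell_type", "hist_mod")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak table missing column(s): ", paste(miss, collapse = ", "))
  if (any(peaks$fold_change < 0)) stop("fold_change must be >= 0")
  if (any(peaks$q_value < 0 | peaks$q_value > 1))
    stop("q_value must be in [0, 1]")
  if (any(peaks$end <= peaks$start | peaks$start < 0))
    stop("peak intervals must satisfy 0 <= start < end")
  peaks
}

#' Read per-sample peak calls from a BED-like file
#'
#' Tab-separated, 0-based half-open. Column indices for the enrichment
#' fold change and the q-value are configurable; MACS2 narrowPeak is the
#' default layout (column 7 = fold change, column 9 = -log10 q, converted
#' back to a probability on read).
#'
#' @param path peak file; gzip transparent.
#' @param sample_id,cell_type,hist_mod labels attached to every record.
#' @param fc_col,q_col 1-based column indices (defaults 7 and 9).
#' @param q_scale \code{"neglog10"} (narrowPeak) or \code{"identity"}.
#' @return validated peak-call data.frame.
#' @export
read_peak_calls <- function(path, sample_id, cell_type, hist_mod,
                            fc_col = 7, q_col = 9,
                            q_scale = c("neglog10", "identity")) {
  q_scale <- match.arg(q_scale)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < max(fc_col, q_col))
    stop("peak file has fewer columns than fc_col/q_col: ", path)
  q <- as.numeric(df[[q_col]])
  if (q_scale == "neglog10") q <- 10^(-q)
  validate_peaks(data.frame(
    chrom = as.character(df[[1]]), start = df[[2]], end = df[[3]],
    fold_change = as.numeric(df[[fc_col]]), q_value = q,
    sample_id = sample_id, cell_type = cell_type, hist_mod = hist_mod,
    stringsAsFactors = FALSE))
}

#' Filter peaks on enrichment and significance
#'
#' Retains peaks with \code{fold_change >= min_fc} (inclusive) and
#' \code{q_value < max_q} (strict), the default thresholds being fold
#' change >= 3 and q < 1e-4.
#'
#' @param peaks peak-call data.frame.
#' @param min_fc minimum fold change (ratio), inclusive.
#' @param max_q q-value bound, exclusive.
#' @return the retained subset.
#' @export
filter_peaks <- function(peaks, min_fc = 3, max_q = 1e-4) {
  validate_peaks(peaks)
  peaks[peaks$fold_change >= min_fc & peaks$q_value < max_q, , drop = FALSE]
}

#' Keep peaks with transcriptional evidence
#'
#' Retains peaks whose mean RNA-seq depth over the peak length is at least
#' \code{min_mean} (inclusive), enriching for transcriptionally active
#' regions. Peaks on chromosomes absent from the track are treated as
#' depth 0 and dropped (with a message).
#'
#' @param peaks peak-call data.frame.
#' @param track a \code{coverage_track} of RNA-seq depth.
#' @param min_mean minimum mean depth (default 0.001).
#' @param uncovered passed to \code{\link{mean_depth}}.
#' @return the retained subset.
#' @export
rna_active_filter <- function(peaks, track, min_mean = 0.001,
                              uncovered = "zero") {
  validate_peaks(peaks)
  if (nrow(peaks) == 0) return(peaks)
  absent <- !peaks$chrom %in% names(track$depth)
  if (any(absent))
    message(sum(absent), " peak(s) on chromosomes absent from the ",
            "coverage track; treated as depth 0")
  md <- vapply(seq_len(nrow(peaks)), function(i) {
    iv <- interval_set(peaks$chrom[i], peaks$start[i], peaks$end[i])
    mean_depth(track, iv, uncovered = uncovered)
  }, numeric(1))
  peaks[md >= min_mean, , drop = FALSE]
}

#' Pool replicate peaks into one cleaned dataset
#'
#' Applies, in order: concatenation of all samples' peaks and merge;
#' exclusion of intervals shorter than \code{min_len} bases; symmetric
#' padding by \code{flank} bases (clipped to chromosome ends) and
#' re-merge; exclusion of exonic bases. Fragments created by the exon
#' subtraction are kept regardless of length (the length filter is applied
#' once, before padding).
#'
#' @param peaks peak-call data.frame sharing one (cell_type, hist_mod).
#' @param exons normalized \code{GRanges} of exonic bases.
#' @param chrom_sizes named chromosome lengths.
#' @param min_len minimum peak length in bases (default 6).
#' @param flank border allowance in bases (default 20).
#' @return a \code{peak_dataset}: list with \code{cell_type},
#'   \code{hist_mod}, \code{regions} (normalized \code{GRanges}),
#'   \code{n_samples}.
#' @export
pool_and_clean <- function(peaks, exons, chrom_sizes,
                           min_len = 6, flank = 20) {
  validate_peaks(peaks)
  ct <- unique(peaks$cell_type)
  hm <- unique(peaks$hist_mod)
  if (length(ct) > 1 || length(hm) > 1)
    stop("pool_and_clean() expects one (cell_type, hist_mod) combination")
  n_samples <- length(unique(peaks$sample_id))
  if (nrow(peaks) == 0) {
    message("empty peak set for ", ct, " / ", hm)
    regions <- GRanges()
  } else {
    pooled <- merge_intervals(
      interval_set(peaks$chrom, peaks$start, peaks$end))
    pooled <- pooled[width(pooled) >= min_len]
    padded <- pad_intervals(pooled, flank, chrom_sizes)
    regions <- subtract_intervals(padded, exons)
    if (length(regions) == 0)
      message("no regions left after cleaning for ", ct, " / ", hm)
  }
  structure(list(cell_type = if (length(ct)) ct else NA_character_,
                 hist_mod = if (length(hm)) hm else NA_character_,
                 regions = regions,
                 n_samples = max(n_samples, 1L)),
            class = "peak_dataset")
}

#' @export
print.peak_dataset <- function(x, ...) {
  cat(sprintf("<peak_dataset> %s / %s: %d regions, %d sample(s)\n",
              x$cell_type, x$hist_mod, length(x$regions), x$n_samples))
  invisible(x)
}

#' Canonical identifier of a dataset
#' @param dataset a \code{peak_dataset}.
#' @return character, "cell_type.hist_mod".
#' @export
dataset_id <- function(dataset) {
  paste(dataset$cell_type, dataset$hist_mod, sep = ".")
}

#' Pseudostate definitions
#'
#' Chromatin pseudostates stand in for full chromatin states when each
#' individual contributes only some histone marks: each is the base-wise
#' intersection of pooled peak sets. The shipped table follows the
#' ChromHMM-style numbering: 7 = H3K4me1 & H3K36me3 (transcribed
#' enhancer), 9 = H3K4me1 & H3K27ac (active enhancer), 10 = H3K4me3 &
#' H3K27ac & H3K4me1 (distal active promoter), 11 = H3K4me3 & H3K4me1,
#' 12 = H3K4me3 & H3K27ac.
#'
#' @param ids subset of c(7, 9, 10, 11, 12).
#' @return named list: state id -> character vector of member marks.
#' @export
pseudostate_definitions <- function(ids = c(7, 9, 10, 11, 12)) {
  all <- list(`7` = c("H3K4me1", "H3K36me3"),
              `9` = c("H3K4me1", "H3K27ac"),
              `10` = c("H3K4me3", "H3K27ac", "H3K4me1"),
              `11` = c("H3K4me3", "H3K4me1"),
              `12` = c("H3K4me3", "H3K27ac"))
  bad <- setdiff(as.character(ids), names(all))
  if (length(bad))
    stop("unknown pseudostate id(s): ", paste(bad, collapse = ", "))
  all[as.character(ids)]
}

#' Build pseudostate datasets by intersecting member marks
#'
#' For each cell type and each pseudostate whose member histone-mark
#' datasets all exist for that cell type, emits one dataset whose region
#' set is the base-wise intersection of the members. Pseudostates with a
#' missing member are skipped (with a message). Mark names match
#' case-insensitively (H3K27ac / H3K27Ac).
#'
#' @param datasets list of \code{peak_dataset} (the pooled, cleaned
#'   histone-mark sets).
#' @param definitions as from \code{\link{pseudostate_definitions}}.
#' @return list of \code{peak_dataset} with \code{hist_mod} set to
#'   \code{"pseudostate<k>"}; \code{n_samples} is the minimum over members.
#' @export
build_pseudostates <- function(datasets,
                               definitions = pseudostate_definitions()) {
  if (is.null(names(definitions)) ||
      !all(names(definitions) %in% c("7", "9", "10", "11", "12")))
    stop("pseudostate ids must be in {7, 9, 10, 11, 12}")
  if (any(lengths(definitions) < 2))
    stop("each pseudostate needs >= 2 member marks")
  ct_of <- vapply(datasets, `[[`, "", "cell_type")
  hm_of <- tolower(vapply(datasets, `[[`, "", "hist_mod"))
  out <- list()
  for (ct in unique(ct_of)) {
    for (sid in names(definitions)) {
      members <- tolower(definitions[[sid]])
      idx <- vapply(members, function(m)
        which(ct_of == ct & hm_of == m)[1], integer(1))
      if (anyNA(idx)) {
        message("pseudostate ", sid, " skipped for ", ct,
                " (missing member mark)")
        next
      }
      sets <- lapply(datasets[idx], `[[`, "regions")
      out[[length(out) + 1L]] <- structure(list(
        cell_type = ct,
        hist_mod = paste0("pseudostate", sid),
        regions = intersect_sets(sets),
        n_samples = min(vapply(datasets[idx], `[[`, 1L, "n_samples"))),
        class = "peak_dataset")
    }
  }
  out
}

#' Extract region sequences from a genome
#'
#' One uppercase DNA sequence per interval, named \code{chrom:start-end}
#' (0-based half-open). Ambiguity codes are preserved as N.
#'
#' @param dataset a \code{peak_dataset} or a \code{GRanges}.
#' @param genome a \code{Biostrings::DNAStringSet} keyed by chromosome.
#' @return \code{DNAStringSet}.
#' @export
extract_sequences <- function(dataset, genome) {
  gr <- if (is(dataset, "GRanges")) dataset else dataset$regions
  if (length(gr) == 0) return(Biostrings::DNAStringSet())
  chr <- as.character(seqnames(gr))
  miss <- setdiff(unique(chr), names(genome))
  if (length(miss))
    stop("genome lacks chromosome(s): ", paste(miss, collapse = ", "))
  too_far <- end(gr) > Biostrings::width(genome)[match(chr, names(genome))]
  if (any(too_far)) {
    i <- which(too_far)[1]
    stop(sprintf("interval beyond chromosome end: %s:%d-%d",
                 chr[i], start(gr)[i] - 1L, end(gr)[i]))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(
    Biostrings::subseq(genome[chr], start = start(gr), end = end(gr)))))
  names(seqs) <- sprintf("%s:%d-%d", chr, start(gr) - 1L, end(gr))
  seqs
}

#' Summary table of datasets (samples and peak counts)
#'
#' @param datasets list of \code{peak_dataset}.
#' @return data.frame with dataset, cell_type, hist_mod, n_samples,
#'   n_peaks.
#' @export
dataset_summary <- function(datasets) {
  data.frame(
    dataset = vapply(datasets, dataset_id, ""),
    cell_type = vapply(datasets, `[[`, "", "cell_type"),
    hist_mod = vapply(datasets, `[[`, "", "hist_mod"),
    n_samples = vapply(datasets, `[[`, 1L, "n_samples"),
    n_peaks = vapply(datasets, function(d) length(d$regions), 1L),
    stringsAsFactors = FALSE)
}
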