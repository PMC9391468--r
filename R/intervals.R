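#' @import methods
#' @importFrom GenomicRanges GRanges reduce intersect setdiff coverage start end width seqnames strand mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors Rle runValue runLength
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
NULL

## All public coordinates in this package are 0-based half-open (BED
## convention). GRanges is the in-memory container (1-based closed); the
## two constructors below are the only places the +1 shift happens.

#' Construct a genomic interval set
#'
#' Builds a \code{GRanges} from 0-based half-open coordinates (BED
#' convention), validating each record. This is the common currency of the
#' peak, pseudostate and sequence-extraction steps.
#'
#' @param chrom character vector of sequence names (non-empty strings).
#' @param start integer vector, 0-based inclusive start offsets (>= 0).
#' @param end integer vector, exclusive end offsets (> start).
#' @param ... further equal-length vectors stored as metadata columns.
#' @return A \code{GRanges} object.
#' @export
interval_set <- function(chrom, start, end, ...) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    stop("chrom, start and end must have equal length")
  bad <- which(is.na(chrom) | !nzchar(chrom) | is.na(start) | is.na(end) |
                 start < 0 | end <= start)
  if (length(bad))
    stop(sprintf("malformed interval at record %d: %s:%s-%s",
                 bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]]))
  gr <- GRanges(chrom, IRanges(start = start + 1, end = end))
  extra <- list(...)
  if (length(extra)) mcols(gr) <- S4Vectors::DataFrame(extra)
  gr
}

#' Interval set as a 0-based data frame
#'
#' @param gr a \code{GRanges}.
#' @return data.frame with columns chrom, start (0-based), end (exclusive)
#'   plus any metadata columns.
#' @export
interval_frame <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L,
                   end = end(gr),
                   stringsAsFactors = FALSE)
  m <- as.data.frame(mcols(gr))
  if (ncol(m)) df <- cbind(df, m)
  rownames(df) <- NULL
  df
}

#' Merge an interval set into its minimal sorted union
#'
#' Overlapping and bookended (end == next start) intervals are merged, so
#' the result covers exactly the union of the input bases. Metadata columns
#' are dropped.
#'
#' @param set a \code{GRanges}.
#' @return normalized \code{GRanges}: sorted, pairwise disjoint per chrom.
#' @export
merge_intervals <- function(set) {
  stopifnot(is(set, "GRanges"))
  sort(reduce(set, ignore.strand = TRUE))
}

#' Intersect two or more interval sets base-wise
#'
#' Returns the bases present in every input set, the operation used to
#' define chromatin pseudostates from pooled histone-mark peak sets.
#'
#' @param sets list of \code{GRanges} (length >= 2).
#' @return normalized \code{GRanges} of the common bases.
#' @export
intersect_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2)
    stop("intersect_sets() needs a list of at least 2 interval sets")
  out <- Reduce(function(a, b)
    GenomicRanges::intersect(a, b, ignore.strand = TRUE), sets)
  sort(reduce(out))
}

#' Subtract one interval set from another
#'
#' Bases in \code{a} but not in \code{b}; intervals may split (used to
#' excise exonic sequence from active regions).
#'
#' @param a,b \code{GRanges}.
#' @return normalized \code{GRanges}.
#' @export
subtract_intervals <- function(a, b) {
  sort(reduce(GenomicRanges::setdiff(a, b, ignore.strand = TRUE)))
}

#' Pad intervals by a symmetric flank, clipped to chromosome bounds
#'
#' Extends every interval \code{flank} bases on both sides (the 20 bp
#' border allowance for motifs straddling peak edges), clips to
#' \code{[0, chrom length]} and re-normalizes.
#'
#' @param set a \code{GRanges}.
#' @param flank non-negative integer, bases added each side.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return normalized \code{GRanges}.
#' @export
pad_intervals <- function(set, flank, chrom_sizes) {
  stopifnot(flank >= 0)
  chr <- as.character(seqnames(set))
  unknown <- setdiff(unique(chr), names(chrom_sizes))
  if (length(unknown))
    stop("chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  if (length(set) == 0) return(merge_intervals(set))
  s0 <- pmax(start(set) - 1L - flank, 0)
  e0 <- pmin(end(set) + flank, unname(chrom_sizes[chr]))
  merge_intervals(interval_set(chr, s0, e0))
}

## ---- coverage tracks -------------------------------------------------

#' Build a coverage track from interval runs
#'
#' A coverage track holds per-base depth as run-length encodings, one per
#' chromosome, in the sparse bedGraph convention: bases not covered by any
#' run have depth 0 but are remembered as "uncovered" so the mean can
#' optionally be restricted to covered bases.
#'
#' @param gr \code{GRanges} with a numeric \code{score} metadata column
#'   (depth per base over the range). Runs must not overlap.
#' @param chrom_sizes optional named lengths; defaults to the furthest end
#'   seen per chromosome.
#' @return object of class \code{coverage_track}.
#' @export
coverage_track <- function(gr, chrom_sizes = NULL) {
  stopifnot(is(gr, "GRanges"), "score" %in% names(mcols(gr)))
  if (any(gr$score < 0)) stop("coverage depths must be >= 0")
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(end(gr), as.character(seqnames(gr)), max)
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  }
  gr <- sort(gr)
  seqlevels(gr) <- names(chrom_sizes)
  seqlengths(gr) <- chrom_sizes
  cov <- coverage(gr, weight = gr$score)
  covered <- coverage(gr) > 0
  structure(list(depth = cov, covered = covered, chrom_sizes = chrom_sizes),
            class = "coverage_track")
}

#' Mean per-base depth of a track over one interval
#'
#' Arithmetic mean of depth over all \code{end - start} bases of the
#' interval. Bases absent from the track count as depth 0 by default
#' (\code{uncovered = "zero"}); \code{uncovered = "ignore"} averages over
#' covered bases only.
#'
#' @param track a \code{coverage_track}.
#' @param iv a length-1 \code{GRanges}.
#' @param uncovered "zero" (default) or "ignore".
#' @return numeric mean depth (0 when the chromosome is absent, or when
#'   no base is covered under \code{"ignore"}).
#' @export
mean_depth <- function(track, iv, uncovered = c("zero", "ignore")) {
  uncovered <- match.arg(uncovered)
  stopifnot(is(track, "coverage_track"), is(iv, "GRanges"), length(iv) == 1)
  if (width(iv) < 1) stop("empty interval")
  chr <- as.character(seqnames(iv))
  if (!chr %in% names(track$depth)) return(0)
  len <- track$chrom_sizes[[chr]]
  i1 <- max(start(iv), 1L)
  i2 <- min(end(iv), len)
  if (i2 < i1) return(0)
  d <- track$depth[[chr]][i1:i2]
  if (uncovered == "zero") {
    sum(d) / width(iv)
  } else {
    m <- track$covered[[chr]][i1:i2]
    nc <- sum(m)
    if (nc == 0) return(0)
    sum(d[m]) / nc
  }
}

## ---- readers / writers ----------------------------------------------

#' Read a BED file (3+ columns) as an interval set
#'
#' Tab-separated, 0-based half-open; gzip transparent. Columns beyond the
#' first three are kept as metadata columns (name, score, strand when
#' present; further columns as \code{V7}, \code{V8}, ...).
#'
#' @param path file path.
#' @return \code{GRanges}.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (ncol(df) < 3) stop("BED needs at least 3 columns: ", path)
  known <- c("chrom", "start", "end", "name", "score", "strand")
  names(df)[seq_len(min(ncol(df), 6))] <- known[seq_len(min(ncol(df), 6))]
  do.call(interval_set, c(list(df$chrom, df$start, df$end),
                          df[-(1:3)]))
}

#' Write an interval set as BED
#'
#' @param gr \code{GRanges}; metadata columns are appended after chrom,
#'   start, end in their stored order.
#' @param path output path (".gz" suffix writes gzip).
#' @export
write_bed <- function(gr, path) {
  df <- interval_frame(gr)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column bedGraph as a coverage track
#'
#' @param path bedGraph path (chrom, start, end, depth); gzip transparent.
#' @param chrom_sizes optional named lengths (recommended, so intervals
#'   beyond the last covered base still average correctly).
#' @return \code{coverage_track}.
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) != 4) stop("bedGraph needs exactly 4 columns: ", path)
  gr <- interval_set(df[[1]], df[[2]], df[[3]], score = as.numeric(df[[4]]))
  coverage_track(gr, chrom_sizes)
}

#' Write a coverage track (or scored intervals) as bedGraph
#' @param gr \code{GRanges} with a \code{score} column.
#' @param path output path.
#' @export
write_bedgraph <- function(gr, path) {
  df <- interval_frame(gr)[, c("chrom", "start", "end", "score")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read exon features from a GFF3 file
#'
#' Imports the file (1-based inclusive coordinates, converted on read) and
#' keeps features of type \code{exon} only, merged into a normalized set.
#'
#' @param path GFF3 path; gzip transparent.
#' @return normalized \code{GRanges} of exonic bases.
#' @export
read_exons_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  merge_intervals(gr[gr$type == "exon"])
}

#' Read a two-column chrom-sizes file
#' @param path text path: name TAB length.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), as.character(df[[1]]))
}
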