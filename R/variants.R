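## Variants (SNV and indel) and REF/ALT flanking-sequence construction.
## Variants are plain data.frames: id, chrom, pos (0-based offset of the
## first affected base), ref, alt (possibly empty strings after
## normalization; a pure insertion has ref == "").

#' Normalize one variant record to its minimal representation
#'
#' Reconciles VCF anchored-base records with dash-notation ("-/G")
#' records: shared leading and trailing bases are trimmed (the position
#' advancing over trimmed leading bases), so a deletion ends with an
#' empty \code{alt} and an insertion with an empty \code{ref}.
#'
#' @param chrom chromosome name.
#' @param pos position of the record: 1-based for \code{coords = "one"}
#'   (VCF), 0-based for \code{coords = "zero"}.
#' @param ref,alt allele strings; \code{"-"} or \code{""} denote empty.
#' @param id variant identifier.
#' @param coords coordinate convention of \code{pos}.
#' @return one-row data.frame: id, chrom, pos (0-based first affected
#'   base), ref, alt.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, id = NA_character_,
                              coords = c("one", "zero")) {
  coords <- match.arg(coords)
  ref <- toupper(sub("^-$", "", ref))
  alt <- toupper(sub("^-$", "", alt))
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("non-ACGT allele in variant ", id, ": ", ref, "/", alt)
  pos0 <- if (coords == "one") as.numeric(pos) - 1 else as.numeric(pos)
  ## trim shared trailing bases
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  ## trim shared leading bases, advancing the position
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos0 <- pos0 + 1
  }
  if (!nchar(ref) && !nchar(alt))
    stop("null variant (REF == ALT) for ", id)
  data.frame(id = as.character(id), chrom = as.character(chrom),
             pos = pos0, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Read variants from a VCF (CHROM POS ID REF ALT subset)
#'
#' Parses the first five columns of VCF 4.x body lines (multi-allelic
#' records are split on comma) and normalizes each record.
#'
#' @param path VCF path; gzip transparent.
#' @return variant data.frame (see \code{\link{normalize_variant}}).
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) return(empty_variants())
  rows <- lapply(body, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    do.call(rbind, lapply(alts, function(a)
      normalize_variant(f[1], as.numeric(f[2]), f[4], a,
                        id = f[3], coords = "one")))
  })
  do.call(rbind, rows)
}

#' Read variants from a dash-notation table
#'
#' Tab-separated with header: id, chrom, pos (0-based first affected
#' base), ref, alt; \code{"-"} marks an empty allele.
#'
#' @param path file path.
#' @return variant data.frame.
#' @export
read_variants_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(id = "character",
                                         chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    normalize_variant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i],
                      id = df$id[i], coords = "zero")))
}

empty_variants <- function() {
  data.frame(id = character(0), chrom = character(0), pos = numeric(0),
             ref = character(0), alt = character(0),
             stringsAsFactors = FALSE)
}

#' Write variants as a minimal VCF
#'
#' Indels are written anchored on the preceding reference base, SNVs as
#' is, so \code{\link{read_variants_vcf}} round-trips to the same
#' normalized records.
#'
#' @param variants variant data.frame (normalized, 0-based).
#' @param genome \code{DNAStringSet} supplying anchor bases.
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (nchar(v$ref) && nchar(v$alt)) {        # substitution
      pos1 <- v$pos + 1
      ref <- v$ref; alt <- v$alt
    } else {                                    # indel: anchor base
      anchor <- as.character(Biostrings::subseq(genome[[v$chrom]],
                                                v$pos, v$pos))
      pos1 <- v$pos                             # anchor is 0-based pos-1
      ref <- paste0(anchor, v$ref)
      alt <- paste0(anchor, v$alt)
    }
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       v$chrom, as.integer(pos1), v$id, ref, alt), con)
  }
  invisible(path)
}

#' Build REF and ALT flanking sequences for one variant
#'
#' \code{seq_ref} is \code{flank} upstream bases + the REF allele +
#' \code{flank} downstream bases; \code{seq_alt} substitutes the ALT
#' allele between the identical flanks. Errors when the genome does not
#' carry the REF allele at the stated position.
#'
#' @param variant one-row variant data.frame (normalized, 0-based).
#' @param genome \code{DNAStringSet}.
#' @param flank flank length in bases (default 30).
#' @return object of class \code{allele_pair}: variant, seq_ref,
#'   seq_alt, flank.
#' @export
extract_allele_sequences <- function(variant, genome, flank = 30) {
  stopifnot(nrow(variant) == 1)
  chr <- variant$chrom
  if (!chr %in% names(genome)) stop("genome lacks chromosome ", chr)
  g <- genome[[chr]]
  pos <- variant$pos                      # 0-based
  nref <- nchar(variant$ref)
  if (pos - flank < 0 || pos + nref + flank > length(g))
    stop("variant ", variant$id, " too close to a chromosome end for a ",
         flank, " bp flank")
  if (nref > 0) {
    obs <- toupper(as.character(Biostrings::subseq(g, pos + 1, pos + nref)))
    if (obs != variant$ref)
      stop("reference mismatch for ", variant$id, ": genome has ", obs,
           ", record says ", variant$ref)
  }
  up <- toupper(as.character(Biostrings::subseq(g, pos - flank + 1, pos)))
  down <- toupper(as.character(
    Biostrings::subseq(g, pos + nref + 1, pos + nref + flank)))
  structure(list(variant = variant,
                 seq_ref = paste0(up, variant$ref, down),
                 seq_alt = paste0(up, variant$alt, down),
                 flank = flank),
            class = "allele_pair")
}

#' @export
print.allele_pair <- function(x, ...) {
  cat(sprintf("<allele_pair> %s %s:%d %s/%s  ref %d bp / alt %d bp\n",
              x$variant$id, x$variant$chrom, x$variant$pos,
              ifelse(nzchar(x$variant$ref), x$variant$ref, "-"),
              ifelse(nzchar(x$variant$alt), x$variant$alt, "-"),
              nchar(x$seq_ref), nchar(x$seq_alt)))
  invisible(x)
}
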