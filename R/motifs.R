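DNA_BASES <- c("A", "C", "G", "T")

## integer encoding: A=1 C=2 G=3 T=4, anything else NA (treated as N)

encode_seq <- function(s) {
  x <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
  x
}

decode_seq <- function(x) {
  out <- rep("N", length(x))
  ok <- !is.na(x)
  out[ok] <- DNA_BASES[x[ok]]
  paste(out, collapse = "")
}

revcomp_int <- function(x) rev(5L - x)

#' Construct a position probability matrix (PWM) object
#'
#' @param probs 4 x width numeric matrix, rows A,C,G,T, columns summing
#'   to 1 (within 1e-9); all entries must be > 0 (apply a pseudocount
#'   before construction).
#' @param id motif identifier.
#' @param nsites number of sites contributing to the matrix.
#' @param evalue discovery significance (NA until assigned).
#' @param source_dataset dataset the motif was discovered in.
#' @return object of class \code{pwm}.
#' @export
pwm <- function(probs, id = "motif", nsites = NA_integer_,
                evalue = NA_real_, source_dataset = NA_character_) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("probs must have 4 rows (A, C, G, T)")
  w <- ncol(probs)
  if (w < 1) stop("pwm must have at least one column")
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("each pwm column must sum to 1")
  if (any(probs <= 0))
    stop("pwm entries must be > 0; apply a pseudocount first")
  rownames(probs) <- DNA_BASES
  structure(list(probs = probs, width = w, id = id, nsites = nsites,
                 evalue = evalue, source_dataset = source_dataset),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s width=%d nsites=%s evalue=%s consensus=%s\n",
              x$id, x$width, x$nsites, format(x$evalue, digits = 3),
              consensus_string(x)))
  invisible(x)
}

#' Consensus string of a PWM (most probable base per column)
#' @param pwm a \code{pwm}.
#' @return character string of length \code{width}.
#' @export
consensus_string <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Per-column information content of a PWM (bits, uniform reference)
#' @param pwm a \code{pwm}.
#' @return numeric vector, one value per column.
#' @export
pwm_information <- function(pwm) {
  apply(pwm$probs, 2, function(p) 2 + sum(p * log2(p)))
}

#' Reverse complement of a PWM
#' @param pwm a \code{pwm}.
#' @return a \code{pwm} for the opposite strand.
#' @export
reverse_complement_pwm <- function(pwm) {
  p <- pwm$probs[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(p) <- DNA_BASES
  out <- pwm
  out$probs <- p
  out
}

#' Build a PWM from aligned sites with a pseudocount
#'
#' @param sites character vector of equal-length DNA strings (ACGT only).
#' @param pseudocount added per cell before normalization (default 0.1).
#' @param ... passed to \code{\link{pwm}}.
#' @return a \code{pwm}; \code{nsites} set to \code{length(sites)}.
#' @export
pwm_from_sites <- function(sites, pseudocount = 0.1, ...) {
  if (!length(sites)) stop("no sites")
  m <- vapply(sites, encode_seq, integer(nchar(sites[1])))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(sites))
  w <- nrow(m)
  counts <- matrix(0, 4, w)
  for (j in seq_len(w))
    counts[, j] <- tabulate(m[j, ], nbins = 4)
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts + pseudocount), "/")
  pwm(probs, nsites = length(sites), ...)
}

## ---- MEME minimal text format ---------------------------------------

#' Write motifs in MEME minimal text format
#'
#' @param motifs list of \code{pwm}.
#' @param path output path.
#' @param bg_freqs optional length-4 background letter frequencies.
#' @export
write_meme <- function(motifs, path, bg_freqs = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, bg_freqs),
                     collapse = " "), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %s",
      m$width, if (is.na(m$nsites)) 0L else m$nsites,
      format(if (is.na(m$evalue)) 0 else m$evalue, digits = 4)), con)
    for (j in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$probs[, j]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' @param path input path.
#' @return list of \code{pwm}.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  lapply(starts, function(i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    j <- i
    while (!grepl("^letter-probability matrix", lines[j])) j <- j + 1
    hdr <- lines[j]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr))
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr)) else NA_integer_
    ev <- if (grepl("E=", hdr))
      as.numeric(sub(".*E=\\s*([0-9eE+.\\-]+).*", "\\1", hdr)) else NA_real_
    rows <- lines[(j + 1):(j + w)]
    probs <- vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4),
      USE.NAMES = FALSE)  # 4 x w
    probs <- probs + 1e-6
    probs <- sweep(probs, 2, colSums(probs), "/")
    pwm(probs, id = id, nsites = nsites, evalue = ev)
  })
}

#' Read motifs from JASPAR PFM text format
#'
#' Count matrices ("A [ 0 3 79 ... ]" rows under a ">ID name" header) are
#' normalized to probabilities with a pseudocount of 1 per cell.
#'
#' @param path input path.
#' @return list of \code{pwm}.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  lapply(starts, function(i) {
    id <- strsplit(sub("^>", "", trimws(lines[i])), "\\s+")[[1]][1]
    rows <- lines[i + 1:4]
    w <- length(strsplit(trimws(gsub("[][ACGTacgt]", " ", rows[1])),
                         "\\s+")[[1]])
    counts <- t(vapply(rows, function(r) {
      r <- gsub("[][ACGTacgt]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(w), USE.NAMES = FALSE))  # rows A,C,G,T -> 4 x w
    probs <- sweep(counts + 1, 2, colSums(counts + 1), "/")
    pwm(probs, id = id, nsites = round(sum(counts[, 1])))
  })
}

## ---- motif-motif comparison (tomtom role) ---------------------------

align_similarity <- function(q, t, min_overlap) {
  ## best Pearson correlation of aligned probability columns over all
  ## offsets; returns list(similarity, offset)
  wq <- ncol(q); wt <- ncol(t)
  best <- -Inf; best_off <- 0L
  for (off in seq(-(wq - min_overlap), wt - min_overlap)) {
    qi <- max(1, 1 - off):min(wq, wt - off)
    if (length(qi) < min_overlap) next
    ti <- qi + off
    r <- suppressWarnings(stats::cor(as.vector(q[, qi]), as.vector(t[, ti])))
    if (is.na(r)) next
    if (r > best) { best <- r; best_off <- off }
  }
  list(similarity = best, offset = best_off)
}

#' Compare a discovered motif against a motif library
#'
#' Simplified motif-to-motif similarity: for each library motif, the best
#' Pearson correlation of aligned probability columns over all offsets and
#' both orientations (overlap at least \code{max(4, floor(min(width)/2))}
#' columns); p-value from column permutations of the query; q-values by
#' Benjamini-Hochberg across the library.
#'
#' @param query a \code{pwm}.
#' @param library list of \code{pwm}.
#' @param n_perm number of column permutations for the null (default 1000).
#' @param seed RNG seed for the permutations.
#' @return data.frame: target, offset, orientation, similarity, p_value,
#'   q_value, sorted by p then target id.
#' @export
compare_motifs <- function(query, library, n_perm = 1000, seed = 1) {
  if (!length(library)) stop("empty motif library")
  score_one <- function(qp, tgt) {
    min_ov <- max(4, floor(min(ncol(qp), tgt$width) / 2))
    fwd <- align_similarity(qp, tgt$probs, min_ov)
    rcp <- reverse_complement_pwm(tgt)$probs
    rev <- align_similarity(qp, rcp, min_ov)
    if (fwd$similarity >= rev$similarity)
      c(sim = fwd$similarity, off = fwd$offset, orient = 1)
    else c(sim = rev$similarity, off = rev$offset, orient = -1)
  }
  obs <- lapply(library, function(t) score_one(query$probs, t))
  ## permutation null: max-over-library distribution would be too strict;
  ## null is per-target, permuting query columns
  old <- .Random.seed_exists()
  set.seed(seed)
  perms <- replicate(n_perm,
                     query$probs[, sample(ncol(query$probs)), drop = FALSE],
                     simplify = FALSE)
  p <- vapply(seq_along(library), function(k) {
    null_sims <- vapply(perms, function(qp)
      score_one(qp, library[[k]])[["sim"]], numeric(1))
    (1 + sum(null_sims >= obs[[k]][["sim"]])) / (n_perm + 1)
  }, numeric(1))
  restore_seed(old)
  out <- data.frame(
    target = vapply(library, `[[`, "", "id"),
    offset = vapply(obs, `[[`, 0, "off"),
    orientation = ifelse(vapply(obs, `[[`, 0, "orient") > 0,
                         "forward", "revcomp"),
    similarity = vapply(obs, `[[`, 0, "sim"),
    p_value = p, stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$target), ]
}

## save/restore the global RNG state so seeded helpers do not perturb
## the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
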