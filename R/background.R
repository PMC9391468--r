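## Background sequence models (order 0 and order 1) and the
## dinucleotide-preserving shuffle used for empirical motif nulls.

#' Fit a mono- or dinucleotide background model
#'
#' Maximum-likelihood model of the input sequences with a pseudocount of
#' 1 per count cell; both strands are pooled, so the model is
#' reverse-complement symmetric. Order 1 conditions each base on its
#' predecessor (capturing nucleotide and dimer biases such as CpG
#' depletion); order 0 is the plain letter-frequency model used for
#' scanning.
#'
#' @param seqs character vector or \code{DNAStringSet}; bases other than
#'   ACGT are ignored.
#' @param order 0 or 1.
#' @param pseudocount added to every count cell (default 1).
#' @return object of class \code{bg_model}: \code{order}, \code{freq}
#'   (length-4 marginal), and for order 1 \code{trans} (4 x 4 matrix,
#'   rows = preceding base, rows summing to 1).
#' @export
fit_background <- function(seqs, order = 1, pseudocount = 1) {
  stopifnot(order %in% c(0, 1))
  seqs <- as.character(seqs)
  if (!length(seqs) || sum(nchar(seqs)) < 100)
    stop("need at least 100 bases of sequence to fit a background")
  enc <- lapply(seqs, encode_seq)
  enc <- c(enc, lapply(enc, revcomp_int))
  mono <- rep(pseudocount, 4)
  di <- matrix(pseudocount, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (x in enc) {
    mono <- mono + tabulate(x, nbins = 4)
    if (order == 1 && length(x) >= 2) {
      a <- x[-length(x)]; b <- x[-1]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok))
        di <- di + matrix(tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16),
                          4, 4, byrow = TRUE)
    }
  }
  freq <- mono / sum(mono)
  names(freq) <- DNA_BASES
  out <- list(order = order, freq = freq)
  if (order == 1) out$trans <- sweep(di, 1, rowSums(di), "/")
  structure(out, class = "bg_model")
}

#' @export
print.bg_model <- function(x, ...) {
  cat(sprintf("<bg_model> order %d; freq: %s\n", x$order,
              paste(sprintf("%s=%.3f", DNA_BASES, x$freq), collapse = " ")))
  invisible(x)
}

#' Sample sequences from a background model
#'
#' @param bg a \code{bg_model}.
#' @param len sequence length (bases).
#' @param n number of sequences.
#' @return character vector of DNA strings.
#' @export
sample_background <- function(bg, len, n = 1) {
  stopifnot(is(bg, "bg_model"), len >= 1)
  vapply(seq_len(n), function(i) {
    x <- integer(len)
    x[1] <- sample.int(4, 1, prob = bg$freq)
    if (bg$order == 1 && len > 1) {
      for (j in 2:len) x[j] <- sample.int(4, 1, prob = bg$trans[x[j - 1], ])
    } else if (len > 1) {
      x[2:len] <- sample.int(4, len - 1, replace = TRUE, prob = bg$freq)
    }
    decode_seq(x)
  }, character(1))
}

#' Dinucleotide-preserving shuffle of a DNA sequence
#'
#' Altschul-Erickson shuffle: a uniform random Eulerian rearrangement of
#' the dinucleotide multigraph, so the shuffled sequence has exactly the
#' original's mono- and dinucleotide counts, first and last base. Used to
#' build empirical nulls that respect dimer composition.
#'
#' @param s DNA string (ACGT; other characters are dropped first).
#' @return shuffled DNA string.
#' @export
shuffle_dinucleotide <- function(s) {
  x <- encode_seq(s)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(decode_seq(x))
  ## edge lists: succ[[v]] = successors of base v in order
  succ <- split(x[-1], x[-n])
  verts <- as.integer(names(succ))
  last_v <- x[n]
  ## choose random terminal edges forming a tree into last_v
  for (attempt in 1:200) {
    last_edge <- vapply(verts, function(v) {
      if (v == last_v) return(NA_integer_)
      e <- succ[[as.character(v)]]
      e[sample.int(length(e), 1)]
    }, integer(1))
    names(last_edge) <- verts
    ## check every vertex reaches last_v via last edges
    ok <- all(vapply(verts, function(v) {
      seen <- integer(0)
      while (v != last_v) {
        if (v %in% seen || !as.character(v) %in% names(last_edge))
          return(FALSE)
        seen <- c(seen, v)
        v <- last_edge[[as.character(v)]]
        if (is.na(v)) return(FALSE)
      }
      TRUE
    }, logical(1)))
    if (ok) break
    if (attempt == 200) return(decode_seq(x))  # give up: identity
  }
  ## shuffle the remaining edges per vertex, append terminal edge last
  pool <- lapply(seq_along(verts), function(i) {
    v <- verts[i]
    e <- succ[[as.character(v)]]
    if (v != last_v) {
      drop_at <- match(last_edge[[as.character(v)]], e)
      e <- e[-drop_at]
    }
    e <- if (length(e)) e[sample.int(length(e))] else integer(0)
    if (v != last_v) e <- c(e, last_edge[[as.character(v)]])
    e
  })
  names(pool) <- as.character(verts)
  ptr <- stats::setNames(rep(1L, length(verts)), as.character(verts))
  out <- integer(n)
  out[1] <- x[1]
  v <- x[1]
  for (i in 2:n) {
    k <- as.character(v)
    nxt <- pool[[k]][ptr[[k]]]
    ptr[[k]] <- ptr[[k]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  decode_seq(out)
}
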