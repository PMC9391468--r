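## De novo motif discovery: seeded EM under the ZOOPS model (zero or one
## occurrence per sequence), both strands, against an order-1 background.
## Discovery significance is an empirical E-value from refitting on
## dinucleotide-preserving shuffles of the sequence set.

## ---- window cache ----------------------------------------------------
## All windows of width w over all sequences and both strands, as one
## integer matrix plus bookkeeping vectors. Windows containing N (NA) are
## dropped. The background log-likelihood of a reverse-strand window is
## that of the forward-strand bases it covers.

build_window_cache <- function(enc, w, bg) {
  n <- length(enc)
  Ws <- list(); sid <- list(); off <- list(); strand <- list(); bgl <- list()
  lf <- log(bg$freq)
  lt <- if (bg$order == 1) log(bg$trans) else NULL
  for (i in seq_len(n)) {
    x <- enc[[i]]
    L <- length(x)
    if (L < w) next
    nwin <- L - w + 1L
    idx <- outer(seq_len(nwin) - 1L, seq_len(w), "+")
    Wf <- matrix(x[idx], nwin, w)
    ## per-position conditional log prob under bg (order 0 or 1)
    cl <- numeric(L)
    cl[1] <- lf[x[1]]
    if (L > 1) {
      if (bg$order == 1) {
        a <- x[-L]; b <- x[-1]
        v <- rep(NA_real_, L - 1)
        ok <- !is.na(a) & !is.na(b)
        v[ok] <- lt[cbind(a[ok], b[ok])]
        cl[-1] <- v
      } else cl[-1] <- lf[x[-1]]
    }
    cl[is.na(cl)] <- 0
    ## window bg ll; first base of a window mid-sequence conditions on the
    ## preceding base (order 1)
    cs <- cumsum(cl)
    bgw <- cs[seq_len(nwin) + w - 1L] - c(0, cs)[seq_len(nwin)]
    xr <- revcomp_int(x)
    Wr <- matrix(xr[idx], nwin, w)
    ## reverse window at row j covers forward bases (L-w+1-j+1)..: map so
    ## that row j of Wr corresponds to forward offset nwin - j + 1
    map <- rev(seq_len(nwin))
    keep_f <- !apply(is.na(Wf), 1, any)
    keep_r <- keep_f[map]
    Ws[[length(Ws) + 1L]] <- Wf[keep_f, , drop = FALSE]
    Ws[[length(Ws) + 1L]] <- Wr[keep_r, , drop = FALSE]
    kf <- sum(keep_f); kr <- sum(keep_r)
    sid[[length(sid) + 1L]] <- rep(i, kf + kr)
    off[[length(off) + 1L]] <- c(which(keep_f), map[keep_r])
    strand[[length(strand) + 1L]] <- c(rep("+", kf), rep("-", kr))
    bgl[[length(bgl) + 1L]] <- c(bgw[keep_f], bgw[map[keep_r]])
  }
  if (!length(Ws))
    return(list(W = matrix(integer(0), 0, w), seq_id = integer(0),
                offset = integer(0), strand = character(0),
                bgll = numeric(0), n_seq = n, m = rep(0L, n), w = w))
  W <- do.call(rbind, Ws)
  seq_id <- unlist(sid)
  m <- tabulate(seq_id, nbins = n)
  list(W = W, seq_id = seq_id, offset = unlist(off),
       strand = unlist(strand), bgll = unlist(bgl),
       n_seq = n, m = m, w = w)
}

site_loglik <- function(W, log_theta) {
  s <- numeric(nrow(W))
  for (p in seq_len(ncol(W)))
    s <- s + log_theta[W[, p] + 4L * (p - 1L)]
  s
}

## one EM run under ZOOPS; returns theta, gamma, z, objective, ll trace
em_zoops <- function(cache, theta0, gamma0 = 0.3, max_iter = 200,
                     tol = 1e-4, em_floor = 1e-6) {
  W <- cache$W
  if (nrow(W) == 0)
    return(list(theta = theta0, gamma = gamma0, z = numeric(0),
                objective = -Inf, ll = numeric(0), nsites = 0))
  w <- ncol(W)
  m <- pmax(cache$m, 1L)
  theta <- theta0
  gamma <- gamma0
  ll_trace <- numeric(0)
  z <- NULL
  for (it in seq_len(max_iter)) {
    lt <- log(theta)
    sll <- site_loglik(W, lt)
    lr <- exp(pmin(sll - cache$bgll, 700))
    S_full <- numeric(cache$n_seq)
    S <- rowsum(lr, cache$seq_id)
    S_full[as.integer(rownames(S))] <- S[, 1]
    denom <- (1 - gamma) + gamma * S_full / m
    ll <- sum(log(denom))
    z <- (gamma / m[cache$seq_id]) * lr / denom[cache$seq_id]
    ## M-step
    counts <- matrix(em_floor, 4, w)
    for (p in seq_len(w)) {
      cs <- rowsum(z, W[, p])
      counts[as.integer(rownames(cs)), p] <-
        counts[as.integer(rownames(cs)), p] + cs[, 1]
    }
    theta <- sweep(counts, 2, colSums(counts), "/")
    Z_i <- gamma * (S_full / m) / denom
    gamma <- min(max(mean(Z_i), 1e-4), 0.999)
    gain <- if (length(ll_trace)) ll - ll_trace[length(ll_trace)] else Inf
    ll_trace <- c(ll_trace, ll)
    if (is.finite(gain) && gain < tol && it > 1) break
  }
  nsites <- sum(z * (site_loglik(W, log(theta)) > cache$bgll)) # soft count
  list(theta = theta, gamma = gamma, z = z,
       objective = zoops_objective(cache, theta, z),
       ll = ll_trace, nsites = sum(z))
}

## expected total log-likelihood ratio of sites, penalized per column
## (BIC-style: 3 free parameters per column)
zoops_objective <- function(cache, theta, z, penalize = TRUE) {
  if (!length(z)) return(-Inf)
  sll <- site_loglik(cache$W, log(theta))
  ellr <- sum(z * (sll - cache$bgll))
  if (!penalize) return(ellr)
  ns <- max(sum(z), 2)
  ellr - 1.5 * ncol(cache$W) * log(ns)
}

## ---- seeding ---------------------------------------------------------

enumerate_seeds <- function(cache, bg, n_seeds = 8, used = character(0)) {
  W <- cache$W
  if (nrow(W) == 0) return(list())
  w <- ncol(W)
  pow <- 4L^(seq_len(w) - 1L)
  code <- as.vector((W - 1L) %*% pow)
  cnt <- tabulate(code + 1L, nbins = 4L^w)
  ks <- which(cnt > 0)
  ## expected count under stationary order-0 view of the background
  decode <- function(k) ((k - 1L) %/% pow) %% 4L + 1L
  kmers <- lapply(ks, decode)
  lp <- vapply(kmers, function(b) sum(log(bg$freq[b])), numeric(1))
  expd <- nrow(W) * exp(lp)
  score <- cnt[ks] * log(cnt[ks] / expd)
  ord <- order(score, decreasing = TRUE)
  out <- list(); seen <- character(0)
  for (i in ord) {
    b <- kmers[[i]]
    key <- decode_seq(b)
    rc <- decode_seq(revcomp_int(b))
    if (key %in% seen || rc %in% seen) next
    if (key %in% used || rc %in% used) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- b
    if (length(out) >= n_seeds) break
  }
  out
}

seed_theta <- function(seed_bases, w, bg) {
  ws <- length(seed_bases)
  theta <- matrix(bg$freq, 4, w)
  left <- max(1L, (w - ws) %/% 2L + 1L)
  for (j in seq_len(ws)) {
    col <- left + j - 1L
    if (col > w) break
    theta[, col] <- 0.05
    theta[seed_bases[j], col] <- 0.85
  }
  sweep(theta, 2, colSums(theta), "/")
}

width_grid <- function(wmin, wmax) {
  g <- wmin
  while (g[length(g)] < wmax) {
    nxt <- min(wmax, max(g[length(g)] + 2L, round(g[length(g)] * 1.25)))
    g <- c(g, nxt)
  }
  unique(g)
}

## ---- public operations ----------------------------------------------

#' Subsample sequences for initial motif discovery
#'
#' Uniform sample without replacement, reproducible under the seed;
#' identity when the input has at most \code{n} sequences. The default of
#' 600 mirrors the usual cap for EM discovery on large peak sets.
#'
#' @param seqs character vector or \code{DNAStringSet}.
#' @param n sample size (default 600).
#' @param seed RNG seed.
#' @return sampled sequences (same type as input).
#' @export
subsample_sequences <- function(seqs, n = 600, seed = 1) {
  stopifnot(n >= 1)
  if (length(seqs) <= n) return(seqs)
  old <- .Random.seed_exists()
  set.seed(seed)
  idx <- sort(sample.int(length(seqs), n))
  restore_seed(old)
  seqs[idx]
}

#' Discover over-represented motifs by seeded ZOOPS EM
#'
#' For each motif: (i) candidate seeds are all \code{wmin}-mers ranked by
#' background-corrected enrichment over both strands; (ii) the best seed
#' is refined by EM under the ZOOPS likelihood (zero or one site per
#' sequence, both strands, supplied background) until the log-likelihood
#' gain falls below \code{tol} or \code{max_iter} iterations; (iii) the
#' motif width is chosen over a grid in \code{[wmin, wmax]} by the
#' penalized expected log-likelihood-ratio objective; (iv) sites with
#' posterior above 0.5 are masked and the search repeats. The final PWM of
#' each motif is re-normalized with a pseudocount of 0.1 per cell.
#'
#' @param seqs character vector or \code{DNAStringSet} (>= 10 sequences,
#'   each at least \code{wmin} bases).
#' @param bg a \code{bg_model} (order 1 recommended for discovery).
#' @param wmin,wmax motif width range (defaults 6 and 30).
#' @param nmotifs maximum number of motifs (default 20).
#' @param seed RNG seed (shuffles and tie-breaks).
#' @param n_null shuffles for the empirical E-value; 0 skips E-value
#'   assignment (motifs keep \code{evalue = NA}).
#' @param max_iter,tol EM stopping rule (defaults 200 and 1e-4).
#' @param source_dataset label stored on each motif.
#' @return list of \code{pwm}, sorted by E-value (ascending) when
#'   E-values are computed, else by objective (descending). Each motif
#'   carries attributes \code{objective}, \code{n_widths}, \code{ll}
#'   (EM log-likelihood trace) and \code{low_complexity}.
#' @export
discover_motifs <- function(seqs, bg, wmin = 6, wmax = 30, nmotifs = 20,
                            seed = 1, n_null = 50, max_iter = 200,
                            tol = 1e-4, source_dataset = NA_character_) {
  seqs <- as.character(seqs)
  if (length(seqs) < 10) stop("need at least 10 sequences")
  if (any(nchar(seqs) < wmin)) stop("every sequence must be >= wmin bases")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old))
  set.seed(seed)
  enc <- lapply(seqs, encode_seq)
  grid <- width_grid(wmin, wmax)
  motifs <- list()
  used_seeds <- character(0)
  for (k in seq_len(nmotifs)) {
    ## sequence state at this motif's discovery (earlier motifs masked);
    ## the empirical E-value must be computed against this state, not
    ## the original set, or every later motif inherits the first
    ## motif's signal through the seed search
    seqs_state <- vapply(enc, decode_seq, character(1))
    cache_min <- build_window_cache(enc, wmin, bg)
    seeds <- enumerate_seeds(cache_min, bg, n_seeds = 3, used = used_seeds)
    if (!length(seeds)) break
    seed_bases <- seeds[[1]]
    used_seeds <- c(used_seeds, decode_seq(seed_bases))
    ## width selection
    best <- NULL
    caches <- list()
    for (w in grid) {
      cache <- build_window_cache(enc, w, bg)
      caches[[as.character(w)]] <- cache
      if (nrow(cache$W) == 0) next
      fit <- em_zoops(cache, seed_theta(seed_bases, w, bg),
                      max_iter = min(max_iter, 60), tol = tol * 10)
      if (is.null(best) || fit$objective > best$objective) {
        best <- fit; best$w <- w
      }
    }
    if (is.null(best) || !is.finite(best$objective)) break
    cache <- caches[[as.character(best$w)]]
    fit <- em_zoops(cache, best$theta, gamma0 = best$gamma,
                    max_iter = max_iter, tol = tol)
    if (fit$nsites < 2) break
    ## final PWM with pseudocount 0.1 per cell
    w <- best$w
    counts <- matrix(0, 4, w)
    for (p in seq_len(w)) {
      cs <- rowsum(fit$z, cache$W[, p])
      counts[as.integer(rownames(cs)), p] <- cs[, 1]
    }
    probs <- sweep(counts + 0.1, 2, colSums(counts + 0.1), "/")
    m <- pwm(probs, id = sprintf("motif_%d", k),
             nsites = as.integer(max(1, round(fit$nsites))),
             source_dataset = source_dataset)
    cons <- strsplit(consensus_string(m), "")[[1]]
    lowc <- max(table(cons)) >= 0.9 * w
    attr(m, "objective") <- fit$objective
    attr(m, "n_widths") <- length(grid)
    attr(m, "ll") <- fit$ll
    attr(m, "low_complexity") <- lowc
    attr(m, "eval_seqs") <- seqs_state
    motifs[[length(motifs) + 1L]] <- m
    if (lowc) break  # degenerate input: stop after one flagged motif
    ## mask accepted sites (posterior > 0.5): set bases to NA
    take <- which(fit$z > 0.5)
    for (j in take) {
      i <- cache$seq_id[j]
      o <- cache$offset[j]
      enc[[i]][o:(o + w - 1L)] <- NA_integer_
    }
  }
  if (n_null > 0 && length(motifs)) {
    for (k in seq_along(motifs)) {
      motifs[[k]]$evalue <- score_evalue(
        motifs[[k]], attr(motifs[[k]], "eval_seqs"), bg,
        n_null = n_null, seed = seed + k,
        widths_examined = length(grid))
    }
    ord <- order(vapply(motifs, `[[`, 0, "evalue"))
  } else {
    ord <- order(-vapply(motifs, function(m) attr(m, "objective"), 0))
  }
  motifs <- lapply(motifs, function(m) {
    attr(m, "eval_seqs") <- NULL
    m
  })
  motifs[ord]
}

#' Empirical discovery E-value of a motif
#'
#' The discovery objective at the motif's width — best enriched seed,
#' then EM refinement, then the penalized expected log-likelihood-ratio
#' objective — is recomputed on dinucleotide-preserving shuffles of the
#' sequence set, and identically on the real set, so observed and null
#' share the seed-selection optimism. The empirical p-value
#' \code{(1 + #(null >= observed)) / (n_null + 1)} is scaled by the
#' number of widths examined during discovery to give an E-value.
#'
#' @param pwm a \code{pwm} discovered from \code{seqs}.
#' @param seqs the sequence set it was discovered in.
#' @param bg the discovery \code{bg_model}.
#' @param n_null number of shuffles (default 50; < 10 warns, < 1 errors).
#' @param seed RNG seed.
#' @param widths_examined multiplicity factor (defaults to the motif's
#'   \code{n_widths} attribute, else 1).
#' @param refit_iter EM iterations per (re)fit (default 25).
#' @return numeric E-value (> 0).
#' @export
score_evalue <- function(pwm, seqs, bg, n_null = 50, seed = 1,
                         widths_examined = NULL, refit_iter = 25) {
  if (n_null < 1) stop("n_null must be >= 1")
  if (n_null < 10) warning("n_null < 10 gives a very coarse E-value")
  if (is.null(widths_examined))
    widths_examined <- if (!is.null(attr(pwm, "n_widths")))
      attr(pwm, "n_widths") else 1
  seqs <- as.character(seqs)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old))
  set.seed(seed)
  w <- pwm$width
  wseed <- min(6L, w)
  objective_of <- function(enc_set) {
    cache_seed <- build_window_cache(enc_set, wseed, bg)
    seeds <- enumerate_seeds(cache_seed, bg, n_seeds = 1)
    if (!length(seeds)) return(-Inf)
    cache <- build_window_cache(enc_set, w, bg)
    em_zoops(cache, seed_theta(seeds[[1]], w, bg),
             max_iter = refit_iter, tol = 1e-3)$objective
  }
  obs <- objective_of(lapply(seqs, encode_seq))
  nulls <- vapply(seq_len(n_null), function(i) {
    shuf <- lapply(seqs, shuffle_dinucleotide)
    objective_of(lapply(shuf, encode_seq))
  }, numeric(1))
  p_emp <- (1 + sum(nulls >= obs)) / (n_null + 1)
  p_emp * widths_examined
}

#' Bonferroni significance threshold
#'
#' Divides \code{alpha} by the product of the multiplicity counts, e.g.
#' \code{significance_threshold(0.01, c(17, 20))} for 17 datasets times
#' 20 motifs per run.
#'
#' @param alpha significance level in (0, 1].
#' @param counts integer vector of multiplicities (all >= 1).
#' @return numeric threshold.
#' @export
significance_threshold <- function(alpha = 0.01, counts = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (any(counts < 1)) stop("counts must all be >= 1")
  alpha / prod(counts)
}
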