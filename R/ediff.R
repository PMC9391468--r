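## The empirical allelic-difference statistic: an E-value from a z-score
## of one pair's REF-ALT difference against the empirical distribution of
## such differences across all eligible pairs of the same dataset.

#' Empirical E-value for one observed difference
#'
#' z = (mean(values) - observed) / sd(values) with the sample (n - 1)
#' standard deviation; the E-value is the two-tailed normal tail
#' probability 2 * (1 - Phi(|z|)).
#'
#' @param values numeric vector of differences forming the empirical
#'   distribution (length >= 3).
#' @param observed the difference under test (normally one of
#'   \code{values}).
#' @return E-value in (0, 1]; 1 with a warning when sd(values) == 0.
#' @export
ediff <- function(values, observed) {
  if (length(values) < 3)
    stop("need at least 3 values to form the empirical distribution")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    warning("zero spread in the difference distribution; E undefined, ",
            "returning 1")
    return(1)
  }
  z <- (mean(values) - observed) / s
  2 * stats::pnorm(-abs(z))
}

#' Allelic-difference E-values per dataset
#'
#' Pairs with \code{min(p_ref, p_alt) < eligibility_p} (strict) form the
#' empirical distribution of each dataset — the statistic is conservative
#' because only pairs where at least one allele matches the motif
#' nominally are considered. Each eligible pair's p-value difference
#' (p_ref - p_alt) and score difference (sc_ref - sc_alt) are converted
#' to E-values against their dataset's distribution, with pass flags at
#' \code{alpha / n_datasets}.
#'
#' @param records scan data.frame (from \code{\link{scan_variants}}).
#' @param alpha significance level (default 0.01).
#' @param eligibility_p nominal-match bound (default 0.05).
#' @param n_datasets multiplicity for the pass threshold; defaults to the
#'   number of distinct dataset ids in \code{records}.
#' @return data.frame of eligible pairs: variant_id, ref, alt,
#'   dataset_id, motif_id, p_ref, p_alt, sc_ref, sc_alt, d_p, d_sc,
#'   e_diff_p, e_diff_sc, pass_p, pass_sc. Datasets with fewer than 3
#'   eligible pairs are skipped with a warning. The pass threshold is
#'   stored as attribute \code{threshold}.
#' @export
ediff_by_dataset <- function(records, alpha = 0.01, eligibility_p = 0.05,
                             n_datasets = NULL) {
  if (is.null(n_datasets)) n_datasets <- length(unique(records$dataset_id))
  thr <- significance_threshold(alpha, max(n_datasets, 1))
  out <- list()
  for (ds in unique(records$dataset_id)) {
    r <- records[records$dataset_id == ds, , drop = FALSE]
    r <- r[pmin(r$p_ref, r$p_alt) < eligibility_p, , drop = FALSE]
    if (nrow(r) < 3) {
      warning("dataset ", ds, " has fewer than 3 eligible pairs; skipped")
      next
    }
    d_p <- r$p_ref - r$p_alt
    d_sc <- r$sc_ref - r$sc_alt
    r$d_p <- d_p
    r$d_sc <- d_sc
    r$e_diff_p <- vapply(d_p, function(x) ediff(d_p, x), numeric(1))
    r$e_diff_sc <- vapply(d_sc, function(x) ediff(d_sc, x), numeric(1))
    r$pass_p <- r$e_diff_p < thr
    r$pass_sc <- r$e_diff_sc < thr
    out[[length(out) + 1L]] <- r
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(records[0, , drop = FALSE],
          data.frame(d_p = numeric(0), d_sc = numeric(0),
                     e_diff_p = numeric(0), e_diff_sc = numeric(0),
                     pass_p = logical(0), pass_sc = logical(0)))
  rownames(res) <- NULL
  keep <- setdiff(names(res), c("strand_ref", "strand_alt",
                                "offset_ref", "offset_alt",
                                "significant_overlap"))
  res <- res[, keep, drop = FALSE]
  attr(res, "threshold") <- thr
  res
}

#' Top allelic difference per variant, table-style
#'
#' For each variant keeps the (motif x dataset) row with the smallest
#' score-difference E-value (ties: smallest p-difference E-value, then
#' lexicographic dataset id, then motif id), mirroring a
#' one-row-per-variant results table.
#'
#' @param ediffs data.frame from \code{\link{ediff_by_dataset}}.
#' @param top_per_variant keep only the best row per variant
#'   (default TRUE).
#' @return data.frame with columns variant_id, ref, alt, p_ref, p_alt,
#'   sc_ref, sc_alt, e_diff_p, e_diff_sc, motif_id, dataset_id,
#'   hist_mod, cell_type, ordered by e_diff_sc.
#' @export
results_table <- function(ediffs, top_per_variant = TRUE) {
  cols <- c("variant_id", "ref", "alt", "p_ref", "p_alt", "sc_ref",
            "sc_alt", "e_diff_p", "e_diff_sc", "pass_p", "pass_sc",
            "motif_id", "dataset_id")
  if (nrow(ediffs) == 0) {
    out <- ediffs[, intersect(cols, names(ediffs)), drop = FALSE]
    out$hist_mod <- character(0)
    out$cell_type <- character(0)
    return(out)
  }
  df <- ediffs[order(ediffs$variant_id, ediffs$e_diff_sc,
                     ediffs$e_diff_p, ediffs$dataset_id,
                     ediffs$motif_id), , drop = FALSE]
  if (top_per_variant)
    df <- df[!duplicated(df$variant_id), , drop = FALSE]
  parts <- strsplit(df$dataset_id, ".", fixed = TRUE)
  df$cell_type <- vapply(parts, `[`, "", 1)
  df$hist_mod <- vapply(parts, function(p)
    paste(p[-1], collapse = "."), "")
  df <- df[order(df$e_diff_sc, df$e_diff_p, df$variant_id), , drop = FALSE]
  rownames(df) <- NULL
  df[, c(intersect(cols, names(df)), "hist_mod", "cell_type")]
}

#' Write a results table with scientific-notation floats
#'
#' @param df data.frame.
#' @param path output path (tab-separated, 3 significant digits for
#'   doubles).
#' @export
write_results <- function(df, path) {
  fmt <- df
  num <- vapply(fmt, is.double, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) formatC(x, digits = 2,
                                                   format = "e"))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
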