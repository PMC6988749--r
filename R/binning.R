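# Abundance-binned error-rate summaries for visualisation. Bins are for
# display only; the model is always fitted on unbinned records.

#' Assign possible errors to abundance bins
#'
#' Bin boundaries are evenly spaced along the log10-abundance axis between
#' the 5% and the 95% abundance quantile of the records; records beyond
#' those quantiles fall into the first/last bin, so every record is
#' assigned.
#'
#' @param pe a `possible_errors` data frame with positive abundances.
#' @param n_bins number of bins (>= 2).
#' @param read_weighted compute the 5%/95% quantiles weighting records by
#'   reads instead of uniformly (default `FALSE`).
#' @return an integer vector of bin indices (1..`n_bins`), with attribute
#'   `"breaks"`: the `n_bins + 1` boundary positions in log10 abundance
#'   (the outermost pair being the 5% and 95% quantiles, not data limits).
#' @export
make_bins <- function(pe, n_bins, read_weighted = FALSE) {
  stopifnot(n_bins >= 2)
  ab <- pe$abundance
  if (anyNA(ab) || any(ab <= 0)) {
    stop("binning requires positive abundance on every record")
  }
  x <- log10(ab)
  if (diff(range(x)) == 0) stop("all abundances identical: degenerate axis")
  if (read_weighted) {
    o <- order(x)
    cw <- cumsum(pe$R[o]) / sum(pe$R)
    q05 <- x[o][which.max(cw >= 0.05)]
    q95 <- x[o][which.max(cw >= 0.95)]
  } else {
    q <- quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
    q05 <- q[1]; q95 <- q[2]
  }
  if (q95 <= q05) stop("degenerate quantile range for binning")
  breaks <- seq(q05, q95, length.out = n_bins + 1)
  idx <- findInterval(x, breaks[2:n_bins], left.open = FALSE) + 1L
  idx <- pmin(pmax(idx, 1L), n_bins)
  attr(idx, "breaks") <- breaks
  idx
}

#' Summarise abundance bins
#'
#' Pools error and read counts within each bin: `p_hat = sum(E) / sum(R)`,
#' binomial standard error `sqrt(p_hat * (1 - p_hat) / sum(R))`, and a 95%
#' confidence interval of `p_hat +/- 1.96 * se`. The x-position of a bin is
#' the geometric mean abundance of its records.
#'
#' Because low-abundance bins have few reads, leading bins can be pooled:
#' either give `pool_first` (merge the first k bins) or `min_reads` (merge
#' leading bins until the pooled read total reaches the minimum). Bins with
#' zero reads anywhere are merged into the preceding bin (or the following
#' one for a leading empty bin), with a warning.
#'
#' @param pe the `possible_errors` data frame the bins were made from.
#' @param bins bin assignment from [make_bins()].
#' @param pool_first merge the first `pool_first` bins into one (default
#'   `NULL`: use `min_reads`).
#' @param min_reads merge leading bins until they jointly hold at least
#'   this many reads (default 0: no pooling).
#' @return a data frame of class `bin_summary`, one row per (merged) bin:
#'   `bin_index`, `log10_low`, `log10_high`, `geo_mean_abundance`,
#'   `pooled_E`, `pooled_R`, `p_hat`, `se`, `ci_lo`, `ci_hi`,
#'   `pooled_from` (number of raw bins merged).
#' @export
summarize_bins <- function(pe, bins, pool_first = NULL, min_reads = 0) {
  n_bins <- max(1L, length(attr(bins, "breaks")) - 1L)
  breaks <- attr(bins, "breaks")
  idx <- as.integer(bins)
  stopifnot(length(idx) == nrow(pe))

  # raw per-bin totals
  E <- vapply(seq_len(n_bins), function(b) sum(pe$E[idx == b]), numeric(1))
  R <- vapply(seq_len(n_bins), function(b) sum(pe$R[idx == b]), numeric(1))
  logab <- log10(pe$abundance)
  sum_log <- vapply(seq_len(n_bins), function(b) sum(logab[idx == b]),
                    numeric(1))
  n_rec <- tabulate(idx, n_bins)

  # which raw bins merge into which output group
  group <- seq_len(n_bins)
  if (!is.null(pool_first)) {
    k <- min(pool_first, n_bins)
    group[seq_len(k)] <- 1L
  } else if (min_reads > 0) {
    k <- 1L
    while (k < n_bins && sum(R[seq_len(k)]) < min_reads) k <- k + 1L
    group[seq_len(k)] <- 1L
  }
  # merge empty-read bins into a neighbour
  for (b in seq_len(n_bins)) {
    g <- group[b]
    if (sum(R[group == g]) == 0) {
      warning("bin ", b, " has zero reads; merged into a neighbour")
      nb <- if (any(group < g)) max(group[group < g]) else
        min(group[group > g])
      group[group == g] <- nb
    }
  }
  groups <- sort(unique(group))
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    sel <- group == groups[i]
    pooled_E <- sum(E[sel]); pooled_R <- sum(R[sel])
    p_hat <- pooled_E / pooled_R
    se <- sqrt(p_hat * (1 - p_hat) / pooled_R)
    lo_break <- breaks[min(which(sel))]
    hi_break <- breaks[max(which(sel)) + 1L]
    data.frame(bin_index = i,
               log10_low = lo_break, log10_high = hi_break,
               geo_mean_abundance = 10^(sum(sum_log[sel]) / sum(n_rec[sel])),
               pooled_E = pooled_E, pooled_R = pooled_R,
               p_hat = p_hat, se = se,
               ci_lo = p_hat - 1.96 * se, ci_hi = p_hat + 1.96 * se,
               pooled_from = sum(sel))
  }))
  class(out) <- c("bin_summary", class(out))
  out
}
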