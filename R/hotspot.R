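# Iterative binomial hotspot exclusion: loci with improbably many errors of
# any type under the current rate model are removed wholesale (all three
# substitutions in all conditions), and the model is refit on the cleaned
# data until the excluded set stabilises.

#' Upper-tail cumulative binomial probability
#'
#' `P(X >= e)` for `X ~ Binomial(r, p)`; the probability of seeing that
#' many or more errors among `r` reads at per-read error rate `p`.
#' Numerically stable for large `r` and small `p` (computed via
#' `stats::pbinom` on the complementary tail).
#'
#' @param e observed error count(s), `0 <= e <= r`.
#' @param r read count(s).
#' @param p expected per-read error rate(s) in `[0, 1]`.
#' @return `P(X >= e)`, vectorised over the inputs.
#' @examples
#' binomial_tail(0, 1000, 1e-5)  # 1: zero or more errors is certain
#' binomial_tail(1, 2, 0.5)      # 0.75
#' @export
binomial_tail <- function(e, r, p) {
  n <- max(length(e), length(r), length(p))
  e <- rep_len(e, n); r <- rep_len(r, n); p <- rep_len(p, n)
  if (any(e < 0 | e > r | e != round(e))) {
    stop("e must be an integer with 0 <= e <= r")
  }
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  out <- rep(1, n)
  pos <- e > 0
  out[pos] <- pbinom(e[pos] - 1, r[pos], p[pos], lower.tail = FALSE)
  out
}

#' Flag hotspot loci
#'
#' A locus is flagged when any of its possible errors — any condition, any
#' substitution type — has an upper-tail binomial probability below
#' `threshold` given its expected rate. Flagging removes the entire locus
#' downstream.
#'
#' @param pe a `possible_errors` data frame.
#' @param expected_rate expected per-read error rate for each row of `pe`
#'   (clipped into `[0, 1]`).
#' @param threshold significance cutoff (default `1e-9`).
#' @return data frame of flagged loci (`contig`, `pos`).
#' @export
flag_hotspots <- function(pe, expected_rate, threshold = 1e-9) {
  stopifnot(length(expected_rate) == nrow(pe))
  p <- pmin(pmax(expected_rate, 0), 1)
  tail_p <- binomial_tail(pe$E, pe$R, p)
  hit <- tail_p < threshold
  unique(data.frame(contig = pe$contig[hit], pos = pe$pos[hit],
                    stringsAsFactors = FALSE))
}

# expected rates for the first-pass constant model: pooled E/R separately
# for C>U and for all other types
.pooled_two_rate <- function(pe) {
  cu <- pe$sub_type == "C>U"
  r <- numeric(nrow(pe))
  pool <- function(sel) if (any(sel)) sum(pe$E[sel]) / sum(pe$R[sel]) else 0
  r[cu] <- pool(cu)
  r[!cu] <- pool(!cu)
  r
}

# expected rates from the refined per-group models used in later iterations:
#  - coding non-C>U records: type + condition intercepts + shared abundance
#    slope (the full model)
#  - coding C>U records: condition intercepts only (the artifact mode is
#    abundance-independent)
#  - noncoding records: pooled constants per C>U/non-C>U group
.model_rates <- function(pe) {
  rate <- .pooled_two_rate(pe)
  coding_ok <- pe$coding & !is.na(pe$abundance) & pe$abundance > 0
  main <- coding_ok & pe$sub_type != "C>U"
  if (sum(main) > 0L && sum(pe$E[main]) > 0L) {
    fit <- tryCatch(
      fit_error_model(pe[main, , drop = FALSE], types = setdiff(
        unique(pe$sub_type[main]), "C>U"), slope = "shared"),
      error = function(e) NULL)
    if (!is.null(fit)) rate[main] <- predict(fit, pe[main, , drop = FALSE])
  }
  cu <- coding_ok & pe$sub_type == "C>U"
  if (sum(cu) > 0L && sum(pe$E[cu]) > 0L) {
    fit_cu <- tryCatch(
      fit_error_model(pe[cu, , drop = FALSE], types = "C>U",
                      type_intercepts = FALSE, slope = "none"),
      error = function(e) NULL)
    if (!is.null(fit_cu)) rate[cu] <- predict(fit_cu, pe[cu, , drop = FALSE])
  }
  rate
}

#' Iterative hotspot exclusion
#'
#' Alternates rate-model fitting and locus exclusion: the first pass uses a
#' constant error rate for all non-C>U records and a separate constant rate
#' for C>U records; subsequent passes refit the full rate model (type and
#' condition intercepts plus a shared log10-abundance slope for coding
#' non-C>U records, a condition-level model for C>U, pooled constants for
#' noncoding records) on the cleaned data and update the exclusions, until
#' the excluded-locus set stops growing or `max_iter` is reached.
#'
#' When no record carries a usable abundance the refined passes fall back
#' to the pooled two-rate model, so the filter also runs on purely
#' noncoding or annotation-free data.
#'
#' @param pe a `possible_errors` data frame.
#' @param threshold significance cutoff for [binomial_tail()] (default
#'   `1e-9`, chosen so the expected number of falsely excluded possible
#'   errors is negligible at genome scale).
#' @param max_iter maximum number of exclusion passes (default 20).
#' @param refine after the first constant-rate pass, refit the full model
#'   each iteration (default `TRUE`); with `FALSE` every pass uses the
#'   pooled two-rate model.
#' @return a list with components
#'   \describe{
#'     \item{pe}{the cleaned possible-error table, with all records at
#'       excluded loci removed;}
#'     \item{report}{a `hotspot_report`: `excluded_loci` (data frame),
#'       `n_iterations`, `per_iteration` (model label and newly excluded
#'       locus count per pass), `threshold`, `converged`, and
#'       `possible_errors_removed`.}
#'   }
#' @export
filter_hotspots <- function(pe, threshold = 1e-9, max_iter = 20L,
                            refine = TRUE) {
  stopifnot(threshold >= 0, max_iter >= 1L)
  excluded <- data.frame(contig = character(), pos = integer(),
                         stringsAsFactors = FALSE)
  per_iter <- list()
  cur <- pe
  n_input <- nrow(pe)
  converged <- FALSE
  have_ab <- any(cur$coding & !is.na(cur$abundance) & cur$abundance > 0)
  for (it in seq_len(max_iter)) {
    model_label <- if (it == 1L || !refine || !have_ab) {
      "constant two-rate"
    } else {
      "full rate model"
    }
    rate <- if (model_label == "constant two-rate") {
      .pooled_two_rate(cur)
    } else {
      .model_rates(cur)
    }
    new_loci <- flag_hotspots(cur, rate, threshold)
    per_iter[[it]] <- data.frame(iteration = it, model = model_label,
                                 new_excluded = nrow(new_loci),
                                 stringsAsFactors = FALSE)
    if (nrow(new_loci) == 0L) {
      # an iteration with no new exclusions: the excluded set is stable
      converged <- TRUE
      break
    }
    excluded <- unique(rbind(excluded, new_loci))
    drop <- .locus_key(cur$contig, cur$pos) %in%
      .locus_key(new_loci$contig, new_loci$pos)
    cur <- cur[!drop, , drop = FALSE]
  }
  if (!converged) {
    warning("hotspot filter did not converge in ", max_iter, " iterations")
  }
  report <- structure(list(
    excluded_loci = excluded,
    n_iterations = length(per_iter),
    per_iteration = do.call(rbind, per_iter),
    threshold = threshold,
    converged = converged,
    possible_errors_removed = n_input - nrow(cur)
  ), class = "hotspot_report")
  list(pe = cur, report = report)
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat("Hotspot exclusion report\n")
  cat("  threshold:", format(x$threshold), "\n")
  cat("  iterations:", x$n_iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  loci excluded:", nrow(x$excluded_loci), "\n")
  cat("  possible errors removed:", x$possible_errors_removed, "\n")
  invisible(x)
}
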