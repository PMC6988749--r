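# Standard S3 methods for the fitted rate model.

#' @export
print.txerr_fit <- function(x, digits = 4, ...) {
  cat("Identity-link Poisson error-rate model\n")
  cat("  records:", x$nobs,
      sprintf("(total E = %d, total R = %s)", as.integer(x$totals["E"]),
              format(x$totals["R"], big.mark = ",", scientific = FALSE)),
      "\n")
  cat("  types:", paste(x$terms$types, collapse = ", "), "\n")
  cat("  conditions:", paste(x$terms$conditions, collapse = ", "), "\n")
  cat("  slope structure:", x$terms$slope, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 10),
      "on", x$df, "free coefficients\n")
  if (x$boundary_hit) cat("  NOTE: fitted rates touch the zero boundary\n")
  cat("\nCoefficients (rates per read; slopes per decade of abundance):\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
#' @method coef txerr_fit
coef.txerr_fit <- function(object, ...) object$coefficients

#' @export
#' @method vcov txerr_fit
vcov.txerr_fit <- function(object, ...) object$vcov

#' @export
#' @method logLik txerr_fit
logLik.txerr_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
#' @method confint txerr_fit
confint.txerr_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  se <- sqrt(diag(object$vcov))[parm]
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - z * se, cf[parm] + z * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2),
                                trim = TRUE), "%")
  out
}

#' Summary of a fitted error-rate model
#'
#' Reports coefficients with Wald standard errors and z-statistics, plus
#' the implied per-(type, condition) intercept rates under the
#' reference-level coding.
#'
#' @param object a `txerr_fit`.
#' @param ... unused.
#' @export
#' @method summary txerr_fit
summary.txerr_fit <- function(object, ...) {
  cf <- object$coefficients
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = cf, `Std. Error` = se, z = cf / se)
  tm <- object$terms
  # implied intercept rate for every (type, condition) cell
  rates <- matrix(cf["(baseline)"], length(tm$types),
                  length(tm$conditions),
                  dimnames = list(tm$types, tm$conditions))
  for (ty in tm$types) {
    nm <- paste0("type:", ty)
    if (nm %in% names(cf)) rates[ty, ] <- rates[ty, ] + cf[nm]
  }
  for (cd in tm$conditions) {
    nm <- paste0("cond:", cd)
    if (nm %in% names(cf)) rates[, cd] <- rates[, cd] + cf[nm]
  }
  structure(list(coefficients = tab, implied_rates = rates,
                 loglik = object$loglik, df = object$df,
                 nobs = object$nobs, boundary_hit = object$boundary_hit,
                 pooled_rate = object$pooled_rate),
            class = "summary.txerr_fit")
}

#' @export
print.summary.txerr_fit <- function(x, digits = 4, ...) {
  cat("Identity-link Poisson error-rate model\n\n")
  printCoefmat(x$coefficients, digits = digits, P.values = FALSE,
               has.Pvalue = FALSE)
  cat("\nImplied intercept rates (errors per read, at abundance 1 ppm):\n")
  print(signif(x$implied_rates, digits))
  cat("\nPooled rate:", signif(x$pooled_rate, digits),
      "  log-likelihood:", format(x$loglik, digits = 10),
      "  df:", x$df, "  n:", x$nobs, "\n")
  if (x$boundary_hit) cat("NOTE: fitted rates touch the zero boundary\n")
  invisible(x)
}

#' Residuals for the error-rate model
#'
#' @param object a `txerr_fit`.
#' @param newdata the `possible_errors` data the model was fitted on (the
#'   fit does not retain its data).
#' @param type `"pearson"` (default), `"deviance"`, or `"response"`.
#' @param ... passed to [predict.txerr_fit()].
#' @export
#' @method residuals txerr_fit
residuals.txerr_fit <- function(object, newdata,
                                type = c("pearson", "deviance", "response"),
                                ...) {
  type <- match.arg(type)
  tm <- object$terms
  keep <- newdata$sub_type %in% tm$types
  if (!is.null(newdata$coding)) keep <- keep & newdata$coding
  dat <- newdata[keep, , drop = FALSE]
  mu <- predict(object, dat, type = "count", ...)
  E <- dat$E
  switch(type,
         response = E - mu,
         pearson = (E - mu) / sqrt(pmax(mu, .Machine$double.eps)),
         deviance = {
           d <- 2 * (ifelse(E > 0, E * log(E / pmax(mu, 1e-300)), 0) -
                       (E - mu))
           sign(E - mu) * sqrt(pmax(d, 0))
         })
}

#' Simulate error counts from a fitted model
#'
#' Draws Poisson counts with mean `R * rate` at each record of `newdata`,
#' the model's own sampling distribution.
#'
#' @param object a `txerr_fit`.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param newdata `possible_errors` records providing `R`, types,
#'   conditions and abundance.
#' @param ... passed to [predict.txerr_fit()].
#' @return a data frame with `nsim` columns `sim_1 ...`, one row per record
#'   of `newdata` used by the model.
#' @export
simulate.txerr_fit <- function(object, nsim = 1, seed = NULL, newdata,
                               ...) {
  if (!is.null(seed)) set.seed(seed)
  tm <- object$terms
  keep <- newdata$sub_type %in% tm$types
  if (!is.null(newdata$coding)) keep <- keep & newdata$coding
  dat <- newdata[keep, , drop = FALSE]
  mu <- predict(object, dat, type = "count", ...)
  out <- as.data.frame(replicate(nsim, rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot binned rates against the fitted model
#'
#' Plots abundance-binned pooled error rates with 95% binomial confidence
#' intervals, overlaid with the fitted model line averaged over types and
#' conditions with weights proportional to each cell's frequency of
#' opportunity (its share of reads).
#'
#' @param x a `txerr_fit`.
#' @param pe the `possible_errors` data to bin (typically the data the
#'   model was fitted on).
#' @param n_bins number of abundance bins (default 10).
#' @param pool_first pool the lowest `pool_first` bins (default 3, which
#'   keeps low-abundance standard errors reasonable).
#' @param ... further arguments to `plot()`.
#' @export
#' @method plot txerr_fit
plot.txerr_fit <- function(x, pe, n_bins = 10, pool_first = 3, ...) {
  tm <- x$terms
  keep <- pe$sub_type %in% tm$types
  if (!is.null(pe$coding)) keep <- keep & pe$coding
  dat <- pe[keep, , drop = FALSE]
  bins <- make_bins(dat, n_bins)
  bs <- summarize_bins(dat, bins, pool_first = pool_first)
  xs <- log10(bs$geo_mean_abundance)
  plot(xs, bs$p_hat, pch = 19,
       ylim = range(c(bs$ci_lo, bs$ci_hi), finite = TRUE),
       xlab = expression(log[10] ~ "protein abundance (ppm)"),
       ylab = "errors per possible error (per read)", ...)
  segments(xs, bs$ci_lo, xs, bs$ci_hi)
  # model line: rate averaged over (type, condition) cells weighted by reads
  grid <- seq(min(xs), max(xs), length.out = 50)
  cells <- expand.grid(sub_type = tm$types, condition = tm$conditions,
                       stringsAsFactors = FALSE)
  w <- vapply(seq_len(nrow(cells)), function(i) {
    sum(dat$R[dat$sub_type == cells$sub_type[i] &
                dat$condition == cells$condition[i]])
  }, numeric(1))
  w <- w / sum(w)
  line <- vapply(grid, function(g) {
    nd <- data.frame(sub_type = cells$sub_type,
                     condition = cells$condition,
                     abundance = 10^g, R = 1L, coding = TRUE)
    sum(w * predict(x, nd))
  }, numeric(1))
  lines(grid, line, lty = 2)
  invisible(bs)
}

#' @importFrom stats printCoefmat
NULL
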