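# Identity-link Poisson rate model with reads as exposure.
#
# The per-read error rate of record i is modelled as an additive function
# of its substitution type, experimental condition and log10 protein
# abundance:
#
#     rate_i = baseline + type_i + cond_i + slope * log10(abundance_i) + ...
#
# and the observed error count E_i is Poisson with mean R_i * rate_i.
# Because the link is the identity, the linear predictor must stay
# nonnegative over the data; the fit maximises the Poisson log-likelihood
# by damped Fisher scoring with feasibility step-halving, starting from the
# always-feasible pooled-rate solution, and reports boundary hits instead
# of silently accepting rates pinned at zero.

# Build the design matrix for a model specification. Returns list(X, info)
# where info carries the factor levels needed to rebuild X for new data.
.build_design <- function(pe, type_levels, cond_levels,
                          type_intercepts, condition_intercepts,
                          slope, slope_type = "G>A",
                          covariates = NULL, covariate_roles = NULL) {
  n <- nrow(pe)
  cols <- list(`(baseline)` = rep(1, n))
  type <- factor(pe$sub_type, levels = type_levels)
  cond <- factor(pe$condition, levels = cond_levels)
  if (anyNA(type)) stop("record with substitution type outside the model's types")
  if (anyNA(cond)) stop("record with condition outside the model's conditions")
  if (type_intercepts && length(type_levels) > 1L) {
    for (lv in type_levels[-1L]) {
      cols[[paste0("type:", lv)]] <- as.numeric(type == lv)
    }
  }
  if (condition_intercepts && length(cond_levels) > 1L) {
    for (lv in cond_levels[-1L]) {
      cols[[paste0("cond:", lv)]] <- as.numeric(cond == lv)
    }
  }
  if (slope != "none") {
    x <- log10(pe$abundance)
    if (anyNA(x)) stop("abundance missing for some records; slope terms need abundance > 0")
    if (slope == "shared") {
      cols[["slope"]] <- x
    } else if (slope == "per_condition") {
      for (lv in cond_levels) {
        cols[[paste0("slope:cond:", lv)]] <- x * (cond == lv)
      }
    } else if (slope == "per_type") {
      for (lv in type_levels) {
        cols[[paste0("slope:type:", lv)]] <- x * (type == lv)
      }
    } else if (slope == "ga_specific") {
      if (!slope_type %in% type_levels) {
        stop("slope type ", slope_type, " is not among the model's types")
      }
      cols[["slope"]] <- x
      cols[[paste0("slope:type:", slope_type)]] <- x * (type == slope_type)
    }
  }
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      role <- if (is.null(covariate_roles[[nm]])) "intercept" else covariate_roles[[nm]]
      if (role == "intercept") {
        cols[[paste0("cov:", nm)]] <- as.numeric(v)
      } else {
        cols[[paste0("cov_slope:", nm)]] <- as.numeric(v) * log10(pe$abundance)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# Poisson log-likelihood for mean mu_i = R_i * rate_i (full likelihood,
# including the lfactorial term, so values are comparable across models)
.pois_ll <- function(E, R, rate) {
  mu <- R * rate
  ll <- -mu - lfactorial(E)
  pos <- E > 0
  if (any(pos & mu <= 0)) return(-Inf)
  ll[pos] <- ll[pos] + E[pos] * log(mu[pos])
  sum(ll)
}

#' Fit the identity-link Poisson error-rate model
#'
#' Models the per-read error rate of each possible-error record as an
#' additive (identity-link) function of substitution type, experimental
#' condition and log10 protein abundance, with the observed error count
#' `E` treated as Poisson with mean `R * rate`. This is the error-rate
#' analogue of a Poisson regression with exposure, except that the rate —
#' not its log — is linear in the predictors, so an abundance slope reads
#' directly as "errors per read per decade of abundance".
#'
#' Intercepts use reference-level coding: the first substitution type and
#' first condition are absorbed into the baseline, and `summary()` reports
#' the implied per-(type, condition) rates. Slope structures:
#' `"none"`, `"shared"` (one slope for all records), `"per_condition"`,
#' `"per_type"`, or `"ga_specific"` (a shared slope plus an additional
#' G>A-specific slope, so the shared-slope model is nested inside it).
#'
#' The likelihood is maximised by damped Fisher scoring started at the
#' pooled rate `sum(E)/sum(R)` (always feasible), with step-halving to keep
#' every fitted rate nonnegative; convergence requires a relative
#' log-likelihood change below `tol`. If the optimum pins fitted rates
#' against zero the fit is returned with `boundary_hit = TRUE`.
#'
#' @param pe a `possible_errors` data frame (see
#'   [build_possible_errors()]). Only coding records with the requested
#'   substitution types are used; records with missing abundance are an
#'   error when a slope term is present.
#' @param types substitution types to include (default: the 11 non-C>U
#'   types present in the data). C>U analyses are run as a separate model
#'   on C>U records alone.
#' @param type_intercepts,condition_intercepts include per-type /
#'   per-condition intercept offsets (default `TRUE`; collapsed
#'   automatically when only one level is present).
#' @param slope slope structure, see above.
#' @param slope_type the type given its own slope under `"ga_specific"`
#'   (default `"G>A"`).
#' @param covariates optional named list of per-record numeric covariates
#'   (e.g. chaperone-client flags, gene length, positions).
#' @param covariate_roles named list mapping covariate names to
#'   `"intercept"` (rate offset) or `"slope"` (abundance-interaction);
#'   default `"intercept"`.
#' @param tol relative log-likelihood convergence tolerance (default
#'   `1e-10`).
#' @param max_iter maximum Fisher-scoring iterations (default 200).
#' @return an object of class `txerr_fit` with components `coefficients`,
#'   `vcov`, `loglik`, `df` (number of free coefficients), `nobs`,
#'   `converged`, `boundary_hit`, `iterations`, and the model structure
#'   needed by `predict()`.
#' @seealso [predict.txerr_fit()], [anova.txerr_fit()], [lrt()],
#'   [aggregate_rate()]
#' @export
fit_error_model <- function(pe,
                            types = NULL,
                            type_intercepts = TRUE,
                            condition_intercepts = TRUE,
                            slope = c("shared", "none", "per_condition",
                                      "per_type", "ga_specific"),
                            slope_type = "G>A",
                            covariates = NULL,
                            covariate_roles = NULL,
                            tol = 1e-10,
                            max_iter = 200L) {
  slope <- match.arg(slope)
  cl <- match.call()
  if (is.null(types)) {
    types <- setdiff(sort(unique(pe$sub_type)), "C>U")
  }
  keep <- pe$sub_type %in% types
  if (!is.null(pe$coding)) keep <- keep & pe$coding
  dat <- pe[keep, , drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- lapply(covariates, function(v) {
      stopifnot(length(v) == nrow(pe))
      v[keep]
    })
  }
  if (nrow(dat) == 0L) stop("no usable records for the requested types")
  if (slope != "none" &&
      (anyNA(dat$abundance) || any(dat$abundance <= 0))) {
    stop("slope terms require positive abundance on every record")
  }

  type_levels <- intersect(sort(types), unique(dat$sub_type))
  cond_levels <- sort(unique(dat$condition))
  X <- .build_design(dat, type_levels, cond_levels, type_intercepts,
                     condition_intercepts, slope, slope_type,
                     covariates, covariate_roles)
  E <- as.numeric(dat$E)
  R <- as.numeric(dat$R)
  p <- ncol(X)
  pooled <- sum(E) / sum(R)

  theta <- c(pooled, rep(0, p - 1L))
  names(theta) <- colnames(X)

  if (sum(E) == 0) {
    # degenerate: MLE pins every rate at the zero boundary
    fit <- list(coefficients = setNames(rep(0, p), colnames(X)),
                vcov = matrix(NA_real_, p, p,
                              dimnames = list(colnames(X), colnames(X))),
                loglik = 0, df = p, nobs = nrow(dat), converged = TRUE,
                boundary_hit = TRUE, iterations = 0L)
  } else {
    rate <- drop(X %*% theta)
    ll <- .pois_ll(E, R, rate)
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      # score and Fisher information for the identity link:
      #   U_j = sum_i (E_i / rate_i - R_i) x_ij
      #   I_jk = sum_i (R_i / rate_i) x_ij x_ik
      safe_rate <- pmax(rate, 1e-300)
      score <- drop(crossprod(X, E / safe_rate - R))
      w <- R / safe_rate
      info <- crossprod(X * sqrt(w))
      step <- tryCatch(solve(info, score), error = function(e) NULL)
      if (is.null(step)) {
        stop("rate model fit failed: singular Fisher information ",
             "(collinear model terms?)")
      }
      alpha <- 1
      repeat {
        theta_new <- theta + alpha * step
        rate_new <- drop(X %*% theta_new)
        ll_new <- if (min(rate_new) < 0) -Inf else .pois_ll(E, R, rate_new)
        if (ll_new >= ll - 1e-12 * (abs(ll) + 1)) break
        alpha <- alpha / 2
        if (alpha < 1e-12) { theta_new <- theta; rate_new <- rate; ll_new <- ll; break }
      }
      done <- abs(ll_new - ll) <= tol * (abs(ll) + 1)
      theta <- theta_new; rate <- rate_new; ll <- ll_new
      if (done) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    if (!converged) {
      stop("rate model fit did not converge in ", max_iter,
           " iterations (last log-likelihood ", format(ll), ")")
    }
    boundary_hit <- min(rate) <= 1e-10 * max(pooled, max(rate))
    safe_rate <- pmax(rate, 1e-300)
    info <- crossprod(X * sqrt(R / safe_rate))
    V <- tryCatch(solve(info), error = function(e)
      matrix(NA_real_, p, p))
    dimnames(V) <- list(colnames(X), colnames(X))
    fit <- list(coefficients = theta, vcov = V, loglik = ll, df = p,
                nobs = nrow(dat), converged = TRUE,
                boundary_hit = boundary_hit, iterations = iter)
  }

  fit$terms <- list(types = type_levels, conditions = cond_levels,
                    type_intercepts = type_intercepts,
                    condition_intercepts = condition_intercepts,
                    slope = slope, slope_type = slope_type,
                    covariate_names = names(covariates),
                    covariate_roles = covariate_roles)
  fit$pooled_rate <- pooled
  fit$totals <- c(E = sum(E), R = sum(R))
  fit$call <- cl
  class(fit) <- "txerr_fit"
  fit
}

#' Predicted per-read error rates
#'
#' Evaluates the fitted additive rate at each record's type, condition and
#' abundance, clipped into `[0, 1]` (rates are probabilities per read).
#'
#' @param object a `txerr_fit`.
#' @param newdata a `possible_errors` data frame; every record must carry a
#'   type and condition known to the fit, and a positive abundance when the
#'   model has slope terms.
#' @param type `"rate"` (default) for per-read rates, `"count"` for
#'   expected error counts `R * rate`.
#' @param covariates optional named list of covariate vectors matching
#'   `newdata`, required when the fit includes covariate terms.
#' @param ... unused.
#' @return numeric vector, one value per row of `newdata`.
#' @export
predict.txerr_fit <- function(object, newdata, type = c("rate", "count"),
                              covariates = NULL, ...) {
  type <- match.arg(type)
  tm <- object$terms
  if (!is.null(tm$covariate_names) && length(tm$covariate_names) &&
      is.null(covariates)) {
    stop("this fit has covariate terms; supply matching covariates")
  }
  if (tm$slope != "none" &&
      (anyNA(newdata$abundance) || any(newdata$abundance <= 0))) {
    stop("abundance missing for some records")
  }
  X <- .build_design(newdata, tm$types, tm$conditions, tm$type_intercepts,
                     tm$condition_intercepts, tm$slope, tm$slope_type,
                     covariates, tm$covariate_roles)
  rate <- pmin(pmax(drop(X %*% object$coefficients), 0), 1)
  if (type == "rate") rate else rate * newdata$R
}

#' Likelihood-ratio chi-square test of nested rate models
#'
#' Compares two fits of the identity-link Poisson model on the same data by
#' the likelihood-ratio statistic `2 * (logLik(alt) - logLik(null))`,
#' referred to a chi-square distribution with `df(alt) - df(null)` degrees
#' of freedom. The degrees of freedom can be overridden when the automatic
#' difference is not the effective number of added parameters.
#'
#' @param null the smaller (nested) fit.
#' @param alt the larger fit.
#' @param df optional override of the degrees of freedom.
#' @return a list with `statistic`, `df`, `p.value`.
#' @export
lrt <- function(null, alt, df = NULL) {
  stopifnot(inherits(null, "txerr_fit"), inherits(alt, "txerr_fit"))
  if (alt$df < null$df) {
    stop("alternative model has fewer parameters than the null; swap the arguments?")
  }
  stat <- 2 * (alt$loglik - null$loglik)
  if (stat < -1e-6 * (abs(alt$loglik) + 1)) {
    stop("alternative log-likelihood is below the null's: the models are ",
         "not nested or a fit failed")
  }
  stat <- max(stat, 0)
  if (is.null(df)) df <- alt$df - null$df
  if (df <= 0) stop("degrees of freedom must be positive")
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' @describeIn lrt `anova()` method: chi-square comparison of two nested
#'   `txerr_fit` models, in the style of `anova(glm1, glm2, test = "Chisq")`.
#' @param object,... for `anova`: two `txerr_fit` objects (null first).
#' @export
anova.txerr_fit <- function(object, ..., df = NULL) {
  fits <- c(list(object), list(...))
  fits <- Filter(function(x) inherits(x, "txerr_fit"), fits)
  if (length(fits) != 2L) {
    stop("supply exactly two txerr_fit objects to compare")
  }
  res <- lrt(fits[[1L]], fits[[2L]], df = df)
  out <- data.frame(
    logLik = c(fits[[1L]]$loglik, fits[[2L]]$loglik),
    Df = c(fits[[1L]]$df, fits[[2L]]$df),
    Deviance = c(NA, res$statistic),
    `Chi Df` = c(NA, res$df),
    `Pr(>Chi)` = c(NA, res$p.value),
    check.names = FALSE
  )
  rownames(out) <- c("null", "alternative")
  structure(out, heading = "Likelihood-ratio test of nested error-rate models",
            class = c("anova", "data.frame"))
}

#' Pooled error rates per possible error and per nucleotide
#'
#' The per-possible-error rate is the pooled `sum(E) / sum(R)` over the
#' requested substitution types. The per-nucleotide rate adds up, within
#' each reference base, the pooled rates of its (up to three) alternative
#' substitution types, then averages across reference bases weighted by
#' their read totals — so with three equally likely types it is exactly
#' three times the per-possible-error rate.
#'
#' @param pe a `possible_errors` data frame.
#' @param types substitution types to include (default: all present).
#' @return a list with `per_possible_error`, `per_nucleotide`, and
#'   `per_type` (named vector of pooled rates per substitution type).
#' @export
aggregate_rate <- function(pe, types = NULL) {
  if (is.null(types)) types <- sort(unique(pe$sub_type))
  dat <- pe[pe$sub_type %in% types, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no records for the requested types")
  Et <- tapply(dat$E, dat$sub_type, sum)
  Rt <- tapply(dat$R, dat$sub_type, sum)
  per_type <- Et / Rt
  ref <- substr(names(per_type), 1L, 1L)
  # per reference base: sum of its alternative-type rates; weight across
  # reference bases by the reads observed at sites with that base
  rate_by_ref <- tapply(per_type, ref, sum)
  reads_by_ref <- tapply(Rt, ref, max)  # R is shared by a site's types
  per_nt <- sum(rate_by_ref * reads_by_ref) / sum(reads_by_ref)
  list(per_possible_error = sum(dat$E) / sum(dat$R),
       per_nucleotide = unname(per_nt),
       per_type = per_type)
}
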