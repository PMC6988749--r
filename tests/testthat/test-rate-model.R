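test_that("a single-intercept fit equals the pooled rate in closed form", {
  set.seed(101)
  for (i in 1:5) {
    n <- 500L
    pe <- data.frame(contig = "c", pos = seq_len(n), condition = "c1",
                     sub_type = "A>G",
                     R = rpois(n, 200) + 1L, coding = TRUE,
                     abundance = 10^runif(n, 0, 3), gene_id = "g",
                     stringsAsFactors = FALSE)
    pe$E <- rbinom(n, pe$R, 1e-3)
    if (sum(pe$E) == 0) next
    fit <- fit_error_model(pe, types = "A>G", type_intercepts = FALSE,
                           condition_intercepts = FALSE, slope = "none")
    pooled <- sum(pe$E) / sum(pe$R)
    expect_equal(unname(coef(fit)[1]), pooled, tolerance = 1e-11)
    expect_equal(fit$df, 1L)
  }
})

test_that("the fit agrees with glm(poisson(identity)) on the same data", {
  cfg <- synth_config("scaled", n_genes = 150L, conditions = "c1",
                      seed = 5L)
  pe <- sim_possible_errors(cfg, loci_per_gene = 4L)
  sub <- pe[pe$sub_type %in% c("A>G", "A>C"), ]
  fit <- fit_error_model(sub, types = c("A>C", "A>G"), slope = "shared")
  x <- log10(sub$abundance)
  ty <- as.numeric(sub$sub_type == "A>G")
  ref <- glm(E ~ 0 + R + I(R * ty) + I(R * x),
             family = poisson(link = "identity"), data = sub,
             start = unname(coef(fit)))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("adding terms never decreases the maximised log-likelihood", {
  cfg <- synth_config("scaled", n_genes = 300L, seed = 8L)
  pe <- sim_possible_errors(cfg, loci_per_gene = 4L)
  f_none <- fit_error_model(pe, slope = "none")
  f_shared <- fit_error_model(pe, slope = "shared")
  f_ga <- fit_error_model(pe, slope = "ga_specific")
  f_pc <- fit_error_model(pe, slope = "per_condition")
  expect_gte(f_shared$loglik, f_none$loglik)
  expect_gte(f_ga$loglik, f_shared$loglik)
  expect_gte(f_pc$loglik, f_shared$loglik)
  # df bookkeeping: ga_specific adds exactly one term to shared
  expect_equal(f_ga$df, f_shared$df + 1L)
})

test_that("likelihood-ratio test behaves at the boundaries", {
  cfg <- synth_config("scaled", n_genes = 100L, seed = 12L)
  pe <- sim_possible_errors(cfg, loci_per_gene = 4L)
  f1 <- fit_error_model(pe, slope = "none")
  f1b <- fit_error_model(pe, slope = "none")
  same <- lrt(f1, f1b, df = 1)
  expect_equal(same$statistic, 0, tolerance = 1e-6)
  expect_equal(same$p.value, 1, tolerance = 1e-6)
  f2 <- fit_error_model(pe, slope = "shared")
  both <- lrt(f1, f2)
  expect_equal(both$df, 1L)
  # manual df override is honoured
  expect_equal(lrt(f1, f2, df = 3)$df, 3)
  expect_error(lrt(f2, f1), "fewer parameters")
  # chi-square reference: statistic 3.84 on 1 df sits at ~0.05
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-2)
  av <- anova(f1, f2)
  expect_s3_class(av, "anova")
  expect_equal(av$`Pr(>Chi)`[2], both$p.value)
})

test_that("predicted rates follow the fitted line exactly", {
  fit <- manual_fit(2e-5, slope = -1e-6)
  nd <- data.frame(sub_type = "A>G", condition = "c1",
                   abundance = c(100, 1000), R = 10L, coding = TRUE)
  expect_equal(predict(fit, nd), c(1.8e-5, 1.7e-5))
  expect_equal(predict(fit, nd, type = "count"), c(1.8e-4, 1.7e-4))
  # rates are clipped into [0, 1]
  nd2 <- data.frame(sub_type = "A>G", condition = "c1",
                    abundance = 1e30, R = 10L, coding = TRUE)
  expect_equal(predict(fit, nd2), 0)
  nd3 <- nd; nd3$abundance <- NA_real_
  expect_error(predict(fit, nd3), "abundance")
  # monotone decreasing in abundance for a negative slope
  grid <- data.frame(sub_type = "A>G", condition = "c1",
                     abundance = 10^seq(0, 4, 0.5), R = 1L, coding = TRUE)
  expect_true(all(diff(predict(fit, grid)) < 0))
})

test_that("an all-zero count vector pins the fit at the zero boundary", {
  pe <- data.frame(contig = "c", pos = 1:50, condition = "c1",
                   sub_type = "A>G", E = 0L, R = 100L, coding = TRUE,
                   abundance = 10, gene_id = "g", stringsAsFactors = FALSE)
  fit <- fit_error_model(pe, types = "A>G", type_intercepts = FALSE,
                         condition_intercepts = FALSE, slope = "none")
  expect_true(fit$boundary_hit)
  expect_equal(unname(coef(fit)[1]), 0)
})

test_that("pooled and per-nucleotide aggregate rates are consistent", {
  pe <- data.frame(contig = "c", pos = rep(1:100, 3), condition = "c1",
                   sub_type = rep(c("A>C", "A>G", "A>U"), each = 100),
                   E = rep(c(5L, 5L, 5L), each = 100) * 0L + 5L,
                   R = 2000L, coding = TRUE, abundance = 10,
                   gene_id = "g", stringsAsFactors = FALSE)
  agg <- aggregate_rate(pe)
  # each type pools to 500/200000 = 2.5e-3
  expect_equal(unname(agg$per_type["A>C"]), 5 / 2000)
  # with three equal-rate types the per-nucleotide rate is exactly 3x
  expect_equal(agg$per_nucleotide, 3 * agg$per_possible_error)
  expect_error(aggregate_rate(pe, types = "G>A"), "no records")
})

test_that("exposure-Poisson and per-read binomial likelihoods agree at low rates", {
  cfg <- synth_config("scaled", n_genes = 200L, conditions = "c1",
                      seed = 21L)
  pe <- sim_possible_errors(cfg, loci_per_gene = 4L)
  sub <- pe[pe$sub_type == "A>G", ]
  fit <- fit_error_model(sub, types = "A>G", type_intercepts = FALSE,
                         condition_intercepts = FALSE, slope = "shared")
  x <- log10(sub$abundance)
  nll_binom <- function(th) {
    p <- th[1] + th[2] * x
    if (any(p <= 0 | p >= 1)) return(1e10)
    -sum(dbinom(sub$E, sub$R, p, log = TRUE))
  }
  ob <- optim(unname(coef(fit)), nll_binom, method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 5000))
  se_slope <- sqrt(vcov(fit)["slope", "slope"])
  expect_lt(abs(ob$par[2] - coef(fit)["slope"]), se_slope)
})

test_that("coefficients recover generating values within Wald intervals", {
  cfg <- synth_config("scaled", n_genes = 400L, seed = 31L)
  pe <- sim_possible_errors(cfg, loci_per_gene = 6L)
  fit <- fit_error_model(pe, slope = "shared")
  tc <- truth_check(list(fit = fit), attr(pe, "truth"))
  se <- sqrt(vcov(fit)["slope", "slope"])
  expect_lt(abs(tc$fit$slope_error), 5 * se)
  sm <- summary(fit)
  expect_true(all(sm$implied_rates > 0))
  expect_equal(dim(sm$implied_rates),
               c(length(fit$terms$types), length(fit$terms$conditions)))
})

test_that("gene-level covariates enter as rate offsets and are detected by lrt", {
  cfg <- synth_config("scaled", n_genes = 400L, conditions = "c1",
                      seed = 61L)
  pe <- sim_possible_errors(cfg, loci_per_gene = 4L)
  # flag half the genes and add a known rate offset to their records
  flagged <- as.numeric(as.integer(sub("g", "", pe$gene_id)) %% 2L == 0L)
  set.seed(62)
  extra <- rbinom(nrow(pe), pe$R, 5e-4 * flagged)
  pe$E <- pe$E + as.integer(extra)
  pe$E <- pmin(pe$E, pe$R)
  f0 <- fit_error_model(pe, slope = "shared")
  f1 <- fit_error_model(pe, slope = "shared",
                        covariates = list(client = flagged))
  expect_equal(f1$df, f0$df + 1L)
  expect_equal(unname(coef(f1)["cov:client"]), 5e-4, tolerance = 0.2)
  expect_lt(lrt(f0, f1)$p.value, 1e-6)
})

test_that("the plot method draws binned rates without error", {
  cfg <- synth_config("scaled", n_genes = 300L, seed = 71L)
  pe <- sim_possible_errors(cfg, loci_per_gene = 5L)
  fit <- fit_error_model(pe, slope = "shared")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  bs <- plot(fit, pe, n_bins = 8, pool_first = 2)
  expect_s3_class(bs, "bin_summary")
  expect_equal(sum(bs$pooled_E),
               sum(pe$E[pe$sub_type %in% fit$terms$types]))
})
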