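make_pe <- function(abundance, E, R) {
  data.frame(contig = "c", pos = seq_along(abundance), condition = "c1",
             sub_type = "A>G", E = as.integer(E), R = as.integer(R),
             coding = TRUE, abundance = abundance, gene_id = "g",
             stringsAsFactors = FALSE)
}

test_that("bin boundaries are even in log abundance between the 5% and 95% quantiles", {
  ab <- 10^seq(0, 4, length.out = 1001)   # uniform on the log axis
  pe <- make_pe(ab, 0, 100)
  bins <- make_bins(pe, 10)
  breaks <- attr(bins, "breaks")
  expect_length(breaks, 11L)
  expect_equal(breaks[1], quantile(log10(ab), 0.05, names = FALSE))
  expect_equal(breaks[11], quantile(log10(ab), 0.95, names = FALSE))
  expect_equal(diff(breaks), rep(diff(breaks)[1], 10), tolerance = 1e-12)
  # records beyond the quantiles land in the edge bins
  expect_equal(bins[1], 1L)
  expect_equal(bins[length(bins)], 10L)
  expect_true(all(bins >= 1L & bins <= 10L))
})

test_that("two bins meet at the log-midpoint of the quantiles", {
  ab <- 10^seq(0, 2, length.out = 101)
  pe <- make_pe(ab, 0, 10)
  bins <- make_bins(pe, 2)
  breaks <- attr(bins, "breaks")
  expect_equal(breaks[2], mean(breaks[c(1, 3)]))
  expect_equal(sort(unique(as.integer(bins))), c(1L, 2L))
  expect_error(make_bins(make_pe(rep(5, 10), 0, 10), 2), "identical")
})

test_that("bin summaries use the stated binomial standard error", {
  # one bin with p_hat = 0.5 over 100 reads: se = 0.05, CI half-width 0.098
  ab <- 10^c(seq(0, 0.9, length.out = 10), seq(1.1, 2, length.out = 10))
  pe <- make_pe(ab, 5, 10)
  bins <- make_bins(pe, 2)
  bs <- summarize_bins(pe, bins)
  expect_equal(bs$p_hat, rep(0.5, nrow(bs)))
  expect_equal(bs$pooled_R, c(100, 100))
  one <- bs[1, ]
  expect_equal(one$se, sqrt(0.5 * 0.5 / 100))
  expect_equal(one$ci_hi - one$p_hat, 1.96 * one$se)
  # p_hat = 0 collapses the interval to a point
  pe0 <- make_pe(10^runif(50, 0, 2), 0, 10)
  bs0 <- summarize_bins(pe0, make_bins(pe0, 2))
  expect_equal(bs0$se, rep(0, nrow(bs0)))
  expect_equal(bs0$ci_lo, bs0$p_hat)
  expect_equal(bs0$ci_hi, bs0$p_hat)
})

test_that("totals are conserved and merged bins pool read-weighted", {
  set.seed(77)
  ab <- 10^rnorm(500, 2, 1)
  pe <- make_pe(ab, rbinom(500, 100, 0.02), 100)
  bins <- make_bins(pe, 10)
  bs <- summarize_bins(pe, bins, pool_first = 3)
  expect_equal(sum(bs$pooled_E), sum(pe$E))
  expect_equal(sum(bs$pooled_R), sum(pe$R))
  expect_equal(nrow(bs), 8L)
  expect_equal(bs$pooled_from[1], 3L)
  # merged p_hat equals the read-weighted mean of the raw parts
  raw <- summarize_bins(pe, bins)
  first3 <- raw[1:3, ]
  expect_equal(bs$p_hat[1],
               sum(first3$p_hat * first3$pooled_R) / sum(first3$pooled_R))
  # geometric-mean x-position lies inside the pooled range
  expect_true(all(log10(bs$geo_mean_abundance) >=
                    c(-Inf, bs$log10_low[-1])))
})

test_that("leading bins merge until the read threshold is met", {
  ab <- 10^seq(0, 3, length.out = 300)
  pe <- make_pe(ab, 0, 10)
  bins <- make_bins(pe, 10)
  raw <- summarize_bins(pe, bins)
  thresh <- sum(raw$pooled_R[1:2]) + 1
  bs <- summarize_bins(pe, bins, min_reads = thresh)
  expect_equal(bs$pooled_from[1], 3L)
  expect_gte(bs$pooled_R[1], thresh)
})

test_that("interior bins track a linear generating model", {
  set.seed(123)
  ab <- 10^rnorm(4000, 2, 1)
  rate <- 2e-3 - 4e-4 * (log10(ab) - 2)
  pe <- make_pe(ab, rbinom(4000, 1000, rate), 1000)
  bins <- make_bins(pe, 8)
  bs <- summarize_bins(pe, bins)
  mid <- (bs$log10_low + bs$log10_high) / 2
  expected <- 2e-3 - 4e-4 * (log10(bs$geo_mean_abundance) - 2)
  interior <- 2:(nrow(bs) - 1)
  within <- abs(bs$p_hat[interior] - expected[interior]) <=
    2 * bs$se[interior]
  expect_gte(mean(within), 0.9)
})
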