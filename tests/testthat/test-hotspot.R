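test_that("binomial tail handles the closed-form cases", {
  expect_equal(binomial_tail(0, 1000, 1e-5), 1)
  expect_equal(binomial_tail(0, 0, 0.5), 1)
  expect_equal(binomial_tail(1, 2, 0.5), 0.75)     # 1 - 0.25
  expect_equal(binomial_tail(5, 5, 0.3), 0.3^5)    # e = r
  expect_error(binomial_tail(3, 2, 0.5), "e must")
  expect_error(binomial_tail(1, 2, 1.5), "p must")
  # stays finite and monotone in e at extreme depth and tiny rate
  tails <- binomial_tail(0:5, 1e7, 1e-8)
  expect_true(all(diff(tails) < 0))
  expect_true(all(tails > 0 & tails <= 1))
})

test_that("flagging is per possible error but exclusion takes the whole locus", {
  cfg <- synth_config("scaled", n_genes = 100L, depth_mean = 1e4,
                      seed = 42L)
  pe <- sim_possible_errors(cfg, loci_per_gene = 5L, hotspot_loci = 10L)
  truth <- attr(pe, "truth")
  res <- filter_hotspots(pe, threshold = 1e-9)
  got <- txerr:::.locus_key(res$report$excluded_loci$contig,
                            res$report$excluded_loci$pos)
  want <- txerr:::.locus_key(truth$hotspots$contig, truth$hotspots$pos)
  # every injected 50x hotspot at depth 1e4 is recalled, nothing else
  expect_setequal(got, want)
  expect_true(res$report$converged)
  # excluding a locus removes all of its records in all conditions/types
  expect_false(any(txerr:::.locus_key(res$pe$contig, res$pe$pos) %in% got))
  removed <- nrow(pe) - nrow(res$pe)
  expect_equal(removed, res$report$possible_errors_removed)
  expect_equal(removed %% 3L, 0L)   # whole sites only
})

test_that("clean data excludes nothing and converges in one pass", {
  cfg <- synth_config("scaled", n_genes = 200L, seed = 3L)
  pe <- sim_possible_errors(cfg, loci_per_gene = 5L)
  res <- filter_hotspots(pe, threshold = 1e-9)
  expect_equal(nrow(res$report$excluded_loci), 0L)
  expect_true(res$report$converged)
  expect_identical(res$pe, pe)
})

test_that("records with zero errors are never flagged", {
  pe <- data.frame(contig = "c", pos = 1:4, condition = "c1",
                   sub_type = "A>G", E = 0L, R = c(10L, 100L, 1000L, 0L),
                   coding = TRUE, abundance = NA_real_, gene_id = "g")
  flagged <- flag_hotspots(pe, rep(1e-6, 4), threshold = 0.999999)
  expect_equal(nrow(flagged), 0L)
})

test_that("a degenerate threshold of 1 flags every locus with observed errors", {
  pe <- data.frame(contig = "c", pos = 1:3, condition = "c1",
                   sub_type = "A>G", E = c(0L, 1L, 5L), R = 100L,
                   coding = TRUE, abundance = NA_real_, gene_id = "g")
  flagged <- flag_hotspots(pe, rep(1e-3, 3), threshold = 1)
  expect_setequal(flagged$pos, c(2L, 3L))
})

test_that("the excluded set grows monotonically across iterations", {
  # two tiers of hotspots: the extreme tier masks the moderate one until
  # it is removed and the pooled rate drops
  set.seed(9)
  n <- 2000L
  pe <- data.frame(contig = "c", pos = seq_len(n), condition = "c1",
                   sub_type = "A>G",
                   E = rbinom(n, 1000L, 1e-4), R = 1000L,
                   coding = FALSE, abundance = NA_real_, gene_id = "g",
                   stringsAsFactors = FALSE)
  pe$E[1:3] <- 900L    # extreme
  pe$E[4:6] <- 12L     # moderate, hidden while the extreme tier inflates
  res <- filter_hotspots(pe, threshold = 1e-9, refine = FALSE)
  expect_gte(res$report$n_iterations, 2L)
  expect_true(all(1:6 %in% res$report$excluded_loci$pos))
  expect_true(res$report$converged)
  # per-iteration exclusions sum to the total
  expect_equal(sum(res$report$per_iteration$new_excluded),
               nrow(res$report$excluded_loci))
})
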