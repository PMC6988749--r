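test_that("loci map to unique genes; overlap and intergenic loci are excluded", {
  genes <- toy_genes(with_overlap = TRUE)
  sites <- bind_sites(toy_site(12, "A", 10),   # geneA only
                      toy_site(17, "C", 10),   # geneA and geneO overlap
                      toy_site(25, "G", 10),   # intergenic (geneO ends at 24)
                      toy_site(35, "G", 10))   # geneB
  res <- assign_loci(sites, genes)
  expect_equal(unname(res$tallies),
               c(2L, 1L, 1L))
  expect_equal(names(res$tallies), c("assigned", "overlap", "intergenic"))
  expect_setequal(res$assignment$gene_id, c("geneA", "geneB"))
  expect_false(17 %in% res$assignment$pos)
})

test_that("possible errors use transcript-strand substitution types", {
  genes <- toy_genes()
  # minus-strand geneB: genomic ref G with 2 reads of A must appear as
  # transcript-level C>U with E = 2
  sites <- toy_site(35, "G", 100, alt = "A", alt_n = 2)
  asgn <- assign_loci(sites, genes)
  built <- build_possible_errors(sites, asgn$assignment, genes,
                                 c(geneA = 5, geneB = 7))
  pe <- built$pe
  expect_equal(nrow(pe), 3L)                      # one record per alt base
  expect_setequal(pe$sub_type, c("C>A", "C>G", "C>U"))
  expect_equal(pe$E[pe$sub_type == "C>U"], 2L)
  expect_equal(pe$E[pe$sub_type == "C>A"], 0L)
  expect_true(all(pe$R == 100L))
  expect_true(all(pe$gene_id == "geneB"))
  expect_equal(unique(pe$abundance), 7)
  # abs_position on the transcript strand: genomic 35 in geneB [30,39) minus
  # strand is 39 - 35 + 1 = 5 nt from the gene start
  expect_true(all(pe$abs_position == 5L))
  expect_true(all(pe$rel_position == 5 / 9))
})

test_that("exclusions and the 3-per-site accounting identity hold", {
  genes <- toy_genes()
  sites <- bind_sites(
    toy_site(12, "A", 50),                      # retained (geneA, abundance)
    toy_site(13, "C", 0),                       # zero reads -> dropped
    toy_site(35, "G", 40),                      # geneB: no abundance -> dropped
    toy_site(52, "G", 30),                      # noncoding: kept, no abundance
    toy_site(25, "U", 10)                       # intergenic -> never a site
  )
  asgn <- assign_loci(sites, genes)
  built <- build_possible_errors(sites, asgn$assignment, genes,
                                 c(geneA = 12))
  acct <- built$accounting
  expect_equal(acct$sites_total, 4L)
  expect_equal(acct$sites_zero_reads, 1L)
  expect_equal(acct$sites_no_abundance, 1L)
  expect_equal(acct$sites_retained, 2L)
  expect_equal(acct$possible_errors, 3L * acct$sites_retained)
  expect_equal(nrow(built$pe), acct$possible_errors)
  # noncoding records carry NA abundance but are present
  expect_true(any(!built$pe$coding & is.na(built$pe$abundance)))
  # E never exceeds R
  expect_true(all(built$pe$E <= built$pe$R))
})

test_that("complementing the genome and flipping strands leaves possible errors invariant", {
  genes <- toy_genes()
  sites <- bind_sites(toy_site(12, "A", 100, alt = "G", alt_n = 3),
                      toy_site(14, "C", 60, alt = "U", alt_n = 1),
                      toy_site(35, "G", 80, alt = "A", alt_n = 2))
  flip_sites <- sites
  flip_sites$ref_base <- txerr:::.complement(sites$ref_base)
  flip_sites[, c("n_A", "n_C", "n_G", "n_U")] <-
    sites[, c("n_U", "n_G", "n_C", "n_A")]
  flip_genes <- genes
  flip_genes$strand <- ifelse(genes$strand == "+", "-", "+")

  ab <- c(geneA = 5, geneB = 7)
  pe1 <- build_possible_errors(sites, assign_loci(sites, genes)$assignment,
                               genes, ab)$pe
  pe2 <- build_possible_errors(flip_sites,
                               assign_loci(flip_sites, flip_genes)$assignment,
                               flip_genes, ab)$pe
  key <- function(p) {
    o <- order(p$pos, p$sub_type)
    p[o, c("pos", "condition", "sub_type", "E", "R", "gene_id")]
  }
  expect_equal(key(pe1), key(pe2), ignore_attr = TRUE)
})

test_that("synonymous classification matches the genetic code", {
  # codon CUG, 3rd position G>A -> CUA: Leu -> Leu, synonymous
  expect_true(classify_synonymous("AUGCUGUAA", 6, "A"))
  # codon AUG, 1st position A>G -> GUG: Met -> Val, nonsynonymous
  expect_false(classify_synonymous("AUGCUGUAA", 1, "G"))
  # stop is an amino-acid class: UAA position 2 A>G -> UGA, stop -> stop
  expect_true(classify_synonymous("AUGCUGUAA", 8, "G"))
  expect_error(classify_synonymous("AUGCUGUAA", 1, "A"), "equals")
  expect_error(classify_synonymous("AUGCUGUAA", 10, "A"), "offset")
  expect_error(classify_synonymous("AUGC", 1, "G"), "multiple of 3")
})

test_that("every substitution in a toy CDS agrees with a translate()-based oracle", {
  cds <- "AUGCUGUAA"
  bases <- strsplit(cds, "")[[1]]
  n_syn <- 0L
  for (off in seq_along(bases)) {
    for (alt in setdiff(c("A", "C", "G", "U"), bases[off])) {
      got <- classify_synonymous(cds, off, alt)
      expect_identical(got, oracle_synonymous(cds, off, alt),
                       info = paste(off, alt))
      n_syn <- n_syn + got
    }
  }
  # hand count: CUG has 4 synonymous substitutions, UAA has 2, AUG none
  expect_equal(n_syn, 6L)
})

test_that("expected synonymous fraction matches brute-force enumeration", {
  genes <- data.frame(gene_id = "g1", contig = "chr1", start = 0L,
                      end = 9L, strand = "+", coding = TRUE,
                      frame_ok = TRUE, stringsAsFactors = FALSE)
  sites <- sites_for_gene(genes[1, ], "AUGCUGUAA", reads = 100L)
  asgn <- assign_loci(sites, genes)
  built <- build_possible_errors(sites, asgn$assignment, genes, c(g1 = 10))
  pe <- annotate_synonymous(built$pe, genes, sites)
  expect_equal(nrow(pe), 27L)
  expect_false(anyNA(pe$synonymous))
  expect_equal(expected_synonymous_fraction(pe, "uniform"), 6 / 27)
  # an all-synonymous subset has fraction exactly 1
  expect_equal(expected_synonymous_fraction(pe[pe$synonymous, ], "uniform"), 1)
  expect_error(expected_synonymous_fraction(pe[0, ]), "no classified")
})

test_that("read-weighted synonymous fraction weights by error events", {
  pe <- data.frame(synonymous = c(TRUE, FALSE, FALSE),
                   E = c(6L, 2L, 0L), R = 100L)
  expect_equal(expected_synonymous_fraction(pe, "reads"), 6 / 8)
})
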