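# Shared fixtures, all built in code at test time.

# A tiny two-contig dataset exercised by the io / assignment tests:
# geneA (+, coding, positions 11..19), geneB (-, coding, 31..39),
# geneNC (+, noncoding, 51..56); geneA and an overlapping geneO share
# positions 16..19 when with_overlap = TRUE.
toy_genes <- function(with_overlap = FALSE) {
  g <- data.frame(
    gene_id = c("geneA", "geneB", "geneNC"),
    contig = "chr1",
    start = c(10L, 30L, 50L),
    end = c(19L, 39L, 56L),
    strand = c("+", "-", "+"),
    coding = c(TRUE, TRUE, FALSE),
    frame_ok = TRUE,
    stringsAsFactors = FALSE
  )
  if (with_overlap) {
    g <- rbind(g, data.frame(gene_id = "geneO", contig = "chr1",
                             start = 15L, end = 24L, strand = "+",
                             coding = TRUE, frame_ok = TRUE))
  }
  class(g) <- c("gene_records", class(g))
  g
}

# site counts with a given reference base and one alternative count
toy_site <- function(pos, ref, reads, alt = NULL, alt_n = 0L,
                     condition = "c1", contig = "chr1") {
  counts <- setNames(rep(0L, 4L), c("A", "C", "G", "U"))
  ref <- txerr:::.norm_base(ref)
  counts[ref] <- reads - alt_n
  if (!is.null(alt)) counts[txerr:::.norm_base(alt)] <- alt_n
  out <- data.frame(contig = contig, pos = as.integer(pos),
                    condition = condition, ref_base = ref,
                    n_A = counts[["A"]], n_C = counts[["C"]],
                    n_G = counts[["G"]], n_U = counts[["U"]],
                    reads = as.integer(reads), stringsAsFactors = FALSE)
  class(out) <- c("site_counts", class(out))
  out
}

bind_sites <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- unique(c("site_counts", class(out)))
  out
}

# site counts spelling out a full gene's reference sequence (transcript
# strand sequence given; stored genomic-strand)
sites_for_gene <- function(gene, tx_seq, reads = 100L, condition = "c1") {
  bases <- txerr:::.norm_base(strsplit(tx_seq, "")[[1]])
  stopifnot(length(bases) == gene$end - gene$start)
  if (gene$strand == "-") {
    bases <- rev(txerr:::.complement(bases))
  }
  do.call(bind_sites, lapply(seq_along(bases), function(i) {
    toy_site(gene$start + i, bases[i], reads, condition = condition,
             contig = gene$contig)
  }))
}

# construct a txerr_fit by hand from known coefficients (baseline +
# optional shared slope), for exact-arithmetic prediction checks
manual_fit <- function(baseline, slope = NULL, types = "A>G",
                       conditions = "c1") {
  cf <- c("(baseline)" = baseline)
  if (!is.null(slope)) cf <- c(cf, slope = slope)
  structure(list(
    coefficients = cf,
    vcov = diag(length(cf)),
    loglik = NA_real_, df = length(cf), nobs = 0L,
    converged = TRUE, boundary_hit = FALSE, iterations = 0L,
    terms = list(types = types, conditions = conditions,
                 type_intercepts = FALSE, condition_intercepts = FALSE,
                 slope = if (is.null(slope)) "none" else "shared",
                 slope_type = "G>A", covariate_names = NULL,
                 covariate_roles = NULL),
    pooled_rate = baseline, totals = c(E = 0, R = 0)
  ), class = "txerr_fit")
}

# independent oracle for synonymous classification: enumerate via
# Biostrings::translate, not via the package's codon logic
oracle_synonymous <- function(cds_rna, offset, alt) {
  s <- strsplit(chartr("U", "T", cds_rna), "")[[1]]
  aa0 <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(s, collapse = "")),
    no.init.codon = TRUE, if.fuzzy.codon = "error"))
  s2 <- s
  s2[offset] <- chartr("U", "T", alt)
  aa1 <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(s2, collapse = "")),
    no.init.codon = TRUE, if.fuzzy.codon = "error"))
  codon <- (offset - 1) %/% 3 + 1
  substr(aa0, codon, codon) == substr(aa1, codon, codon)
}
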