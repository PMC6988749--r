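# Locus-to-gene assignment and construction of possible-error records.

#' Assign nucleotide loci to genes
#'
#' Maps each observed locus to the unique gene whose interval contains it.
#' Loci covered by two or more gene intervals cannot be given a single
#' error rate or protein abundance and are excluded, as are intergenic
#' loci; both exclusions are tallied, not errors.
#'
#' @param sites a `site_counts` data frame (any number of conditions bound
#'   together; assignment is per locus, not per condition).
#' @param genes a `gene_records` data frame from [read_annotation()].
#' @return a list with components
#'   \describe{
#'     \item{assignment}{data frame `contig`, `pos`, `gene_id` for uniquely
#'       assigned loci;}
#'     \item{tallies}{named integer vector with counts of loci `assigned`,
#'       excluded for `overlap`, and `intergenic`.}
#'   }
#' @export
assign_loci <- function(sites, genes) {
  loci <- unique(data.frame(contig = sites$contig, pos = sites$pos,
                            stringsAsFactors = FALSE))
  if (nrow(loci) == 0L) {
    return(list(assignment = data.frame(contig = character(),
                                        pos = integer(),
                                        gene_id = character(),
                                        stringsAsFactors = FALSE),
                tallies = c(assigned = 0L, overlap = 0L, intergenic = 0L)))
  }
  locus_gr <- GenomicRanges::GRanges(
    seqnames = loci$contig,
    ranges = IRanges::IRanges(start = loci$pos, width = 1L)
  )
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  )
  hits <- GenomicRanges::findOverlaps(locus_gr, gene_gr,
                                      ignore.strand = TRUE)
  n_genes_per_locus <- tabulate(S4Vectors::queryHits(hits), nrow(loci))
  single <- n_genes_per_locus == 1L
  keep_hit <- single[S4Vectors::queryHits(hits)]
  assignment <- data.frame(
    contig = loci$contig[S4Vectors::queryHits(hits)[keep_hit]],
    pos = loci$pos[S4Vectors::queryHits(hits)[keep_hit]],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)[keep_hit]],
    stringsAsFactors = FALSE
  )
  list(assignment = assignment,
       tallies = c(assigned = sum(single),
                   overlap = sum(n_genes_per_locus >= 2L),
                   intergenic = sum(n_genes_per_locus == 0L)))
}

#' Build possible-error records
#'
#' Expands each retained site (a locus observed in one condition) into three
#' possible-error records, one per alternative base, on the transcript
#' strand: for minus-strand genes both the reference base and the observed
#' alternative counts are complemented, so substitution types always read as
#' mRNA substitutions (e.g. `G>A` at a genomic position in a minus-strand
#' gene appears as `C>U`).
#'
#' Exclusions applied here, in order, each tallied in the accounting report:
#' sites at unassigned loci (overlapping genes or intergenic), sites with
#' zero reads, coding-gene sites whose gene has no (or zero) protein
#' abundance, and sites whose reference base is inconsistent across
#' conditions at the same locus. Noncoding-gene sites are retained without
#' abundance (they are filterable but not modelled).
#'
#' @param sites a `site_counts` data frame covering all conditions.
#' @param assignment the `assignment` element from [assign_loci()].
#' @param genes a `gene_records` data frame.
#' @param abundance named abundance vector from [read_abundance()].
#' @return a list with components
#'   \describe{
#'     \item{pe}{a data frame of class `possible_errors`, one row per
#'       (locus, condition, substitution type): `contig`, `pos`,
#'       `condition`, `sub_type` (e.g. `"C>U"`), `E`, `R`, `gene_id`,
#'       `coding`, `abundance` (`NA` for noncoding), `gene_length`,
#'       `abs_position` (1-based nt from gene start on the transcript
#'       strand), `rel_position`;}
#'     \item{accounting}{named list of locus/site/possible-error counts at
#'       every exclusion step (`loci_observed`, `loci_assigned`,
#'       `sites_total`, `sites_zero_reads`, `sites_no_abundance`,
#'       `sites_ref_mismatch`, `sites_retained`, `possible_errors`).}
#'   }
#' @export
build_possible_errors <- function(sites, assignment, genes, abundance) {
  acct <- list()
  acct$loci_observed <- nrow(unique(sites[, c("contig", "pos")]))
  acct$loci_assigned <- nrow(assignment)

  key_site <- .locus_key(sites$contig, sites$pos)
  key_asgn <- .locus_key(assignment$contig, assignment$pos)
  idx <- match(key_site, key_asgn)
  assigned <- !is.na(idx)
  acct$sites_total <- sum(assigned)

  df <- sites[assigned, , drop = FALSE]
  df$gene_id <- assignment$gene_id[idx[assigned]]

  gidx <- match(df$gene_id, genes$gene_id)
  df$strand <- genes$strand[gidx]
  df$coding <- genes$coding[gidx]
  df$gene_start <- genes$start[gidx]
  df$gene_end <- genes$end[gidx]

  # reference base must be consistent across conditions at a locus
  k <- .locus_key(df$contig, df$pos)
  ur <- unique(paste(k, df$ref_base, sep = "|"))
  uk <- sub("\\|[ACGU]$", "", ur)
  bad_loci <- unique(uk[duplicated(uk)])
  ref_mismatch <- k %in% bad_loci
  acct$sites_ref_mismatch <- sum(ref_mismatch)
  df <- df[!ref_mismatch, , drop = FALSE]

  zero_reads <- df$reads == 0L
  acct$sites_zero_reads <- sum(zero_reads)
  df <- df[!zero_reads, , drop = FALSE]

  df$abundance <- unname(abundance[df$gene_id])
  no_ab <- df$coding & (is.na(df$abundance) | df$abundance <= 0)
  acct$sites_no_abundance <- sum(no_ab)
  df <- df[!no_ab, , drop = FALSE]
  df$abundance[!df$coding] <- NA_real_

  acct$sites_retained <- nrow(df)
  acct$possible_errors <- 3L * nrow(df)

  if (nrow(df) == 0L) {
    pe <- data.frame(contig = character(), pos = integer(),
                     condition = character(), sub_type = character(),
                     E = integer(), R = integer(), gene_id = character(),
                     coding = logical(), abundance = numeric(),
                     gene_length = integer(), abs_position = integer(),
                     rel_position = numeric(), stringsAsFactors = FALSE)
    class(pe) <- c("possible_errors", class(pe))
    return(list(pe = pe, accounting = acct))
  }

  # transcript-strand reference base and per-base counts
  minus <- df$strand == "-"
  tref <- df$ref_base
  tref[minus] <- .complement(tref[minus])

  # counts keyed by transcript-strand base: on minus strand the transcript
  # base X was observed as complement(X) on the genomic strand
  cnt <- as.matrix(df[, c("n_A", "n_C", "n_G", "n_U")])
  colnames(cnt) <- RNA_BASES
  tcnt <- cnt
  tcnt[minus, ] <- cnt[minus, c("U", "G", "C", "A")]

  # three alternative bases per site, transcript strand
  alt_lookup <- rbind(A = c("C", "G", "U"), C = c("A", "G", "U"),
                      G = c("A", "C", "U"), U = c("A", "C", "G"))
  alt_mat <- alt_lookup[tref, , drop = FALSE]
  n <- nrow(df)
  rep3 <- rep(seq_len(n), each = 3L)
  alt <- as.vector(t(alt_mat))
  E <- tcnt[cbind(rep3, match(alt, RNA_BASES))]

  gene_length <- df$gene_end - df$gene_start
  abs_pos <- ifelse(minus, df$gene_end - df$pos + 1L,
                    df$pos - df$gene_start)

  pe <- data.frame(
    contig = df$contig[rep3],
    pos = df$pos[rep3],
    condition = df$condition[rep3],
    sub_type = paste0(tref[rep3], ">", alt),
    E = as.integer(E),
    R = df$reads[rep3],
    gene_id = df$gene_id[rep3],
    coding = df$coding[rep3],
    abundance = df$abundance[rep3],
    gene_length = as.integer(gene_length[rep3]),
    abs_position = as.integer(abs_pos[rep3]),
    rel_position = abs_pos[rep3] / gene_length[rep3],
    stringsAsFactors = FALSE
  )
  class(pe) <- c("possible_errors", class(pe))
  list(pe = pe, accounting = acct)
}

#' All 12 substitution types, and the standard analysis subsets
#'
#' @param subset one of `"all"` (12 types), `"non-CU"` (11 types,
#'   excluding `C>U`), `"non-CU-GA"` (10 types, excluding `C>U` and
#'   `G>A`), or `"CU"` (`C>U` alone).
#' @return character vector of substitution type labels (`"X>Y"`).
#' @export
sub_types <- function(subset = c("all", "non-CU", "non-CU-GA", "CU")) {
  subset <- match.arg(subset)
  all_types <- as.vector(outer(RNA_BASES, RNA_BASES, function(a, b)
    paste0(a, ">", b)))
  all_types <- all_types[substr(all_types, 1, 1) !=
                           substr(all_types, 3, 3)]
  all_types <- sort(all_types)
  switch(subset,
         all = all_types,
         `non-CU` = setdiff(all_types, "C>U"),
         `non-CU-GA` = setdiff(all_types, c("C>U", "G>A")),
         CU = "C>U")
}
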