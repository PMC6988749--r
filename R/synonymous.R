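# Synonymous/nonsynonymous classification of possible errors under the
# standard genetic code. Stop codons are treated as an amino-acid class of
# their own (stop->stop substitutions are synonymous).

# amino acid (or "*") for an RNA codon string, standard code
.codon_aa <- function(codons) {
  dna <- chartr("U", "T", codons)
  aa <- Biostrings::GENETIC_CODE[dna]
  if (anyNA(aa)) {
    stop("invalid codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "))
  }
  unname(aa)
}

#' Classify a single substitution as synonymous or not
#'
#' Given a coding sequence on the transcript strand, a position within it
#' and an alternative base, reports whether the substituted codon encodes
#' the same amino acid under the standard genetic code. Stop is treated as
#' an amino-acid class, so a stop-codon position can have synonymous
#' substitutions.
#'
#' @param cds coding sequence (single string, RNA or DNA alphabet), length a
#'   multiple of 3.
#' @param offset 1-based position of the substituted nucleotide within
#'   `cds`.
#' @param alt the alternative base; must differ from the reference base at
#'   `offset`.
#' @return `TRUE` if the substitution is synonymous.
#' @examples
#' classify_synonymous("AUGCUG", 6, "A")  # CUG -> CUA, both Leu: TRUE
#' classify_synonymous("AUGCUG", 1, "G")  # AUG -> GUG, Met -> Val: FALSE
#' @export
classify_synonymous <- function(cds, offset, alt) {
  cds <- .norm_base(strsplit(toupper(cds), "")[[1L]])
  n <- length(cds)
  if (n %% 3L != 0L) stop("CDS length must be a multiple of 3")
  if (length(offset) != 1L || offset < 1L || offset > n) {
    stop("offset outside CDS")
  }
  alt <- .norm_base(alt)
  if (alt == cds[offset]) stop("alternative base equals the reference base")
  codon_start <- offset - (offset - 1L) %% 3L
  codon <- cds[codon_start:(codon_start + 2L)]
  mutated <- codon
  mutated[(offset - 1L) %% 3L + 1L] <- alt
  .codon_aa(paste(codon, collapse = "")) ==
    .codon_aa(paste(mutated, collapse = ""))
}

# Reconstruct per-contig reference sequences (RNA alphabet, genomic strand)
# from the ref_base column of the site-count tables. Returns a list of
# character vectors indexed by 1-based position; positions never observed
# are NA.
.genome_from_sites <- function(sites) {
  out <- list()
  for (ctg in unique(sites$contig)) {
    s <- sites[sites$contig == ctg, , drop = FALSE]
    v <- rep(NA_character_, max(s$pos))
    v[s$pos] <- s$ref_base
    out[[ctg]] <- v
  }
  out
}

#' Annotate possible errors with synonymous status
#'
#' Adds a logical `synonymous` column to a possible-error table by
#' reconstructing each coding gene's CDS from the reference bases of the
#' site-count tables (no separate genome FASTA is needed: the count tables
#' carry the reference base of every observed locus). Noncoding records and
#' records in genes with incomplete coverage or out-of-frame lengths get
#' `NA`.
#'
#' @param pe a `possible_errors` data frame.
#' @param genes a `gene_records` data frame.
#' @param sites the `site_counts` data the possible errors were built from
#'   (used only for its reference bases).
#' @return `pe` with a `synonymous` column added.
#' @export
annotate_synonymous <- function(pe, genes, sites) {
  genome <- .genome_from_sites(sites)
  pe$synonymous <- NA
  gidx <- match(pe$gene_id, genes$gene_id)
  target <- which(pe$coding & genes$frame_ok[gidx])

  if (!length(target)) return(pe)

  # per-record codon retrieval: transcript-strand base at transcript
  # position abs_position +/- its codon neighbours
  rows <- pe[target, , drop = FALSE]
  g <- genes[gidx[target], , drop = FALSE]
  minus <- g$strand == "-"

  # genomic position of transcript offset k (1-based):
  #   plus strand:  start0 + k ; minus strand: end - k + 1
  tpos_to_gpos <- function(k) ifelse(minus, g$end - k + 1L, g$start + k)

  codon_off <- (rows$abs_position - 1L) %% 3L            # 0,1,2 within codon
  codon_first <- rows$abs_position - codon_off           # transcript pos of codon start

  base_at <- function(tpos) {
    gpos <- tpos_to_gpos(tpos)
    b <- rep(NA_character_, length(gpos))
    for (ctg in unique(rows$contig)) {
      sel <- rows$contig == ctg
      v <- genome[[ctg]]
      ok <- sel & gpos >= 1L & gpos <= length(v)
      b[ok] <- v[gpos[ok]]
    }
    b[minus & !is.na(b)] <- .complement(b[minus & !is.na(b)])
    b
  }
  b1 <- base_at(codon_first)
  b2 <- base_at(codon_first + 1L)
  b3 <- base_at(codon_first + 2L)
  complete <- !is.na(b1) & !is.na(b2) & !is.na(b3)

  codon <- paste0(b1, b2, b3)
  alt <- substr(rows$sub_type, 3L, 3L)
  mutated <- codon
  for (j in 0:2) {
    sel <- codon_off == j & complete
    substr(mutated[sel], j + 1L, j + 1L) <- alt[sel]
  }
  syn <- rep(NA, nrow(rows))
  syn[complete] <- .codon_aa(codon[complete]) == .codon_aa(mutated[complete])
  pe$synonymous[target] <- syn
  pe
}

#' Fraction of possible errors (or error events) that are synonymous
#'
#' With `weighting = "uniform"` this is the fraction of possible-error
#' records whose substitution would be synonymous — the "at random across
#' the genome" expectation. With `weighting = "reads"` each record is
#' weighted by its observed error count `E`, giving the synonymous fraction
#' of observed error events.
#'
#' @param pe a `possible_errors` data frame with a `synonymous` column.
#' @param weighting `"uniform"` or `"reads"`.
#' @return a fraction in `[0, 1]`.
#' @export
expected_synonymous_fraction <- function(pe,
                                         weighting = c("uniform", "reads")) {
  weighting <- match.arg(weighting)
  if (is.null(pe$synonymous)) {
    stop("possible errors carry no synonymous column; run annotate_synonymous()")
  }
  ok <- !is.na(pe$synonymous)
  if (!any(ok)) stop("no classified possible errors")
  syn <- pe$synonymous[ok]
  if (weighting == "uniform") {
    mean(syn)
  } else {
    w <- pe$E[ok]
    if (sum(w) == 0) stop("no observed error events to weight by")
    sum(w * syn) / sum(w)
  }
}
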