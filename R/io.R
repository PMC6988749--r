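# Input readers and output writers for the standard file dialects:
# per-site base-count TSV, GFF3 annotation, abundance TSV.

#' Read a per-site base-count table
#'
#' Reads one condition's per-site base counts from a tab-separated file with
#' header columns `contig`, `position`, `ref_base`, `n_A`, `n_C`, `n_G`,
#' `n_T`. Positions are 1-based genomic coordinates; counts are reported on
#' the genomic (plus) strand. An optional `reads` column, if present, must
#' equal the sum of the four base counts on every row.
#'
#' Reference bases are normalised to the RNA alphabet (`T` becomes `U`)
#' because downstream error types are expressed as mRNA substitutions.
#' Rows with zero total reads are retained; they are excluded later, when
#' possible-error records are built.
#'
#' @param path path to the TSV file.
#' @param condition a condition label attached to every row (e.g.
#'   `"rich_midlog"`).
#' @return a `data.frame` of class `site_counts` with columns `contig`,
#'   `pos`, `condition`, `ref_base` (RNA alphabet), `n_A`, `n_C`, `n_G`,
#'   `n_U` (genomic-strand counts; `n_U` holds the file's `n_T`), and
#'   `reads` (the row sum).
#' @seealso [write_site_counts()], [build_possible_errors()]
#' @export
read_site_counts <- function(path, condition) {
  stopifnot(is.character(path), length(path) == 1L,
            is.character(condition), length(condition) == 1L)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "contig"),
                          data.table = FALSE, showProgress = FALSE)
  required <- c("contig", "position", "ref_base", "n_A", "n_C", "n_G", "n_T")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("count table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(dt) == 0L) {
    out <- data.frame(contig = character(), pos = integer(),
                      condition = character(), ref_base = character(),
                      n_A = integer(), n_C = integer(), n_G = integer(),
                      n_U = integer(), reads = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("site_counts", class(out))
    return(out)
  }
  counts <- as.matrix(dt[, c("n_A", "n_C", "n_G", "n_T")])
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    bad <- which(rowSums(is.na(counts) | counts < 0 |
                           counts != round(counts)) > 0)[1L]
    stop("malformed count row at line ", bad + 1L, " of ", path,
         ": counts must be nonnegative integers")
  }
  reads <- as.integer(rowSums(counts))
  if ("reads" %in% names(dt)) {
    mism <- which(dt$reads != reads)
    if (length(mism)) {
      stop("inconsistent counts at line ", mism[1L] + 1L, " of ", path,
           ": reads column (", dt$reads[mism[1L]],
           ") != sum of base counts (", reads[mism[1L]], ")")
    }
  }
  key <- .locus_key(dt$contig, dt$position)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate locus ", dup, " in ", path,
         " (positions must be unique per contig and condition)")
  }
  out <- data.frame(contig = as.character(dt$contig),
                    pos = as.integer(dt$position),
                    condition = condition,
                    ref_base = .norm_base(dt$ref_base),
                    n_A = as.integer(dt$n_A), n_C = as.integer(dt$n_C),
                    n_G = as.integer(dt$n_G), n_U = as.integer(dt$n_T),
                    reads = reads, stringsAsFactors = FALSE)
  class(out) <- c("site_counts", class(out))
  out
}

#' Write a per-site base-count table
#'
#' Inverse of [read_site_counts()]: writes the on-disk dialect (column
#' `n_T`, DNA-alphabet reference base) so that a write/read round trip
#' reproduces the records exactly.
#'
#' @param sites a `site_counts` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(sites, path) {
  ref <- sites$ref_base
  ref[ref == "U"] <- "T"
  out <- data.frame(contig = sites$contig, position = sites$pos,
                    ref_base = ref, n_A = sites$n_A, n_C = sites$n_C,
                    n_G = sites$n_G, n_T = sites$n_U,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read gene models from a GFF3 annotation
#'
#' Imports `gene` and `CDS` features and returns one record per gene in the
#' internal 0-based half-open coordinate convention (GFF3 is 1-based
#' inclusive; conversion happens only at this boundary). A gene is flagged
#' as coding when a CDS feature points at it via `Parent` (or when its
#' `gene_biotype`/`biotype` attribute is `"protein_coding"`). Coding genes
#' whose span is not a multiple of 3 are kept but flagged, with a warning.
#'
#' Features without a strand or without an ID are skipped; the number
#' skipped is recorded in the `"skipped"` attribute of the result.
#'
#' @param path path to a GFF3 file.
#' @return a `data.frame` of class `gene_records` with columns `gene_id`,
#'   `contig`, `start` (0-based), `end` (half-open, i.e. the GFF3 end),
#'   `strand` (`"+"`/`"-"`), `coding` (logical) and `frame_ok` (logical;
#'   `FALSE` when a coding gene's length is not a multiple of 3).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  genes <- gr[type == "gene"]
  gmeta <- S4Vectors::mcols(genes)
  ids <- as.character(gmeta$ID)
  strand <- as.character(GenomicRanges::strand(genes))
  keep <- !is.na(ids) & ids != "" & strand %in% c("+", "-")
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(n_skipped, " gene feature(s) without strand or ID were skipped")
  }
  genes <- genes[keep]
  gmeta <- S4Vectors::mcols(genes)
  ids <- as.character(gmeta$ID)

  cds <- gr[type == "CDS"]
  cds_parents <- character(0)
  if (length(cds)) {
    p <- S4Vectors::mcols(cds)$Parent
    cds_parents <- unique(unlist(as.list(p)))
  }
  biotype <- rep(NA_character_, length(genes))
  for (col in c("gene_biotype", "biotype")) {
    if (col %in% names(gmeta)) {
      v <- as.character(gmeta[[col]])
      biotype[is.na(biotype)] <- v[is.na(biotype)]
    }
  }
  coding <- ids %in% cds_parents |
    (!is.na(biotype) & biotype == "protein_coding")

  out <- data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    coding = coding,
    stringsAsFactors = FALSE
  )
  out$frame_ok <- !out$coding | ((out$end - out$start) %% 3L == 0L)
  if (any(!out$frame_ok)) {
    warning(sum(!out$frame_ok),
            " coding gene(s) whose length is not a multiple of 3 were flagged")
  }
  attr(out, "skipped") <- n_skipped
  class(out) <- c("gene_records", class(out))
  out
}

#' Write gene models to GFF3
#'
#' Converts internal 0-based half-open gene records back to 1-based
#' inclusive GFF3 `gene` features (with a matching `CDS` line for coding
#' genes), so that annotation coordinates round-trip exactly.
#'
#' @param genes a `gene_records` data frame (see [read_annotation()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$gene_biotype <-
    ifelse(genes$coding, "protein_coding", "noncoding")
  cds <- gr[genes$coding]
  if (length(cds)) {
    S4Vectors::mcols(cds)$type <- "CDS"
    S4Vectors::mcols(cds)$phase <- 0L
    cds_ids <- S4Vectors::mcols(cds)$ID
    S4Vectors::mcols(cds)$Parent <- as.character(cds_ids)
    S4Vectors::mcols(cds)$ID <- paste0("cds-", cds_ids)
    gr <- c(gr, cds)
  }
  rtracklayer::export(sort(gr), path, format = "gff3")
  invisible(path)
}

#' Read a gene-level protein abundance table
#'
#' Reads a two-column TSV (gene id, abundance in ppm). Genes with zero or
#' missing abundance are dropped from the mapping — they trigger exclusion
#' of their sites downstream — and tallied in the `"excluded_zero"`
#' attribute. Negative abundances are a validation error. When a gene id
#' appears more than once the last value wins, with a warning.
#'
#' @param path path to the TSV file (header optional; the first two columns
#'   are used).
#' @return a named numeric vector mapping gene id to abundance (> 0), with
#'   attribute `excluded_zero` giving the number of genes dropped for zero
#'   or missing abundance.
#' @export
read_abundance <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          data.table = FALSE, showProgress = FALSE)
  if (ncol(dt) < 2L) stop("abundance table must have two columns")
  ids <- as.character(dt[[1L]])
  ab <- suppressWarnings(as.numeric(dt[[2L]]))
  if (any(!is.na(ab) & ab < 0)) {
    stop("negative abundance for gene ",
         ids[which(!is.na(ab) & ab < 0)[1L]])
  }
  if (anyDuplicated(ids)) {
    warning(sum(duplicated(ids)),
            " duplicate gene id(s) in abundance table; last value wins")
  }
  # last value wins for duplicates, then zero/missing entries are dropped
  last <- !duplicated(ids, fromLast = TRUE)
  ids <- ids[last]
  ab <- ab[last]
  keep <- !is.na(ab) & ab > 0
  excluded_zero <- sum(!keep)
  out <- setNames(ab[keep], ids[keep])
  attr(out, "excluded_zero") <- excluded_zero
  out
}

#' Write possible-error records to TSV
#'
#' @param pe a possible-error data frame (see [build_possible_errors()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_possible_errors <- function(pe, path) {
  data.table::fwrite(as.data.frame(pe), path, sep = "\t", na = "NA")
  invisible(path)
}

#' Write excluded hotspot loci as BED
#'
#' Writes one 1-bp BED interval (0-based half-open) per excluded locus.
#'
#' @param report a `hotspot_report` (see [filter_hotspots()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hotspot_bed <- function(report, path) {
  loci <- report$excluded_loci
  bed <- data.frame(chrom = loci$contig, start = loci$pos - 1L,
                    end = loci$pos, stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
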