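# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes: per-site reads as exposure, error counts binomial in
# reads with a rate linear in log10 protein abundance plus type/condition
# intercepts, rare hotspot loci with inflated rates, and an
# abundance-independent C>U artifact mode. Binomial (not Poisson) draws are
# used deliberately: they are exact at any rate, the Poisson model being
# the fitting approximation.

#' Synthetic dataset configuration
#'
#' Builds and validates a generator configuration. The `"realistic"` preset
#' mirrors the study regime: four experimental conditions, mean depth ~100
#' reads/site, non-C>U intercepts ~1.4e-5 errors/read (G>A 3.0e-5), shared
#' abundance slope -8.4e-7 per decade with a steeper G>A slope of -2.9e-6,
#' and an abundance-independent C>U mode at 1.0e-4. The `"scaled"` preset
#' (intercepts ~1e-3, slope -1e-4/decade, depth 1e3, three conditions,
#' 2,000 short genes) trades realism for statistical power so that
#' parameter-recovery runs are fast.
#'
#' @param preset `"realistic"` or `"scaled"`; individual fields can then be
#'   overridden by name.
#' @param ... overrides of any configuration field: `n_genes`,
#'   `gene_length_mean`, `gene_length_dispersion` (negative-binomial size
#'   for the codon count), `conditions`, `depth_mean`, `depth_coupling`
#'   (reads scale with `(abundance / 10^abund_mu)^coupling`),
#'   `base_intercept`, `ga_intercept`, `cu_intercept` (errors/read at 1
#'   ppm), `slope`, `ga_slope`, `cu_slope` (errors/read per decade),
#'   `abund_mu`, `abund_sigma` (log10 ppm), `hotspot_fraction`,
#'   `hotspot_multiplier`, `cu_artifact` (logical; `FALSE` gives C>U the
#'   shared slope), `overlap_fraction`, `noncoding_fraction`,
#'   `missing_abundance_fraction`, `intergenic_gap_mean`, `contig`, `seed`.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(preset = c("realistic", "scaled"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "realistic") {
    list(
      n_genes = 150L,
      gene_length_mean = 300,
      gene_length_dispersion = 5,
      conditions = c("rich_midlog", "rich_stationary",
                     "minimal_midlog", "minimal_stationary"),
      depth_mean = 100,
      depth_coupling = 0.5,
      base_intercept = 1.4e-5,
      ga_intercept = 3.0e-5,
      cu_intercept = 1.0e-4,
      slope = -8.4e-7,
      ga_slope = -2.9e-6,
      cu_slope = 0,
      abund_mu = 1.5,
      abund_sigma = 1,
      hotspot_fraction = 0,
      hotspot_multiplier = 50,
      cu_artifact = TRUE,
      overlap_fraction = 0,
      noncoding_fraction = 0.05,
      missing_abundance_fraction = 0.1,
      intergenic_gap_mean = 50,
      contig = "chrSim",
      seed = 1L
    )
  } else {
    list(
      n_genes = 2000L,
      gene_length_mean = 6,
      gene_length_dispersion = 1e6,
      conditions = c("c1", "c2", "c3"),
      depth_mean = 1000,
      depth_coupling = 0,
      base_intercept = 1e-3,
      ga_intercept = 1e-3,
      cu_intercept = 2e-3,
      slope = -1e-4,
      ga_slope = -1e-4,
      cu_slope = 0,
      abund_mu = 2,
      abund_sigma = 1,
      hotspot_fraction = 0,
      hotspot_multiplier = 50,
      cu_artifact = TRUE,
      overlap_fraction = 0,
      noncoding_fraction = 0,
      missing_abundance_fraction = 0,
      intergenic_gap_mean = 20,
      contig = "chrSim",
      seed = 1L
    )
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  cfg$preset <- preset

  # feasibility: every true rate must be nonnegative across the abundance
  # range the distribution will effectively produce (+/- 4 sd)
  xr <- cfg$abund_mu + c(-4, 4) * cfg$abund_sigma
  rates <- c(cfg$base_intercept + cfg$slope * xr,
             cfg$ga_intercept + cfg$ga_slope * xr,
             cfg$cu_intercept +
               (if (cfg$cu_artifact) cfg$cu_slope else cfg$slope) * xr)
  if (any(rates < 0)) {
    stop("infeasible config: a true rate goes negative within the ",
         "abundance range (check intercepts vs slopes)")
  }
  if (cfg$gene_length_mean < 6) stop("gene_length_mean must be >= 6")
  class(cfg) <- "synth_config"
  cfg
}

# true per-read rate for transcript-strand substitution types, given the
# config and log10 abundance x (NA abundance -> rate at the intercept)
.true_rate <- function(cfg, sub_type, x) {
  x <- ifelse(is.na(x), 0, x)
  ga <- sub_type == "G>A"
  cu <- sub_type == "C>U"
  cu_slope <- if (cfg$cu_artifact) cfg$cu_slope else cfg$slope
  rate <- cfg$base_intercept + cfg$slope * x
  rate[ga] <- cfg$ga_intercept + cfg$ga_slope * x[ga]
  rate[cu] <- cfg$cu_intercept + cu_slope * x[cu]
  pmin(pmax(rate, 0), 0.25)
}

#' Generate a synthetic dataset on disk
#'
#' Writes per-condition base-count TSVs, a GFF3 annotation, an abundance
#' TSV and a truth record (JSON) into `dir`, in exactly the dialects the
#' ingest functions read. Genes are placed on both strands of one synthetic
#' contig; intergenic gap loci are included in the count tables (they
#' exercise the intergenic exclusion), reads are Poisson around the depth
#' model, and error counts are Binomial(R, rate) with the rate from the
#' true linear model, inflated at hotspot loci (one substitution type per
#' hotspot, all conditions). The same seed and config give byte-identical
#' files.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file `paths` and the `truth` record
#'   (true coefficients, per-gene table, hotspot loci, overlap loci).
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  cfg <- config
  n <- cfg$n_genes

  codons <- pmax(2L, rnbinom(n, size = cfg$gene_length_dispersion,
                             mu = cfg$gene_length_mean / 3))
  len <- 3L * codons
  strand <- sample(c("+", "-"), n, replace = TRUE)
  coding <- runif(n) >= cfg$noncoding_fraction
  overlap_prev <- runif(n) < cfg$overlap_fraction
  overlap_prev[1L] <- FALSE

  start <- integer(n)  # 0-based
  cursor <- 0L
  gaps <- rpois(n, cfg$intergenic_gap_mean)
  overlap_loci <- integer(0)
  for (i in seq_len(n)) {
    if (overlap_prev[i]) {
      ov <- min(9L, len[i - 1L] - 3L, len[i] - 3L)
      start[i] <- cursor - ov
      overlap_loci <- c(overlap_loci, (start[i] + 1L):cursor)
    } else {
      start[i] <- cursor + gaps[i]
    }
    cursor <- start[i] + len[i]
  }
  end <- start + len
  gene_id <- sprintf("g%04d", seq_len(n))

  genes <- data.frame(gene_id = gene_id, contig = cfg$contig,
                      start = start, end = end, strand = strand,
                      coding = coding,
                      frame_ok = TRUE, stringsAsFactors = FALSE)
  class(genes) <- c("gene_records", class(genes))

  # abundances (log10-normal); noncoding genes get none
  ab <- 10^rnorm(n, cfg$abund_mu, cfg$abund_sigma)
  ab_missing <- coding & (runif(n) < cfg$missing_abundance_fraction)

  # genome: random bases at every position up to the last gene end
  glen <- max(end)
  genome <- sample(RNA_BASES, glen, replace = TRUE)

  # map every genomic position to its gene (first gene wins in overlaps;
  # assignment excludes those loci anyway)
  gene_at <- rep(NA_integer_, glen)
  for (i in rev(seq_len(n))) gene_at[(start[i] + 1L):end[i]] <- i

  pos <- seq_len(glen)
  gidx <- gene_at
  genic <- !is.na(gidx)

  # hotspot loci: among genic loci, one inflated substitution type each
  n_hot <- round(cfg$hotspot_fraction * sum(genic))
  hot_pos <- if (n_hot > 0) sort(sample(pos[genic], n_hot)) else integer(0)
  hot_alt <- character(length(hot_pos))

  # per-position transcript-strand ref base and log10 abundance
  minus <- genic & strand[gidx] == "-"
  tref <- genome
  tref[minus] <- .complement(genome[minus])
  x <- rep(NA_real_, glen)
  has_ab <- genic & coding[gidx]
  x[has_ab] <- log10(ab[gidx[has_ab]])

  alt_lookup <- rbind(A = c("C", "G", "U"), C = c("A", "G", "U"),
                      G = c("A", "C", "U"), U = c("A", "C", "G"))
  alts <- alt_lookup[tref, , drop = FALSE]  # transcript strand
  if (length(hot_pos)) {
    pick <- sample.int(3L, length(hot_pos), replace = TRUE)
    hot_alt <- alts[cbind(hot_pos, pick)]
  }

  # per-read depth scale from the abundance coupling
  depth <- rep(cfg$depth_mean, glen)
  if (cfg$depth_coupling != 0) {
    sc <- rep(1, glen)
    sc[has_ab] <- (ab[gidx[has_ab]] / 10^cfg$abund_mu)^cfg$depth_coupling
    depth <- depth * sc
  }

  paths <- list()
  for (cond in cfg$conditions) {
    R <- rpois(glen, depth)
    cnt <- matrix(0L, glen, 4L, dimnames = list(NULL, RNA_BASES))
    for (k in 1:3) {
      alt_t <- alts[, k]
      rate <- .true_rate(cfg, paste0(tref, ">", alt_t), x)
      if (length(hot_pos)) {
        hit <- hot_pos[hot_alt == alt_t[hot_pos]]
        rate[hit] <- pmin(rate[hit] * cfg$hotspot_multiplier, 0.25)
      }
      E <- rbinom(glen, R, rate)
      # map the transcript-strand alternative back to the genomic strand
      alt_g <- ifelse(minus, .complement(alt_t), alt_t)
      idx4 <- match(alt_g, RNA_BASES)
      cnt[cbind(seq_len(glen), idx4)] <-
        cnt[cbind(seq_len(glen), idx4)] + E
    }
    err_tot <- as.integer(rowSums(cnt))
    ref_n <- pmax(R - err_tot, 0L)
    cnt[cbind(seq_len(glen), match(genome, RNA_BASES))] <-
      cnt[cbind(seq_len(glen), match(genome, RNA_BASES))] + ref_n
    ref_out <- genome
    ref_out[ref_out == "U"] <- "T"
    tab <- data.frame(contig = cfg$contig, position = pos,
                      ref_base = ref_out,
                      n_A = cnt[, "A"], n_C = cnt[, "C"],
                      n_G = cnt[, "G"], n_T = cnt[, "U"],
                      stringsAsFactors = FALSE)
    f <- file.path(dir, paste0("counts_", cond, ".tsv"))
    data.table::fwrite(tab, f, sep = "\t")
    paths[[paste0("counts_", cond)]] <- f
  }

  gff <- file.path(dir, "genes.gff3")
  write_annotation(genes, gff)
  paths$annotation <- gff

  ab_out <- ab
  ab_out[ab_missing] <- 0
  abfile <- file.path(dir, "abundance.tsv")
  data.table::fwrite(data.frame(gene_id = gene_id[coding],
                                abundance = ab_out[coding]),
                     abfile, sep = "\t")
  paths$abundance <- abfile

  truth <- list(
    config = unclass(cfg),
    coefficients = list(base_intercept = cfg$base_intercept,
                        ga_intercept = cfg$ga_intercept,
                        cu_intercept = cfg$cu_intercept,
                        slope = cfg$slope, ga_slope = cfg$ga_slope,
                        cu_slope = if (cfg$cu_artifact) cfg$cu_slope else cfg$slope),
    genes = data.frame(gene_id = gene_id, start = start, end = end,
                       strand = strand, coding = coding,
                       abundance = ab, abundance_reported = !ab_missing,
                       stringsAsFactors = FALSE),
    hotspots = data.frame(contig = rep(cfg$contig, length(hot_pos)),
                          pos = hot_pos, sub_type =
                            if (length(hot_pos))
                              paste0(tref[hot_pos], ">", hot_alt)
                            else character(0),
                          stringsAsFactors = FALSE),
    overlap_loci = sort(unique(overlap_loci))
  )
  tf <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tf, auto_unbox = TRUE, digits = NA)
  paths$truth <- tf
  invisible(list(paths = paths, truth = truth))
}

#' Simulate possible-error records in memory
#'
#' Fast path for statistical simulations (parameter recovery, type-I error,
#' hotspot recall): draws possible-error records directly from the
#' generating model without writing files or running the assignment stage.
#' Each gene contributes `loci_per_gene` loci with a uniformly random
#' reference base; reads are Poisson(`depth_mean`) per site and condition,
#' error counts Binomial(R, rate).
#'
#' @param config a [synth_config()]; `n_genes`, `conditions`,
#'   `depth_mean`, the intercepts/slopes and the abundance distribution
#'   are taken from it.
#' @param loci_per_gene loci simulated per gene (default 6).
#' @param hotspot_loci number of hotspot loci to inject (default 0); each
#'   gets one substitution type's rate multiplied by
#'   `config$hotspot_multiplier` in all conditions.
#' @param seed optional seed (defaults to `config$seed`).
#' @return a `possible_errors` data frame (records with zero reads are
#'   dropped, as the pipeline would); the generating truth is attached as
#'   attribute `"truth"` (coefficients and hotspot loci).
#' @export
sim_possible_errors <- function(config, loci_per_gene = 6L,
                                hotspot_loci = 0L, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  cfg <- config
  n <- cfg$n_genes
  n_loci <- n * loci_per_gene
  gene_of <- rep(seq_len(n), each = loci_per_gene)
  ab <- 10^rnorm(n, cfg$abund_mu, cfg$abund_sigma)
  tref <- sample(RNA_BASES, n_loci, replace = TRUE)
  pos <- seq_len(n_loci)

  hot_pos <- if (hotspot_loci > 0) {
    sort(sample.int(n_loci, hotspot_loci))
  } else integer(0)

  alt_lookup <- rbind(A = c("C", "G", "U"), C = c("A", "G", "U"),
                      G = c("A", "C", "U"), U = c("A", "C", "G"))
  alts <- alt_lookup[tref, , drop = FALSE]
  hot_alt <- if (length(hot_pos)) {
    alts[cbind(hot_pos, sample.int(3L, length(hot_pos), replace = TRUE))]
  } else character(0)

  x <- log10(ab)[gene_of]
  out <- vector("list", length(cfg$conditions))
  for (ci in seq_along(cfg$conditions)) {
    R <- rpois(n_loci, cfg$depth_mean)
    blocks <- vector("list", 3L)
    for (k in 1:3) {
      st <- paste0(tref, ">", alts[, k])
      rate <- .true_rate(cfg, st, x)
      if (length(hot_pos)) {
        hit <- hot_pos[hot_alt == alts[hot_pos, k]]
        rate[hit] <- pmin(rate[hit] * cfg$hotspot_multiplier, 0.25)
      }
      E <- rbinom(n_loci, R, rate)
      blocks[[k]] <- data.frame(
        contig = cfg$contig, pos = pos,
        condition = cfg$conditions[ci], sub_type = st,
        E = E, R = R, gene_id = sprintf("g%04d", gene_of),
        coding = TRUE, abundance = ab[gene_of],
        stringsAsFactors = FALSE)
    }
    out[[ci]] <- do.call(rbind, blocks)
  }
  pe <- do.call(rbind, out)
  pe <- pe[pe$R > 0L, , drop = FALSE]
  class(pe) <- c("possible_errors", class(pe))
  attr(pe, "truth") <- list(
    coefficients = list(base_intercept = cfg$base_intercept,
                        ga_intercept = cfg$ga_intercept,
                        cu_intercept = cfg$cu_intercept,
                        slope = cfg$slope, ga_slope = cfg$ga_slope,
                        cu_slope = if (cfg$cu_artifact) cfg$cu_slope else cfg$slope),
    hotspots = data.frame(contig = rep(cfg$contig, length(hot_pos)),
                          pos = hot_pos,
                          sub_type = if (length(hot_pos))
                            paste0(tref[hot_pos], ">", hot_alt)
                          else character(0),
                          stringsAsFactors = FALSE)
  )
  pe
}

#' Compare pipeline outputs with the generating truth
#'
#' @param result a list with any of: `hotspot_report` (from
#'   [filter_hotspots()]), `fit` (a `txerr_fit` with a shared slope term).
#' @param truth a truth record from [generate_dataset()] /
#'   [sim_possible_errors()] (the `truth` element / attribute).
#' @return a list report: for hotspots, `recall`, `false_positives`,
#'   `n_true`; for the fit, `slope_hat`, `slope_true`, `slope_error`,
#'   `ci_covers` (95% Wald interval).
#' @export
truth_check <- function(result, truth) {
  out <- list()
  if (!is.null(result$hotspot_report)) {
    rep_ <- result$hotspot_report
    true_keys <- .locus_key(truth$hotspots$contig, truth$hotspots$pos)
    got_keys <- .locus_key(rep_$excluded_loci$contig,
                           rep_$excluded_loci$pos)
    out$hotspot <- list(
      n_true = length(true_keys),
      recall = if (length(true_keys))
        mean(true_keys %in% got_keys) else NA_real_,
      false_positives = sum(!(got_keys %in% true_keys))
    )
  }
  if (!is.null(result$fit)) {
    fit <- result$fit
    if (!"slope" %in% names(coef(fit))) {
      stop("fit has no shared slope term to check")
    }
    slope_true <- truth$coefficients$slope
    ci <- confint(fit)["slope", ]
    out$fit <- list(slope_hat = unname(coef(fit)["slope"]),
                    slope_true = slope_true,
                    slope_error = unname(coef(fit)["slope"]) - slope_true,
                    ci_covers = ci[1] <= slope_true && slope_true <= ci[2])
  }
  if (!length(out)) stop("result carries neither a hotspot report nor a fit")
  out
}
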