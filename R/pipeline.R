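# End-to-end orchestration: simulate/ingest -> assign -> build possible
# errors -> hotspot filter -> fit & compare models -> bin -> write outputs.

#' Run the full error-rate pipeline from one configuration
#'
#' Executes every stage in order and writes all outputs to `outdir`:
#' `possible_errors.tsv`, `accounting.json` (locus/site/possible-error
#' counts at every exclusion step), `hotspots.bed` and
#' `hotspot_report.json`, `fits.json` (coefficients and log-likelihoods),
#' `comparisons.tsv` (nested-model chi-square tests), and `bins.tsv`.
#'
#' The configuration is a list (or path to a YAML file) with components:
#' \describe{
#'   \item{synthetic}{arguments for [synth_config()] — the dataset is
#'     generated under `outdir/data`; alternatively}
#'   \item{inputs}{a manifest: `counts` (list of `list(path =, condition =)`
#'     entries, one file per condition), `annotation` (GFF3 path),
#'     `abundance` (TSV path);}
#'   \item{hotspot}{`threshold` (default 1e-9), `max_iter` (default 20);}
#'   \item{model}{`types` subset name for [sub_types()] (default
#'     `"non-CU"`), `include_cu` (default `FALSE`; including C>U among the
#'     modelled types is refused unless this is set — C>U rates are
#'     dominated by preparation artifacts and are analysed separately),
#'     `cu_model` (default `TRUE`: also fit the C>U-only model);}
#'   \item{binning}{`n_bins` (default 10), `pool_first` (default 3);}
#'   \item{seed}{single RNG seed for any synthetic generation.}
#' }
#'
#' Model comparisons are fixed: no-slope vs shared-slope (the expression
#' dependence test) and shared-slope vs G>A-specific slope.
#'
#' @param config a list as above, or the path of a YAML file containing it.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `pe` (cleaned possible errors),
#'   `accounting`, `hotspot_report`, `fits`, `comparisons`, `bins`, and
#'   `paths` of all written files.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- list()

  # --- stage: inputs (synthetic generation or manifest) ------------------
  if (!is.null(config$synthetic)) {
    sargs <- config$synthetic
    preset <- if (is.null(sargs$preset)) "realistic" else sargs$preset
    sargs$preset <- NULL
    if (!is.null(config$seed)) sargs$seed <- config$seed
    scfg <- do.call(synth_config, c(list(preset = preset), sargs))
    gen <- generate_dataset(scfg, file.path(outdir, "data"))
    manifest <- list(
      counts = lapply(scfg$conditions, function(cd)
        list(path = gen$paths[[paste0("counts_", cd)]], condition = cd)),
      annotation = gen$paths$annotation,
      abundance = gen$paths$abundance
    )
    truth <- gen$truth
  } else if (!is.null(config$inputs)) {
    manifest <- config$inputs
    truth <- NULL
  } else {
    stop("config must provide either 'synthetic' or 'inputs'")
  }

  message("ingesting ", length(manifest$counts), " count table(s)")
  sites <- do.call(rbind, lapply(manifest$counts, function(m)
    read_site_counts(m$path, m$condition)))
  genes <- read_annotation(manifest$annotation)
  abundance <- read_abundance(manifest$abundance)

  # --- stage: assignment and possible errors -----------------------------
  asgn <- assign_loci(sites, genes)
  message("loci: ", sum(asgn$tallies), " observed; ",
          asgn$tallies["assigned"], " assigned, ",
          asgn$tallies["overlap"], " excluded in overlapping genes, ",
          asgn$tallies["intergenic"], " intergenic")
  built <- build_possible_errors(sites, asgn$assignment, genes, abundance)
  pe <- annotate_synonymous(built$pe, genes, sites)
  acct <- built$accounting
  acct$loci_overlap_excluded <- unname(asgn$tallies["overlap"])
  acct$loci_intergenic <- unname(asgn$tallies["intergenic"])
  message("sites: ", acct$sites_total, " in assigned loci; ",
          acct$sites_zero_reads, " excluded with zero reads, ",
          acct$sites_no_abundance, " excluded without protein abundance; ",
          acct$sites_retained, " retained -> ", acct$possible_errors,
          " possible errors")

  # --- stage: hotspot filter --------------------------------------------
  hcfg <- config$hotspot
  threshold <- if (is.null(hcfg$threshold)) 1e-9 else hcfg$threshold
  max_iter <- if (is.null(hcfg$max_iter)) 20L else hcfg$max_iter
  filt <- filter_hotspots(pe, threshold = threshold, max_iter = max_iter)
  pe_clean <- filt$pe
  acct$hotspot_loci_excluded <- nrow(filt$report$excluded_loci)
  acct$hotspot_possible_errors_removed <- filt$report$possible_errors_removed
  acct$possible_errors_clean <- nrow(pe_clean)
  message("hotspots: ", acct$hotspot_loci_excluded, " loci excluded (",
          acct$hotspot_possible_errors_removed, " possible errors) in ",
          filt$report$n_iterations, " iteration(s)")

  # --- stage: model fitting and comparisons ------------------------------
  mcfg <- config$model
  types_name <- if (is.null(mcfg$types)) "non-CU" else mcfg$types
  types <- sub_types(types_name)
  include_cu <- isTRUE(mcfg$include_cu)
  if ("C>U" %in% types && !include_cu) {
    stop("C>U is among the modelled types; C>U rates are artifact-prone ",
         "and analysed separately. Set model$include_cu = TRUE to override.")
  }
  types <- intersect(types, unique(pe_clean$sub_type[pe_clean$coding]))

  modelled <- pe_clean$coding & pe_clean$sub_type %in% types &
    !is.na(pe_clean$abundance) & pe_clean$abundance > 0
  dat <- pe_clean[modelled, , drop = FALSE]
  acct$possible_errors_modelled <- nrow(dat)

  fit_null <- fit_error_model(dat, types = types, slope = "none")
  fit_shared <- fit_error_model(dat, types = types, slope = "shared")
  fits <- list(null = fit_null, shared = fit_shared)
  comparisons <- list()
  cmp_slope <- lrt(fit_null, fit_shared)
  comparisons[["slope"]] <- data.frame(
    null = "null", alt = "shared", statistic = cmp_slope$statistic,
    df = cmp_slope$df, p.value = cmp_slope$p.value,
    stringsAsFactors = FALSE)
  if ("G>A" %in% types) {
    fit_ga <- fit_error_model(dat, types = types, slope = "ga_specific")
    fits$ga_specific <- fit_ga
    cmp_ga <- lrt(fit_shared, fit_ga)
    comparisons[["ga_slope"]] <- data.frame(
      null = "shared", alt = "ga_specific", statistic = cmp_ga$statistic,
      df = cmp_ga$df, p.value = cmp_ga$p.value, stringsAsFactors = FALSE)
  }
  cu_model <- if (is.null(mcfg$cu_model)) TRUE else isTRUE(mcfg$cu_model)
  if (cu_model && any(pe_clean$coding & pe_clean$sub_type == "C>U" &
                        !is.na(pe_clean$abundance))) {
    cu_dat <- pe_clean[pe_clean$coding & pe_clean$sub_type == "C>U" &
                         !is.na(pe_clean$abundance) &
                         pe_clean$abundance > 0, , drop = FALSE]
    fits$cu_null <- fit_error_model(cu_dat, types = "C>U",
                                    type_intercepts = FALSE,
                                    slope = "none")
    fits$cu_shared <- fit_error_model(cu_dat, types = "C>U",
                                      type_intercepts = FALSE,
                                      slope = "shared")
    cmp_cu <- lrt(fits$cu_null, fits$cu_shared)
    comparisons[["cu_slope"]] <- data.frame(
      null = "cu_null", alt = "cu_shared", statistic = cmp_cu$statistic,
      df = cmp_cu$df, p.value = cmp_cu$p.value, stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, comparisons)

  # --- stage: binning ----------------------------------------------------
  bcfg <- config$binning
  n_bins <- if (is.null(bcfg$n_bins)) 10L else bcfg$n_bins
  pool_first <- if (is.null(bcfg$pool_first)) 3L else bcfg$pool_first
  bins <- make_bins(dat, n_bins)
  bin_summary <- summarize_bins(dat, bins, pool_first = pool_first)

  # --- stage: outputs ----------------------------------------------------
  paths$possible_errors <- file.path(outdir, "possible_errors.tsv")
  write_possible_errors(pe_clean, paths$possible_errors)
  paths$accounting <- file.path(outdir, "accounting.json")
  jsonlite::write_json(acct, paths$accounting, auto_unbox = TRUE,
                       digits = NA)
  paths$hotspots_bed <- file.path(outdir, "hotspots.bed")
  write_hotspot_bed(filt$report, paths$hotspots_bed)
  paths$hotspot_report <- file.path(outdir, "hotspot_report.json")
  jsonlite::write_json(
    list(threshold = filt$report$threshold,
         n_iterations = filt$report$n_iterations,
         converged = filt$report$converged,
         per_iteration = filt$report$per_iteration,
         excluded_loci = filt$report$excluded_loci),
    paths$hotspot_report, auto_unbox = TRUE, digits = NA)
  paths$fits <- file.path(outdir, "fits.json")
  jsonlite::write_json(
    lapply(fits, function(f) list(
      coefficients = as.list(coef(f)), loglik = f$loglik, df = f$df,
      nobs = f$nobs, boundary_hit = f$boundary_hit)),
    paths$fits, auto_unbox = TRUE, digits = NA)
  paths$comparisons <- file.path(outdir, "comparisons.tsv")
  data.table::fwrite(comparisons, paths$comparisons, sep = "\t")
  paths$bins <- file.path(outdir, "bins.tsv")
  data.table::fwrite(as.data.frame(bin_summary), paths$bins, sep = "\t")

  invisible(list(pe = pe_clean, accounting = acct,
                 hotspot_report = filt$report, fits = fits,
                 comparisons = comparisons, bins = bin_summary,
                 truth = truth, paths = paths))
}
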