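.runConfigDefaults <- function() {
  list(
    seed = 1L,
    outdir = ".",
    stages = list(simulate = TRUE, classify = TRUE, islands = TRUE,
                  concordance = FALSE, expression = TRUE),
    inputs = list(gff3 = NULL, repeats_bed = NULL, site_tsv = NULL,
                  site_tsv_b = NULL, counts_tsv = NULL, chrom_sizes = NULL,
                  cpg_index_bed = NULL),
    simulation = list(),
    params = list(min_coverage = 10, llr_threshold = 2,
                  min_call_fraction = 0.10, alpha = 0.05,
                  promoter_bp = 200, promoter_floor = 0.03,
                  window_bp = 50000, penalty = 40, drop_cutoff = 0.2,
                  fpkm_variant = "standard", transform = "identity",
                  site_mode = "site-binomial", site_error_rate = 0.05)
  )
}

.mergeConfig <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a pipeline run configuration (YAML)
#'
#' Validates keys against the known schema (unknown keys are rejected)
#' and fills defaults. Sections: `seed`, `outdir`, `stages` (toggles),
#' `inputs` (paths, for runs on real data), `simulation` (overrides
#' passed to [simulationConfig()]), `params` (stage parameters).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list merged on top (same schema).
#' @return Validated config list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .runConfigDefaults()
  if (!is.null(path)) cfg <- .mergeConfig(cfg, yaml::read_yaml(path))
  if (length(overrides)) cfg <- .mergeConfig(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

#' Run the methylome pipeline end-to-end
#'
#' Executes the enabled stages in dependency order — simulate (or load
#' inputs), coverage + call-density filtering, gene-body and promoter
#' classification, TE-island segmentation, cross-table concordance,
#' expression link — writing each stage's tables under `outdir` and
#' returning a run report (per-stage row counts, parameters, file
#' checksums, and a per-stage summary of total sites, methylated sites,
#' mean methylation and GBM/UM counts). All randomness derives from the
#' config seed, so identical config + seed reproduces byte-identical
#' outputs. Missing inputs for enabled stages are reported before any
#' stage runs.
#'
#' @param config A config list from [readRunConfig()] (or compatible).
#' @return The run report, invisibly also written as
#'   `run_report.json` under `outdir`.
#' @export
runPipeline <- function(config = readRunConfig()) {
  config <- .mergeConfig(.runConfigDefaults(), config)
  st <- config$stages
  pr <- config$params
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # ---- preflight: every enabled stage must have its inputs
  if (!isTRUE(st$simulate)) {
    need <- c(gff3 = "classify", site_tsv = "classify")
    if (isTRUE(st$islands)) need <- c(need, repeats_bed = "islands",
                                      chrom_sizes = "islands")
    if (isTRUE(st$expression)) need <- c(need, counts_tsv = "expression")
    miss <- names(need)[vapply(names(need), function(k) {
      is.null(config$inputs[[k]])
    }, TRUE)]
    if (length(miss)) {
      stop("missing input(s) for enabled stage(s): ",
           paste(miss, collapse = ", "))
    }
  }
  if (isTRUE(st$concordance) && !isTRUE(st$simulate) &&
      is.null(config$inputs$site_tsv_b)) {
    stop("missing input(s) for enabled stage(s): site_tsv_b")
  }

  report <- list(seed = config$seed, params = pr, stages = list())
  files <- character(0)
  out <- function(name) file.path(outdir, name)

  # ---- acquire data
  if (isTRUE(st$simulate)) {
    .log("simulate", "generating synthetic methylome")
    simcfg <- do.call(simulationConfig,
                      c(list(seed = config$seed), config$simulation))
    sim <- simulateMethylome(simcfg)
    genes <- sim$genes; repeats <- sim$repeats
    sites_raw <- sim$sites; chrom_sizes <- sim$chrom_sizes
    counts <- sim$counts; gene_lengths <- sim$gene_lengths
    index <- cpgIndex(sim$truth@site_probs)
    writeGff3(genes, out("genes.gff3"))
    writeRepeatBed(repeats, out("repeats.bed"))
    writeSiteTable(sites_raw, out("sites_raw.tsv"))
    writeCountsTable(counts, gene_lengths, out("counts.tsv"))
    writeGroundTruth(sim$truth, out("ground_truth.json"))
    files <- c(files, out(c("genes.gff3", "repeats.bed", "sites_raw.tsv",
                            "counts.tsv", "ground_truth.json")))
    report$stages$simulate <- list(
      n_genes = length(genes), n_repeats = length(repeats),
      n_sites = length(sites_raw), n_islands = length(sim$truth@islands))
  } else {
    .log("load", "reading inputs")
    genes <- readGff3(config$inputs$gff3)
    sites_raw <- readSiteTable(config$inputs$site_tsv)
    repeats <- if (!is.null(config$inputs$repeats_bed)) {
      readRepeatBed(config$inputs$repeats_bed)
    } else NULL
    chrom_sizes <- if (!is.null(config$inputs$chrom_sizes)) {
      readChromSizes(config$inputs$chrom_sizes)
    } else NULL
    index <- if (!is.null(config$inputs$cpg_index_bed)) {
      cpgIndex(config$inputs$cpg_index_bed)
    } else NULL
    if (!is.null(config$inputs$counts_tsv)) {
      ct <- readCountsTable(config$inputs$counts_tsv)
      counts <- ct$counts; gene_lengths <- ct$gene_lengths
    }
  }

  # ---- filter
  .log("filter", "min coverage ", pr$min_coverage)
  sites <- filterSites(sites_raw, pr$min_coverage)
  n_low <- S4Vectors::metadata(sites)$n_removed
  dropped <- character(0)
  if (!is.null(index)) {
    sites <- filterLowCallSequences(sites, index, pr$min_call_fraction)
    dropped <- S4Vectors::metadata(sites)$dropped_sequences
  }
  writeSiteTable(sites, out("sites_filtered.tsv"))
  files <- c(files, out("sites_filtered.tsv"))
  jsonlite::write_json(
    list(n_input = length(sites_raw), n_below_coverage = n_low,
         dropped_sequences = dropped, n_retained = length(sites)),
    out("filter_report.json"), auto_unbox = TRUE)
  files <- c(files, out("filter_report.json"))
  report$stages$filter <- list(n_input = length(sites_raw),
                               n_below_coverage = n_low,
                               n_retained = length(sites))

  flags <- binarizeSites(sites, mode = pr$site_mode,
                         error_rate = pr$site_error_rate,
                         alpha = pr$alpha)
  summaryRow <- function(s, f) {
    list(total_sites = length(s), methylated_sites = sum(f),
         mean_methylation = mean(methFrequency(s)))
  }
  report$summary <- summaryRow(sites, flags)

  # ---- classification
  if (isTRUE(st$classify)) {
    .log("classify", "gene bodies and promoters")
    gbm <- classifyGeneBodies(genes, sites, alpha = pr$alpha,
                              site_mode = pr$site_mode,
                              site_error_rate = pr$site_error_rate)
    pmg <- classifyPromoters(genes, sites, alpha = pr$alpha,
                             promoter_bp = pr$promoter_bp,
                             promoter_floor = pr$promoter_floor,
                             site_mode = pr$site_mode,
                             site_error_rate = pr$site_error_rate)
    writeClassification(gbm, out("gene_body_classes.tsv"))
    writeClassification(pmg, out("promoter_classes.tsv"))
    prof <- metaProfile(genes, sites)
    writeTsv(prof, out("metaprofile.tsv"))
    files <- c(files, out(c("gene_body_classes.tsv",
                            "promoter_classes.tsv", "metaprofile.tsv")))
    report$stages$classify <- list(
      n_genes = nrow(gbm),
      gbm = sum(gbm$class == "GBM"), um = sum(gbm$class == "UM"),
      unclassified = sum(gbm$class == "unclassified"),
      pmg = sum(pmg$class == "PMG"), pum = sum(pmg$class == "PUM"))
    report$summary$gbm <- sum(gbm$class == "GBM")
    report$summary$um <- sum(gbm$class == "UM")
  }

  # ---- TE islands
  if (isTRUE(st$islands) && !is.null(repeats) && !is.null(chrom_sizes)) {
    .log("islands", "window ", pr$window_bp, " penalty ", pr$penalty)
    isl <- findTEIslands(repeats, chrom_sizes, pr$window_bp, pr$penalty,
                         pr$drop_cutoff)
    writeIslandBed(isl$islands, out("te_islands.bed"))
    files <- c(files, out("te_islands.bed"))
    cmp <- if (length(isl$islands)) {
      tryCatch(compareIslandMethylation(sites, isl$islands),
               error = function(e) NULL)
    }
    report$stages$islands <- list(
      n_islands = length(isl$islands),
      island_bp = sum(GenomicRanges::width(isl$islands)),
      methylation_test = cmp[c("statistic", "p_value", "median_inside",
                               "median_outside")])
  }

  # ---- concordance
  if (isTRUE(st$concordance)) {
    .log("concordance", "joining site tables")
    b <- if (isTRUE(st$simulate)) {
      simulateSiteCalls(sim$truth, simcfg, replicate = 2,
                        read_level = FALSE)$sites
    } else {
      readSiteTable(config$inputs$site_tsv_b)
    }
    b <- filterSites(b, pr$min_coverage)
    rep_c <- concordanceReport(sites, b)
    jsonlite::write_json(rep_c[c("n_shared", "n_unique_a", "n_unique_b",
                                 "pearson_r", "r_p_value")],
                         out("concordance.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, out("concordance.json"))
    report$stages$concordance <- rep_c[c("n_shared", "pearson_r",
                                         "r_p_value")]
  }

  # ---- expression
  if (isTRUE(st$expression) && exists("counts", inherits = FALSE)) {
    .log("expression", "FPKM and methylation link")
    fpkm <- computeFpkm(counts, gene_lengths, variant = pr$fpkm_variant)
    writeTsv(data.frame(gene_id = rownames(fpkm),
                        mean_fpkm = rowMeans(fpkm)),
             out("fpkm_mean.tsv"))
    files <- c(files, out("fpkm_mean.tsv"))
    res <- list()
    if (isTRUE(st$classify)) {
      res$gbm_vs_um <- compareExpressionByClass(fpkm, gbm)[
        c("statistic", "p_value", "median_1", "median_2")]
      corr <- methylationExpressionCorrelation(fpkm, gbm,
                                               transform = pr$transform)
      res$methylation_correlation <- corr
    }
    report$stages$expression <- res
  }

  cs <- tools::md5sum(files)
  names(cs) <- basename(files)  # keep the report outdir-independent
  report$checksums <- as.list(cs)
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  .log("done", "report written to ", out("run_report.json"))
  invisible(report)
}
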