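## Pipeline driver: simulate -> metrics -> background -> contamination ->
## sensitivity -> concordance -> report, from one validated config.

.STAGES <- c("simulate", "metrics", "background", "contamination",
             "sensitivity", "concordance", "report")

.defaultConfig <- function() {
  list(
    seed = NULL,
    regions = list(chrom = "chr1", start = 1, end = 10000),
    genotypes = list(n_lines = 10, variant_density = 0.01,
                     het_prob = 0.35, hom_prob = 0.15),
    library = list(total_read_pairs = 20000, conversion_efficiency = 0.01,
                   on_target_fraction = 0.6, improper_pair_fraction = 0.02,
                   per_base_error_rate = 5e-4, read_span = 100),
    masses = c(6.25, 12.5, 25, 50, 100, 200),
    thresholds = list(het_window = c(0.40, 0.60), hom_threshold = 0.90,
                      background_max_freq = 0.01, genotype_min_freq = 0.10,
                      maf_bins = c(0, 0.05, 0.10, 0.15, 1.0),
                      min_mean_depth = 0),
    detector = list(min_fraction = 0.02, min_alt_reads = 5),
    saturation = list(fractions = c(0.1, 0.25, 0.5, 0.75, 1.0)),
    contamination = list(fraction = 0.005, mass = 50,
                         downsample_reads = NULL),
    concordance = list(n_libraries = 3))
}

#' Validate a pipeline run configuration
#'
#' Fills unset fields from the defaults and checks every threshold range
#' and the presence of the master seed (every stochastic stage derives its
#' own seed from it). Errors before any work when invalid.
#'
#' @param config named list, e.g. from [readRunConfig()].
#' @return The completed config, invisibly usable by [runPipeline()].
#' @export
validateRunConfig <- function(config) {
  merged <- modifyList(.defaultConfig(), config)
  if (is.null(merged$seed) || !is.numeric(merged$seed) ||
      length(merged$seed) != 1L || is.na(merged$seed))
    stop("config validation: a single integer 'seed' is required")
  th <- merged$thresholds
  if (length(th$het_window) != 2L || th$het_window[1] > th$het_window[2] ||
      th$het_window[1] < 0 || th$het_window[2] > 1)
    stop("config validation: het_window must be a sub-interval of [0, 1]")
  if (th$hom_threshold <= th$het_window[2] || th$hom_threshold >= 1)
    stop("config validation: hom_threshold must lie above the het window")
  if (th$background_max_freq <= 0 || th$background_max_freq >= 1)
    stop("config validation: background_max_freq must lie in (0, 1)")
  if (th$genotype_min_freq <= 0 || th$genotype_min_freq >= 1)
    stop("config validation: genotype_min_freq must lie in (0, 1)")
  if (any(diff(th$maf_bins) <= 0))
    stop("config validation: maf_bins must be strictly increasing")
  if (any(merged$masses <= 0))
    stop("config validation: masses must be positive")
  if (any(merged$saturation$fractions <= 0 |
            merged$saturation$fractions > 1))
    stop("config validation: saturation fractions must lie in (0, 1]")
  cf <- merged$contamination$fraction
  if (cf < 0 || cf >= 1)
    stop("config validation: contamination fraction must lie in [0, 1)")
  merged
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return Validated config list (see [validateRunConfig()]).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("masses")) if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  if (!is.null(cfg$thresholds))
    cfg$thresholds <- lapply(cfg$thresholds, unlist)
  if (!is.null(cfg$saturation))
    cfg$saturation <- lapply(cfg$saturation, unlist)
  validateRunConfig(cfg)
}

.configRegions <- function(config) {
  r <- config$regions
  if (!is.null(r$bed)) return(readRegionsBed(r$bed))
  GRanges(r$chrom, IRanges(as.integer(r$start), as.integer(r$end)))
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the evaluation pipeline
#'
#' Executes the requested stages from a validated config: simulate
#' libraries over the input-mass grid, compute filter/coverage/saturation
#' metrics, background error-rate distributions, the single- vs multiplex
#' contamination estimate, MAF-stratified detection sensitivity and
#' multi-library concordance, then render a markdown report. All tables are
#' written as TSV under \code{outDir}, a machine-readable summary as
#' \code{metrics.json}, and a log of versions, seeds and parameters as
#' \code{run_log.txt}. Re-running with the same config reproduces identical
#' outputs.
#'
#' @param config config list (validated with [validateRunConfig()];
#'   a plain list is validated here).
#' @param outDir output directory.
#' @param stages character vector of stages to run, or \code{"all"}.
#' @return The report bundle: a list with the per-stage results and file
#'   paths, suitable for [renderReport()].
#' @export
runPipeline <- function(config, outDir, stages = "all") {
  config <- validateRunConfig(config)
  if (identical(stages, "all")) stages <- .STAGES
  bad <- setdiff(stages, .STAGES)
  if (length(bad))
    stop("config validation: unknown stage(s): ",
         paste(bad, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  regions <- .configRegions(config)
  bundle <- list(config = config, outDir = outDir, stages = stages)

  log <- c(sprintf("PoolCapQC %s", as.character(utils::packageVersion("PoolCapQC"))),
           sprintf("R %s.%s", R.version$major, R.version$minor),
           sprintf("master seed: %s", format(seed)),
           sprintf("stages: %s", paste(stages, collapse = ", ")),
           "config:", utils::capture.output(utils::str(config)))
  writeLines(log, file.path(outDir, "run_log.txt"))

  ## --- simulate ------------------------------------------------------
  lp <- config$library
  mkParams <- function(mass, label, contamination = 0) {
    LibrarySimParams(inputMassNg = mass,
                     totalReadPairs = lp$total_read_pairs,
                     seed = childSeed(seed, label),
                     conversionEfficiency = lp$conversion_efficiency,
                     onTargetFraction = lp$on_target_fraction,
                     improperPairFraction = lp$improper_pair_fraction,
                     perBaseErrorRate = lp$per_base_error_rate,
                     contaminationFraction = contamination,
                     readSpan = lp$read_span)
  }
  genomes <- simulateGenotypes(config$genotypes$n_lines, regions,
                               config$genotypes$variant_density,
                               seed = childSeed(seed, "genotypes"),
                               hetProb = config$genotypes$het_prob,
                               homProb = config$genotypes$hom_prob)
  catalog <- genotypeCatalog(genomes)
  pool <- PoolSpec(names(genomes))
  sampleNames <- sprintf("mass_%g", config$masses)
  datasets <- NULL
  if ("simulate" %in% stages ||
      any(c("metrics", "background", "sensitivity", "concordance") %in%
            stages)) {
    datasets <- lapply(seq_along(config$masses), function(i)
      simulateReads(pool, genomes,
                    mkParams(config$masses[i], sampleNames[i]),
                    regions, sampleName = sampleNames[i]))
    names(datasets) <- sampleNames
    if ("simulate" %in% stages) {
      for (s in sampleNames)
        writeDataset(datasets[[s]], file.path(outDir, "simulate", s))
      bundle$datasets <- datasets
    }
  }
  bundle$truth <- list(genomes = genomes, catalog = catalog, pool = pool,
                       regions = regions)

  ## --- metrics -------------------------------------------------------
  if (any(c("metrics", "sensitivity", "concordance") %in% stages)) {
    filt <- lapply(sampleNames, function(s)
      filterReads(readRecords(datasets[[s]], s)))
    names(filt) <- sampleNames
    breakdown <- do.call(rbind, lapply(sampleNames, function(s) {
      data.frame(sample = s, input_mass_ng = config$masses[match(
        s, sampleNames)], t(filterCounts(filt[[s]]$breakdown)),
        t(setNames(filterRates(filt[[s]]$breakdown),
                   paste0("rate_", .FILTER_CATS))))
    }))
    profiles <- lapply(sampleNames, function(s)
      coverageProfile(filt[[s]]$pass, regions))
    names(profiles) <- sampleNames
    covSummary <- do.call(rbind, lapply(sampleNames, function(s) {
      eff <- coverageEfficiency(profiles[[s]], c(1, 100, 200, 500))
      data.frame(sample = s, mean_depth = meanDepth(profiles[[s]]),
                 pct_ge_1 = eff[["1"]], pct_ge_100 = eff[["100"]],
                 pct_ge_200 = eff[["200"]], pct_ge_500 = eff[["500"]],
                 pct_gt_500 = percentTargetsAbove(profiles[[s]], 500))
    }))
    sat <- do.call(rbind, lapply(sampleNames, function(s) {
      rr <- readRecords(datasets[[s]], s)
      grid <- unique(round(config$saturation$fractions *
                             nrow(readRecords(rr))))
      out <- saturationCurve(rr, regions, grid,
                             seed = childSeed(seed, paste0("sat_", s)))
      cbind(sample = s, out)
    }))
    bundle$metrics <- list(breakdown = breakdown, coverage = covSummary,
                           saturation = sat, profiles = profiles,
                           filtered = filt)
    if ("metrics" %in% stages) {
      .writeTsv(breakdown, file.path(outDir, "filter_breakdown.tsv"))
      .writeTsv(covSummary, file.path(outDir, "coverage_summary.tsv"))
      .writeTsv(sat, file.path(outDir, "saturation.tsv"))
    }
  }

  ## --- background ----------------------------------------------------
  if ("background" %in% stages) {
    bg <- buildBackgroundCatalog(catalog, regions,
                                 maxFreq = config$thresholds$background_max_freq)
    dists <- lapply(sampleNames, function(s)
      backgroundRates(alleleCounts(datasets[[s]], s), bg))
    names(dists) <- sampleNames
    bgSummary <- do.call(rbind, lapply(sampleNames, function(s)
      data.frame(sample = s, n_alleles = length(errorFreqs(dists[[s]])),
                 mean_rate = dists[[s]]@mean, sd_rate = dists[[s]]@sd,
                 n_excluded = dists[[s]]@nExcluded)))
    hb <- c(0, 1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3, 1e-2, 1)
    hists <- do.call(rbind, lapply(sampleNames, function(s)
      cbind(sample = s, errorHistogram(dists[[s]], hb))))
    bundle$background <- list(catalog = bg, distributions = dists,
                              summary = bgSummary, histograms = hists)
    .writeTsv(bgSummary, file.path(outDir, "background_summary.tsv"))
    .writeTsv(hists, file.path(outDir, "background_histograms.tsv"))
  }

  ## --- contamination -------------------------------------------------
  if ("contamination" %in% stages) {
    cs <- .contaminationStage(config, genomes, catalog, regions, seed,
                              mkParams)
    bundle$contamination <- cs
    .writeTsv(cs$report@perSample,
              file.path(outDir, "contamination_groups.tsv"))
    jsonlite::write_json(
      list(test_means = as.list(cs$report@testMeans),
           control_means = as.list(cs$report@controlMeans),
           estimate = contaminationEstimate(cs$report)),
      file.path(outDir, "contamination_report.json"),
      auto_unbox = TRUE, digits = NA)
  }

  ## --- sensitivity ---------------------------------------------------
  if (any(c("sensitivity", "concordance") %in% stages)) {
    truth <- buildTruthSet(pool, catalog, "SNV",
                           hetWindow = config$thresholds$het_window,
                           homThreshold = config$thresholds$hom_threshold)
    if (config$thresholds$min_mean_depth > 0)
      truth <- maskLowCoverage(truth, bundle$metrics$profiles,
                               config$thresholds$min_mean_depth)
    callSets <- lapply(sampleNames, function(s)
      naiveDetector(alleleCounts(datasets[[s]], s),
                    minFraction = config$detector$min_fraction,
                    minAltReads = config$detector$min_alt_reads))
    names(callSets) <- sampleNames
    if ("sensitivity" %in% stages) {
      sens <- do.call(rbind, lapply(sampleNames, function(s)
        cbind(sample = s,
              sensitivityBins(detectionSensitivity(
                truth, callSets[[s]], bins = config$thresholds$maf_bins)))))
      bundle$sensitivity <- list(truth = truth, callSets = callSets,
                                 table = sens)
      .writeTsv(sens, file.path(outDir, "sensitivity.tsv"))
      .writeTsv(truthRecords(truth), file.path(outDir, "truth_set.tsv"))
    }
    if ("concordance" %in% stages) {
      nl <- min(config$concordance$n_libraries, length(callSets))
      top <- rev(sampleNames)[seq_len(nl)]
      conc <- concordanceClassify(callSets[top])
      bundle$concordance <- conc
      .writeTsv(conc@variants, file.path(outDir, "concordance.tsv"))
    }
  }

  ## --- summary + report ---------------------------------------------
  bundle$metricsJson <- .metricsSummary(bundle)
  jsonlite::write_json(bundle$metricsJson,
                       file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if ("report" %in% stages)
    renderReport(bundle, file.path(outDir, "report.md"))
  invisible(bundle)
}

## Two single-line specimens captured alone and together; the second is the
## contamination donor for the first.
.contaminationStage <- function(config, genomes, catalog, regions, seed,
                                mkParams) {
  lines <- names(genomes)[seq_len(min(2L, length(genomes)))]
  if (length(lines) < 2L)
    stop("contamination stage needs at least 2 simulated lines")
  pools <- lapply(lines, function(l) PoolSpec(l))
  names(pools) <- lines
  mass <- config$contamination$mass
  cf <- config$contamination$fraction
  simOne <- function(i, contamination, label) {
    coc <- if (contamination > 0) pools[-i] else NULL
    simulateReads(pools[[i]], genomes, mkParams(mass, label, contamination),
                  regions, cocaptured = coc, sampleName = lines[i])
  }
  single <- lapply(seq_along(lines), function(i)
    alleleCounts(simOne(i, 0, paste0("con_s_", i)), lines[i]))
  multi <- lapply(seq_along(lines), function(i)
    alleleCounts(simOne(i, cf, paste0("con_m_", i)), lines[i]))
  names(single) <- names(multi) <- lines
  perLine <- lapply(lines, function(l)
    backgroundAlleles(buildBackgroundCatalog(
      subsetCatalog(catalog, l), regions,
      maxFreq = config$thresholds$background_max_freq)))
  names(perLine) <- lines
  gt <- genotypeAlleles(subsetCatalog(catalog, lines),
                        minFreq = config$thresholds$genotype_min_freq)
  groups <- buildContaminationGroups(gt[lines], perLine)
  report <- estimateContamination(
    single, multi, groups,
    downsampleTo = config$contamination$downsample_reads,
    readSpan = config$library$read_span,
    seed = childSeed(seed, "con_thin"))
  list(report = report, groups = groups, injected = cf)
}

.metricsSummary <- function(bundle) {
  out <- list()
  if (!is.null(bundle$metrics)) {
    b <- bundle$metrics$breakdown
    out$duplicate_rate_by_mass <- setNames(as.list(b$rate_duplicate),
                                           b$sample)
    out$pass_rate_by_mass <- setNames(as.list(b$rate_pass), b$sample)
    cv <- bundle$metrics$coverage
    out$mean_depth_by_mass <- setNames(as.list(cv$mean_depth), cv$sample)
  }
  if (!is.null(bundle$background))
    out$mean_background_rate <- setNames(
      as.list(bundle$background$summary$mean_rate),
      bundle$background$summary$sample)
  if (!is.null(bundle$contamination)) {
    out$contamination_estimate <-
      contaminationEstimate(bundle$contamination$report)
    out$contamination_injected <- bundle$contamination$injected
  }
  if (!is.null(bundle$sensitivity)) {
    s <- bundle$sensitivity$table
    out$sensitivity <- lapply(split(s, s$sample), function(d)
      setNames(as.list(d$sensitivity), d$bin))
  }
  if (!is.null(bundle$concordance))
    out$concordance <- as.list(concordanceClasses(bundle$concordance))
  out
}
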