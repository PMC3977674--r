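#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file of key/value sections covering the
#' viewing geometry, the shape-model parameters, the FROA parameters, the
#' statistics options, the experiment design and the master seed. See
#' \code{system.file("extdata", "demo-config.yaml", package = "froa")}
#' for a complete annotated example. Every numeric parameter is validated
#' against its documented bounds before any work is done.
#'
#' @param path YAML config path.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    geometry = list(frame_px = 800L, frame_deg = 18),
    shape_models = list(smoothing_sigma = 5, kappa_min = 0.005,
                        r_min = 2, r_max = 20, kappa_sat = 0.1,
                        prominence = 0.005, band_px = 10),
    froa = list(region_radius_deg = 1, n_iterations = 1000L,
                null_density = "uniform_object", ci = "one_sided"),
    stats = list(bonferroni = FALSE, welch = FALSE),
    seed = 1L)
  for (sec in names(defaults)) {
    if (is.list(defaults[[sec]])) {
      for (k in names(defaults[[sec]])) {
        if (is.null(cfg[[sec]][[k]])) {
          cfg[[sec]][[k]] <- defaults[[sec]][[k]]
        }
      }
    } else if (is.null(cfg[[sec]])) {
      cfg[[sec]] <- defaults[[sec]]
    }
  }
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(cfg$geometry$frame_px >= 16, "geometry.frame_px must be >= 16")
  chk(cfg$geometry$frame_deg > 0, "geometry.frame_deg must be > 0")
  chk(cfg$froa$n_iterations >= 100, "froa.n_iterations must be >= 100")
  chk(cfg$froa$region_radius_deg >= 0,
      "froa.region_radius_deg must be >= 0")
  chk(cfg$froa$ci %in% c("one_sided", "two_sided"),
      "froa.ci must be one_sided or two_sided")
  chk(cfg$froa$null_density %in%
        c("uniform_object", "uniform_frame", "saliency"),
      "froa.null_density must be uniform_object, uniform_frame or saliency")
  sm <- cfg$shape_models
  chk(sm$smoothing_sigma >= 1, "shape_models.smoothing_sigma must be >= 1")
  chk(sm$kappa_min > 0 && sm$kappa_sat > 0,
      "shape_models kappa thresholds must be > 0")
  chk(sm$r_min > 0 && sm$r_min <= sm$r_max,
      "shape_models radii must satisfy 0 < r_min <= r_max")
  chk(sm$band_px >= 1, "shape_models.band_px must be >= 1")
  chk(!is.null(cfg$experiment), "experiment section is required")
  chk(!is.null(cfg$experiment$groups) &&
        length(cfg$experiment$groups) >= 1,
      "experiment.groups must list >= 1 group")
  chk(.isCount(cfg$experiment$n_trials %||% 0) &&
        (cfg$experiment$n_trials %||% 0) >= 1,
      "experiment.n_trials must be a positive count")
  cfg
}

#' Run the end-to-end FROA pipeline
#'
#' Subcommands: \code{simulate} (synthetic stimuli + fixation CSV),
#' \code{build-models} (silhouette, curvature, three ROI masks and the
#' cut table per stimulus), \code{analyze} (preprocessing, FROA, scanpath
#' metrics), \code{stats} (mixed ANOVA, planned comparisons, metric
#' tests), \code{report} (plain-text summary), and \code{all}. Every
#' stage writes its artifacts under \code{out} together with a run
#' manifest (config echo, seed, package version); identical config and
#' seed reproduce identical outputs.
#'
#' @param subcommand one of \code{"simulate"}, \code{"build-models"},
#'   \code{"analyze"}, \code{"stats"}, \code{"report"}, \code{"all"}.
#' @param config config list from \code{\link{readPipelineConfig}} or a
#'   YAML path.
#' @param out output directory.
#' @param seed optional master-seed override.
#' @param logLevel \code{"info"} or \code{"quiet"}.
#' @return invisibly, a list of artifact paths (and result tables for the
#'   stages that were run).
#' @export
runPipeline <- function(subcommand = c("all", "simulate", "build-models",
                                       "analyze", "stats", "report"),
                        config, out = "froa-out", seed = NULL,
                        logLevel = c("info", "quiet")) {
  subcommand <- match.arg(subcommand)
  logLevel <- match.arg(logLevel)
  if (is.character(config)) {
    config <- readPipelineConfig(config)
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  log <- function(...) {
    if (logLevel == "info") message("[froa] ", sprintf(...))
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  geometry <- viewingGeometry(config$geometry$frame_px,
                              config$geometry$frame_deg)
  paths <- list(
    data = file.path(out, "data"),
    models = file.path(out, "models"),
    mmc = file.path(out, "mmc_table.csv"),
    metrics = file.path(out, "metrics.csv"),
    anova = file.path(out, "anova.csv"),
    comparisons = file.path(out, "comparisons.csv"),
    report = file.path(out, "report.txt"),
    manifest = file.path(out, "run_manifest.txt"))
  res <- list(paths = paths)
  steps <- if (subcommand == "all") {
    c("simulate", "build-models", "analyze", "stats", "report")
  } else subcommand

  if ("simulate" %in% steps) {
    log("simulate: generating synthetic experiment (seed %d)", config$seed)
    design <- .designFromConfig(config)
    gen <- generateExperiment(design, paths$data, seed = config$seed,
                              geometry = geometry)
    res$simulate <- gen
  }
  if ("build-models" %in% steps) {
    log("build-models: ROI models for each stimulus")
    res$models <- .buildModelsStage(config, paths)
  }
  if ("analyze" %in% steps) {
    log("analyze: preprocessing, FROA and scanpath metrics")
    res$analyze <- .analyzeStage(config, paths, geometry)
  }
  if ("stats" %in% steps) {
    log("stats: group-level inference")
    res$stats <- .statsStage(config, paths)
  }
  if ("report" %in% steps) {
    log("report: writing %s", paths$report)
    res$report <- .reportStage(config, paths)
  }
  writeLines(c(sprintf("froa_version: %s",
                       as.character(utils::packageVersion("froa"))),
               sprintf("seed: %d", config$seed),
               sprintf("subcommand: %s", subcommand),
               paste0("config: ",
                      gsub("\n", "; ", yaml::as.yaml(config)))),
             paths$manifest)
  invisible(res)
}

.designFromConfig <- function(config) {
  ex <- config$experiment
  groups <- lapply(ex$groups, function(g) {
    out <- list(nParticipants = g$n_participants %||% 4L)
    for (k in c("nFixations", "roiPreference", "stepMean", "stepShape",
                "durationMean", "durationShape", "participantSdDeg")) {
      yk <- gsub("([A-Z])", "_\\L\\1", k, perl = TRUE)
      if (!is.null(g[[yk]])) out[[k]] <- g[[yk]]
    }
    out
  })
  list(groups = groups, nTrials = ex$n_trials,
       stimuli = as.list(ex$stimuli %||% c("dumbbell", "chain3")))
}

.loadStimuli <- function(paths) {
  stimDir <- file.path(paths$data, "stimuli")
  files <- list.files(stimDir, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no stimulus masks under ", stimDir, "; run simulate first",
         call. = FALSE)
  }
  masks <- lapply(files, readMaskPNG)
  names(masks) <- sub("\\.png$", "", basename(files))
  masks
}

.buildModelsStage <- function(config, paths) {
  sm <- config$shape_models
  masks <- .loadStimuli(paths)
  dir.create(paths$models, showWarnings = FALSE)
  models <- list()
  for (nm in names(masks)) {
    sil <- extractContour(masks[[nm]])
    curv <- computeCurvature(sil, sm$smoothing_sigma)
    pol <- buildPolarityMasks(curv, sil, kappaMin = sm$kappa_min,
                              rMin = sm$r_min, rMax = sm$r_max,
                              kappaSat = sm$kappa_sat)
    cuts <- computePartCuts(sil,
                            detectConcavityExtrema(curv, sm$prominence))
    pb <- buildPartBoundaryMask(sil, cuts, sm$band_px)
    for (lab in c("concave", "convex")) {
      writeMaskPNG(pol[[lab]]@mask,
                   file.path(paths$models,
                             sprintf("%s_%s.png", nm, lab)))
    }
    writeMaskPNG(pb@mask,
                 file.path(paths$models,
                           sprintf("%s_part_boundary.png", nm)))
    writeCutsCSV(cuts, file.path(paths$models,
                                 sprintf("%s_cuts.csv", nm)))
    models[[nm]] <- list(concave = pol$concave, convex = pol$convex,
                         part_boundary = pb)
  }
  models
}

.loadModels <- function(paths, stimNames) {
  models <- list()
  for (nm in stimNames) {
    one <- list()
    for (lab in c("concave", "convex", "part_boundary")) {
      f <- file.path(paths$models, sprintf("%s_%s.png", nm, lab))
      if (!file.exists(f)) {
        stop("missing ROI model ", f, "; run build-models first",
             call. = FALSE)
      }
      one[[lab]] <- roiMask(readMaskPNG(f), lab)
    }
    models[[nm]] <- one
  }
  models
}

.analyzeStage <- function(config, paths, geometry) {
  fixPath <- file.path(paths$data, "fixations.csv")
  records <- preprocessFixations(readFixations(fixPath), geometry)
  masks <- .loadStimuli(paths)
  models <- .loadModels(paths, unique(records$stimulus))
  nullDensity <- config$froa$null_density
  if (nullDensity == "saliency") {
    nullDensity <- lapply(masks, saliencyMap)
  }
  sils <- masks
  mmcTab <- runFroa(records, sils, models, geometry = geometry,
                    regionRadiusDeg = config$froa$region_radius_deg,
                    nullDensity = nullDensity,
                    nIterations = config$froa$n_iterations,
                    seed = .deriveSeed(config$seed, "froa"),
                    ci = config$froa$ci)
  utils::write.csv(mmcTab, paths$mmc, row.names = FALSE)
  amps <- saccadeAmplitudes(records, geometry)
  dws <- dwellTimes(records)
  writeMetricsCSV(amps, dws, paths$metrics)
  list(mmc = mmcTab, amplitudes = amps, dwells = dws)
}

.statsStage <- function(config, paths) {
  mmcTab <- utils::read.csv(paths$mmc, stringsAsFactors = FALSE)
  metrics <- utils::read.csv(paths$metrics, stringsAsFactors = FALSE)
  an <- mixedAnova(mmcTab)
  cmp <- plannedComparisons(mmcTab,
                            bonferroni = isTRUE(config$stats$bonferroni))
  met <- c("mean_amplitude_deg", "mean_dwell_ms")
  tt <- twoSampleTests(metrics, metrics = met,
                       welch = isTRUE(config$stats$welch))
  utils::write.csv(an, paths$anova, row.names = FALSE)
  utils::write.csv(cmp, paths$comparisons, row.names = FALSE)
  list(anova = an, comparisons = cmp, metricTests = tt)
}

.reportStage <- function(config, paths) {
  st <- .statsStage(config, paths)
  lines <- formatStatsReport(st$anova, st$comparisons, st$metricTests,
                             path = paths$report)
  invisible(lines)
}
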