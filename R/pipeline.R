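#' Default pipeline configuration
#'
#' All stage parameters in one list, with the study's stated values as
#' defaults: rolling-ball radius 50 px, 5-frame rolling average, 10/50 Hz
#' frame-rate presets via the compartment, Shapiro-Wilk alpha 0.05.
#'
#' @return named list of defaults; override via [readPipelineConfig()] or
#'   by editing the list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    out_dir = "nmjca_out",
    preprocess = list(rolling_ball_radius = 50L, max_shift = 10L,
                      residual_threshold = 0.2, min_rois = 3L),
    trace = list(smooth_window = 5L, noise_band_k = 1,
                 min_dff_window = 2),
    minis = list(threshold_sigma = 3, min_separation_s = 0.2,
                 frequency_window_s = 5, amplitude_window_s = 20),
    stats = list(alpha = 0.05, control = "WT"),
    simulate = list(enabled = TRUE, n_larvae = 10,
                    genotype_scales = c(WT = 1, mutant = 0.5),
                    frequencies = c(10, 20, 40, 80),
                    compartment = "cytosol", noise_sd = 20),
    traces = character()  # csv paths when not simulating
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [defaultPipelineConfig()];
#' everything else keeps its default.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultPipelineConfig(), user)
  if (!is.null(user$simulate$genotype_scales))
    cfg$simulate$genotype_scales <- unlist(user$simulate$genotype_scales)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read, trace analysis, and the statistical comparison
#' in order, persisting every intermediate: `features.csv` (per
#' larva x frequency datapoints), `normalized.csv` (control-normalized
#' values), `stats_effects.csv` (mixed-model effect table),
#' `group_summary.csv`, a human-readable `report.txt`, and `log.txt`
#' recording parameters and seed. Stage failures abort with the failing
#' stage named.
#'
#' @param config list from [readPipelineConfig()] /
#'   [defaultPipelineConfig()], or a YAML path.
#' @return list with `features`, `effects`, `summary`, `outDir`,
#'   invisibly.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "log.txt")
  logLine <- function(...) cat(..., "\n", sep = "", file = logPath,
                               append = TRUE)
  cat("", file = logPath)
  logLine("nmjCa ", as.character(utils::packageVersion("nmjCa")),
          " | seed=", config$seed)
  logLine("config: ", paste(deparse(config), collapse = " "))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  feats <- stage("input", {
    if (isTRUE(config$simulate$enabled)) {
      s <- config$simulate
      simulateCohort(nLarvae = s$n_larvae,
                     genotypeScales = s$genotype_scales,
                     frequencies = s$frequencies,
                     compartment = s$compartment,
                     noiseSd = s$noise_sd, seed = config$seed)
    } else {
      if (!length(config$traces))
        stop("no input traces given and simulation disabled")
      missing <- config$traces[!file.exists(config$traces)]
      if (length(missing))
        stop("input trace file not found: ", missing[1])
      rows <- lapply(config$traces, function(p) {
        tr <- readTraceCsv(p)
        a <- analyzeTrace(tr,
                          smoothWindow = config$trace$smooth_window,
                          noiseBandK = config$trace$noise_band_k,
                          minDffWindow = config$trace$min_dff_window)
        cbind(data.frame(larva_id = tr@meta$larva_id %||% basename(p),
                         genotype = tr@meta$genotype %||% "unknown",
                         frequency = if (length(tr@stim)) tr@stim[3]
                                     else NA,
                         batch_id = tr@meta$batch_id %||% "batch1"),
              as.data.frame(a$features)[, "max_dff", drop = FALSE])
      })
      do.call(rbind, rows)
    }
  })
  utils::write.csv(feats, file.path(outDir, "features.csv"),
                   row.names = FALSE)
  logLine("features: ", nrow(feats), " datapoints")

  norm <- stage("normalize", {
    ctrl <- config$stats$control
    topFreq <- max(feats$frequency)
    sel <- feats$frequency == topFreq
    data.frame(larva_id = feats$larva_id[sel],
               genotype = feats$genotype[sel],
               normalized = normalizeToControl(feats$max_dff[sel],
                                               feats$genotype[sel], ctrl))
  })
  utils::write.csv(norm, file.path(outDir, "normalized.csv"),
                   row.names = FALSE)

  stat <- stage("stats", {
    multiGroupTest(data.frame(value = feats$max_dff,
                              genotype = feats$genotype,
                              frequency = feats$frequency,
                              larva_id = feats$larva_id))
  })
  utils::write.csv(stat$effects, file.path(outDir, "stats_effects.csv"),
                   row.names = FALSE)
  gsum <- groupSummary(norm$normalized, norm$genotype)
  utils::write.csv(cbind(group = rownames(gsum), gsum),
                   file.path(outDir, "group_summary.csv"),
                   row.names = FALSE)

  rep <- c(sprintf("nmjCa pipeline report (seed %d)", config$seed),
           "", sprintf("%d datapoints (%d larvae)", nrow(feats),
                       length(unique(feats$larva_id))),
           "", "Effects (mixed-effects repeated-measures ANOVA):",
           utils::capture.output(print(stat$effects, row.names = FALSE)),
           "", "Normalized group summary (control mean = 1):",
           utils::capture.output(print(cbind(group = rownames(gsum), gsum),
                                       row.names = FALSE)))
  writeLines(rep, file.path(outDir, "report.txt"))
  logLine("done")
  invisible(list(features = feats, effects = stat$effects,
                 summary = gsum, outDir = outDir))
}

#' Generate the bundled test fixture set
#'
#' Writes a small, fully synthetic dataset: a drifting bouton movie with
#' its ROI label mask, a static two-channel image pair, and per-trace CSVs
#' with ground-truth sidecars. Regeneration with the same seed is
#' byte-identical.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return list of written paths, invisibly.
#' @export
makeFixtures <- function(seed = 1L, dir = "fixtures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # unstimulated movie so the QC residual measures motion, not signal
  cfg <- simConfig("cytosol", duration = 4, stim = c(1, 0.5, 0),
                   noise = list(gaussianSd = 0),
                   geometry = list(imageShape = c(40L, 40L), nBoutons = 2L,
                                   boutonRadius = 3),
                   seed = seed)
  sim <- simulateMovie(cfg)
  paths <- character()
  p <- file.path(dir, "movie.tif")
  writeMovie(sim$movie, p); paths <- c(paths, p)
  lab <- matrix(0L, 40, 40)
  for (k in seq_along(sim$rois))
    if (sim$rois[[k]]@kind == "bouton") lab[roiMask(sim$rois[[k]])] <- k
  p <- file.path(dir, "rois.tif")
  writeLabelMask(lab, p); paths <- c(paths, p)
  tr <- simulateTrace(simConfig("er", duration = 20,
                                noise = list(gaussianSd = 5),
                                seed = seed))
  p <- file.path(dir, "trace_er.csv")
  writeTraceCsv(tr$trace, p); paths <- c(paths, p)
  sp <- simulateStaticPair(simConfig("cytosol", seed = seed,
                                     geometry = list(imageShape = c(48L, 48L))))
  p <- file.path(dir, "static_marker.tif")
  writeMovie(CaMovie(array(sp$marker, c(1, dim(sp$marker))), 1, "marker"),
             p)
  paths <- c(paths, p)
  p <- file.path(dir, "static_reference.tif")
  writeMovie(CaMovie(array(sp$reference, c(1, dim(sp$reference))), 1,
                     "reference"), p)
  paths <- c(paths, p)
  invisible(paths)
}
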