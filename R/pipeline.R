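## Orchestration: run bundles, the per-run EGG -> BOLD -> PLV chain, and
## the cohort-level pipeline with QC exclusions, group inference and
## provenance-stamped outputs.

#' Pipeline options
#'
#' Collects every tunable default of the analysis stages.
#'
#' @param band gastric search band in Hz.
#' @param windowS,overlapS Welch parameters in seconds.
#' @param halfwidth filter half width in Hz.
#' @param minLagS minimum surrogate shift in seconds.
#' @param nTrim initial volumes excluded.
#' @param fwhm smoothing kernel FWHM in mm.
#' @param variant confound regression variant.
#' @param threshold cluster-forming t threshold.
#' @param nPerm sign-flip permutations.
#' @param connectivity cluster connectivity.
#' @param promThreshold,freqTol EGG quality thresholds.
#' @param seed RNG seed for the permutation stages.
#' @return named list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(band = GASTRIC_BAND, windowS = 200,
                           overlapS = 150, halfwidth = 0.015,
                           minLagS = 60, nTrim = 15L, fwhm = 3,
                           variant = "main_gsr", threshold = 2.3,
                           nPerm = 10000L, connectivity = 26L,
                           promThreshold = 4, freqTol = 0.01, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Extract the gastric phase of a run on the full BOLD volume grid
#'
#' Welch spectrum, in-band peak per channel, channel selection, quality
#' grading, narrow-band filtering of the selected channel, Hilbert phase at
#' the EGG rate, and decimation to the volume grid (untrimmed; the
#' initial-volume exclusion is applied inside the PLV stage).
#'
#' @param egg an \code{\link{EGGRecording}}.
#' @param TR repetition time in seconds.
#' @param nVolumes number of BOLD volumes.
#' @param opts a \code{\link{pipelineConfig}}.
#' @return list: \code{phase} (full-grid \code{\link{PhaseSeries}} at
#'   1/TR), \code{peakFreq}, \code{channel}, \code{quality}, \code{peaks},
#'   \code{spectrum}.
#' @export
prepareGastricPhase <- function(egg, TR, nVolumes,
                                opts = pipelineConfig()) {
  spec <- welchSpectrum(egg, opts$windowS, opts$overlapS)
  peaks <- findGastricPeak(spec, opts$band, opts$promThreshold)
  quality <- assessEggQuality(list(peaks), opts$freqTol, opts$promThreshold)
  sel <- selectGastricChannel(peaks)
  filt <- bandpassAroundPeak(egg@samples[sel$channel, ], egg@fs,
                             sel$peak$peakFreq, opts$halfwidth)
  ph10 <- hilbertPhase(filt, egg@fs)
  phase <- gastricToBoldGrid(ph10, TR, nTrim = 0L, nVolumes = nVolumes)
  list(phase = phase, peakFreq = sel$peak$peakFreq, channel = sel$channel,
       quality = quality, peaks = peaks, spectrum = spec)
}

#' Prepare a BOLD run for synchrony analysis
#'
#' Confound regression (per variant), 3-D Gaussian smoothing, voxelwise
#' band-pass around the gastric peak at the BOLD rate, and Hilbert phase
#' extraction. Stage order (regression, then smoothing, then filtering) is
#' fixed and recorded in the output.
#'
#' @param run a \code{\link{BOLDRun}}.
#' @param confounds data.frame of nuisance series.
#' @param peakFreq gastric peak frequency in Hz.
#' @param opts a \code{\link{pipelineConfig}}.
#' @return list: \code{theta} (voxels x volumes phase matrix on the full
#'   grid), \code{run} (the filtered \code{\link{BOLDRun}}), \code{stages}.
#' @export
prepareBoldRun <- function(run, confounds, peakFreq,
                           opts = pipelineConfig()) {
  design <- buildConfoundDesign(confounds, opts$variant)
  run <- regressConfounds(run, design)
  run <- smoothGaussian(run, opts$fwhm)
  filt <- t(bandpassAroundPeak(t(run@data), fs = 1 / run@TR,
                               peakFreq = peakFreq,
                               halfwidth = opts$halfwidth))
  theta <- hilbertPhaseMatrix(filt)
  list(theta = theta, run = initialize(run, data = filt),
       stages = c("regress", "smooth", "bandpass", "hilbert"))
}

#' Assemble and validate a run bundle from files
#'
#' Loads BOLD + mask (NIfTI), confounds (TSV) and EGG (TSV + JSON sidecar),
#' checks that series lengths agree, runs the EGG quality assessment and
#' computes mean FD. Level-3 EGG marks the bundle excluded.
#'
#' @param paths named list: \code{bold}, \code{mask} (optional),
#'   \code{confounds}, \code{egg}, \code{ppg} (optional TSV with a
#'   \code{ppg} column and JSON sidecar carrying \code{fs}).
#' @param opts a \code{\link{pipelineConfig}}.
#' @return list of class \code{RunBundle}.
#' @export
loadRunBundle <- function(paths, opts = pipelineConfig()) {
  bold <- readBoldRun(paths$bold, paths$mask)
  confounds <- readConfounds(paths$confounds)
  if (nrow(confounds) != nVolumes(bold))
    stop("confounds (", nrow(confounds), " rows) do not match the BOLD run (",
         nVolumes(bold), " volumes)")
  egg <- readEggRecording(paths$egg)
  needS <- nVolumes(bold) * bold@TR
  if (ncol(egg@samples) / egg@fs < needS)
    stop("EGG recording shorter than the BOLD run")
  gast <- prepareGastricPhase(egg, bold@TR, nVolumes(bold), opts)
  ppg <- NULL
  if (!is.null(paths$ppg)) {
    side <- jsonlite::read_json(sub("\\.[^.]+$", ".json", paths$ppg),
                                simplifyVector = TRUE)
    tab <- utils::read.table(paths$ppg, sep = "\t", header = TRUE)
    ppg <- list(samples = tab$ppg, fs = side$fs)
  }
  bundle <- list(bold = bold, confounds = confounds, egg = egg,
                 gastric = gast, ppg = ppg,
                 subjectId = egg@subjectId, runId = egg@runId,
                 meanFd = mean(confounds$framewise_displacement),
                 eggLevel = gast$quality$level,
                 excluded = gast$quality$excluded)
  class(bundle) <- "RunBundle"
  bundle
}

#' Build a run bundle from simulated objects
#'
#' Same validation and EGG preparation as \code{\link{loadRunBundle}}, but
#' straight from one run of a \code{\link{genCohort}} cohort, with no
#' files involved.
#'
#' @param simRun one run entry of a simulated cohort (list with \code{egg},
#'   \code{bold}, \code{confounds}, optional \code{ppg}).
#' @param opts a \code{\link{pipelineConfig}}.
#' @return list of class \code{RunBundle}.
#' @export
bundleFromSim <- function(simRun, opts = pipelineConfig()) {
  bold <- simRun$bold
  gast <- prepareGastricPhase(simRun$egg, bold@TR, nVolumes(bold), opts)
  bundle <- list(bold = bold, confounds = simRun$confounds,
                 egg = simRun$egg, gastric = gast, ppg = simRun$ppg,
                 subjectId = bold@subjectId, runId = bold@runId,
                 meanFd = mean(simRun$confounds$framewise_displacement),
                 eggLevel = gast$quality$level,
                 excluded = gast$quality$excluded)
  class(bundle) <- "RunBundle"
  bundle
}

#' Run the full synchrony pipeline over a set of run bundles
#'
#' Applies EGG and motion QC exclusions, executes the per-run chain
#' (confound regression, smoothing, gastric-band filtering, phase
#' extraction, PLV with circular-shift surrogates), averages runs within
#' subject, and performs the group cluster-mass sign-flip test. When
#' \code{outDir} is given, maps (NIfTI), cluster tables (TSV) and a JSON
#' provenance record are written there.
#'
#' @param bundles list of \code{RunBundle}s (from \code{\link{loadRunBundle}}
#'   or simulation).
#' @param opts a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory.
#' @return list: \code{runResults} (per kept run: delta maps, null spec,
#'   peak frequency), \code{subjectMaps}, \code{group} (sign-flip test
#'   output), \code{qc} (exclusion table), \code{provenance}.
#' @export
runPipeline <- function(bundles, opts = pipelineConfig(), outDir = NULL) {
  if (length(bundles) < 1L) stop("no run bundles supplied")
  eggKeep <- !vapply(bundles, `[[`, logical(1), "excluded")
  meanFd <- vapply(bundles, `[[`, numeric(1), "meanFd")
  fdKeep <- if (length(bundles) >= 3L) motionExclusion(meanFd)
            else rep(TRUE, length(bundles))
  keep <- eggKeep & fdKeep
  qc <- data.frame(
    subject = vapply(bundles, `[[`, character(1), "subjectId"),
    run = vapply(bundles, `[[`, character(1), "runId"),
    eggLevel = vapply(bundles, function(b) b$eggLevel, integer(1)),
    meanFd = meanFd, kept = keep)
  if (!any(keep)) stop("all runs were excluded by QC")
  kept <- bundles[keep]
  runResults <- lapply(kept, function(b) {
    prep <- prepareBoldRun(b$bold, b$confounds, b$gastric$peakFreq, opts)
    nulls <- makeNullShifts(nVolumes(b$bold), opts$minLagS, b$bold@TR,
                            opts$nTrim)
    maps <- deltaMap(prep$theta, b$gastric$phase, nulls,
                     mask = b$bold@mask, gridShape = b$bold@gridShape,
                     id = paste(b$subjectId, b$runId, sep = "_"))
    list(subject = b$subjectId, run = b$runId, maps = maps, nulls = nulls,
         peakFreq = b$gastric$peakFreq)
  })
  bySubject <- split(runResults,
                     vapply(runResults, `[[`, character(1), "subject"))
  subjectMaps <- lapply(bySubject, function(rs) {
    list(empirical = averageMaps(lapply(rs, function(r) r$maps$empirical),
                                 rs[[1]]$subject),
         nullMedian = averageMaps(lapply(rs, function(r) r$maps$nullMedian),
                                  rs[[1]]$subject))
  })
  group <- NULL
  if (length(subjectMaps) >= 5L) {
    emp <- t(vapply(subjectMaps, function(s) mapValues(s$empirical),
                    numeric(nVoxels(subjectMaps[[1]]$empirical))))
    nul <- t(vapply(subjectMaps, function(s) mapValues(s$nullMedian),
                    numeric(nVoxels(subjectMaps[[1]]$nullMedian))))
    set.seed(opts$seed)
    group <- signflipClusterTest(emp, nul, kept[[1]]$bold@gridShape,
                                 kept[[1]]$bold@mask, opts$nPerm,
                                 opts$threshold, opts$connectivity)
  }
  prov <- list(package = "gastroSync",
               version = as.character(utils::packageVersion("gastroSync")),
               seed = opts$seed,
               configHash = substr(paste(
                 unlist(opts)[order(names(unlist(opts)))],
                 collapse = "|"), 1L, 200L),
               nBundles = length(bundles), nKept = sum(keep))
  out <- list(runResults = runResults, subjectMaps = subjectMaps,
              group = group, qc = qc, provenance = prov)
  if (!is.null(outDir)) writePipelineOutputs(out, kept, opts, outDir)
  out
}

writePipelineOutputs <- function(res, kept, opts, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$qc, file.path(outDir, "qc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (r in res$runResults) {
    stem <- file.path(outDir, paste(r$subject, r$run, sep = "_"))
    writeBrainMap(r$maps$delta, paste0(stem, "_delta.nii"))
    jsonlite::write_json(list(lags = nullLags(r$nulls),
                              min_lag_s = r$nulls@minLagS,
                              n_trim = r$nulls@nTrim,
                              peak_freq = r$peakFreq),
                         paste0(stem, "_nullspec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$group)) {
    utils::write.table(clusterTable(res$group$clusters),
                       file.path(outDir, "clusters.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(res$provenance,
                       file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
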