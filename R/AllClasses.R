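#' @import methods
NULL

## Central data containers. All are plain S4 with validity checks; values
## that downstream stages rely on (finite phases, PLVs in [0,1], positive
## rates) are enforced at construction time so failures surface early.

#' Multichannel cutaneous EGG recording
#'
#' Holds raw gastric voltage samples, one row per channel, together with the
#' sampling rate and identifiers. The gastric phase used throughout the
#' synchrony analysis is derived from one channel of this object.
#'
#' @slot samples numeric matrix, channels x time, in mV.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one label per channel.
#' @slot subjectId,runId identifiers carried into provenance records.
#' @export
setClass("EGGRecording",
  representation(samples = "matrix", fs = "numeric",
                 channelLabels = "character",
                 subjectId = "character", runId = "character"),
  prototype(subjectId = NA_character_, runId = NA_character_))

setValidity("EGGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@samples) < 1L)
    msg <- c(msg, "at least one channel is required")
  if (any(!is.finite(object@samples)))
    msg <- c(msg, "samples contain non-finite values")
  if (length(object@channelLabels) != nrow(object@samples))
    msg <- c(msg, "channelLabels length must equal the number of channels")
  if (length(msg)) msg else TRUE
})

#' @describeIn EGGRecording constructor.
#' @param samples,fs,channelLabels,subjectId,runId see slots.
#' @export
EGGRecording <- function(samples, fs, channelLabels = NULL,
                         subjectId = NA_character_, runId = NA_character_) {
  samples <- rbind(samples)
  if (is.null(channelLabels))
    channelLabels <- paste0("EGG", seq_len(nrow(samples)))
  new("EGGRecording", samples = samples, fs = fs,
      channelLabels = channelLabels,
      subjectId = as.character(subjectId), runId = as.character(runId))
}

#' Welch power spectrum of an EGG recording
#'
#' @slot freqs frequency grid in Hz, strictly increasing from >= 0.
#' @slot power channels x frequencies matrix of spectral power density.
#' @slot windowS,overlapS Welch segment length and overlap in seconds.
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", power = "matrix",
                 windowS = "numeric", overlapS = "numeric"))

setValidity("PowerSpectrum", function(object) {
  msg <- character()
  if (length(object@freqs) < 2L || object@freqs[1] < 0 ||
      any(diff(object@freqs) <= 0))
    msg <- c(msg, "freqs must be strictly increasing and start at >= 0")
  if (ncol(object@power) != length(object@freqs))
    msg <- c(msg, "power must have one column per frequency")
  if (any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Single BOLD run as a voxels-by-volumes matrix
#'
#' Rows correspond to the \code{TRUE} entries of \code{mask} laid out over
#' \code{gridShape} in column-major (array) order.
#'
#' @slot data numeric matrix, in-mask voxels x volumes.
#' @slot mask logical vector of length \code{prod(gridShape)}.
#' @slot gridShape integer length-3 volume dimensions.
#' @slot voxelSize numeric length-3 voxel edge lengths in mm.
#' @slot TR repetition time in seconds.
#' @slot affine 4x4 voxel-to-world matrix (identity-scaled by default).
#' @slot subjectId,runId identifiers.
#' @export
setClass("BOLDRun",
  representation(data = "matrix", mask = "logical", gridShape = "integer",
                 voxelSize = "numeric", TR = "numeric", affine = "matrix",
                 subjectId = "character", runId = "character"))

setValidity("BOLDRun", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L)
    msg <- c(msg, "gridShape must have length 3")
  if (length(object@mask) != prod(object@gridShape))
    msg <- c(msg, "mask length must equal prod(gridShape)")
  if (nrow(object@data) != sum(object@mask))
    msg <- c(msg, "data must have one row per in-mask voxel")
  if (ncol(object@data) < 2L)
    msg <- c(msg, "at least two volumes are required")
  if (object@TR <= 0) msg <- c(msg, "TR must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn BOLDRun constructor.
#' @param data,mask,gridShape,voxelSize,TR,affine,subjectId,runId see slots.
#' @export
BOLDRun <- function(data, mask, gridShape, voxelSize = c(3, 3, 3), TR = 2,
                    affine = NULL, subjectId = NA_character_,
                    runId = NA_character_) {
  gridShape <- as.integer(gridShape)
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  new("BOLDRun", data = data, mask = as.logical(mask), gridShape = gridShape,
      voxelSize = voxelSize, TR = TR, affine = affine,
      subjectId = as.character(subjectId), runId = as.character(runId))
}

#' Instantaneous phase series
#'
#' Phase in radians on a regular time grid, wrapped to (-pi, pi].
#'
#' @slot theta phase per sample, radians.
#' @slot fs sampling rate in Hz.
#' @slot t0Offset time of the first retained sample, seconds.
#' @slot nTrimmed number of initial samples that were discarded upstream.
#' @export
setClass("PhaseSeries",
  representation(theta = "numeric", fs = "numeric",
                 t0Offset = "numeric", nTrimmed = "integer"),
  prototype(t0Offset = 0, nTrimmed = 0L))

setValidity("PhaseSeries", function(object) {
  msg <- character()
  if (any(!is.finite(object@theta)))
    return("theta contains non-finite values")
  if (length(object@theta) &&
      (min(object@theta) <= -pi - 1e-9 || max(object@theta) > pi + 1e-9))
    msg <- c(msg, "theta must be wrapped to (-pi, pi]")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhaseSeries constructor; wraps theta into (-pi, pi].
#' @param theta,fs,t0Offset,nTrimmed see slots.
#' @export
PhaseSeries <- function(theta, fs, t0Offset = 0, nTrimmed = 0L) {
  new("PhaseSeries", theta = wrapPhase(theta), fs = fs,
      t0Offset = t0Offset, nTrimmed = as.integer(nTrimmed))
}

#' Circular-shift surrogate specification
#'
#' Enumerates the circular lags (in samples at the BOLD rate) used to build
#' the surrogate null for the phase-locking value. Lag zero is excluded by a
#' guard of \code{minLagS} seconds plus the initial-volume trim.
#'
#' @slot lags integer vector of circular shifts in samples.
#' @slot minLagS minimum shift magnitude, seconds.
#' @slot guard per-side guard in samples (minLagS/TR + nTrim).
#' @slot nTrim number of initial volumes excluded before the PLV.
#' @slot nSamples full-grid series length the lags refer to.
#' @export
setClass("NullSpec",
  representation(lags = "integer", minLagS = "numeric", guard = "integer",
                 nTrim = "integer", nSamples = "integer"))

setValidity("NullSpec", function(object) {
  msg <- character()
  if (any(object@lags == 0L)) msg <- c(msg, "lag 0 is not a surrogate")
  if (length(object@lags) &&
      (min(object@lags) < object@guard ||
       max(object@lags) >= object@nSamples - object@guard + 1L))
    msg <- c(msg, "lags must lie within [guard, nSamples - guard)")
  if (length(msg)) msg else TRUE
})

#' Scalar brain map over a masked grid
#'
#' Shared container for empirical PLV, median-null PLV and PLV-delta maps
#' (\code{mapType} records which). Values are one per in-mask voxel.
#'
#' @slot values numeric vector over in-mask voxels.
#' @slot mask logical vector over the full grid.
#' @slot gridShape integer length-3.
#' @slot mapType one of "plv", "null_plv", "delta", "t", "other".
#' @slot id free-form identifier (subject/run).
#' @export
setClass("BrainMap",
  representation(values = "numeric", mask = "logical", gridShape = "integer",
                 mapType = "character", id = "character"),
  prototype(mapType = "other", id = NA_character_))

setValidity("BrainMap", function(object) {
  msg <- character()
  if (length(object@values) != sum(object@mask))
    msg <- c(msg, "values must have one entry per in-mask voxel")
  if (length(object@mask) != prod(object@gridShape))
    msg <- c(msg, "mask length must equal prod(gridShape)")
  if (object@mapType %in% c("plv", "null_plv") && length(object@values) &&
      (min(object@values) < -1e-9 || max(object@values) > 1 + 1e-9))
    msg <- c(msg, "PLV values must lie in [0, 1]")
  if (object@mapType == "delta" && length(object@values) &&
      max(abs(object@values)) > 1 + 1e-9)
    msg <- c(msg, "delta values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn BrainMap constructor.
#' @param values,mask,gridShape,mapType,id see slots.
#' @export
BrainMap <- function(values, mask, gridShape, mapType = "other",
                     id = NA_character_) {
  new("BrainMap", values = as.numeric(values), mask = as.logical(mask),
      gridShape = as.integer(gridShape), mapType = mapType,
      id = as.character(id))
}

#' Suprathreshold clusters of a group t-map
#'
#' @slot labels integer vector over in-mask voxels; 0 = background.
#' @slot masses sum of t-values per cluster.
#' @slot sizes voxel count per cluster.
#' @slot pFwe family-wise-error corrected p per cluster (NA before testing).
#' @slot threshold cluster-forming t threshold.
#' @slot connectivity 6, 18 or 26.
#' @export
setClass("ClusterSet",
  representation(labels = "integer", masses = "numeric", sizes = "integer",
                 pFwe = "numeric", threshold = "numeric",
                 connectivity = "integer"))

setValidity("ClusterSet", function(object) {
  msg <- character()
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  if (length(object@masses) != length(object@sizes) ||
      length(object@masses) != length(object@pFwe))
    msg <- c(msg, "masses, sizes and pFwe must have equal length")
  if (any(!is.na(object@pFwe) & (object@pFwe <= 0 | object@pFwe > 1)))
    msg <- c(msg, "pFwe must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Labelled vertices on a unit hemisphere sphere
#'
#' @slot coords n x 3 matrix of unit vectors.
#' @slot labels logical vector, one per vertex.
#' @slot hemisphere "L" or "R".
#' @export
setClass("SphereAnnotation",
  representation(coords = "matrix", labels = "logical",
                 hemisphere = "character"))

setValidity("SphereAnnotation", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be n x 3")
  nrm <- sqrt(rowSums(object@coords^2))
  if (any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "coords must be unit vectors")
  if (length(object@labels) != nrow(object@coords))
    msg <- c(msg, "labels must have one entry per vertex")
  if (!object@hemisphere %in% c("L", "R"))
    msg <- c(msg, "hemisphere must be 'L' or 'R'")
  if (length(msg)) msg else TRUE
})

#' @describeIn SphereAnnotation constructor (renormalizes coords).
#' @param coords,labels,hemisphere see slots.
#' @export
SphereAnnotation <- function(coords, labels, hemisphere) {
  coords <- coords / sqrt(rowSums(coords^2))
  new("SphereAnnotation", coords = coords, labels = as.logical(labels),
      hemisphere = hemisphere)
}
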