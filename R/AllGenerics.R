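#' @include AllClasses.R
NULL

#' Sampling rate accessor
#' @param x an object with a sampling rate.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
setMethod("samplingRate", "EGGRecording", function(x) x@fs)

#' @rdname samplingRate
setMethod("samplingRate", "PhaseSeries", function(x) x@fs)

#' Number of channels
#' @param x an \code{EGGRecording}.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
setMethod("nChannels", "EGGRecording", function(x) nrow(x@samples))

#' Channel labels
#' @param x an \code{EGGRecording}.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname channelLabels
setMethod("channelLabels", "EGGRecording", function(x) x@channelLabels)

#' Number of volumes in a BOLD run
#' @param x a \code{BOLDRun}.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname nVolumes
setMethod("nVolumes", "BOLDRun", function(x) ncol(x@data))

#' Number of in-mask voxels
#' @param x a \code{BOLDRun} or \code{BrainMap}.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname nVoxels
setMethod("nVoxels", "BOLDRun", function(x) nrow(x@data))

#' @rdname nVoxels
setMethod("nVoxels", "BrainMap", function(x) length(x@values))

#' Repetition time in seconds
#' @param x a \code{BOLDRun}.
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname repetitionTime
setMethod("repetitionTime", "BOLDRun", function(x) x@TR)

#' Voxel values of a map or run
#' @param x a \code{BrainMap} or \code{BOLDRun}.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname mapValues
setMethod("mapValues", "BrainMap", function(x) x@values)

#' Phase vector in radians
#' @param x a \code{PhaseSeries}.
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))

#' @rdname phase
setMethod("phase", "PhaseSeries", function(x) x@theta)

#' Surrogate lags in samples
#' @param x a \code{NullSpec}.
#' @export
setGeneric("nullLags", function(x) standardGeneric("nullLags"))

#' @rdname nullLags
setMethod("nullLags", "NullSpec", function(x) x@lags)

#' Number of surrogates
#' @param x a \code{NullSpec}.
#' @export
setGeneric("nNull", function(x) standardGeneric("nNull"))

#' @rdname nNull
setMethod("nNull", "NullSpec", function(x) length(x@lags))

#' Cluster summary table
#'
#' One row per cluster with size, mass and (if tested) FWE-corrected p.
#' @param x a \code{ClusterSet}.
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname clusterTable
setMethod("clusterTable", "ClusterSet", function(x) {
  data.frame(cluster = seq_along(x@masses), size = x@sizes,
             mass = x@masses, p_fwe = x@pFwe)
})

setMethod("show", "EGGRecording", function(object) {
  cat("EGGRecording:", nChannels(object), "channel(s),",
      ncol(object@samples), "samples at", object@fs, "Hz (",
      sprintf("%.1f", ncol(object@samples) / object@fs), "s )\n")
  cat("  subject:", object@subjectId, " run:", object@runId, "\n")
})

setMethod("show", "PowerSpectrum", function(object) {
  cat("PowerSpectrum:", nrow(object@power), "channel(s),",
      length(object@freqs), "bins,",
      sprintf("df = %.4g Hz", diff(object@freqs[1:2])),
      sprintf("(Welch %gs/%gs)\n", object@windowS, object@overlapS))
})

setMethod("show", "BOLDRun", function(object) {
  cat("BOLDRun:", nVoxels(object), "voxels x", nVolumes(object),
      "volumes, TR =", object@TR, "s, grid",
      paste(object@gridShape, collapse = "x"), "\n")
})

setMethod("show", "PhaseSeries", function(object) {
  cat("PhaseSeries:", length(object@theta), "samples at", object@fs,
      "Hz, trimmed:", object@nTrimmed, "\n")
})

setMethod("show", "NullSpec", function(object) {
  cat("NullSpec:", length(object@lags), "circular-shift surrogates,",
      "min lag", object@minLagS, "s, guard", object@guard, "samples\n")
})

setMethod("show", "BrainMap", function(object) {
  cat("BrainMap (", object@mapType, "): ", nVoxels(object),
      " voxels, range [", sprintf("%.4f", min(object@values)), ", ",
      sprintf("%.4f", max(object@values)), "]\n", sep = "")
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet:", length(object@masses), "cluster(s), t >",
      object@threshold, ", connectivity", object@connectivity, "\n")
  if (length(object@masses)) print(clusterTable(object))
})

setMethod("show", "SphereAnnotation", function(object) {
  cat("SphereAnnotation:", nrow(object@coords), "vertices, hemisphere",
      object@hemisphere, ",", sum(object@labels), "labelled\n")
})
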