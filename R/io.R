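## Reading and writing the on-disk formats: tab-separated EGG/PPG samples
## with JSON sidecars, fMRIPrep-style confound tables, and NIfTI volumes
## (via RNifti) for BOLD data and brain maps.

#' Write an EGG recording as TSV + JSON sidecar
#'
#' @param rec an \code{\link{EGGRecording}}.
#' @param path output TSV path (one column per channel); the sidecar is
#'   written next to it with extension \code{.json}.
#' @return invisibly, the sidecar path.
#' @export
writeEggRecording <- function(rec, path) {
  tab <- as.data.frame(t(rec@samples))
  colnames(tab) <- rec@channelLabels
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(list(fs = rec@fs, channel_labels = rec@channelLabels,
                            subject = rec@subjectId, run = rec@runId),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read an EGG recording from TSV + JSON sidecar
#' @param path TSV path written by \code{\link{writeEggRecording}}.
#' @return an \code{\link{EGGRecording}}.
#' @export
readEggRecording <- function(path) {
  side <- sub("\\.[^.]+$", ".json", path)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs) || meta$fs <= 0)
    stop("sidecar ", side, " lacks a positive 'fs'")
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  EGGRecording(t(as.matrix(tab)), fs = meta$fs,
               channelLabels = as.character(meta$channel_labels),
               subjectId = meta$subject, runId = meta$run)
}

#' Write a BOLD run as 4-D NIfTI
#' @param run a \code{\link{BOLDRun}}; out-of-mask voxels are written as 0.
#' @param path output \code{.nii} path.
#' @export
writeBoldRun <- function(run, path) {
  arr <- array(0, c(run@gridShape, nVolumes(run)))
  full <- array(0, run@gridShape)
  for (v in seq_len(nVolumes(run))) {
    full[run@mask] <- run@data[, v]
    arr[, , , v] <- full
  }
  img <- RNifti::asNifti(arr, reference = NULL)
  RNifti::pixdim(img) <- c(run@voxelSize, run@TR)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a mask or brain map as 3-D NIfTI
#' @param map a \code{\link{BrainMap}}.
#' @param path output \code{.nii} path.
#' @export
writeBrainMap <- function(map, path) {
  arr <- array(0, map@gridShape)
  arr[map@mask] <- map@values
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a 4-D NIfTI BOLD volume plus 3-D mask into a BOLDRun
#'
#' @param boldPath 4-D NIfTI path.
#' @param maskPath 3-D NIfTI mask path (non-zero = in mask); NULL uses all
#'   voxels.
#' @param TR repetition time in seconds; taken from the NIfTI header when
#'   NULL.
#' @param subjectId,runId identifiers.
#' @return a \code{\link{BOLDRun}}.
#' @export
readBoldRun <- function(boldPath, maskPath = NULL, TR = NULL,
                        subjectId = NA_character_, runId = NA_character_) {
  img <- RNifti::readNifti(boldPath)
  d <- dim(img)
  if (length(d) != 4L) stop(boldPath, " is not a 4-D volume")
  pd <- RNifti::pixdim(img)
  if (is.null(TR)) TR <- pd[4]
  mask <- if (is.null(maskPath)) rep(TRUE, prod(d[1:3])) else {
    m <- RNifti::readNifti(maskPath)
    if (!all(dim(m)[1:3] == d[1:3]))
      stop("mask grid does not match the BOLD grid")
    as.vector(m != 0)
  }
  mat <- matrix(img, nrow = prod(d[1:3]), ncol = d[4])[mask, , drop = FALSE]
  BOLDRun(mat, mask, d[1:3], voxelSize = pd[1:3], TR = TR,
          subjectId = subjectId, runId = runId)
}

#' Read an fMRIPrep-style confounds table
#'
#' @param path tab-separated file with one row per volume.
#' @param required column names that must be present (default the ten
#'   nuisance series).
#' @return data.frame.
#' @export
readConfounds <- function(path, required = CONFOUND_NAMES) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  missing <- setdiff(required, colnames(tab))
  if (length(missing))
    stop("confounds file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(tab$framewise_displacement < 0, na.rm = TRUE))
    stop("framewise displacement must be non-negative")
  tab
}

#' Write a power spectrum as a tab-separated table
#' @param spec a \code{\link{PowerSpectrum}}.
#' @param path output TSV path.
#' @export
writeSpectrum <- function(spec, path) {
  tab <- data.frame(freq_hz = spec@freqs, t(spec@power))
  colnames(tab)[-1] <- paste0("channel_", seq_len(nrow(spec@power)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a sphere annotation as a per-vertex table
#' @param ann a \code{\link{SphereAnnotation}}.
#' @param path output TSV path (vertex, x, y, z, label).
#' @export
writeSphereAnnotation <- function(ann, path) {
  tab <- data.frame(vertex = seq_len(nrow(ann@coords)),
                    x = ann@coords[, 1], y = ann@coords[, 2],
                    z = ann@coords[, 3], label = as.integer(ann@labels))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a sphere annotation from a per-vertex table
#' @param path TSV with columns vertex, x, y, z, label.
#' @param hemisphere "L" or "R".
#' @return a \code{\link{SphereAnnotation}}.
#' @export
readSphereAnnotation <- function(path, hemisphere) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  SphereAnnotation(as.matrix(tab[, c("x", "y", "z")]), tab$label != 0,
                   hemisphere)
}
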