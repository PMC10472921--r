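## Phase-locking core: PLV, the circular-shift surrogate null, per-voxel
## PLV-delta maps and the cross-subject surrogate null.

#' Resample a gastric phase series onto the BOLD volume grid
#'
#' Takes the 10 Hz instantaneous phase at the volume onset times (every
#' \code{TR * fs}-th sample) and drops the first \code{nTrim} volumes,
#' mirroring the exclusion applied to the BOLD series before the PLV.
#'
#' @param phaseSeries a \code{\link{PhaseSeries}} at the EGG rate.
#' @param TR repetition time in seconds.
#' @param nTrim initial volumes to drop (default 15, i.e. 30 s at TR = 2).
#' @param nVolumes optional expected number of volumes; errors on mismatch.
#' @return a \code{\link{PhaseSeries}} at 1/TR Hz with \code{nTrimmed} set.
#' @export
gastricToBoldGrid <- function(phaseSeries, TR, nTrim = 15L,
                              nVolumes = NULL) {
  step <- TR * phaseSeries@fs
  if (abs(step - round(step)) > 1e-9)
    stop("TR must be an integer number of EGG samples")
  step <- as.integer(round(step))
  idx <- seq(1L, length(phaseSeries@theta), by = step)
  if (!is.null(nVolumes)) {
    if (length(idx) < nVolumes)
      stop("gastric phase covers ", length(idx),
           " volumes but the BOLD run has ", nVolumes)
    idx <- idx[seq_len(nVolumes)]
  }
  theta <- phaseSeries@theta[idx]
  if (nTrim > 0L) theta <- theta[-seq_len(nTrim)]
  PhaseSeries(theta, fs = 1 / TR, t0Offset = nTrim * TR,
              nTrimmed = as.integer(nTrim))
}

#' Phase-locking value
#'
#' \eqn{PLV = | (1/T) \sum_t e^{i(\theta_x(t) - \theta_y(t))} |}: 1 when a
#' perfectly consistent phase lag exists, near 0 for unrelated phases.
#' \code{thetaY} may be a matrix with one series per row, giving one PLV per
#' row.
#'
#' @param thetaX numeric phase vector (radians) or \code{PhaseSeries}.
#' @param thetaY numeric phase vector, matrix (series x time) or
#'   \code{PhaseSeries}.
#' @return numeric scalar or vector in [0, 1].
#' @export
plv <- function(thetaX, thetaY) {
  if (is(thetaX, "PhaseSeries")) thetaX <- thetaX@theta
  if (is(thetaY, "PhaseSeries")) thetaY <- thetaY@theta
  if (is.matrix(thetaY)) {
    if (ncol(thetaY) != length(thetaX))
      stop("phase series lengths differ (", length(thetaX), " vs ",
           ncol(thetaY), ")")
    if (length(thetaX) < 2L) stop("need at least two time points")
    z <- exp(1i * thetaY) %*% exp(-1i * thetaX)
    return(as.numeric(Mod(z)) / length(thetaX))
  }
  if (length(thetaX) != length(thetaY))
    stop("phase series lengths differ (", length(thetaX), " vs ",
         length(thetaY), ")")
  if (length(thetaX) < 2L) stop("need at least two time points")
  Mod(mean(exp(1i * (thetaX - thetaY))))
}

#' Enumerate circular-shift surrogate lags
#'
#' Lags are taken on the full-length BOLD-rate grid as \code{L .. n - L - 1}
#' with \code{L = minLagS/TR + nTrim} samples, so every surrogate is at
#' least \code{minLagS} seconds away from the empirical alignment even after
#' the initial-volume trim. At the defaults (TR = 2 s, 15 trimmed volumes)
#' a 15-min run (450 volumes) yields 360 surrogates and a 10-min run (300
#' volumes) yields 210.
#'
#' @param nSamples full-grid series length in volumes.
#' @param minLagS minimum shift in seconds (default 60).
#' @param TR repetition time in seconds (default 2).
#' @param nTrim initial volumes excluded before the PLV (default 15).
#' @return a \code{\link{NullSpec}}.
#' @export
makeNullShifts <- function(nSamples, minLagS = 60, TR = 2, nTrim = 15L) {
  L <- as.integer(round(minLagS / TR)) + as.integer(nTrim)
  if (nSamples <= 2L * L)
    stop("recording too short: ", nSamples, " volumes leaves no lag in [",
         L, ", ", nSamples - L, ")")
  lags <- seq.int(L, nSamples - L - 1L)
  new("NullSpec", lags = as.integer(lags), minLagS = minLagS,
      guard = L, nTrim = as.integer(nTrim), nSamples = as.integer(nSamples))
}

## Empirical and surrogate PLVs for every voxel in one pass.
##
## boldTheta: voxels x nSamples phase matrix on the FULL volume grid;
## gastricTheta: full-grid gastric phase (length nSamples). The first
## nulls@nTrim samples are excluded from the sum; surrogates rotate the
## gastric series on the full grid *before* the trim. Computed as a
## circular cross-correlation of unit phasors via FFT, which equals the
## explicit rotate-trim-PLV loop to numerical precision.
plvWithNulls <- function(boldTheta, gastricTheta, nulls) {
  n <- nulls@nSamples
  if (length(gastricTheta) != n || ncol(boldTheta) != n)
    stop("series length does not match the null specification")
  nTrim <- nulls@nTrim
  tEff <- n - nTrim
  a <- exp(1i * t(boldTheta))           # time x voxels
  if (nTrim > 0L) a[seq_len(nTrim), ] <- 0
  b <- exp(1i * gastricTheta)
  C <- stats::mvfft(Conj(stats::mvfft(a)) * stats::fft(b),
                    inverse = TRUE) / n
  plvAll <- Mod(t(C)) / tEff            # voxels x lags (lag 0 first column)
  list(empirical = plvAll[, 1L],
       null = plvAll[, nulls@lags + 1L, drop = FALSE])
}

#' Voxelwise PLV, median surrogate PLV and PLV-delta
#'
#' For every voxel, the empirical PLV between the voxel phase and the
#' gastric phase (both with the first \code{nulls@nTrim} volumes excluded),
#' the median PLV across all circular-shift surrogates of the gastric
#' series, and their difference (PLV-delta), the run-level synchrony
#' effect size.
#'
#' @param boldTheta voxels x volumes matrix of BOLD phases on the full
#'   (untrimmed) volume grid.
#' @param gastricPhase \code{\link{PhaseSeries}} on the full volume grid.
#' @param nulls a \code{\link{NullSpec}} for the same grid length.
#' @param mask,gridShape passed through to the returned maps.
#' @param id identifier stored in the maps.
#' @return list of three \code{\link{BrainMap}}s: \code{empirical},
#'   \code{nullMedian}, \code{delta}.
#' @export
deltaMap <- function(boldTheta, gastricPhase, nulls, mask = NULL,
                     gridShape = NULL, id = NA_character_) {
  if (nNull(nulls) < 1L) stop("the null specification contains no lags")
  theta <- if (is(gastricPhase, "PhaseSeries")) gastricPhase@theta
           else gastricPhase
  res <- plvWithNulls(boldTheta, theta, nulls)
  med <- apply(res$null, 1L, stats::median)
  if (is.null(mask)) {
    mask <- rep(TRUE, nrow(boldTheta))
    gridShape <- c(nrow(boldTheta), 1L, 1L)
  }
  list(empirical = BrainMap(res$empirical, mask, gridShape, "plv", id),
       nullMedian = BrainMap(med, mask, gridShape, "null_plv", id),
       delta = BrainMap(res$empirical - med, mask, gridShape, "delta", id))
}

#' Average run-level maps into a subject map
#'
#' @param maps list of \code{\link{BrainMap}}s on the same mask.
#' @param id identifier for the output.
#' @return a \code{\link{BrainMap}} of the voxelwise mean.
#' @export
averageMaps <- function(maps, id = NA_character_) {
  vals <- rowMeans(vapply(maps, mapValues, numeric(nVoxels(maps[[1]]))))
  BrainMap(vals, maps[[1]]@mask, maps[[1]]@gridShape, maps[[1]]@mapType, id)
}

#' Cross-subject surrogate null
#'
#' For each subject, the PLV of that subject's voxel phases against every
#' other subject's gastric phase; series are truncated to the shortest
#' common length. Summarized per voxel by the median across donors.
#'
#' @param brainThetaList list (per subject) of voxels x time phase
#'   matrices (trimmed series).
#' @param gastricThetaList list (per subject) of gastric phase vectors
#'   (trimmed series).
#' @return list per subject with \code{null} (voxels x donors PLV matrix)
#'   and \code{nullMedian}.
#' @export
crossSubjectNull <- function(brainThetaList, gastricThetaList) {
  nS <- length(brainThetaList)
  if (nS < 2L) stop("need at least two subjects")
  tMin <- min(c(vapply(brainThetaList, ncol, 1L),
                vapply(gastricThetaList, length, 1L)))
  lapply(seq_len(nS), function(i) {
    donors <- setdiff(seq_len(nS), i)
    nullM <- vapply(donors, function(j) {
      plv(gastricThetaList[[j]][seq_len(tMin)],
          brainThetaList[[i]][, seq_len(tMin), drop = FALSE])
    }, numeric(nrow(brainThetaList[[i]])))
    list(null = nullM, nullMedian = apply(nullM, 1L, stats::median))
  })
}
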