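## BOLD preparation: PPG peak detection, RETROICOR regressors, nuisance
## design construction (four variants), OLS confound regression, masked
## Gaussian smoothing and motion-based run exclusion. The contracted stage
## order is regression -> smoothing -> gastric-band filtering.

#' The ten nuisance series tested for gastric synchrony
#' @export
CONFOUND_NAMES <- c("csf", "white_matter", "global_signal",
                    "framewise_displacement",
                    "trans_x", "trans_y", "trans_z",
                    "rot_x", "rot_y", "rot_z")

MOTION_NAMES <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

#' Detect systolic peaks in a pulse-oximetry trace
#'
#' Local maxima above an adaptive threshold (60th percentile plus a fraction
#' of the robust amplitude), cleaned so successive peaks are at least 0.3 s
#' apart (the larger peak wins). Inter-beat intervals outside 0.3-2.0 s are
#' flagged.
#'
#' @param x numeric PPG samples.
#' @param fs sampling rate in Hz (500 in a typical scanner setup).
#' @return list with \code{peakTimes} (s), \code{intervals} (s) and logical
#'   \code{flagged} per interval.
#' @export
detectPpgPeaks <- function(x, fs) {
  if (length(x) / fs < 10) stop("PPG trace must be at least 10 s long")
  if (stats::sd(x) == 0) {
    warning("flat PPG signal; no peaks detected")
    return(list(peakTimes = numeric(0), intervals = numeric(0),
                flagged = logical(0)))
  }
  ## light smoothing (20 ms) stabilises local maxima against sensor noise
  w <- max(1L, as.integer(0.02 * fs))
  if (w > 1L) x <- stats::filter(x, rep(1 / w, w), sides = 2)
  x[is.na(x)] <- 0
  x <- as.numeric(x)
  thr <- stats::quantile(x, 0.5) +
    0.45 * (stats::quantile(x, 0.99) - stats::quantile(x, 0.5))
  n <- length(x)
  isPk <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
              x[2:(n - 1)] >= x[3:n], FALSE) & x > thr
  idx <- which(isPk)
  if (length(idx) > 1L) {
    minGap <- as.integer(0.3 * fs)
    keep <- rep(TRUE, length(idx))
    last <- 1L
    for (i in 2L:length(idx)) {
      if (idx[i] - idx[last] < minGap) {
        if (x[idx[i]] > x[idx[last]]) { keep[last] <- FALSE; last <- i }
        else keep[i] <- FALSE
      } else last <- i
    }
    idx <- idx[keep]
  }
  pt <- (idx - 1L) / fs
  iv <- diff(pt)
  list(peakTimes = pt, intervals = iv,
       flagged = iv < 0.3 | iv > 2.0)
}

#' Cardiac RETROICOR regressors
#'
#' Assigns each frame a cardiac phase \eqn{\phi(t) = 2\pi (t - t_{prev}) /
#' (t_{next} - t_{prev})} from the surrounding systolic peaks and returns
#' \code{cos(m phi), sin(m phi)} for harmonics m = 1..\code{nHarmonics}.
#' Frames outside the detected peak span reuse the nearest cardiac cycle.
#'
#' @param peakTimes systolic peak times in seconds (>= 2).
#' @param frameTimes volume acquisition times in seconds.
#' @param nHarmonics number of harmonics (default 3, i.e. 6 columns).
#' @return matrix volumes x (2 * nHarmonics), columns
#'   \code{cardiac_cos1, cardiac_sin1, ...}.
#' @export
retroicorRegressors <- function(peakTimes, frameTimes, nHarmonics = 3) {
  if (length(peakTimes) < 2L) stop("need at least two cardiac peaks")
  pt <- sort(peakTimes)
  ## nearest-cycle extrapolation: clamp frames into the peak span using the
  ## first/last inter-beat interval
  phi <- vapply(frameTimes, function(t) {
    if (t <= pt[1]) {
      ibi <- pt[2] - pt[1]
      ph <- 2 * pi * ((t - pt[1]) %% ibi) / ibi
    } else if (t >= pt[length(pt)]) {
      ibi <- pt[length(pt)] - pt[length(pt) - 1L]
      ph <- 2 * pi * ((t - pt[length(pt)]) %% ibi) / ibi
    } else {
      i <- findInterval(t, pt)
      ph <- 2 * pi * (t - pt[i]) / (pt[i + 1L] - pt[i])
    }
    ph
  }, numeric(1))
  out <- do.call(cbind, lapply(seq_len(nHarmonics), function(m) {
    cbind(cos(m * phi), sin(m * phi))
  }))
  colnames(out) <- as.vector(vapply(seq_len(nHarmonics), function(m) {
    c(sprintf("cardiac_cos%d", m), sprintf("cardiac_sin%d", m))
  }, character(2)))
  out
}

#' Build a nuisance design matrix
#'
#' Four recipes are supported. \code{main_gsr}: intercept, global signal,
#' framewise displacement, the six motion estimates, their backward-difference
#' derivatives, the squares of the motion estimates and of the derivatives,
#' and six aCompCor components. \code{no_gsr}: the same minus the global
#' signal. \code{gsr_retroicor}: \code{main_gsr} plus six cardiac RETROICOR
#' columns. \code{minimal}: intercept and CSF only. Derivatives and squares
#' are scoped to the six motion estimates.
#'
#' @param tab data.frame with one row per volume; required columns depend on
#'   the variant (fMRIPrep-style names, see \code{\link{CONFOUND_NAMES}};
#'   aCompCor as \code{a_comp_cor_00..05}, RETROICOR as
#'   \code{cardiac_cos1..sin3}).
#' @param variant one of \code{"main_gsr"}, \code{"no_gsr"},
#'   \code{"gsr_retroicor"}, \code{"minimal"}.
#' @return list with \code{matrix} (volumes x regressors, named columns
#'   including \code{intercept}) and \code{variant}.
#' @export
buildConfoundDesign <- function(tab, variant = c("main_gsr", "no_gsr",
                                                 "gsr_retroicor",
                                                 "minimal")) {
  variant <- match.arg(variant)
  need <- switch(variant,
    minimal = "csf",
    main_gsr = c("global_signal", "framewise_displacement", MOTION_NAMES),
    no_gsr = c("framewise_displacement", MOTION_NAMES),
    gsr_retroicor = c("global_signal", "framewise_displacement",
                      MOTION_NAMES))
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stop("confound table is missing required column(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(tab)
  X <- list(intercept = rep(1, n))
  if (variant == "minimal") {
    X$csf <- tab$csf
  } else {
    if (variant != "no_gsr") X$global_signal <- tab$global_signal
    X$framewise_displacement <- tab$framewise_displacement
    for (m in MOTION_NAMES) X[[m]] <- tab[[m]]
    for (m in MOTION_NAMES) {
      d <- c(0, diff(tab[[m]]))
      X[[paste0(m, "_derivative1")]] <- d
      X[[paste0(m, "_power2")]] <- tab[[m]]^2
      X[[paste0(m, "_derivative1_power2")]] <- d^2
    }
    acc <- grep("^a_comp_cor_0[0-5]$", colnames(tab), value = TRUE)
    for (a in sort(acc)) X[[a]] <- tab[[a]]
    if (variant == "gsr_retroicor") {
      rcols <- grep("^cardiac_(cos|sin)[1-3]$", colnames(tab), value = TRUE)
      if (length(rcols) == 0L)
        stop("confound table is missing required column(s): cardiac_cos1..cardiac_sin3")
      for (rc in rcols) X[[rc]] <- tab[[rc]]
    }
  }
  m <- do.call(cbind, X)
  colnames(m) <- names(X)
  list(matrix = m, variant = variant)
}

#' Regress nuisance series out of a BOLD run
#'
#' Per-voxel ordinary-least-squares residualization against the design.
#' Rank-deficient designs have their collinear columns dropped with a
#' warning. Residuals are orthogonal to every retained design column.
#'
#' @param run a \code{\link{BOLDRun}}.
#' @param design output of \code{\link{buildConfoundDesign}} (or any list
#'   with a \code{matrix} element with one row per volume).
#' @return a \code{\link{BOLDRun}} of residuals.
#' @export
regressConfounds <- function(run, design) {
  X <- design$matrix
  if (nrow(X) != nVolumes(run))
    stop("design has ", nrow(X), " rows but the run has ", nVolumes(run),
         " volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning("dropping collinear design column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  resid <- t(qr.resid(qrX, t(run@data)))
  initialize(run, data = resid)
}

#' Spatially smooth a BOLD run with a 3-D Gaussian kernel
#'
#' Separable Gaussian smoothing per volume with sigma =
#' \code{fwhm / (2 sqrt(2 log 2))} per axis, scaled by the voxel size.
#' Smoothing is confined to the mask and normalized by the smoothed mask so
#' edge voxels are not dimmed.
#'
#' @param run a \code{\link{BOLDRun}}.
#' @param fwhm full width at half maximum in mm (default 3; 0 = identity).
#' @return smoothed \code{\link{BOLDRun}}.
#' @export
smoothGaussian <- function(run, fwhm = 3) {
  if (fwhm < 0) stop("fwhm must be non-negative")
  if (fwhm == 0) return(run)
  dims <- run@gridShape
  sigmaVox <- (fwhm / (2 * sqrt(2 * log(2)))) / run@voxelSize
  kernels <- lapply(1:3, function(ax) {
    s <- sigmaVox[ax]
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(( -r:r)^2) / (2 * s^2))
    k / sum(k)
  })
  maskArr <- array(0, dims)
  maskArr[run@mask] <- 1
  smMask <- gaussSmooth3d(maskArr, kernels)
  out <- run@data
  for (v in seq_len(ncol(out))) {
    vol <- array(0, dims)
    vol[run@mask] <- run@data[, v]
    sm <- gaussSmooth3d(vol, kernels)
    out[, v] <- sm[run@mask] / smMask[run@mask]
  }
  initialize(run, data = out)
}

## separable 3-D convolution with zero padding
gaussSmooth3d <- function(arr, kernels) {
  d <- dim(arr)
  for (ax in 1:3) {
    k <- kernels[[ax]]
    r <- (length(k) - 1L) / 2L
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = d[ax])
    n <- nrow(m)
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    sm <- fftConvSame(padded, k)[(r + 1L):(r + n), , drop = FALSE]
    arr <- aperm(array(sm, d[perm]), order(perm))
  }
  arr
}

#' Flag runs with excessive head motion
#'
#' A run is excluded when its mean framewise displacement exceeds the group
#' mean by more than two group standard deviations.
#'
#' @param meanFd numeric vector of per-run mean FD values (>= 3 entries).
#' @param nSd exclusion threshold in group SDs (default 2).
#' @return logical keep flags, \code{FALSE} = excluded.
#' @export
motionExclusion <- function(meanFd, nSd = 2) {
  if (length(meanFd) < 3L) stop("need at least three runs")
  thr <- mean(meanFd) + nSd * stats::sd(meanFd)
  meanFd <= thr
}
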