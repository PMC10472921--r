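## Seeded generators for synthetic EGG / BOLD / confound / PPG cohorts with
## the statistical structure the synchrony analysis assumes: a narrow-band,
## phase-drifting gastric oscillator; BOLD voxels a known subset of which
## holds a tunable phase lock to that oscillator; nuisance series that can
## share the gastric rhythm; and a pulse trace with known beat times.

#' Simulation configuration
#'
#' Defaults mirror the acquisition this pipeline targets: 15-min runs at
#' TR = 2 s, a 10 Hz EGG with a subject-specific peak near 0.05 Hz
#' (SD 0.005, truncated to the 0.033-0.066 Hz normogastric band), two runs
#' per subject, and a 12x12x12 voxel grid of 3 mm voxels with a 27-voxel
#' coupled block.
#'
#' @param nSubjects,runsPerSubject cohort layout.
#' @param runDurationS run length in seconds (900 or 600).
#' @param eggFs EGG sampling rate in Hz.
#' @param TR repetition time in seconds.
#' @param gridShape,voxelSize BOLD grid.
#' @param nCoupledVoxels size of the gastric-coupled block.
#' @param couplingPlvTarget nominal PLV of coupled voxels in [0, 1].
#' @param couplingJitterFreq frequency (Hz) of the phase-jitter modulation
#'   used to realise the coupling target (kept inside the gastric passband).
#' @param peakFreqMean,peakFreqSd,peakFreqBand subject peak distribution.
#' @param phaseDriftSd,phaseDriftTau gastric oscillator phase drift
#'   (stationary SD in radians; relaxation time in seconds).
#' @param eggSnr amplitude ratio of the gastric rhythm to 1/f noise on the
#'   best channel.
#' @param channelAmps relative gastric amplitude of the four EGG channels.
#' @param boldNoiseSd,boldAr1 BOLD noise level and AR(1) coefficient.
#' @param nLatent,fcStrength subject-specific connectivity structure:
#'   number of latent time courses and their mixing amplitude.
#' @param confoundCoupling PLV-scale coupling of the shared artifact to the
#'   gastric rhythm (0 disables artifact injection).
#' @param boldArtifactAmp amplitude of the shared artifact added to BOLD
#'   voxels when \code{confoundCoupling > 0}.
#' @param subjectStability 1 = coupling strength, peak frequency and
#'   connectivity structure stable across a subject's runs; 0 = redrawn
#'   per run.
#' @param couplingRange multiplicative range (low, high) of the per-subject
#'   coupling draw around \code{couplingPlvTarget}.
#' @param heartRateBpm mean heart rate for the PPG generator.
#' @param ppgFs PPG sampling rate in Hz.
#' @param seed RNG seed.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(nSubjects = 23L, runsPerSubject = 2L,
                      runDurationS = 900, eggFs = 10, TR = 2,
                      gridShape = c(12L, 12L, 12L), voxelSize = c(3, 3, 3),
                      nCoupledVoxels = 27L, couplingPlvTarget = 0.5,
                      couplingJitterFreq = 0.005,
                      peakFreqMean = 0.05, peakFreqSd = 0.005,
                      peakFreqBand = c(0.033, 0.066),
                      phaseDriftSd = 1.3, phaseDriftTau = 150,
                      eggSnr = 8, channelAmps = c(3, 2, 1.5, 1.2),
                      boldNoiseSd = 0.5, boldAr1 = 0.3,
                      nLatent = 5L, fcStrength = 0.4,
                      confoundCoupling = 0, boldArtifactAmp = 0.8,
                      subjectStability = 1, couplingRange = c(0.4, 1.6),
                      heartRateBpm = 70, ppgFs = 500, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$runDurationS > 0, cfg$eggFs > 0, cfg$TR > 0,
            cfg$couplingPlvTarget >= 0, cfg$couplingPlvTarget <= 1,
            cfg$confoundCoupling >= 0, cfg$confoundCoupling <= 1,
            cfg$subjectStability >= 0, cfg$subjectStability <= 1)
  cfg$nVolumes <- as.integer(round(cfg$runDurationS / cfg$TR))
  class(cfg) <- "SimConfig"
  cfg
}

## phase-jitter amplitude realising a PLV target: a sinusoidal phase
## modulation of amplitude A has |mean exp(i A cos)| = |J0(A)|, so A =
## J0^{-1}(target) on [0, first zero of J0]
jitterAmpForPlv <- function(target) {
  if (target >= 1) return(0)
  if (target <= 0) return(2.404826)
  stats::uniroot(function(a) besselJ(a, 0) - target,
                 c(0, 2.404825), tol = 1e-10)$root
}

## Ornstein-Uhlenbeck process, stationary start
ouProcess <- function(n, dt, tau, stationarySd) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, stationarySd)
  a <- exp(-dt / tau)
  s <- stationarySd * sqrt(1 - a^2)
  innov <- stats::rnorm(n - 1, 0, s)
  for (k in 2:n) x[k] <- a * x[k - 1] + innov[k - 1]
  x
}

## 1/f amplitude-shaped Gaussian noise, unit SD
oneOverFNoise <- function(n, fs) {
  z <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))  # avoid the DC singularity
  f <- pmin(f, n - f + 1)
  z <- z / sqrt(f)
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  x / stats::sd(x)
}

## AR(1)-plus-white noise matrix, series x time, unit total SD
arNoiseMatrix <- function(nSeries, nTime, rho, sd = 1) {
  w <- matrix(stats::rnorm(nSeries * nTime), nSeries, nTime)
  if (rho != 0) {
    for (k in 2:nTime) w[, k] <- rho * w[, k - 1] + w[, k]
    w <- w * sqrt(1 - rho^2)
  }
  w * sd
}

#' Generate a gastric oscillator phase track
#'
#' Unwrapped instantaneous phase of a narrow-band oscillator: a linear ramp
#' at \code{peakFreq} plus Ornstein-Uhlenbeck phase drift.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param peakFreq oscillator frequency in Hz.
#' @return numeric unwrapped phase at \code{cfg$eggFs}.
#' @export
genGastricOscillator <- function(cfg, peakFreq) {
  n <- as.integer(round(cfg$runDurationS * cfg$eggFs))
  tt <- (seq_len(n) - 1L) / cfg$eggFs
  drift <- ouProcess(n, 1 / cfg$eggFs, cfg$phaseDriftTau, cfg$phaseDriftSd)
  2 * pi * peakFreq * tt + drift
}

#' Generate a multichannel EGG recording
#'
#' Four channels sharing one gastric oscillator at channel-specific
#' amplitudes, plus 1/f noise and a weak 1.2 Hz cardiac bleed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param oscPhase unwrapped oscillator phase from
#'   \code{\link{genGastricOscillator}} (drawn if NULL).
#' @param peakFreq used when \code{oscPhase} is NULL.
#' @param subjectId,runId identifiers.
#' @param seed optional seed (uses the current RNG stream when NULL).
#' @return an \code{\link{EGGRecording}}; the oscillator phase is attached
#'   as attribute \code{"oscPhase"}.
#' @export
genEggRecording <- function(cfg, oscPhase = NULL, peakFreq = cfg$peakFreqMean,
                            subjectId = "s1", runId = "r1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(oscPhase)) oscPhase <- genGastricOscillator(cfg, peakFreq)
  n <- length(oscPhase)
  tt <- (seq_len(n) - 1L) / cfg$eggFs
  gast <- cos(oscPhase)
  noiseAmp <- max(cfg$channelAmps) / cfg$eggSnr
  samples <- t(vapply(cfg$channelAmps, function(a) {
    a * gast + noiseAmp * oneOverFNoise(n, cfg$eggFs) +
      0.2 * noiseAmp * cos(2 * pi * 1.2 * tt + stats::runif(1, 0, 2 * pi))
  }, numeric(n)))
  rec <- EGGRecording(samples, fs = cfg$eggFs,
                      subjectId = subjectId, runId = runId)
  attr(rec, "oscPhase") <- oscPhase
  rec
}

## coupled-block voxel indices: a cube centred in the grid
coupledBlockIndices <- function(gridShape, nCoupled) {
  side <- pmin(max(1L, round(nCoupled^(1 / 3))), gridShape)
  while (prod(side) < nCoupled && any(side < gridShape)) {
    ax <- which.max(gridShape - side)
    side[ax] <- side[ax] + 1L
  }
  start <- pmax(1L, (gridShape - side) %/% 2L + 1L)
  coords <- as.matrix(expand.grid(
    x = start[1]:(start[1] + side[1] - 1L),
    y = start[2]:(start[2] + side[2] - 1L),
    z = start[3]:(start[3] + side[3] - 1L)))
  idx <- coords[, 1] + gridShape[1] * ((coords[, 2] - 1L) +
                                         gridShape[2] * (coords[, 3] - 1L))
  sort(idx)[seq_len(min(nCoupled, length(idx)))]
}

#' Generate a BOLD run with a gastric-coupled voxel block
#'
#' Coupled voxels follow \code{cos(gastric phase + lag + jitter)} where the
#' jitter is a slow sinusoidal phase modulation whose amplitude is set by
#' the closed form \code{PLV = J0(A)} to realise \code{couplingPlv};
#' uncoupled voxels are AR(1)-plus-white noise mixed with subject-specific
#' latent time courses (the connectivity fingerprint). An optional shared
#' artifact series is added to every voxel.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param oscPhase unwrapped 10 Hz gastric oscillator phase.
#' @param couplingPlv realised coupling target (default
#'   \code{cfg$couplingPlvTarget}).
#' @param mixing optional voxels x nLatent mixing matrix (drawn if NULL).
#' @param artifact optional artifact series (length = volumes).
#' @param subjectId,runId identifiers.
#' @param seed optional seed.
#' @return a \code{\link{BOLDRun}} with ground truth attached as attribute
#'   \code{"truth"} (coupled indices in mask order, lags, realised target,
#'   gastric phase on the volume grid).
#' @export
genCoupledBold <- function(cfg, oscPhase, couplingPlv = cfg$couplingPlvTarget,
                           mixing = NULL, artifact = NULL,
                           subjectId = "s1", runId = "r1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nVox <- prod(cfg$gridShape)
  nT <- cfg$nVolumes
  step <- as.integer(round(cfg$TR * cfg$eggFs))
  thetaBold <- oscPhase[seq(1L, by = step, length.out = nT)]
  tt <- (seq_len(nT) - 1L) * cfg$TR
  mask <- rep(TRUE, nVox)
  coupled <- coupledBlockIndices(cfg$gridShape, cfg$nCoupledVoxels)
  data <- arNoiseMatrix(nVox, nT, cfg$boldAr1, cfg$boldNoiseSd)
  ## subject-specific connectivity structure on uncoupled voxels
  if (is.null(mixing))
    mixing <- matrix(stats::rnorm(nVox * cfg$nLatent, 0, cfg$fcStrength),
                     nVox, cfg$nLatent)
  latents <- arNoiseMatrix(cfg$nLatent, nT, 0.5)
  data <- data + mixing %*% latents
  ## coupled block: tuned phase lock to the gastric rhythm (zero coupling
  ## means no gastric carrier at all)
  lags <- stats::runif(length(coupled), 0, 2 * pi)
  if (couplingPlv > 0 && length(coupled)) {
    A <- jitterAmpForPlv(couplingPlv)
    psi <- stats::runif(length(coupled), 0, 2 * pi)
    jitter <- outer(psi, 2 * pi * cfg$couplingJitterFreq * tt,
                    function(p, w) A * cos(w + p))
    data[coupled, ] <- data[coupled, ] +
      cos(outer(lags, thetaBold, `+`) + jitter)
  }
  if (!is.null(artifact)) data <- data + outer(
    stats::rnorm(nVox, cfg$boldArtifactAmp, 0.1 * cfg$boldArtifactAmp),
    artifact)
  run <- BOLDRun(data, mask, cfg$gridShape, cfg$voxelSize, cfg$TR,
                 subjectId = subjectId, runId = runId)
  attr(run, "truth") <- list(coupledIdx = coupled, lags = lags,
                             couplingPlv = couplingPlv,
                             thetaBold = wrapPhase(thetaBold))
  run
}

#' Generate a confound table and a PPG trace
#'
#' All ten nuisance columns plus six aCompCor columns. When
#' \code{cfg$confoundCoupling > 0}, a gastric-locked artifact series is
#' injected into the global signal and the x-translation and x/z-rotation
#' columns (the motion-borne artifact, optionally shared with the BOLD
#' data), and an independent gastric-locked series into the CSF column.
#' The PPG trace has systolic peaks at known beat times.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param oscPhase unwrapped 10 Hz gastric oscillator phase.
#' @param artifactScale per-run multiplier on the artifact amplitude.
#' @param seed optional seed.
#' @param makePpg synthesise the PPG trace (skipped when FALSE; beat times
#'   are still returned).
#' @return list: \code{confounds} (data.frame), \code{ppg} (list with
#'   \code{samples}, \code{fs}, \code{beatTimes}), \code{artifact} (the
#'   motion-borne series to share with BOLD, or NULL).
#' @export
genConfoundsAndPpg <- function(cfg, oscPhase, artifactScale = 1,
                               seed = NULL, makePpg = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  nT <- cfg$nVolumes
  step <- as.integer(round(cfg$TR * cfg$eggFs))
  thetaBold <- oscPhase[seq(1L, by = step, length.out = nT)]
  tt <- (seq_len(nT) - 1L) * cfg$TR
  base <- function() arNoiseMatrix(1L, nT, 0.3)[1L, ]
  tab <- data.frame(csf = base(), white_matter = base(),
                    global_signal = base(),
                    framewise_displacement = abs(base()) * 0.05 + 0.02,
                    trans_x = base() * 0.1, trans_y = base() * 0.1,
                    trans_z = base() * 0.1, rot_x = base() * 0.002,
                    rot_y = base() * 0.002, rot_z = base() * 0.002)
  for (i in 0:5) tab[[sprintf("a_comp_cor_0%d", i)]] <- base()
  artifact <- NULL
  if (cfg$confoundCoupling > 0) {
    lockSeries <- function() {
      A <- jitterAmpForPlv(cfg$confoundCoupling)
      psi <- stats::runif(1, 0, 2 * pi)
      lag <- stats::runif(1, 0, 2 * pi)
      cos(thetaBold + lag + A * cos(2 * pi * cfg$couplingJitterFreq * tt +
                                      psi))
    }
    artifact <- artifactScale * lockSeries()
    csfLock <- artifactScale * lockSeries()
    ## motion estimates measure the shared motion almost noise-free, so the
    ## artifact dominates those columns; the global signal carries it on
    ## top of genuine whole-brain fluctuations
    tab$global_signal <- tab$global_signal + 1.5 * artifact
    tab$trans_x <- tab$trans_x + 0.2 * artifact
    tab$rot_x <- tab$rot_x + 0.004 * artifact
    tab$rot_z <- tab$rot_z + 0.004 * artifact
    tab$csf <- tab$csf + csfLock
  }
  ## PPG: Gaussian systolic pulses at a subject heart rate with mild HRV
  hr <- cfg$heartRateBpm / 60
  beats <- cumsum(stats::rnorm(ceiling(cfg$runDurationS * hr * 1.2),
                               1 / hr, 0.02 / hr))
  beats <- beats[beats < cfg$runDurationS - 0.5]
  ppg <- NULL
  if (makePpg) {
    nPpg <- as.integer(cfg$runDurationS * cfg$ppgFs)
    ppg <- numeric(nPpg)
    halfWin <- as.integer(0.3 * cfg$ppgFs)   # pulses are compact in time
    for (b in beats) {
      ctr <- as.integer(round(b * cfg$ppgFs)) + 1L
      idx <- max(1L, ctr - halfWin):min(nPpg, ctr + halfWin)
      ppg[idx] <- ppg[idx] + exp(-(((idx - 1L) / cfg$ppgFs - b)^2) /
                                   (2 * 0.05^2))
    }
    ppg <- ppg + 0.02 * stats::rnorm(nPpg)
  }
  list(confounds = tab,
       ppg = list(samples = ppg, fs = cfg$ppgFs, beatTimes = beats),
       artifact = artifact)
}

#' Generate a full multi-subject, multi-run cohort
#'
#' Draws subject-level parameters (peak frequency, coupling strength,
#' connectivity mixing) once per subject when \code{subjectStability = 1},
#' or afresh for every run when 0, then generates EGG, BOLD, confounds and
#' PPG per run. Deterministic for a given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param includePpg generate PPG traces (default TRUE).
#' @return list of class \code{SimCohort}: \code{cfg} and \code{subjects},
#'   each subject a list of runs with elements \code{egg}, \code{bold},
#'   \code{confounds}, \code{ppg} and \code{truth}.
#' @export
genCohort <- function(cfg, includePpg = TRUE) {
  set.seed(cfg$seed)
  drawPeak <- function() {
    repeat {
      f <- stats::rnorm(1, cfg$peakFreqMean, cfg$peakFreqSd)
      if (f >= cfg$peakFreqBand[1] && f <= cfg$peakFreqBand[2]) return(f)
    }
  }
  drawCoupling <- function() {
    min(0.95, max(0, cfg$couplingPlvTarget *
                       stats::runif(1, cfg$couplingRange[1],
                                    cfg$couplingRange[2])))
  }
  nVox <- prod(cfg$gridShape)
  subjects <- lapply(seq_len(cfg$nSubjects), function(s) {
    stable <- cfg$subjectStability >= stats::runif(1)
    peakS <- drawPeak(); coupS <- drawCoupling()
    mixS <- matrix(stats::rnorm(nVox * cfg$nLatent, 0, cfg$fcStrength),
                   nVox, cfg$nLatent)
    runs <- lapply(seq_len(cfg$runsPerSubject), function(r) {
      peak <- if (stable) peakS else drawPeak()
      coup <- if (stable) coupS else drawCoupling()
      mix <- if (stable) mixS else
        matrix(stats::rnorm(nVox * cfg$nLatent, 0, cfg$fcStrength),
               nVox, cfg$nLatent)
      osc <- genGastricOscillator(cfg, peak)
      egg <- genEggRecording(cfg, oscPhase = osc,
                             subjectId = paste0("s", s),
                             runId = paste0("r", r))
      cp <- genConfoundsAndPpg(cfg, osc,
                               artifactScale = stats::runif(1, 0.05, 1),
                               makePpg = includePpg)
      bold <- genCoupledBold(cfg, osc, couplingPlv = coup, mixing = mix,
                             artifact = cp$artifact,
                             subjectId = paste0("s", s),
                             runId = paste0("r", r))
      truth <- attr(bold, "truth")
      truth$peakFreq <- peak
      truth$oscPhase <- osc
      list(egg = egg, bold = bold, confounds = cp$confounds,
           ppg = if (includePpg) cp$ppg else NULL, truth = truth)
    })
    runs
  })
  structure(list(cfg = cfg, subjects = subjects), class = "SimCohort")
}

#' Generate a labelled synthetic sphere pair
#'
#' Quasi-uniform vertices per hemisphere from a deterministic Fibonacci
#' lattice, with one contiguous label patch of the requested fraction. With
#' \code{symmetric = TRUE} the left patch is the sagittal mirror (x
#' negated) of the right patch, assigned by nearest neighbour.
#'
#' @param nVertices vertices per hemisphere (>= 100).
#' @param labelFraction fraction of vertices labelled.
#' @param symmetric mirror the left patch from the right.
#' @param seed RNG seed for the patch centre.
#' @return list with \code{L} and \code{R} \code{\link{SphereAnnotation}}s.
#' @export
genSphereAnnotation <- function(nVertices, labelFraction, symmetric = FALSE,
                                seed = 1L) {
  if (nVertices < 100L) stop("need at least 100 vertices")
  set.seed(seed)
  coords <- fibonacciSphere(nVertices)
  nLab <- round(labelFraction * nVertices)
  makePatch <- function(centre) {
    lab <- logical(nVertices)
    if (nLab > 0) {
      sim <- as.numeric(coords %*% centre)
      lab[order(sim, decreasing = TRUE)[seq_len(nLab)]] <- TRUE
    }
    lab
  }
  centreR <- stats::rnorm(3)
  centreR <- centreR / sqrt(sum(centreR^2))
  labR <- makePatch(centreR)
  labL <- if (symmetric) {
    mirrored <- coords[labR, , drop = FALSE] %*% diag(c(-1, 1, 1))
    lab <- logical(nVertices)
    if (sum(labR)) {
      nn <- max.col(mirrored %*% t(coords), ties.method = "first")
      lab[nn] <- TRUE
    }
    lab
  } else {
    centreL <- stats::rnorm(3)
    makePatch(centreL / sqrt(sum(centreL^2)))
  }
  list(L = SphereAnnotation(coords, labL, "L"),
       R = SphereAnnotation(coords, labR, "R"))
}

fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
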