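## Shared signal-processing primitives: FIR design, zero-phase filtering,
## analytic-signal phase. Matrix variants operate column-wise via mvfft so
## whole BOLD runs are filtered in a handful of FFTs.

#' Wrap phase values into (-pi, pi]
#' @param theta numeric vector of angles in radians.
#' @return wrapped angles.
#' @export
wrapPhase <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

## Hamming-windowed sinc band-pass taps. Cutoffs in Hz, odd length so the
## group delay is an integer number of samples.
firBandpassTaps <- function(fs, low, high, nTaps) {
  if (low <= 0 || high >= fs / 2)
    stop("band [", low, ", ", high, "] Hz infeasible at fs = ", fs, " Hz")
  if (nTaps %% 2L == 0L) nTaps <- nTaps + 1L
  m <- (nTaps - 1L) / 2L
  k <- -m:m
  f1 <- low / fs
  f2 <- high / fs
  h <- ifelse(k == 0L, 2 * (f2 - f1),
              (sin(2 * pi * f2 * k) - sin(2 * pi * f1 * k)) / (pi * k))
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h * w
}

## Linear convolution of each column of x with kernel h, via FFT, returning
## only the "same"-aligned part (centre of the full convolution). h must
## have odd length.
fftConvSame <- function(x, h) {
  x <- cbind(x)
  n <- nrow(x)
  k <- length(h)
  half <- (k - 1L) %/% 2L
  nfft <- stats::nextn(n + k - 1L, 2)
  H <- stats::fft(c(h, rep(0, nfft - k)))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  y[(half + 1L):(half + n), , drop = FALSE]
}

## Zero-phase FIR filtering with reflect padding of one filter length per
## side. Equivalent to forward-backward application: the effective kernel is
## the (symmetric) autocorrelation of the taps, so the net phase shift is
## exactly zero.
zeroPhaseFilter <- function(x, taps) {
  vec <- is.null(dim(x))
  x <- cbind(x)
  n <- nrow(x)
  k <- length(taps)
  g <- stats::convolve(taps, rev(taps), type = "open")  # taps * rev(taps)
  pad <- min(k, n - 1L)
  idxTop <- (pad + 1L):2L
  idxBot <- (n - 1L):(n - pad)
  xp <- rbind(x[idxTop, , drop = FALSE], x, x[idxBot, , drop = FALSE])
  y <- fftConvSame(xp, g)
  y <- y[(pad + 1L):(pad + n), , drop = FALSE]
  if (vec) drop(y) else y
}

#' Band-pass a signal around the gastric peak frequency
#'
#' Linear-phase FIR band-pass (Hamming-windowed sinc) applied with zero net
#' phase shift, with reflect padding at the edges. The filter length spans
#' \code{orderCycles} cycles of \code{peakFreq}, the same design at any
#' sampling rate, so EGG (10 Hz) and BOLD-rate (1/TR) series receive the
#' same spectral treatment.
#'
#' @param x numeric vector, or a matrix with one series per column.
#' @param fs sampling rate in Hz.
#' @param peakFreq centre frequency in Hz.
#' @param halfwidth half passband width in Hz (default 0.015).
#' @param orderCycles filter length in cycles of \code{peakFreq}.
#' @return filtered vector or matrix matching \code{x}.
#' @export
bandpassAroundPeak <- function(x, fs, peakFreq, halfwidth = 0.015,
                               orderCycles = 6) {
  if (!is.finite(peakFreq) || peakFreq - halfwidth <= 0)
    stop("peakFreq - halfwidth must be positive")
  if (fs / 2 <= peakFreq + halfwidth)
    stop("band extends beyond the Nyquist frequency at fs = ", fs)
  nTaps <- as.integer(round(orderCycles / peakFreq * fs))
  taps <- firBandpassTaps(fs, peakFreq - halfwidth, peakFreq + halfwidth,
                          nTaps)
  zeroPhaseFilter(x, taps)
}

## Analytic signal via the FFT method (one-sided spectrum doubling).
analyticSignal <- function(x) {
  vec <- is.null(dim(x))
  x <- cbind(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  z <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
  if (vec) drop(z) else z
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal by the FFT method and returns the angle as a
#' \code{\link{PhaseSeries}}. The input is expected to be narrow-band
#' (already band-passed); no taper is applied at the edges.
#'
#' @param x numeric vector (band-limited), length >= 16.
#' @param fs sampling rate in Hz.
#' @return a \code{PhaseSeries}.
#' @export
hilbertPhase <- function(x, fs) {
  if (length(x) < 16L) stop("need at least 16 samples")
  if (stats::sd(x) == 0) stop("constant input has undefined phase")
  PhaseSeries(Arg(analyticSignal(x)), fs = fs)
}

## Matrix version used for whole BOLD runs: returns voxels x time phase
## matrix (input voxels x time).
hilbertPhaseMatrix <- function(x) {
  t(Arg(analyticSignal(t(x))))
}

#' Resample a signal to a new rate
#'
#' Rational resampling with an explicit zero-phase anti-alias low-pass
#' (windowed sinc, cutoff 0.45 of the output rate) ahead of the rate
#' change; integer decimation is done by direct sample picking, other
#' ratios via \code{signal::resample}. Used to bring 5000 Hz (or 500 Hz)
#' physiological recordings to the 10 Hz EGG analysis rate.
#'
#' @param x numeric vector.
#' @param fsIn,fsOut input and output rates in Hz, \code{fsIn >= fsOut > 0}.
#' @return numeric vector of length \code{round(length(x) * fsOut / fsIn)}.
#' @export
resampleSignal <- function(x, fsIn, fsOut) {
  if (!is.finite(fsIn) || !is.finite(fsOut) || fsIn <= 0 || fsOut <= 0)
    stop("sampling rates must be positive")
  if (fsOut > fsIn) stop("upsampling is not supported (fsOut > fsIn)")
  if (fsOut == fsIn) return(x)
  r <- ratioAsIntegers(fsOut, fsIn)
  nOut <- round(length(x) * fsOut / fsIn)
  ## zero-phase anti-alias low-pass at 0.45 * fsOut
  fc <- 0.45 * fsOut / fsIn
  nTaps <- min(8191L, as.integer(10 * ceiling(fsIn / fsOut)) + 1L)
  m <- (nTaps - 1L) %/% 2L
  k <- -m:m
  h <- ifelse(k == 0L, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  h <- h * (0.54 + 0.46 * cos(pi * k / m))
  h <- h / sum(h)                       # unit DC gain
  xf <- zeroPhaseFilter(x, h)
  y <- if (r[1] == 1L) xf[seq(1L, by = r[2], length.out = nOut)]
       else signal::resample(xf, r[1], r[2])
  length(y) <- nOut
  if (anyNA(y)) y[is.na(y)] <- y[max(which(!is.na(y)))]
  y
}

ratioAsIntegers <- function(a, b) {
  ## smallest integers p/q with a/b = p/q (rates are rationals in practice)
  f <- MASS_fractions(a / b)
  c(f[1], f[2])
}

## minimal continued-fraction rationalization (avoids an extra dependency)
MASS_fractions <- function(x, tol = 1e-9, maxIter = 40L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  for (i in seq_len(maxIter)) {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (abs(p2 / q2 - x) < tol * max(1, abs(x))) return(c(p2, q2))
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(r - a) < 1e-15) break
    r <- 1 / (r - a)
  }
  c(p1, q1)
}

#' Voxelwise gastric-band phase of a BOLD run
#'
#' Band-passes every voxel around the gastric peak at the BOLD rate and
#' extracts the instantaneous phase via the Hilbert transform.
#'
#' @param run a \code{\link{BOLDRun}} (already confound-regressed and
#'   smoothed, when those stages apply).
#' @param peakFreq gastric peak frequency in Hz.
#' @param halfwidth filter half width in Hz (default 0.015).
#' @return voxels x volumes matrix of phases on the full volume grid.
#' @export
boldPhase <- function(run, peakFreq, halfwidth = 0.015) {
  filt <- t(bandpassAroundPeak(t(run@data), fs = 1 / run@TR,
                               peakFreq = peakFreq, halfwidth = halfwidth))
  hilbertPhaseMatrix(filt)
}
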