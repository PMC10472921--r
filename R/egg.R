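## EGG preprocessing: Welch spectra, gastric peak detection in the
## normogastric band, channel selection and three-level quality grading.

#' Default normogastric search band (Hz)
#' @export
GASTRIC_BAND <- c(0.033, 0.066)

#' Welch power spectrum of an EGG recording
#'
#' Averaged modified periodograms with a Hann window. The frequency
#' resolution is \code{1/windowS}.
#'
#' @param rec an \code{\link{EGGRecording}}.
#' @param windowS segment length in seconds (default 200).
#' @param overlapS segment overlap in seconds (default 150).
#' @return a \code{\link{PowerSpectrum}}.
#' @export
welchSpectrum <- function(rec, windowS = 200, overlapS = 150) {
  stopifnot(is(rec, "EGGRecording"))
  fs <- rec@fs
  n <- ncol(rec@samples)
  nper <- as.integer(round(windowS * fs))
  if (n < nper)
    stop("recording (", sprintf("%.1f", n / fs),
         " s) is shorter than one Welch window (", windowS, " s)")
  if (overlapS >= windowS) stop("overlapS must be smaller than windowS")
  step <- as.integer(round((windowS - overlapS) * fs))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- nper %/% 2L + 1L
  freqs <- (seq_len(nf) - 1L) * fs / nper
  power <- matrix(0, nrow(rec@samples), nf)
  for (s in starts) {
    seg <- rec@samples[, s:(s + nper - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, w, `*`)
    P <- Mod(stats::mvfft(t(seg)))^2 * scale
    P <- t(P[seq_len(nf), , drop = FALSE])
    ## one-sided: double all bins except DC (and Nyquist when present)
    dbl <- rep(2, nf); dbl[1L] <- 1
    if (nper %% 2L == 0L) dbl[nf] <- 1
    power <- power + sweep(P, 2L, dbl, `*`)
  }
  new("PowerSpectrum", freqs = freqs, power = power / length(starts),
      windowS = windowS, overlapS = overlapS)
}

#' Locate the gastric spectral peak in each channel
#'
#' Finds, per channel, the frequency of maximal power inside the search
#' band, requiring an interior local maximum (edge bins are only accepted
#' when no interior local maximum exists, in which case the peak is
#' flagged). A low-prominence flag fires when the peak power falls below
#' \code{promThreshold} times the median in-band power.
#'
#' @param spec a \code{\link{PowerSpectrum}}.
#' @param band length-2 numeric, search band in Hz.
#' @param promThreshold prominence ratio below which a peak is flagged
#'   (default 4).
#' @return data.frame with one row per channel: \code{channel},
#'   \code{peakFreq}, \code{peakPower}, \code{prominence},
#'   \code{interiorMax}, \code{lowProminence}.
#' @export
findGastricPeak <- function(spec, band = GASTRIC_BAND, promThreshold = 4) {
  stopifnot(is(spec, "PowerSpectrum"))
  if (band[1] < spec@freqs[1] || band[2] > spec@freqs[length(spec@freqs)])
    stop("search band [", band[1], ", ", band[2],
         "] Hz lies outside the spectrum's frequency range")
  sel <- which(spec@freqs >= band[1] & spec@freqs <= band[2])
  if (length(sel) < 1L) stop("no frequency bins inside the search band")
  out <- lapply(seq_len(nrow(spec@power)), function(ch) {
    p <- spec@power[ch, ]
    inband <- p[sel]
    ## interior local maxima: strictly above both neighbours (neighbours may
    ## lie just outside the band)
    isMax <- vapply(sel, function(i) {
      lo <- if (i > 1L) p[i - 1L] else -Inf
      hi <- if (i < length(p)) p[i + 1L] else -Inf
      p[i] >= lo && p[i] >= hi && (p[i] > lo || p[i] > hi)
    }, logical(1))
    cand <- sel[isMax]
    interior <- length(cand) > 0L
    if (!interior) cand <- sel
    i <- cand[which.max(p[cand])]
    prom <- if (stats::median(inband) > 0) p[i] / stats::median(inband) else Inf
    data.frame(channel = ch, peakFreq = spec@freqs[i], peakPower = p[i],
               prominence = prom, interiorMax = interior,
               lowProminence = !interior || prom < promThreshold)
  })
  do.call(rbind, out)
}

#' Select the gastric channel
#'
#' Defaults to the channel with the largest in-band spectral peak; when the
#' channel with the second-largest peak carries a strictly better quality
#' level it is preferred. An explicit \code{override} always wins.
#'
#' @param peaks data.frame from \code{\link{findGastricPeak}}.
#' @param qualityLevels optional integer vector (1 = best) per channel.
#' @param override optional channel index forced by the analyst.
#' @return list with \code{channel} and the matching \code{peak} row.
#' @export
selectGastricChannel <- function(peaks, qualityLevels = NULL,
                                 override = NULL) {
  if (!is.null(override)) {
    return(list(channel = override,
                peak = peaks[peaks$channel == override, , drop = FALSE]))
  }
  usable <- peaks[is.finite(peaks$peakPower), , drop = FALSE]
  if (nrow(usable) == 0L || all(usable$lowProminence & !usable$interiorMax))
    stop("no channel shows a detectable gastric peak (quality level 3)")
  ord <- usable$channel[order(usable$peakPower, decreasing = TRUE)]
  sel <- ord[1L]
  if (!is.null(qualityLevels) && length(ord) >= 2L &&
      qualityLevels[ord[2L]] < qualityLevels[ord[1L]])
    sel <- ord[2L]
  list(channel = sel, peak = peaks[peaks$channel == sel, , drop = FALSE])
}

#' Grade EGG recording quality on three levels
#'
#' Three criteria are evaluated: a clear in-band peak (interior local
#' maximum with prominence ratio >= \code{promThreshold}), cross-channel
#' consistency of the peak frequency, and cross-run consistency. All three
#' true gives level 1 (high); a clear peak with an inconsistency gives level
#' 2 (medium); no clear peak gives level 3 (low), which marks the recording
#' as excluded from synchrony analyses.
#'
#' @param peaksPerRun list (one element per run) of data.frames from
#'   \code{\link{findGastricPeak}}.
#' @param freqTol consistency tolerance on the peak frequency in Hz
#'   (default 0.01).
#' @param promThreshold prominence ratio defining a clear peak (default 4).
#' @return list with \code{level}, logical \code{criteria} (clearPeak,
#'   crossChannel, crossRun), \code{excluded} and \code{notes}.
#' @export
assessEggQuality <- function(peaksPerRun, freqTol = 0.01,
                             promThreshold = 4) {
  if (length(peaksPerRun) < 1L) stop("at least one run is required")
  clearByRun <- vapply(peaksPerRun, function(pk) {
    any(pk$interiorMax & pk$prominence >= promThreshold)
  }, logical(1))
  clearPeak <- all(clearByRun)
  ## consistency is judged among channels that themselves show a clear peak
  chanConsistent <- all(vapply(peaksPerRun, function(pk) {
    ok <- pk[pk$interiorMax & pk$prominence >= promThreshold, , drop = FALSE]
    if (nrow(ok) < 2L) return(TRUE)
    diff(range(ok$peakFreq)) <= freqTol
  }, logical(1)))
  bestFreqs <- vapply(peaksPerRun, function(pk) {
    pk$peakFreq[which.max(pk$peakPower)]
  }, numeric(1))
  runConsistent <- length(bestFreqs) < 2L ||
    diff(range(bestFreqs)) <= freqTol
  criteria <- c(clearPeak = clearPeak, crossChannel = chanConsistent,
                crossRun = runConsistent)
  level <- if (all(criteria)) 1L else if (clearPeak) 2L else 3L
  notes <- character()
  if (!clearPeak) notes <- c(notes, "no clear in-band peak")
  if (!chanConsistent) notes <- c(notes, "peak differs across channels")
  if (!runConsistent) notes <- c(notes, "peak differs across runs")
  list(level = level, criteria = criteria, excluded = level == 3L,
       notes = if (length(notes)) paste(notes, collapse = "; ") else "ok")
}
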