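## EGG-confound synchrony: PLV of each nuisance series with the gastric
## phase, shifted-EGG nulls, paired t-tests across runs, and the relation
## of confound synchrony to brain-wide PLV-delta under different
## preprocessing variants.

#' PLV of each confound series with the gastric phase
#'
#' Each of the ten nuisance series is treated exactly like a voxel:
#' band-passed around the gastric peak at the BOLD rate, phase-extracted via
#' the Hilbert transform, and compared to the gastric phase empirically and
#' under every circular-shift surrogate. Constant series (e.g. an all-zero
#' FD) have an undefined phase and are flagged and excluded.
#'
#' @param tab data.frame with the columns in \code{\link{CONFOUND_NAMES}},
#'   one row per volume (full, untrimmed grid).
#' @param gastricPhase \code{\link{PhaseSeries}} on the full volume grid.
#' @param peakFreq gastric peak frequency in Hz.
#' @param nulls \code{\link{NullSpec}} for the grid length.
#' @param TR repetition time in seconds.
#' @param halfwidth filter half width in Hz (default 0.015).
#' @return data.frame: \code{confound}, \code{empiricalPlv},
#'   \code{nullMedianPlv}, \code{delta}, \code{flagged}.
#' @export
confoundPlvDelta <- function(tab, gastricPhase, peakFreq, nulls, TR,
                             halfwidth = 0.015) {
  missing <- setdiff(CONFOUND_NAMES, colnames(tab))
  if (length(missing))
    stop("confound table is missing: ", paste(missing, collapse = ", "))
  if (nrow(tab) != nulls@nSamples)
    stop("confound series length must equal the volume count")
  out <- lapply(CONFOUND_NAMES, function(nm) {
    x <- tab[[nm]]
    if (stats::sd(x) == 0) {
      return(data.frame(confound = nm, empiricalPlv = NA_real_,
                        nullMedianPlv = NA_real_, delta = NA_real_,
                        flagged = TRUE))
    }
    xf <- bandpassAroundPeak(x, fs = 1 / TR, peakFreq = peakFreq,
                             halfwidth = halfwidth)
    th <- Arg(analyticSignal(xf))
    res <- plvWithNulls(matrix(th, 1L), phase(gastricPhase), nulls)
    med <- stats::median(res$null[1L, ])
    data.frame(confound = nm, empiricalPlv = res$empirical[1L],
               nullMedianPlv = med, delta = res$empirical[1L] - med,
               flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Paired t-tests of empirical versus null confound PLV across runs
#'
#' One paired t-test per confound over runs, Benjamini-Hochberg corrected
#' across the ten confounds. Confounds flagged undefined in any run are
#' skipped with a note.
#'
#' @param resultsPerRun list of data.frames from
#'   \code{\link{confoundPlvDelta}}, one per run (>= 3 runs).
#' @param q FDR level (default 0.05).
#' @return data.frame: \code{confound}, \code{t}, \code{df}, \code{p},
#'   \code{fdrSignificant}, \code{skipped}.
#' @export
confoundSyncTtests <- function(resultsPerRun, q = 0.05) {
  if (length(resultsPerRun) < 3L)
    stop("need at least three runs for a paired t-test")
  emp <- vapply(resultsPerRun, function(r) r$empiricalPlv,
                numeric(length(CONFOUND_NAMES)))
  nul <- vapply(resultsPerRun, function(r) r$nullMedianPlv,
                numeric(length(CONFOUND_NAMES)))
  flg <- vapply(resultsPerRun, function(r) r$flagged,
                logical(length(CONFOUND_NAMES)))
  out <- do.call(rbind, lapply(seq_along(CONFOUND_NAMES), function(i) {
    if (any(flg[i, ])) {
      return(data.frame(confound = CONFOUND_NAMES[i], t = NA_real_,
                        df = NA_integer_, p = NA_real_, skipped = TRUE))
    }
    d <- emp[i, ] - nul[i, ]
    if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
      tt <- list(statistic = c(t = 0), parameter = length(d) - 1L,
                 p.value = 1)
    } else tt <- stats::t.test(emp[i, ], nul[i, ], paired = TRUE)
    data.frame(confound = CONFOUND_NAMES[i],
               t = unname(tt$statistic), df = as.integer(tt$parameter),
               p = tt$p.value, skipped = FALSE)
  }))
  out$fdrSignificant <- NA
  ok <- !out$skipped
  out$fdrSignificant[ok] <- fdrBH(out$p[ok], q)
  out
}

#' Correlate EGG-confound synchrony with brain-wide PLV-delta
#'
#' Brain-wide synchrony per run is the mean PLV-delta within the mask;
#' it is rank-correlated (Spearman, average ranks for ties) with each
#' confound's empirical PLV across runs, separately per preprocessing
#' variant.
#'
#' @param confoundPlvPerRun list of data.frames from
#'   \code{\link{confoundPlvDelta}}, one per run (>= 5 runs).
#' @param brainwideDelta named list per variant of numeric vectors (one
#'   mean-delta value per run).
#' @param q FDR level applied across confounds within a variant.
#' @return data.frame: \code{variant}, \code{confound}, \code{rho},
#'   \code{p}, \code{fdrSignificant}.
#' @export
syncBrainwideCorrelation <- function(confoundPlvPerRun, brainwideDelta,
                                     q = 0.05) {
  nRuns <- length(confoundPlvPerRun)
  if (nRuns < 5L) stop("need at least five runs")
  emp <- vapply(confoundPlvPerRun, function(r) r$empiricalPlv,
                numeric(length(CONFOUND_NAMES)))
  out <- do.call(rbind, lapply(names(brainwideDelta), function(var) {
    bw <- brainwideDelta[[var]]
    if (length(bw) != nRuns)
      stop("variant '", var, "' has ", length(bw), " values for ", nRuns,
           " runs")
    rows <- do.call(rbind, lapply(seq_along(CONFOUND_NAMES), function(i) {
      x <- emp[i, ]
      if (anyNA(x) || stats::sd(x) == 0)
        return(data.frame(variant = var, confound = CONFOUND_NAMES[i],
                          rho = NA_real_, p = NA_real_))
      ct <- suppressWarnings(stats::cor.test(x, bw, method = "spearman"))
      data.frame(variant = var, confound = CONFOUND_NAMES[i],
                 rho = unname(ct$estimate), p = ct$p.value)
    }))
    ok <- !is.na(rows$p)
    rows$fdrSignificant <- NA
    rows$fdrSignificant[ok] <- fdrBH(rows$p[ok], q)
    rows
  }))
  out
}

#' Compare preprocessing variants at the map level
#'
#' Paired t-test across voxels of two group t-maps plus suprathreshold
#' voxel counts and percentages per variant.
#'
#' @param tMinimal,tStrict t statistic per in-mask voxel under the minimal
#'   and strict variants (same mask).
#' @param threshold suprathreshold cut (default 2.3).
#' @return list: \code{t}, \code{df}, \code{p} (paired over voxels),
#'   \code{countMinimal}, \code{countStrict}, \code{pctMinimal},
#'   \code{pctStrict}, \code{zeroVarianceDifference}.
#' @export
compareVariants <- function(tMinimal, tStrict, threshold = 2.3) {
  if (length(tMinimal) != length(tStrict))
    stop("t-maps are on different masks")
  d <- tMinimal - tStrict
  zeroVar <- stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)
  if (zeroVar) {
    tt <- list(statistic = c(t = 0), parameter = length(d) - 1L, p.value = 1)
  } else tt <- stats::t.test(tMinimal, tStrict, paired = TRUE)
  nv <- length(tMinimal)
  list(t = unname(tt$statistic), df = as.integer(tt$parameter),
       p = tt$p.value,
       countMinimal = sum(tMinimal > threshold),
       countStrict = sum(tStrict > threshold),
       pctMinimal = 100 * sum(tMinimal > threshold) / nv,
       pctStrict = 100 * sum(tStrict > threshold) / nv,
       zeroVarianceDifference = zeroVar)
}
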