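## Test-retest battery: run-to-run correlation of summary synchrony,
## parcelwise similarity across runs, EGG peak reliability and
## functional-connectivity fingerprinting.

#' Correlate a per-subject measure across two runs
#'
#' Pearson correlation of the run-1 versus run-2 values with df = n - 2 and
#' a two-sided p; applied, e.g., to the mean PLV-delta within the
#' significant-cluster mask or within the GM mask.
#'
#' @param run1,run2 paired numeric vectors, one value per subject (>= 4).
#' @return list: \code{r}, \code{df}, \code{p}, \code{n}.
#' @export
runRetestCorrelation <- function(run1, run2) {
  if (length(run1) != length(run2)) stop("runs must be paired")
  n <- length(run1)
  if (n < 4L) stop("need at least four subjects")
  if (stats::sd(run1) == 0 || stats::sd(run2) == 0)
    stop("zero variance across subjects: correlation undefined")
  ct <- stats::cor.test(run1, run2)
  list(r = unname(ct$estimate), df = unname(ct$parameter),
       p = ct$p.value, n = n)
}

#' Build a block parcellation of a masked grid
#'
#' Deterministically splits the grid into roughly equal rectangular blocks
#' (a stand-in for an anatomical atlas on synthetic grids). Parcels empty
#' within the mask are dropped.
#'
#' @param gridShape integer length-3.
#' @param mask logical over the full grid.
#' @param nParcels requested number of parcels (approximate).
#' @return list: \code{labels} (integer per in-mask voxel, 1..n),
#'   \code{nParcels}.
#' @export
makeBlockParcellation <- function(gridShape, mask, nParcels = 100L) {
  per <- max(1L, round(nParcels^(1 / 3)))
  cuts <- lapply(1:3, function(ax) {
    pmin(per, gridShape[ax])
  })
  idx <- arrayInd(which(mask), gridShape)
  bins <- vapply(1:3, function(ax) {
    as.integer(cut(idx[, ax], breaks = seq(0.5, gridShape[ax] + 0.5,
                                           length.out = cuts[[ax]] + 1L)))
  }, integer(nrow(idx)))
  raw <- bins[, 1L] + cuts[[1]] * ((bins[, 2L] - 1L) +
                                     cuts[[2]] * (bins[, 3L] - 1L))
  labels <- as.integer(factor(raw))
  list(labels = labels, nParcels = max(labels))
}

## parcel-mean of a per-voxel vector
parcelMeans <- function(values, labels) {
  as.numeric(tapply(values, labels, mean))
}

#' Parcelwise similarity of maps across runs
#'
#' Per run, the vector of parcel-mean map values; Pearson r for every
#' unordered run pair; and a one-sample t-test of those r values against
#' zero (on the raw correlations, df = number of pairs - 1).
#'
#' @param mapsPerRun list of per-voxel value vectors, one per run (>= 3).
#' @param parcellation output of \code{\link{makeBlockParcellation}}.
#' @return list: \code{pairR} (one r per unordered pair), \code{meanR},
#'   \code{sdR}, \code{t}, \code{df}, \code{p}, \code{nPairs}.
#' @export
parcelwiseSimilarity <- function(mapsPerRun, parcellation) {
  nRuns <- length(mapsPerRun)
  if (nRuns < 3L) stop("need at least three runs")
  pm <- vapply(mapsPerRun, parcelMeans, numeric(parcellation$nParcels),
               labels = parcellation$labels)
  pairs <- utils::combn(nRuns, 2L)
  rs <- apply(pairs, 2L, function(pr) {
    stats::cor(pm[, pr[1]], pm[, pr[2]])
  })
  tt <- if (stats::sd(rs) <= 1e-12 * (abs(mean(rs)) + 1)) {
    list(statistic = sign(mean(rs)) * Inf, parameter = length(rs) - 1L,
         p.value = if (mean(rs) == 0) 1 else 0)
  } else stats::t.test(rs, mu = 0)
  list(pairR = rs, meanR = mean(rs), sdR = stats::sd(rs),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, nPairs = ncol(pairs))
}

#' Reliability of the EGG peak frequency across settings
#'
#' Pearson correlation between, e.g., the lab and in-scanner peak
#' frequencies of the same subjects.
#'
#' @param labPeaks,scannerPeaks paired numeric vectors in Hz (>= 4).
#' @return list: \code{r}, \code{df}, \code{p}, \code{n}.
#' @export
eggPeakReliability <- function(labPeaks, scannerPeaks) {
  runRetestCorrelation(labPeaks, scannerPeaks)
}

#' Functional-connectivity fingerprinting across runs
#'
#' Per run, parcel-mean time series are correlated into a parcels x parcels
#' matrix whose unique upper-triangle edges form the run's connectivity
#' fingerprint. Every unordered run pair gets the Pearson correlation of
#' its two edge vectors, and within-subject pairs are compared to
#' between-subject pairs with an independent two-sample t-test.
#'
#' @param runData list with one element per run: list(\code{series} =
#'   voxels x time matrix or parcels x time matrix, \code{subject} = id).
#' @param parcellation output of \code{\link{makeBlockParcellation}}, or
#'   NULL when \code{series} is already parcels x time.
#' @param excludeSharedRun drop between-subject pairs that share a run
#'   (never the case with distinct runs; kept for API symmetry).
#' @return list: \code{withinR}, \code{betweenR}, \code{t}, \code{df},
#'   \code{p}, \code{meanWithin}, \code{meanBetween}, \code{nEdges}.
#' @export
fcFingerprint <- function(runData, parcellation = NULL,
                          excludeSharedRun = FALSE) {
  nRuns <- length(runData)
  subjects <- vapply(runData, function(r) as.character(r$subject),
                     character(1))
  if (length(unique(subjects)) < 2L || nRuns < 4L)
    stop("need at least two subjects with two runs each")
  edges <- lapply(runData, function(r) {
    ts <- r$series
    if (!is.null(parcellation)) {
      ts <- do.call(rbind, lapply(seq_len(parcellation$nParcels),
        function(pc) colMeans(ts[parcellation$labels == pc, , drop = FALSE])))
    }
    keep <- apply(ts, 1L, stats::sd) > 0
    if (!all(keep)) {
      message("dropping ", sum(!keep), " zero-variance parcel(s)")
      ts <- ts[keep, , drop = FALSE]
    }
    cm <- stats::cor(t(ts))
    cm[upper.tri(cm)]
  })
  nEdge <- unique(lengths(edges))
  if (length(nEdge) != 1L)
    stop("runs yield differing edge counts (zero-variance parcels differ)")
  pairs <- utils::combn(nRuns, 2L)
  prR <- apply(pairs, 2L, function(pr) {
    stats::cor(edges[[pr[1]]], edges[[pr[2]]])
  })
  within <- subjects[pairs[1L, ]] == subjects[pairs[2L, ]]
  tt <- stats::t.test(prR[within], prR[!within], var.equal = TRUE)
  list(withinR = prR[within], betweenR = prR[!within],
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       meanWithin = mean(prR[within]), meanBetween = mean(prR[!within]),
       nEdges = nEdge)
}
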