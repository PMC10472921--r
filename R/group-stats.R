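## Group inference: paired t-maps, cluster mass, sign-flip max-mass
## permutation FWE, BH-FDR, Dice overlap and the hemisphere-symmetric spin
## test.

#' Paired t-map of empirical versus median-null PLV
#'
#' Per voxel, a paired t statistic over subjects of \code{empirical -
#' nullMedian} with df = n - 1 (sample SD, n - 1 denominator). Voxels with
#' zero between-subject variance get t = 0 and are flagged.
#'
#' @param empirical,nullMedian subjects x voxels matrices (runs already
#'   averaged per subject).
#' @return list with \code{t} (per voxel), \code{df} and logical
#'   \code{zeroVariance} flags.
#' @export
pairedTMap <- function(empirical, nullMedian) {
  if (!all(dim(empirical) == dim(nullMedian)))
    stop("empirical and null matrices must have matching shapes")
  n <- nrow(empirical)
  if (n < 3L) stop("need at least three subjects")
  d <- empirical - nullMedian
  m <- colMeans(d)
  s <- sqrt(colSums(sweep(d, 2L, m)^2) / (n - 1))
  zero <- s == 0
  tt <- ifelse(zero, 0, m / (s / sqrt(n)))
  list(t = tt, df = n - 1L, zeroVariance = zero)
}

## Expand in-mask values onto the full grid, background filled with -Inf so
## it can never join a cluster.
maskToGrid <- function(values, mask, gridShape, fill = -Inf) {
  g <- rep(fill, prod(gridShape))
  g[mask] <- values
  g
}

#' Extract suprathreshold clusters and their masses
#'
#' Connected components of \code{t > threshold} on the 3-D grid under the
#' requested connectivity; a cluster's mass is the sum of its t-values.
#'
#' @param tvals t statistic per in-mask voxel.
#' @param gridShape integer length-3 grid dimensions.
#' @param mask logical vector over the full grid.
#' @param threshold cluster-forming threshold (default 2.3).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return a \code{\link{ClusterSet}} (empty when nothing is above
#'   threshold); \code{pFwe} is NA until a permutation test fills it.
#' @export
clustersAndMass <- function(tvals, gridShape, mask, threshold = 2.3,
                            connectivity = 26L) {
  grid <- maskToGrid(tvals, mask, gridShape)
  lab <- .labelClusters3d(grid, as.integer(gridShape), threshold,
                          as.integer(connectivity))
  masses <- attr(lab, "masses")
  sizes <- attr(lab, "sizes")
  new("ClusterSet", labels = lab[mask], masses = as.numeric(masses),
      sizes = as.integer(sizes),
      pFwe = rep(NA_real_, length(masses)), threshold = threshold,
      connectivity = as.integer(connectivity))
}

#' Sign-flip cluster-mass permutation test
#'
#' Family-wise-error corrected cluster inference: the observed clusters of
#' the paired t-map are compared to the distribution of the maximum cluster
#' mass obtained by multiplying each subject's difference map by an
#' independent random sign (equivalent to swapping that subject's empirical
#' and null maps) \code{nPerm} times. \code{pFwe = (1 + #\{max null mass >=
#' mass\}) / (1 + nPerm)}.
#'
#' @param empirical,nullMedian subjects x voxels matrices.
#' @param gridShape,mask,threshold,connectivity as in
#'   \code{\link{clustersAndMass}}.
#' @param nPerm number of sign-flip permutations (default 10000).
#' @param alpha significance level for the \code{significant} flags
#'   (default 0.05).
#' @return list with \code{clusters} (a \code{\link{ClusterSet}} with
#'   \code{pFwe} filled), \code{tmap}, \code{nullMaxMass} and
#'   \code{significantMask} (logical per in-mask voxel).
#' @export
signflipClusterTest <- function(empirical, nullMedian, gridShape, mask,
                                nPerm = 10000L, threshold = 2.3,
                                connectivity = 26L, alpha = 0.05) {
  n <- nrow(empirical)
  if (n < 2L) stop("sign flipping is degenerate with fewer than 2 subjects")
  if (n < 5L) warning("fewer than 5 subjects: permutation p-values are coarse")
  if (nPerm < 100L) warning("nPerm < 100 gives very coarse p-values")
  tm <- pairedTMap(empirical, nullMedian)
  obs <- clustersAndMass(tm$t, gridShape, mask, threshold, connectivity)
  d <- empirical - nullMedian
  ## sign flips leave voxelwise sums of squares unchanged, so the permuted
  ## t only needs the flipped mean: t = m / sqrt((ss/n - m^2) / (n - 1)) / ...
  ss <- colSums(d^2)
  dims <- as.integer(gridShape)
  nullMax <- numeric(nPerm)
  for (p in seq_len(nPerm)) {
    f <- sample(c(-1, 1), n, replace = TRUE)
    m <- as.numeric(crossprod(d, f)) / n
    v <- (ss - n * m^2) / (n - 1)
    v[v < 0] <- 0
    tt <- ifelse(v == 0, 0, m / sqrt(v / n))
    nullMax[p] <- .maxClusterMass3d(maskToGrid(tt, mask, gridShape), dims,
                                    threshold, as.integer(connectivity))
  }
  pFwe <- vapply(obs@masses, function(ms) {
    (1 + sum(nullMax >= ms)) / (1 + nPerm)
  }, numeric(1))
  obs@pFwe <- pFwe
  sigClusters <- which(pFwe < alpha)
  sigMask <- obs@labels %in% sigClusters
  list(clusters = obs, tmap = tm, nullMaxMass = nullMax,
       significantMask = sigMask)
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure at level \code{q} (via \code{stats::p.adjust}).
#'
#' @param pvals p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return logical rejection flags.
#' @export
fdrBH <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Dice similarity of two binary maps
#'
#' \code{2 |A & B| / (|A| + |B|)}; defined as 0 (with a message) when both
#' maps are empty.
#'
#' @param a,b logical vectors on the same voxel/vertex set.
#' @return numeric in [0, 1].
#' @export
diceSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("maps differ in length")
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    message("both maps are empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / denom
}

#' Uniform random 3-D rotation matrix
#'
#' QR orthonormalization of a Gaussian 3x3 matrix with the determinant
#' fixed to +1 (a proper rotation, Haar-uniform).
#'
#' @return 3x3 rotation matrix.
#' @export
randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## rotated label map: every vertex inherits the label of the nearest
## rotated vertex (ties broken by lowest index), so labels stay on the
## vertex set and the labelled area is preserved in expectation
projectLabels <- function(ann, rotation) {
  ## nearest rotated vertex to v = nearest original vertex to R^T v
  nn <- .nnMaxDot(ann@coords %*% rotation, ann@coords)
  ann@labels[nn]
}

#' Hemisphere-symmetric spin test of spatial overlap
#'
#' The empirical Dice similarity between a fixed annotation and a target
#' annotation (both given as left/right hemisphere sphere annotations) is
#' compared against a null distribution obtained by applying a uniformly
#' random rotation to the right-hemisphere target and the sagittally
#' mirrored rotation (x negated) to the left hemisphere, preserving
#' hemispheric symmetry. Rotated labels are reassigned to vertices by
#' nearest-neighbour projection. \code{p = (1 + #\{null >= empirical\}) /
#' (1 + nPerm)}.
#'
#' @param fixedL,fixedR,targetL,targetR \code{\link{SphereAnnotation}}s with
#'   matched vertex sets per hemisphere.
#' @param nPerm number of rotations (default 10000).
#' @return list with \code{dice} (empirical), \code{nullDice}, \code{p}.
#' @export
spinTest <- function(fixedL, fixedR, targetL, targetR, nPerm = 10000L) {
  if (sum(fixedL@labels) + sum(fixedR@labels) == 0L ||
      sum(targetL@labels) + sum(targetR@labels) == 0L)
    stop("annotations with no labelled vertices cannot be tested")
  fixedAll <- c(fixedL@labels, fixedR@labels)
  empirical <- diceSimilarity(fixedAll, c(targetL@labels, targetR@labels))
  M <- diag(c(-1, 1, 1))               # sagittal mirror
  nullDice <- vapply(seq_len(nPerm), function(i) {
    R3 <- randomRotation()
    rotR <- projectLabels(targetR, R3)
    rotL <- projectLabels(targetL, M %*% R3 %*% M)
    diceSimilarity(fixedAll, c(rotL, rotR))
  }, numeric(1))
  list(dice = empirical, nullDice = nullDice,
       p = (1 + sum(nullDice >= empirical)) / (1 + nPerm))
}
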