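test_that("paired t-maps match hand computation and flag zero variance", {
  emp <- rbind(c(1, 1, 2), c(2, 1, 2), c(3, 1, 2))
  nul <- matrix(c(0, 1, 1), 3, 3, byrow = FALSE)
  nul[, 2] <- emp[, 2]          # d = 0 everywhere
  nul[, 3] <- emp[, 3] - 1      # constant positive d
  nul[, 1] <- 0
  tm <- pairedTMap(emp, nul)
  # d = (1, 2, 3): t = 2 / (1 / sqrt(3))
  expect_equal(tm$t[1], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tm$df, 2L)
  expect_equal(tm$t[2], 0)
  # constant nonzero d has zero variance: flagged, t = 0
  expect_true(tm$zeroVariance[3])
  expect_equal(tm$t[3], 0)
  expect_error(pairedTMap(emp[1:2, ], nul[1:2, ]), "three subjects")
})

test_that("cluster extraction agrees with a flood-fill oracle at all connectivities", {
  dims <- c(8L, 8L, 8L)
  mask <- rep(TRUE, prod(dims))
  set.seed(61)
  for (rep in 1:6) {
    tv <- rnorm(prod(dims), mean = 1.3)
    for (conn in c(6L, 18L, 26L)) {
      cs <- clustersAndMass(tv, dims, mask, threshold = 2.3,
                            connectivity = conn)
      oracle <- bfsClusters(tv > 2.3, dims, conn)
      # same partition: label images agree up to renumbering
      expect_equal(max(oracle), length(cs@masses))
      if (max(oracle) > 0) {
        tab <- table(cs@labels, as.vector(oracle)[mask])
        expect_true(all(rowSums(tab > 0)[-1] <= 1))
        # masses agree as multisets
        oMass <- sort(tapply(tv[oracle > 0], oracle[oracle > 0], sum))
        expect_equal(sort(cs@masses), as.numeric(oMass), tolerance = 1e-10)
      }
    }
  }
})

test_that("cluster topology follows the chosen connectivity", {
  dims <- c(4L, 4L, 4L)
  mask <- rep(TRUE, 64)
  tv <- rep(0, 64)
  # two face-adjacent voxels
  tv[c(1, 2)] <- 3
  cs <- clustersAndMass(tv, dims, mask, 2.3, 26L)
  expect_equal(length(cs@masses), 1)
  expect_equal(cs@masses, 6)
  # two diagonal voxels: one cluster under 26, two under 6
  tv2 <- rep(0, 64)
  tv2[1] <- 3; tv2[1 + 1 + 4 + 16] <- 3   # full diagonal neighbour
  expect_equal(length(clustersAndMass(tv2, dims, mask, 2.3, 26L)@masses), 1)
  expect_equal(length(clustersAndMass(tv2, dims, mask, 2.3, 6L)@masses), 2)
  # nothing above threshold: empty set is valid
  cs0 <- clustersAndMass(rep(0, 64), dims, mask, 2.3, 26L)
  expect_length(cs0@masses, 0)
})

test_that("raising the threshold never increases a cluster's mass", {
  dims <- c(6L, 6L, 6L)
  mask <- rep(TRUE, prod(dims))
  set.seed(62)
  tv <- rnorm(prod(dims), 1.5)
  lo <- clustersAndMass(tv, dims, mask, 2.0)
  hi <- clustersAndMass(tv, dims, mask, 2.8)
  expect_lte(if (length(hi@masses)) max(hi@masses) else 0,
             if (length(lo@masses)) max(lo@masses) else 0)
  expect_lte(sum(hi@sizes), sum(lo@sizes))
})

test_that("sign-flip permutation inference is valid and permutation-invariant", {
  dims <- c(6L, 6L, 6L)
  nv <- prod(dims)
  mask <- rep(TRUE, nv)
  set.seed(63)
  n <- 8
  emp <- matrix(rnorm(n * nv, 0.2, 1), n)
  nul <- matrix(rnorm(n * nv, 0.2, 1), n)
  # inject a strong common effect in a 3x3x3 block
  block <- as.vector(outer(2:4, outer(2:4, 2:4, function(y, z)
    6 * ((y - 1) + 6 * (z - 1))), `+`))
  emp[, block] <- emp[, block] + 2
  set.seed(64)
  res <- signflipClusterTest(emp, nul, dims, mask, nPerm = 400L)
  expect_s4_class(res$clusters, "ClusterSet")
  expect_true(all(res$clusters@pFwe > 0 & res$clusters@pFwe <= 1))
  # the injected cluster is found at the p floor
  expect_equal(min(res$clusters@pFwe), 1 / 401, tolerance = 1e-12)
  # significant voxels overlap the true block
  expect_gt(diceSimilarity(res$significantMask, seq_len(nv) %in% block),
            0.5)

  # invariance: relabelling voxels by a grid isometry (x reversed, axes
  # 1 and 2 swapped) leaves masses and p-values unchanged
  perm <- as.vector(aperm(array(seq_len(nv), dims)[6:1, , ], c(2, 1, 3)))
  set.seed(64)
  res2 <- signflipClusterTest(emp[, perm], nul[, perm], dims, mask,
                              nPerm = 400L)
  expect_equal(length(res2$clusters@masses), length(res$clusters@masses))
  expect_equal(sort(res2$clusters@masses), sort(res$clusters@masses),
               tolerance = 1e-10)

  expect_error(signflipClusterTest(emp[1, , drop = FALSE],
                                   nul[1, , drop = FALSE], dims, mask),
               "degenerate")
  # both the small-n and the low-permutation-count warnings fire
  expect_warning(expect_warning(
    signflipClusterTest(emp[1:3, ], nul[1:3, ], dims, mask, nPerm = 50L)))
})

test_that("Benjamini-Hochberg flags match hand-worked step-up examples", {
  # p(4) = 0.04 <= 4/4 * 0.05 -> everything rejected
  expect_equal(fdrBH(c(0.01, 0.02, 0.03, 0.04)), rep(TRUE, 4))
  # 0.04 > 1/3 * 0.05 and larger ps fail too -> nothing rejected
  expect_equal(fdrBH(c(0.04, 0.5, 0.9)), rep(FALSE, 3))
  expect_equal(fdrBH(rep(0, 5)), rep(TRUE, 5))
  expect_equal(fdrBH(numeric(0)), logical(0))
  expect_error(fdrBH(c(0.5, 1.2)), "0, 1")
  # monotone in q
  p <- c(0.001, 0.01, 0.04, 0.2, 0.6)
  expect_true(all(fdrBH(p, 0.01) <= fdrBH(p, 0.1)))
})

test_that("Dice similarity covers identity, disjoint and partial overlap", {
  a <- c(rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(diceSimilarity(a, a), 1)
  b <- c(rep(FALSE, 4), rep(TRUE, 4), FALSE, FALSE)
  expect_equal(diceSimilarity(a, b), 0)
  # |a| = 4, |b| = 6, overlap 2 -> 0.4
  b2 <- c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 4), FALSE, FALSE)
  expect_equal(diceSimilarity(a, b2), 0.4)
  expect_message(z <- diceSimilarity(logical(5), logical(5)), "empty")
  expect_equal(z, 0)
  expect_error(diceSimilarity(a, a[1:5]), "length")
})

test_that("random rotations are proper and spins preserve labels and symmetry", {
  set.seed(65)
  for (i in 1:20) {
    R3 <- randomRotation()
    expect_equal(crossprod(R3), diag(3), tolerance = 1e-12)
    expect_equal(det(R3), 1, tolerance = 1e-12)
  }

  ann <- genSphereAnnotation(300, 0.2, symmetric = TRUE, seed = 66)
  # symmetric annotation: left labels are the mirrored right labels
  expect_equal(sum(ann$L@labels), sum(ann$R@labels), tolerance = 2)

  set.seed(67)
  st <- spinTest(ann$L, ann$R, ann$L, ann$R, nPerm = 30L)
  expect_equal(st$dice, 1)
  expect_true(all(st$nullDice >= 0 & st$nullDice <= 1))
  expect_true(st$p >= 1 / 31 && st$p <= 1)

  # mirrored rotation of a bilaterally symmetric map keeps the two
  # hemisphere Dice contributions equal
  M <- diag(c(-1, 1, 1))
  set.seed(68)
  for (i in 1:5) {
    R3 <- randomRotation()
    rotR <- gastroSync:::projectLabels(ann$R, R3)
    rotL <- gastroSync:::projectLabels(ann$L, M %*% R3 %*% M)
    dR <- diceSimilarity(ann$R@labels, rotR)
    dL <- diceSimilarity(ann$L@labels, rotL)
    expect_lt(abs(dR - dL), 0.15)   # nearest-neighbour tolerance
    # labelled area conserved up to nearest-neighbour multiplicity
    expect_lt(abs(sum(rotR) - sum(ann$R@labels)), 0.2 * sum(ann$R@labels))
  }

  empty <- SphereAnnotation(ann$L@coords, logical(300), "L")
  expect_error(spinTest(empty, empty, empty, empty, nPerm = 5L),
               "no labelled")
})
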