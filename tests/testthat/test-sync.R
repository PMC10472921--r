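test_that("PLV matches its definition, hand cases and a scalar-loop oracle", {
  # analytic cases
  th <- runif(100, -pi, pi)
  expect_equal(plv(th, th), 1)
  expect_equal(plv(th, wrapPhase(th + 1.1)), 1, tolerance = 1e-12)
  expect_equal(plv(c(0, pi / 2, pi), c(0, 0, 0)), 1 / 3, tolerance = 1e-12)

  # invariance to a global phase offset
  tx <- runif(200, -pi, pi)
  ty <- runif(200, -pi, pi)
  expect_equal(plv(tx, ty), plv(wrapPhase(tx + 2.5), wrapPhase(ty + 2.5)),
               tolerance = 1e-12)

  # vectorized = scalar loop to 1e-12 on random pairs
  set.seed(21)
  for (i in 1:50) {
    a <- runif(37, -pi, pi)
    b <- runif(37, -pi, pi)
    expect_equal(plv(a, b), plvLoop(a, b), tolerance = 1e-12)
  }
  # matrix form agrees with the loop row-wise
  M <- matrix(runif(5 * 37, -pi, pi), 5)
  pm <- plv(a, M)
  for (v in 1:5) expect_equal(pm[v], plvLoop(M[v, ], a), tolerance = 1e-12)

  expect_error(plv(1:5 / 10, 1:6 / 10), "lengths differ")
})

test_that("independent uniform phases give PLV near the random-walk expectation", {
  set.seed(22)
  T <- 10000
  vals <- replicate(200, plv(runif(T, -pi, pi), runif(T, -pi, pi)))
  expected <- sqrt(pi) / (2 * sqrt(T))
  expect_gt(mean(vals), expected * 0.5)
  expect_lt(mean(vals), expected * 1.5)
})

test_that("gastric phase decimation to the volume grid trims and preserves slopes", {
  fs <- 10
  theta <- wrapPhase(2 * pi * 0.05 * (0:8999) / fs)
  ph <- PhaseSeries(theta, fs)
  g <- gastricToBoldGrid(ph, TR = 2, nTrim = 15L)
  expect_length(phase(g), 435)
  expect_equal(samplingRate(g), 0.5)
  expect_equal(g@nTrimmed, 15L)

  # a linear ramp keeps its slope after decimation
  d <- wrapPhase(diff(phase(g)))
  expect_equal(unique(round(d, 10)), round(2 * pi * 0.05 * 2, 10))

  # nTrim = 0 is pure decimation
  g0 <- gastricToBoldGrid(ph, TR = 2, nTrim = 0L)
  expect_length(phase(g0), 450)
  expect_equal(phase(g0), theta[seq(1, 9000, by = 20)])

  expect_error(gastricToBoldGrid(ph, TR = 2, nVolumes = 1000), "covers")
})

test_that("circular-shift grids reproduce the run-length dependent surrogate counts", {
  # 15-minute runs: 450 volumes -> 360 surrogates
  ns15 <- makeNullShifts(450)
  expect_equal(nNull(ns15), 360)
  expect_equal(range(nullLags(ns15)), c(45, 404))
  # 10-minute runs: 300 volumes -> 210 surrogates
  expect_equal(nNull(makeNullShifts(300)), 210)
  # degenerate grid refused
  expect_error(makeNullShifts(90), "too short")
  expect_error(makeNullShifts(60), "too short")
})

test_that("delta maps equal an explicit rotate-trim oracle and detect lag-0 copies", {
  set.seed(33)
  N <- 80
  V <- 12
  th <- matrix(runif(V * N, -pi, pi), V)
  g <- runif(N, -pi, pi)
  th[1, ] <- g                       # voxel 1 = exact copy
  ns <- makeNullShifts(N, minLagS = 10, TR = 2, nTrim = 5L)
  gp <- PhaseSeries(g, 0.5)
  dm <- deltaMap(th, gp, ns)

  expect_equal(mapValues(dm$empirical)[1], 1, tolerance = 1e-12)
  expect_gt(mapValues(dm$delta)[1], 0)
  expect_true(all(abs(mapValues(dm$delta)) <= 1))

  # oracle: explicit full-grid rotation, then trim, then PLV
  trim <- 1:5
  for (v in c(1, 5, 12)) {
    emp <- plvLoop(g[-trim], th[v, -trim])
    nulls <- vapply(nullLags(ns), function(l) {
      gr <- g[((0:(N - 1) + l) %% N) + 1]
      plvLoop(gr[-trim], th[v, -trim])
    }, numeric(1))
    expect_equal(mapValues(dm$empirical)[v], emp, tolerance = 1e-10)
    expect_equal(mapValues(dm$nullMedian)[v], median(nulls),
                 tolerance = 1e-10)
  }

  # averaging two identical runs leaves the map unchanged
  avg <- averageMaps(list(dm$delta, dm$delta))
  expect_equal(mapValues(avg), mapValues(dm$delta))
})

test_that("uncoupled voxels have centred deltas and calibrated null medians", {
  # voxels within one run share the gastric realization, so the
  # below-median proportion is overdispersed per run; calibration is
  # checked on the across-run average
  props <- vapply(1:6, function(s) {
    set.seed(440 + s)
    cfg <- tinyCfg(gridShape = c(10L, 10L, 5L), nCoupledVoxels = 0L,
                   couplingPlvTarget = 0, runDurationS = 900)
    osc <- genGastricOscillator(cfg, 0.05)
    bold <- genCoupledBold(cfg, osc, couplingPlv = 0)
    th <- boldPhase(bold, 0.05)
    gp <- oscToBoldPhase(osc, cfg)
    dm <- deltaMap(th, gp, makeNullShifts(cfg$nVolumes))
    # central tendency of delta within +/- 0.05 over 500 voxels
    expect_lt(abs(mean(mapValues(dm$delta))), 0.05)
    mean(mapValues(dm$empirical) < mapValues(dm$nullMedian))
  }, numeric(1))
  expect_gt(mean(props), 0.4)
  expect_lt(mean(props), 0.6)
})

test_that("cross-subject nulls exclude the own stomach and truncate lengths", {
  set.seed(55)
  ths <- list(matrix(runif(3 * 60, -pi, pi), 3),
              matrix(runif(3 * 50, -pi, pi), 3),
              matrix(runif(3 * 60, -pi, pi), 3))
  gs <- list(runif(60, -pi, pi), runif(50, -pi, pi), runif(60, -pi, pi))
  # subject 1's brain locked to its own stomach only
  ths[[1]][1, ] <- gs[[1]][1:60]
  res <- crossSubjectNull(ths, gs)
  expect_length(res, 3)
  expect_equal(ncol(res[[1]]$null), 2)   # donors exclude self
  # own-stomach coupling does not leak into the cross-subject null
  expect_lt(res[[1]]$nullMedian[1], 0.5)
  expect_error(crossSubjectNull(ths[1], gs[1]), "two subjects")

  # independent rhythms: null deltas centred near zero (PLV scale ~ 1/sqrt(T))
  expect_lt(abs(mean(res[[2]]$nullMedian) - sqrt(pi) / (2 * sqrt(50))), 0.15)
})
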