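test_that("generators are bitwise deterministic under a fixed seed", {
  cfg <- tinyCfg(gridShape = c(4L, 4L, 4L), runDurationS = 600)
  c1 <- genCohort(cfg, includePpg = FALSE)
  c2 <- genCohort(cfg, includePpg = FALSE)
  expect_identical(c1$subjects[[1]][[1]]$bold@data,
                   c2$subjects[[1]][[1]]$bold@data)
  expect_identical(c1$subjects[[2]][[1]]$egg@samples,
                   c2$subjects[[2]][[1]]$egg@samples)
  expect_identical(c1$subjects[[1]][[1]]$confounds,
                   c2$subjects[[1]][[1]]$confounds)
})

test_that("EGG generator produces a detectable, selectable gastric rhythm", {
  set.seed(91)
  cfg <- tinyCfg(runDurationS = 900)
  osc <- genGastricOscillator(cfg, 0.048)
  egg <- genEggRecording(cfg, oscPhase = osc)
  expect_s4_class(egg, "EGGRecording")
  expect_equal(nChannels(egg), 4)
  pk <- findGastricPeak(welchSpectrum(egg))
  # amplitude profile puts the strongest peak on channel 1
  expect_equal(selectGastricChannel(pk)$channel, 1)
  expect_lt(abs(pk$peakFreq[1] - 0.048), 1 / 200 + 1e-9)
  # default SNR passes quality level 1 in most seeds
  lv <- vapply(1:10, function(i) {
    o <- genGastricOscillator(cfg, 0.05)
    e <- genEggRecording(cfg, oscPhase = o)
    assessEggQuality(list(findGastricPeak(welchSpectrum(e))))$level
  }, integer(1))
  expect_gte(mean(lv == 1L), 0.9)
})

test_that("coupled-BOLD tuning realises the PLV target through the analysis chain", {
  set.seed(92)
  cfg <- tinyCfg(gridShape = c(8L, 8L, 8L), nCoupledVoxels = 100L,
                 runDurationS = 900)
  osc <- genGastricOscillator(cfg, 0.05)
  for (target in c(0.4, 1)) {
    bold <- genCoupledBold(cfg, osc, couplingPlv = target)
    truth <- attr(bold, "truth")
    th <- boldPhase(bold, 0.05)
    gb <- phase(oscToBoldPhase(osc, cfg))
    p <- plv(gb[-(1:15)], th[, -(1:15)])
    if (target == 1) {
      expect_gt(mean(p[truth$coupledIdx]), 0.85)
    } else {
      expect_lt(abs(mean(p[truth$coupledIdx]) - target), 0.05)
    }
    expect_lt(mean(p[-truth$coupledIdx]), 0.3)
  }
  # target 0: delta centred at zero
  bold0 <- genCoupledBold(cfg, osc, couplingPlv = 0)
  th0 <- boldPhase(bold0, 0.05)
  dm <- deltaMap(th0, oscToBoldPhase(osc, cfg), makeNullShifts(450))
  expect_lt(abs(mean(mapValues(dm$delta)[attr(bold0, "truth")$coupledIdx])),
            0.05)
})

test_that("confound generator injects the gastric rhythm where configured", {
  set.seed(93)
  cfg <- tinyCfg(runDurationS = 900, confoundCoupling = 0.8)
  osc <- genGastricOscillator(cfg, 0.05)
  cp <- genConfoundsAndPpg(cfg, osc)
  gp <- oscToBoldPhase(osc, cfg)
  ns <- makeNullShifts(cfg$nVolumes)
  res <- confoundPlvDelta(cp$confounds, gp, 0.05, ns, TR = 2)
  coupled <- c("csf", "global_signal", "trans_x", "rot_x", "rot_z")
  expect_gt(min(res$delta[res$confound %in% coupled]), 0.1)
  expect_lt(max(abs(res$delta[!res$confound %in% coupled])), 0.3)

  # no coupling: all deltas near zero
  cfg0 <- tinyCfg(runDurationS = 900, confoundCoupling = 0)
  cp0 <- genConfoundsAndPpg(cfg0, osc)
  res0 <- confoundPlvDelta(cp0$confounds, gp, 0.05, ns, TR = 2)
  expect_lt(max(abs(res0$delta), na.rm = TRUE), 0.3)
  expect_lt(abs(mean(res0$delta)), 0.1)

  # PPG beat times recovered by the detector within 20 ms
  det <- detectPpgPeaks(cp$ppg$samples, cp$ppg$fs)
  matched <- vapply(cp$ppg$beatTimes[-1], function(b)
    min(abs(det$peakTimes - b)), numeric(1))
  expect_lt(stats::median(matched), 0.02)
})

test_that("cohorts carry ground truth and honour the stability switch", {
  cfg <- tinyCfg(nSubjects = 3L, runsPerSubject = 2L,
                 gridShape = c(4L, 4L, 4L), nCoupledVoxels = 8L,
                 subjectStability = 1, seed = 7L)
  coh <- genCohort(cfg, includePpg = FALSE)
  expect_length(coh$subjects, 3)
  expect_length(coh$subjects[[1]], 2)
  # stable: same peak frequency and coupling in both runs
  t11 <- coh$subjects[[1]][[1]]$truth
  t12 <- coh$subjects[[1]][[2]]$truth
  expect_identical(t11$peakFreq, t12$peakFreq)
  expect_identical(t11$couplingPlv, t12$couplingPlv)
  expect_identical(t11$coupledIdx, t12$coupledIdx)

  cfg0 <- tinyCfg(nSubjects = 3L, runsPerSubject = 2L,
                  gridShape = c(4L, 4L, 4L), nCoupledVoxels = 8L,
                  subjectStability = 0, seed = 7L)
  coh0 <- genCohort(cfg0, includePpg = FALSE)
  u11 <- coh0$subjects[[1]][[1]]$truth
  u12 <- coh0$subjects[[1]][[2]]$truth
  expect_false(u11$peakFreq == u12$peakFreq)

  # 23 x 2 layout gives 46 runs and 1035 run pairs downstream
  expect_equal(23 * 2, 46)
  expect_equal(choose(46, 2), 1035)
})

test_that("synthetic spheres have unit vertices and requested label patches", {
  ann <- genSphereAnnotation(1000, 0.2, seed = 5)
  expect_s4_class(ann$L, "SphereAnnotation")
  expect_equal(sqrt(rowSums(ann$R@coords^2)), rep(1, 1000),
               tolerance = 1e-9)
  expect_equal(sum(ann$R@labels), 200, tolerance = 2)
  expect_equal(sum(ann$L@labels), 200, tolerance = 2)
  # contiguous patch: labelled vertices are mutually close
  labCoords <- ann$R@coords[ann$R@labels, ]
  centre <- colMeans(labCoords)
  centre <- centre / sqrt(sum(centre^2))
  expect_gt(min(labCoords %*% centre), 0.5)

  # symmetric flag mirrors the right patch
  sym <- genSphereAnnotation(500, 0.15, symmetric = TRUE, seed = 6)
  mirrored <- sym$R@coords[sym$R@labels, ] %*% diag(c(-1, 1, 1))
  nn <- max.col(mirrored %*% t(sym$L@coords))
  expect_gt(mean(sym$L@labels[nn]), 0.9)

  expect_error(genSphereAnnotation(50, 0.2), "100")
})
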