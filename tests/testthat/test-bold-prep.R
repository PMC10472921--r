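test_that("PPG peak detection recovers beats and handles degenerate input", {
  fs <- 100
  tt <- (0:(60 * fs - 1)) / fs
  res <- detectPpgPeaks(sin(2 * pi * 1 * tt), fs)
  expect_true(abs(length(res$peakTimes) - 60) <= 1)
  expect_equal(mean(res$intervals), 1, tolerance = 0.02)

  # pulse-shaped template at 72 bpm: mean interval 0.833 +/- 0.01 s
  set.seed(3)
  beats <- cumsum(rnorm(80, 60 / 72, 0.005))
  beats <- beats[beats < 59]
  ppg <- numeric(60 * fs)
  for (b in beats) ppg <- ppg + exp(-((tt - b)^2) / (2 * 0.05^2))
  res2 <- detectPpgPeaks(ppg + 0.01 * rnorm(length(ppg)), fs)
  expect_equal(mean(res2$intervals), 60 / 72, tolerance = 0.01)
  # detected times within 20 ms of emitted beat times
  matched <- vapply(res2$peakTimes, function(p) min(abs(beats - p)),
                    numeric(1))
  expect_lt(median(matched), 0.02)

  expect_warning(res3 <- detectPpgPeaks(numeric(2000), fs), "flat")
  expect_length(res3$peakTimes, 0)
  expect_error(detectPpgPeaks(rnorm(100), 100), "10 s")
})

test_that("RETROICOR rows encode the cardiac phase harmonics", {
  # regular 1 Hz beats
  pt <- 0:10
  # frame at a peak: phase 0
  expect_equal(retroicorRegressors(pt, 3)[1, ],
               c(cardiac_cos1 = 1, cardiac_sin1 = 0, cardiac_cos2 = 1,
                 cardiac_sin2 = 0, cardiac_cos3 = 1, cardiac_sin3 = 0),
               tolerance = 1e-12)
  # mid-cycle: phase pi
  expect_equal(unname(retroicorRegressors(pt, 3.5)[1, ]),
               c(-1, 0, 1, 0, -1, 0), tolerance = 1e-12)
  # quarter-cycle: phase pi/2
  expect_equal(unname(retroicorRegressors(pt, 3.25)[1, ]),
               c(0, 1, -1, 0, 0, -1), tolerance = 1e-12)

  # harmonic identity cos^2 + sin^2 = 1 on irregular beats and frames
  set.seed(9)
  pt2 <- cumsum(runif(40, 0.7, 1.3))
  fr <- seq(0, max(pt2) + 2, by = 2)
  R <- retroicorRegressors(pt2, fr)
  for (m in 1:3)
    expect_equal(R[, 2 * m - 1]^2 + R[, 2 * m]^2, rep(1, nrow(R)),
                 tolerance = 1e-12)

  expect_error(retroicorRegressors(1, 1:3), "two cardiac peaks")
})

test_that("confound design variants contain exactly the documented columns", {
  set.seed(2)
  n <- 50
  tab <- as.data.frame(matrix(rnorm(n * 10), n,
                              dimnames = list(NULL, CONFOUND_NAMES)))
  tab$framewise_displacement <- abs(tab$framewise_displacement)
  for (i in 0:5) tab[[sprintf("a_comp_cor_0%d", i)]] <- rnorm(n)

  mini <- buildConfoundDesign(tab, "minimal")
  expect_equal(colnames(mini$matrix), c("intercept", "csf"))

  main <- buildConfoundDesign(tab, "main_gsr")
  cn <- colnames(main$matrix)
  # 6 motion + 6 derivatives + 12 squares = 24 motion-derived columns
  motionish <- grepl("^(trans|rot)_", cn)
  expect_equal(sum(motionish), 24)
  expect_true(all(c("intercept", "global_signal",
                    "framewise_displacement") %in% cn))
  expect_equal(sum(grepl("^a_comp_cor", cn)), 6)
  expect_equal(ncol(main$matrix), 1 + 1 + 1 + 24 + 6)

  nog <- buildConfoundDesign(tab, "no_gsr")
  expect_setdiff <- setdiff(cn, colnames(nog$matrix))
  expect_equal(expect_setdiff, "global_signal")

  tab$cardiac_cos1 <- rnorm(n); tab$cardiac_sin1 <- rnorm(n)
  tab$cardiac_cos2 <- rnorm(n); tab$cardiac_sin2 <- rnorm(n)
  tab$cardiac_cos3 <- rnorm(n); tab$cardiac_sin3 <- rnorm(n)
  retro <- buildConfoundDesign(tab, "gsr_retroicor")
  expect_equal(ncol(retro$matrix), ncol(main$matrix) + 6)

  tab2 <- tab[, setdiff(colnames(tab), "rot_z")]
  expect_error(buildConfoundDesign(tab2, "main_gsr"), "rot_z")
})

test_that("confound regression produces residuals orthogonal to the design", {
  set.seed(13)
  n <- 300
  tab <- data.frame(global_signal = rnorm(n), framewise_displacement =
                      abs(rnorm(n)), trans_x = rnorm(n), trans_y = rnorm(n),
                    trans_z = rnorm(n), rot_x = rnorm(n), rot_y = rnorm(n),
                    rot_z = rnorm(n), csf = rnorm(n))
  des <- buildConfoundDesign(tab, "main_gsr")
  sig <- sin(2 * pi * 0.05 * (0:(n - 1)) * 2)
  dat <- rbind(tab$global_signal,                 # equals a design column
               sig,                               # independent signal
               sig + 0.9 * tab$global_signal)     # signal + confound
  run <- BOLDRun(dat, rep(TRUE, 3), c(3, 1, 1), TR = 2)
  out <- regressConfounds(run, des)
  expect_lt(max(abs(out@data[1, ])), 1e-8)
  expect_gt(cor(out@data[2, ], sig), 0.9)

  # noise-free recovery: with the confound itself as the only regressor the
  # signal comes back essentially unchanged
  n2 <- 400
  gs2 <- rnorm(n2)
  sig2 <- sin(2 * pi * 0.05 * (0:(n2 - 1)) * 2)
  run2 <- BOLDRun(rbind(sig2 + 0.9 * gs2, sig2), rep(TRUE, 2), c(2, 1, 1),
                  TR = 2)
  out2 <- regressConfounds(run2, list(matrix = cbind(intercept = 1,
                                                     global_signal = gs2)))
  expect_gt(cor(out2@data[1, ], sig2), 0.99)
  # a voxel orthogonal to the design returns unchanged up to mean removal
  expect_equal(out2@data[2, ], sig2 - mean(sig2), tolerance = 0.05)
  # orthogonality to every design column
  dots <- abs(out@data %*% des$matrix)
  norms <- outer(sqrt(rowSums(out@data^2)),
                 sqrt(colSums(des$matrix^2)))
  expect_true(all(dots <= 1e-8 * pmax(norms, 1)))

  # rank-deficient design: collinear column dropped with a warning
  tab$rot_z <- tab$rot_y
  desBad <- buildConfoundDesign(tab, "main_gsr")
  expect_warning(regressConfounds(run, desBad), "collinear")
})

test_that("Gaussian smoothing has the requested FWHM and preserves DC", {
  dims <- c(15L, 15L, 15L)
  mask <- rep(TRUE, prod(dims))
  # impulse at the centre
  dat <- matrix(0, prod(dims), 2)
  centre <- 8 + 15 * (7 + 15 * 7)
  dat[centre, ] <- 1
  run <- BOLDRun(dat, mask, dims, voxelSize = c(3, 3, 3), TR = 2)
  sm <- smoothGaussian(run, fwhm = 6)   # 2 voxels FWHM
  vol <- array(0, dims)
  vol[mask] <- sm@data[, 1]
  prof <- vol[, 8, 8]
  # half maximum crossing ~1 voxel from the peak on either side
  halfmax <- max(prof) / 2
  above <- range(which(prof >= halfmax))
  expect_equal(diff(above) + 1, 3)      # 2-voxel FWHM spans ~3 samples
  # fitted Gaussian sigma close to fwhm / 2.355 in voxel units
  xs <- which(prof > max(prof) * 1e-4)
  fit <- lm(log(prof[xs]) ~ xs + I(xs^2))
  sigmaFit <- sqrt(-1 / (2 * coef(fit)[3]))
  expect_equal(unname(sigmaFit), 2 / 2.3548, tolerance = 0.1)

  # identity at fwhm = 0, DC preserved, mask-normalized at edges
  expect_identical(smoothGaussian(run, 0), run)
  const <- BOLDRun(matrix(3, prod(dims), 2), mask, dims, TR = 2)
  smc <- smoothGaussian(const, 6)
  expect_equal(smc@data, matrix(3, prod(dims), 2), tolerance = 1e-6)
  expect_error(smoothGaussian(run, -1), "non-negative")
})

test_that("motion exclusion flags runs beyond two group SDs of mean FD", {
  expect_true(all(motionExclusion(c(0.1, 0.1, 0.1, 0.1))))
  flags <- motionExclusion(c(rep(0.1, 9), 1.0))
  expect_equal(unname(flags), c(rep(TRUE, 9), FALSE))
  expect_error(motionExclusion(numeric(0)), "three")
  expect_error(motionExclusion(c(0.1, 0.2)), "three")
})
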