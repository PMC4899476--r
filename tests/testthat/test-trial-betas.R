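# Single-trial beta estimation and pattern-set assembly.

test_that("noiseless round trip: estimated betas equal embedded amplitudes", {
  fx <- noiselessSession()
  pat <- buildPatternSet(fx$runs, fx$design, fx$rois, "left_insula")
  b <- betaValues(pat)
  lab <- trialLabels(pat)
  rows <- seq_len(length(roiMask(fx$rois, "left_insula")))
  truth <- fx$amp[rows, paste(lab$task, lab$level, sep = ".")]
  expect_lt(max(abs(b - truth) / pmax(abs(truth), 1e-9)), 1e-6)
})

test_that("single-trial estimator is linear and zero on constant series", {
  fx <- noiselessSession()
  run <- fx$runs[[1]]
  ev <- runEvents(sessionRun(fx$design, 1))
  vox <- roiMask(fx$rois, "left_insula")
  b1 <- estimateTrialBeta(run, ev$onset_s[3], vox)
  # doubling the embedded signal doubles the beta
  run2 <- run
  run2@data <- 100 + 2 * (run@data - 100) * (run@data > 0)
  b2 <- estimateTrialBeta(run2, ev$onset_s[3], vox)
  expect_equal(b2, 2 * b1, tolerance = 1e-6)
  # constant voxel time series -> beta 0
  runc <- run
  runc@data[] <- ifelse(run@data > 0, 100, 0)
  expect_equal(max(abs(estimateTrialBeta(runc, ev$onset_s[3], vox))), 0)
  # a window truncated by the run end is an explicit error
  expect_error(estimateTrialBeta(run, 416 * 2 - 4, vox), "window")
})

test_that("pattern sets carry 45 labeled non-catch trials per run", {
  fx <- noiselessSession()
  pat <- buildPatternSet(fx$runs, fx$design, fx$rois, "left_insula")
  expect_s4_class(pat, "TrialPatternSet")
  expect_true(validObject(pat))
  lab <- trialLabels(pat)
  expect_equal(ncol(betaValues(pat)), 180L)
  expect_equal(nrow(betaValues(pat)),
               length(roiMask(fx$rois, "left_insula")))
  expect_equal(as.integer(table(lab$run_index)), rep(45L, 4))
  for (r in 1:4)
    expect_equal(as.integer(table(lab$level[lab$run_index == r])), rep(15L, 3))
  # trials ordered by (run, onset)
  expect_false(is.unsorted(lab$run_index))
  for (r in 1:4)
    expect_false(is.unsorted(lab$onset_s[lab$run_index == r],
                             strictly = TRUE))
  expect_error(buildPatternSet(fx$runs[1:3], fx$design, fx$rois,
                               "left_insula"))
  expect_error(buildPatternSet(fx$runs, fx$design, fx$rois, "nope"))
})

test_that("default full-size pattern sets have the published voxel count", {
  # geometry only; betas at full scale are exercised in the acceptance run
  rois <- buildGeometry()
  expect_equal(length(roiMask(rois, "left_insula")), 1533L)
})

test_that("beta recovery is unbiased under noise at Monte Carlo tolerance", {
  fx <- noiselessSession()
  sig <- fx$sig
  noise <- noiseConfig(white_sd = 1.6, ar1_coeff = 0.3,
                       drift_amplitude = 0.5)
  run <- simulateRun(sessionRun(fx$design, 1), fx$rois, sig, noise,
                     seed = 31, amplitudes = fx$amp)
  pat_run <- insulaMVPA:::.estimateBetas(
    insulaMVPA:::.maskTimeSeries(run, roiMask(fx$rois, "left_insula")),
    runEvents(sessionRun(fx$design, 1))$onset_s[
      !runEvents(sessionRun(fx$design, 1))$is_catch], 2, "local")
  ev <- runEvents(sessionRun(fx$design, 1))
  ev <- ev[!ev$is_catch, ]
  rows <- seq_len(length(roiMask(fx$rois, "left_insula")))
  truth <- fx$amp[rows, paste(ev$task, ev$level, sep = ".")]
  err <- pat_run - truth
  # bias across ~4000 voxel-trials is far below the per-beta noise SD
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)) + 0.02)
})
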