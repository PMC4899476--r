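# BOLD simulation: HRF shape, geometry, embedded signal structure.

test_that("the hemodynamic kernel has canonical shape and timing", {
  k0 <- canonicalHRF(duration_s = 0, support_s = 32)
  tt <- attr(k0, "times")
  expect_lte(max(k0), 1); expect_gt(max(k0), 0.85)   # unit-peak kernel, TR-sampled
  expect_true(tt[which.max(k0)] >= 4 && tt[which.max(k0)] <= 6)
  expect_gt(sum(k0), 0)                          # positive net response
  k <- canonicalHRF(tr_s = 2, duration_s = 2)
  expect_length(k, 6L)                           # 12 s support at TR 2 s
  expect_gt(sum(k), 0)
  expect_equal(k[1], 0, tolerance = 1e-6)        # silent at onset
})

test_that("default geometry reproduces the published ROI sizes, disjoint", {
  rois <- buildGeometry()
  expect_equal(length(roiMask(rois, "left_insula")), 1533L)
  expect_equal(length(roiMask(rois, "right_insula")), 1346L)
  expect_equal(length(roiMask(rois, "ctrl_white_matter")), 500L)
  expect_equal(length(roiMask(rois, "ctrl_ba21")), 750L)
  all_idx <- unlist(rois@masks)
  expect_equal(length(all_idx), length(unique(all_idx)))
  expect_true(validObject(rois))
})

test_that("tuning annotation matches the configured fractions and clusters", {
  sig <- signalConfig()
  rois <- buildGeometry(sig)
  for (nm in c("left_insula", "right_insula")) {
    tun <- roiTuning(rois, nm)
    V <- length(roiMask(rois, nm))
    expect_lte(abs(sum(tun == "vitality_preferring") -
                   round(sig@frac_vitality_voxels * V)), 1)
    expect_lte(abs(sum(tun == "velocity_preferring") -
                   round(sig@frac_velocity_voxels * V)), 1)
    # the vitality cluster is contiguous: its coordinate spread is far
    # smaller than the whole mask's
    co <- arrayInd(roiMask(rois, nm), rois@dim)
    vit <- tun == "vitality_preferring"
    expect_lt(mean(apply(co[vit, ], 2, sd)), mean(apply(co, 2, sd)))
  }
  expect_error(roiTuning(rois, "ctrl_ba21"))
})

test_that("simulated runs are deterministic and finite", {
  fx <- noiselessSession()
  r1 <- simulateRun(sessionRun(fx$design, 1), fx$rois, fx$sig, fx$noise,
                    seed = 77)
  r2 <- simulateRun(sessionRun(fx$design, 1), fx$rois, fx$sig, fx$noise,
                    seed = 77)
  expect_identical(r1@data, r2@data)
  expect_equal(dim(r1@data)[4], 416L)
  expect_true(all(is.finite(r1@data)))
})

test_that("with noise off the trial-window signal equals amplitude x kernel", {
  fx <- noiselessSession()
  run <- fx$runs[[1]]
  ev <- runEvents(sessionRun(fx$design, 1))
  kernel <- as.numeric(canonicalHRF(2, 2))
  vox_all <- unlist(fx$rois@masks)
  flat <- matrix(run@data, prod(fx$rois@dim), 416)
  i <- 7L   # an arbitrary trial
  v0 <- floor(ev$onset_s[i] / 2) + 1L
  cond <- paste(ev$task[i], ev$level[i], sep = ".")
  baseline <- 100
  for (vi in c(1L, 50L, length(vox_all))) {
    expected <- baseline * (1 + fx$amp[vi, cond] * kernel / 100)
    expect_equal(unname(flat[vox_all[vi], v0:(v0 + 5)]), expected,
                 tolerance = 1e-10)
  }
})

test_that("the region-mean response is task-balanced and controls are untuned", {
  fx <- noiselessSession()
  # demeaned tuned deviations: mask-mean amplitude identical across tasks
  off <- 0L
  for (nm in roiNames(fx$rois)) {
    V <- length(fx$rois@masks[[nm]])
    rows <- off + seq_len(V); off <- off + V
    m <- colMeans(fx$amp[rows, , drop = FALSE])
    expect_equal(unname(m), rep(1, 6), tolerance = 1e-12)
    if (!nm %in% names(fx$rois@tuning))   # control ROIs: common only
      expect_true(all(abs(fx$amp[rows, ] - 1) < 1e-12))
  }
  # a null configuration embeds no condition differences anywhere
  sig0 <- signalConfig(delta = 0, level_delta = 0)
  amp0 <- insulaMVPA:::.voxelAmplitudes(fx$rois, sig0, 5)
  expect_true(all(abs(amp0 - 1) < 1e-12))
})
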