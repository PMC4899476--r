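# Decoding: CV scheme, SVM contrasts, permutation null, Wilcoxon test,
# univariate control.

test_that("the CV scheme is the four alternate-run folds", {
  cv <- makeCVFolds()
  expect_length(cv, 4L)
  expect_identical(cv[[1]], list(train = c(1L, 3L), test = c(2L, 4L)))
  expect_identical(cv[[2]], list(train = c(2L, 4L), test = c(1L, 3L)))
  expect_identical(cv[[3]], list(train = c(2L, 3L), test = c(1L, 4L)))
  expect_identical(cv[[4]], list(train = c(1L, 4L), test = c(2L, 3L)))
  for (fold in cv) {
    expect_length(intersect(fold$train, fold$test), 0L)
    expect_setequal(union(fold$train, fold$test), 1:4)
    # one vitality run (1, 2) and one velocity run (3, 4) on each side
    expect_length(intersect(fold$train, 1:2), 1L)
    expect_length(intersect(fold$train, 3:4), 1L)
  }
})

test_that("decoding is near perfect in the separable limit and the folds are balanced", {
  fx <- noiselessSession()   # strong signal, zero noise
  pat <- buildPatternSet(fx$runs, fx$design, fx$rois, "left_insula")
  res <- decodeContrast(pat, crossTaskContrasts()[[1]])
  expect_true(validObject(res))
  expect_gte(meanAccuracy(res), 0.95)
  expect_equal(meanAccuracy(res), mean(foldAccuracies(res)))
  # weights: planted vitality voxels positive, velocity voxels negative
  tun <- roiTuning(fx$rois, "left_insula")
  w <- rowMeans(foldWeights(res))
  expect_gt(mean(w[tun == "vitality_preferring"]), 0)
  expect_lt(mean(w[tun == "velocity_preferring"]), 0)
})

test_that("control-ROI and within-task decoding sit at chance", {
  fx <- noisySubject()
  patc <- buildPatternSet(fx$runs, fx$design, fx$rois, "ctrl_ba21")
  acc_c <- mean(vapply(crossTaskContrasts(), function(ct)
    meanAccuracy(decodeContrast(patc, ct)), numeric(1)))
  expect_gt(acc_c, 0.35); expect_lt(acc_c, 0.65)
  # level_delta = 0: within-task contrasts undecodable even in the insula
  pati <- buildPatternSet(fx$runs, fx$design, fx$rois, "left_insula")
  acc_w <- mean(vapply(withinTaskContrasts()[c(2, 5)], function(ct)
    meanAccuracy(decodeContrast(pati, ct)), numeric(1)))
  expect_gt(acc_w, 0.35); expect_lt(acc_w, 0.65)
})

test_that("the permutation null is reproducible and centers on 50%", {
  fx <- noisySubject()
  pat <- buildPatternSet(fx$runs, fx$design, fx$rois, "ctrl_white_matter")
  ct <- crossTaskContrasts()[[1]]
  n1 <- permutationNull(pat, ct, n_perm = 2, seed = 5)
  n2 <- permutationNull(pat, ct, n_perm = 2, seed = 5)
  expect_identical(n1, n2)
  expect_length(n1$null_accuracies, 2L)
  n <- permutationNull(pat, ct, n_perm = 60, seed = 6)
  se <- sd(n$null_accuracies) / sqrt(60)
  expect_lt(abs(n$chance_estimate - 0.5), 4 * se + 0.02)
  expect_error(permutationNull(pat, ct, n_perm = 0))
  # empirical p bounds
  p <- permutationP(0.99, n$null_accuracies)
  expect_gt(p, 0); expect_lte(p, 1)
  expect_equal(permutationP(-1, n$null_accuracies), 1)
})

test_that("exact Wilcoxon signed-rank matches enumeration, references and symmetry", {
  # 16 distinct values all above chance: single extreme sign assignment
  w <- wilcoxonGroup(seq(0.51, 0.66, by = 0.01))
  expect_equal(w$p_value, 1 / 2^16)
  expect_equal(w$statistic, 16 * 17 / 2)
  # brute-force enumeration oracle at n = 6
  set.seed(21)
  for (k in 1:8) {
    acc <- 0.5 + round(rnorm(6, 0.02, 0.05), 3)
    acc <- acc[acc != 0.5]
    if (length(acc) < 2) next
    expect_equal(wilcoxonGroup(acc)$p_value,
                 bruteForceSignedRankP(acc - 0.5), tolerance = 1e-12)
  }
  # tie-free case agrees with the exact psignrank distribution
  acc <- 0.5 + c(0.011, -0.022, 0.033, 0.044, -0.055, 0.066, 0.077)
  d <- acc - 0.5
  W <- sum(rank(abs(d))[d > 0])
  expect_equal(wilcoxonGroup(acc)$p_value,
               1 - psignrank(W - 1, length(d)))
  # symmetric +/- pairs of equal magnitude: p close to 0.5, not significant
  sym <- 0.5 + c(0.01, -0.01, 0.03, -0.03, 0.05, -0.05)
  expect_gt(wilcoxonGroup(sym)$p_value, 0.3)
  expect_error(wilcoxonGroup(rep(0.5, 5)))
})

test_that("univariate control detects planted global offsets and only those", {
  # hand-made 3-subject table: t matches direct arithmetic
  tab <- data.frame(subject_id = c("a", "b", "c"), roi = "left_insula",
                    vitality_mean = c(101, 102, 103),
                    velocity_mean = c(100.5, 101.0, 102.8))
  out <- univariateROICheck(tab)
  d <- c(0.5, 1.0, 0.2)
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_error(univariateROICheck(tab[1, , drop = FALSE]))
  # planted global vitality offset is detected across simulated subjects
  sig_off <- signalConfig(task_mean_offset = 0.5)
  rois <- buildGeometry(sig_off, scale = 0.05)
  subs <- lapply(1:4, function(s)
    simulateSubject(sprintf("s%d", s), seed = 100 + s, rois = rois,
                    signal = sig_off))
  res <- univariateROICheck(subs, roi_names = c("left_insula", "ctrl_ba21"))
  expect_lt(res$p_value[res$roi == "left_insula"], 0.05)
  expect_gt(res$mean_diff[res$roi == "left_insula"], 0)
})
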