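# Kinematics: velocity profiles, DTW, judgment simulation and log fit.

test_that("minimum-jerk profiles integrate to the path length and sample at rate", {
  for (tm in c(500, 1000, 1600)) {
    tr <- generateVelocityProfile(tm, path_length_m = 0.5, seed = 1,
                                  perturbation_sd = 0)
    speed <- trajectoryChannel(tr, "modulus")
    expect_equal(nrow(trajectorySamples(tr)), round(tm / 10))
    # discrete integral of speed = path length (midpoint rule)
    expect_equal(sum(speed) * 0.01, 0.5, tolerance = 1e-3)
    # bell shape: peak near mid-movement, endpoints near zero
    expect_gt(which.max(speed) / length(speed), 0.4)
    expect_lt(which.max(speed) / length(speed), 0.6)
    expect_lt(speed[1], 0.05 * max(speed))
    expect_lt(speed[length(speed)], 0.05 * max(speed))
  }
})

test_that("calibrated stimuli reproduce the published mean velocities", {
  # 600 / 1000 / 1400 ms actions travel 0.636 / 0.570 / 0.532 m
  expect_equal(stimulusPathLength(600), 0.636)
  expect_equal(stimulusPathLength(1000), 0.570)
  expect_equal(stimulusPathLength(1400), 0.532)
  tr <- generateVelocityProfile(1000, seed = 1, perturbation_sd = 0)
  expect_equal(mean(trajectoryChannel(tr, "modulus")), 0.57,
               tolerance = 1e-3)
  tr6 <- generateVelocityProfile(600, seed = 1, perturbation_sd = 0)
  expect_equal(mean(trajectoryChannel(tr6, "modulus")), 1.06,
               tolerance = 1e-2)
})

test_that("degenerate and invalid profile arguments are rejected or trivial", {
  expect_error(generateVelocityProfile(-100, 0.5))
  expect_error(generateVelocityProfile(1000, -1))
  expect_error(generateVelocityProfile(2000, 0.5))
  tiny <- generateVelocityProfile(600, path_length_m = 1e-4, seed = 1)
  expect_lt(max(trajectoryChannel(tiny, "modulus")), 1e-3)
})

test_that("DTW equals exhaustive path enumeration on short series", {
  expect_equal(dtwDistance(c(0, 1, 2), c(0, 2)),
               bruteForceDTW(c(0, 1, 2), c(0, 2)))
  set.seed(11)
  for (k in 1:20) {
    a <- rnorm(sample(1:6, 1))
    b <- rnorm(sample(1:6, 1))
    expect_equal(dtwDistance(a, b), bruteForceDTW(a, b), tolerance = 1e-12)
  }
})

test_that("DTW is symmetric, non-negative and zero on identical series", {
  set.seed(4)
  for (k in 1:10) {
    a <- rnorm(sample(3:40, 1)); b <- rnorm(sample(3:40, 1))
    expect_equal(dtwDistance(a, b), dtwDistance(b, a))
    expect_gte(dtwDistance(a, b), 0)
    expect_equal(dtwDistance(a, a), 0)
  }
  expect_error(dtwDistance(numeric(0), 1))
  expect_error(dtwDistance(c(1, NA), c(1, 2)))
})

test_that("pairwise DTW matrix over 36 stimuli is well-formed and consistent", {
  trajs <- generateStimulusSet(seed = 3)
  m <- pairwiseDTWMatrix(trajs, "modulus")
  d <- dtwDistances(m)
  expect_equal(dim(d), c(36L, 36L))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 36))
  # one entry recomputed independently from the extracted channels
  i <- 5L; j <- 29L
  expect_equal(d[i, j],
               dtwDistance(trajectoryChannel(trajs[[i]], "modulus"),
                           trajectoryChannel(trajs[[j]], "modulus")))
  # duplicate labels and wrong counts are rejected
  expect_error(pairwiseDTWMatrix(trajs[c(1:35, 1)]), "duplicate")
  expect_error(pairwiseDTWMatrix(trajs[1:35]), "36")
})

test_that("same-duration stimuli are mutually closer than across durations", {
  trajs <- generateStimulusSet(seed = 3)
  for (mode in c("modulus", "vx")) {
    rep <- durationGroupingCheck(pairwiseDTWMatrix(trajs, mode))
    expect_true(rep$within_less)
    expect_lt(rep$within_mean, rep$between_mean)
  }
})

test_that("duration grouping means match hand arithmetic on a 4-stimulus toy", {
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 2
  d[1, 3] <- d[3, 1] <- 5; d[1, 4] <- d[4, 1] <- 6
  d[2, 3] <- d[3, 2] <- 7; d[2, 4] <- d[4, 2] <- 8
  toy <- new("DTWDistanceMatrix", distances = d,
             objects = c("bottle", "can", "bottle", "can"),
             levels = c(1L, 1L, 2L, 2L), mode = "modulus")
  rep <- durationGroupingCheck(toy)
  expect_equal(rep$within_mean, (1 + 2) / 2)
  expect_equal(rep$between_mean, (5 + 6 + 7 + 8) / 4)
  expect_true(rep$within_less)
  # all-equal distances: within == between, flag FALSE
  d2 <- matrix(3, 4, 4); diag(d2) <- 0
  toy2 <- new("DTWDistanceMatrix", distances = d2,
              objects = toy@objects, levels = toy@levels, mode = "modulus")
  rep2 <- durationGroupingCheck(toy2)
  expect_equal(rep2$within_mean, rep2$between_mean)
  expect_false(rep2$within_less)
})

test_that("judgment simulation is deterministic and ordered by task intercept", {
  j1 <- simulateJudgments(noise_sd = 0.3, n_subjects = 6, seed = 9)
  j2 <- simulateJudgments(noise_sd = 0.3, n_subjects = 6, seed = 9)
  expect_identical(j1, j2)
  expect_true(all(j1$score >= 1 & j1$score <= 5))
  # velocity curve sits above vitality by construction of the defaults
  expect_gt(mean(j1$score[j1$task == "velocity"]),
            mean(j1$score[j1$task == "vitality"]))
})

test_that("log fit is exact on noiseless data and near zero on pure noise", {
  j0 <- simulateJudgments(a_task = c(vitality = 10, velocity = 10.2),
                          b_task = c(vitality = -1, velocity = -1),
                          noise_sd = 0, n_subjects = 3, seed = 1)
  f <- suppressWarnings(fitLogJudgment(j0, "vitality"))  # perfect-fit note
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 10, tolerance = 1e-9)
  expect_equal(f$slope, -1, tolerance = 1e-9)
  # flat curve + large noise: no systematic trend
  jn <- simulateJudgments(a_task = c(vitality = 3, velocity = 3),
                          b_task = c(vitality = 0, velocity = 0),
                          noise_sd = 1.5, n_subjects = 40, seed = 2)
  expect_lt(fitLogJudgment(jn, "vitality")$r_squared, 0.5)
  expect_error(fitLogJudgment(j0[j0$exec_time_ms == 500, ], "vitality"))
})

test_that("log-fit slope recovery stays within Monte Carlo bounds", {
  # moderate noise, 18 subjects, many seeds: recovered slope unbiased
  slopes <- vapply(1:60, function(s) {
    j <- simulateJudgments(a_task = c(vitality = 20.47, velocity = 20.64),
                           b_task = c(vitality = -2.58, velocity = -2.58),
                           noise_sd = 0.4, n_subjects = 18, seed = s)
    fitLogJudgment(j, "vitality")$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-2.58)), 3 * se + 0.02)
  # and fits on the calibrated defaults are strong, log-like trends
  j <- simulateJudgments(seed = 5)
  expect_gt(fitLogJudgment(j, "vitality")$r_squared, 0.85)
  expect_gt(fitLogJudgment(j, "velocity")$r_squared, 0.85)
})
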