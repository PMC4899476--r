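# Group maps: ranking, selection, overlap, nulls, FDR.

# minimal DecodingResult with given fold weights
mkResult <- function(w, subject = "s1", roi = "roi") {
  W <- matrix(rep(w, 4), ncol = 4)
  rownames(W) <- paste0("vox", seq_along(w))
  new("DecodingResult", subject_id = subject, roi_name = roi,
      contrast = "rude_vs_fast", fold_accuracies = rep(0.6, 4),
      mean_accuracy = 0.6, weights = W,
      null_accuracies = numeric(0), chance_estimate = NA_real_)
}

test_that("voxel ranking orders by |weight| with stable signs and ties", {
  m <- rankDiscriminativeVoxels(mkResult(c(3, -1, 2)))
  expect_equal(m@rank, c(1L, 3L, 2L))
  expect_equal(unname(sign(m@weight)), c(1, -1, 1))
  # relabeling voxels permutes ranks identically
  perm <- c(2, 3, 1)
  m2 <- rankDiscriminativeVoxels(mkResult(c(3, -1, 2)[perm]))
  expect_equal(m2@rank, m@rank[perm])
  # ties broken by voxel id
  mt <- rankDiscriminativeVoxels(mkResult(c(2, -2, 1)))
  expect_equal(mt@rank, c(1L, 2L, 3L))
  # collapsing contrasts averages signed weights
  mc <- rankDiscriminativeVoxels(list(mkResult(c(3, -1, 2)),
                                      mkResult(c(1, 3, -2))))
  expect_equal(unname(mc@weight), c(2, 1, 0))
  bad <- mkResult(c(1, 2, 3)); bad@weights[1, 2] <- NA
  expect_error(rankDiscriminativeVoxels(bad), "missing")
})

test_that("top-fraction selection sizes follow round(f x V)", {
  w <- rnorm(1346)
  m <- rankDiscriminativeVoxels(mkResult(w))
  expect_equal(sum(selectTopFraction(m, 0.5)@selected), 673L)
  expect_equal(sum(selectTopFraction(m, 0.35)@selected), round(0.35 * 1346))
  expect_equal(sum(selectTopFraction(m, 1.0)@selected), 1346L)
  expect_error(selectTopFraction(m, 0))
  expect_error(selectTopFraction(m, 1.2))
  # the selected voxels are exactly the top-ranked ones
  s <- selectTopFraction(m, 0.1)
  expect_true(all(s@rank[s@selected] <= round(0.1 * 1346)))
})

test_that("group overlap counts match a hand tally and conserve totals", {
  maps <- list(
    selectTopFraction(rankDiscriminativeVoxels(
      mkResult(c(5, 4, 3, 2, 1, -6, 0.5, 0.2, 0.1, 0.05))), 0.5),
    selectTopFraction(rankDiscriminativeVoxels(
      mkResult(c(5, -4, 0.1, 2, 1, 0.2, 3, 0.3, 0.05, 0.01))), 0.5),
    selectTopFraction(rankDiscriminativeVoxels(
      mkResult(c(-5, 0.1, 0.2, 2, 1, 0.3, 3, 4, 0.05, 0.01))), 0.5))
  gm <- groupOverlap(maps)
  oc <- overlapCounts(gm)
  # independent tally over the three subjects' selection masks
  sel <- vapply(maps, function(m) m@selected, logical(10))
  sgn <- vapply(maps, function(m) m@weight >= 0, logical(10))
  expect_equal(oc$overlap_total, unname(rowSums(sel)))
  expect_equal(oc$overlap_pos, unname(rowSums(sel & sgn)))
  expect_equal(oc$overlap_neg, unname(rowSums(sel & !sgn)))
  # conservation: total selections = S x round(f V)
  expect_equal(sum(oc$overlap_total), 3L * 5L)
  # all-subjects-positive and disjoint-selection edge cases
  allpos <- replicate(4, selectTopFraction(rankDiscriminativeVoxels(
    mkResult(c(9, 1, 0.5, 0.1))), 0.25), simplify = FALSE)
  expect_equal(overlapCounts(groupOverlap(allpos))$overlap_pos[1], 4L)
  expect_error(groupOverlap(list(maps[[1]],
                                 rankDiscriminativeVoxels(mkResult(1:10)))),
               "selected")
})

test_that("binomial overlap tail probabilities are exact", {
  expect_equal(binomialOverlapPvalue(0, 16, 0.5), 1.0)
  expect_equal(binomialOverlapPvalue(16, 16, 0.5), 2^-16)
  expect_equal(binomialOverlapPvalue(10, 16, 0.5), 14893 / 65536)
  # direct summation of binomial terms as an independent check
  direct <- sum(choose(16, 10:16)) / 2^16
  expect_equal(binomialOverlapPvalue(10, 16, 0.5), direct)
  expect_error(binomialOverlapPvalue(17, 16, 0.5))
})

test_that("the Monte Carlo null converges to the binomial closed form", {
  null <- monteCarloOverlapNull(V = 300, S = 16, f = 0.5, n_iter = 3000,
                                seed = 8)
  for (k in c(8, 10, 12)) {
    mc <- unname(null$tail[as.character(k)])
    exact <- binomialOverlapPvalue(k, 16, 0.5)
    se <- null$iter_fraction_sd[k + 1] / sqrt(null$n_iter)
    expect_lt(abs(mc - exact), 3 * se + 1e-4)
  }
  # degenerate f = 1: every voxel always selected by all subjects
  n1 <- monteCarloOverlapNull(V = 20, S = 4, f = 1, n_iter = 50, seed = 1)
  expect_equal(unname(n1$tail[as.character(4)]), 1, tolerance = 1e-3)
  # reproducibility
  expect_identical(monteCarloOverlapNull(50, 8, 0.5, 100, seed = 3),
                   monteCarloOverlapNull(50, 8, 0.5, 100, seed = 3))
})

test_that("BH thresholding reproduces hand-computed step-up decisions", {
  # 10 small + 90 large p-values: exactly the small ones survive
  p <- c(rep(0.001, 10), rep(0.9, 90))
  expect_equal(fdrThreshold(p, q = 0.05)$mask, c(rep(TRUE, 10),
                                                 rep(FALSE, 90)))
  # all p = 1: empty mask
  expect_false(any(fdrThreshold(rep(1, 50), 0.05)$mask))
  # the marginal overlap >= 10/16 tail (~0.227) cannot survive BH anywhere
  expect_false(any(fdrThreshold(rep(14893 / 65536, 200), 0.05)$mask))
})

test_that("group map p-values, FDR mask and signs are coherent", {
  pos <- c(16L, 15L, 3L, 2L, rep(1L, 20))
  neg <- c(0L, 1L, 1L, 1L, rep(0L, 20))
  gm <- new("GroupOverlapMap", roi_name = "left_insula",
            overlap_pos = pos, overlap_neg = neg, n_subjects = 16L,
            fraction = 0.5)
  gm <- overlapPValues(gm, "binomial")
  expect_equal(gm@p_value,
               binomialOverlapPvalue(pos + neg, 16, 0.5))
  gm <- fdrThreshold(gm, 0.05)
  expect_true(all(fdrMask(gm)[1:2]))
  expect_false(any(fdrMask(gm)[5:24]))
  expect_equal(attr(gm, "min_surviving_overlap"), 16L)
  expect_equal(groupMapSigns(gm)[1:4], c(1L, 1L, 1L, 1L))
  # monte carlo route fills the same field
  gm2 <- overlapPValues(gm, "monte_carlo", n_iter = 500, seed = 2)
  expect_length(gm2@p_value, length(pos))
  expect_true(all(gm2@p_value > 0 & gm2@p_value <= 1))
})
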