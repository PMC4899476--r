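# Independent oracles and shared fixtures, built in code at test time.

# Brute-force DTW: exhaustive recursion over all monotone warping paths.
# Independent of the package's dynamic-programming implementation; only
# feasible for short series.
bruteForceDTW <- function(a, b) {
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    cands <- c(
      if (i > 1) rec(i - 1, j),
      if (j > 1) rec(i, j - 1),
      if (i > 1 && j > 1) rec(i - 1, j - 1))
    c0 + min(cands)
  }
  rec(length(a), length(b))
}

# Brute-force one-sided signed-rank p: enumerate all 2^n sign patterns.
bruteForceSignedRankP <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% r
  mean(W_all >= W_obs - 1e-12)
}

# Shared small noise-free session (signal embedded, noise and drift off),
# built once per test run.
.fixture_env <- new.env(parent = emptyenv())

noiselessSession <- function() {
  if (is.null(.fixture_env$noiseless)) {
    sig <- signalConfig(delta = 0.6, subject_delta_sd = 0,
                        cluster_displacement_sd = 0)
    rois <- buildGeometry(sig, scale = 0.06)
    noise0 <- noiseConfig(white_sd = 0, drift_amplitude = 0)
    design <- generateSessionDesign("sub-fx", seed = 202)
    runs <- lapply(1:4, function(r)
      simulateRun(sessionRun(design, r), rois, sig, noise0, seed = 404,
                  subject_id = "sub-fx"))
    amp <- insulaMVPA:::.voxelAmplitudes(rois, sig, 404)
    .fixture_env$noiseless <- list(sig = sig, rois = rois, noise = noise0,
                                   design = design, runs = runs, amp = amp)
  }
  .fixture_env$noiseless
}

# One noisy default-signal subject at reduced scale, shared across tests.
noisySubject <- function() {
  if (is.null(.fixture_env$noisy)) {
    sig <- signalConfig()
    rois <- buildGeometry(sig, scale = 0.125)
    .fixture_env$noisy <- c(
      simulateSubject("sub-nx", seed = 909, rois = rois, signal = sig),
      list(template = rois))
  }
  .fixture_env$noisy
}
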