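# Synthetic BOLD generator: canonical HRF, ROI lattice geometry with
# task-tuned voxel populations, and the 4-D run simulator.

#' Canonical double-gamma hemodynamic response kernel
#'
#' The SPM-style double-gamma impulse response (peak ~5 s, undershoot ~15 s)
#' convolved with a boxcar of the event duration, sampled on the TR grid and
#' normalized to unit peak. The kernel support is truncated at `support_s`
#' (12 s by default, i.e. 6 samples at TR 2 s): with the paradigm's minimum
#' 12 s inter-stimulus interval this makes consecutive trial responses
#' non-overlapping, so the windowed single-trial fit is exact in the
#' noiseless limit.
#'
#' @param tr_s sampling interval (the repetition time), s.
#' @param duration_s event (boxcar) duration, s; 0 gives the impulse
#'   response itself.
#' @param support_s kernel support, s; samples are taken at
#'   0, tr_s, ..., < support_s.
#' @return Numeric vector of kernel values with a "times" attribute.
#' @export
#' @examples
#' k <- canonicalHRF()
#' attr(k, "times")[which.max(k)]   # peak ~6 s for a 2 s event
canonicalHRF <- function(tr_s = 2, duration_s = 2, support_s = 12) {
  .assertScalarNumber(tr_s, "tr_s", positive = TRUE)
  if (duration_s < 0) stop("'duration_s' must be >= 0", call. = FALSE)
  dt <- 0.05
  tt <- seq(0, 32, by = dt)
  h <- dgamma(tt, shape = 6, rate = 1) - dgamma(tt, shape = 16, rate = 1) / 6
  if (duration_s > 0) {
    box <- rep(1, max(1L, round(duration_s / dt)))
    h <- convolve(h, rev(box), type = "open")[seq_along(tt)] * dt
  }
  h <- h / max(h)
  times <- seq(0, support_s - 1e-9, by = tr_s)
  k <- h[round(times / dt) + 1L]
  attr(k, "times") <- times
  k
}

# radius (in voxels) of a ball holding ~n voxels
.ballRadius <- function(n) (3 * n / (4 * pi))^(1 / 3)

# the n lattice voxels nearest to `center`, as linear indices
.ballVoxels <- function(dim, center, n) {
  cx <- seq_len(dim[1]); cy <- seq_len(dim[2]); cz <- seq_len(dim[3])
  d2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, "+"),
              (cz - center[3])^2, "+")
  order(d2)[seq_len(n)]
}

#' Build the ROI lattice geometry with task-tuning annotation
#'
#' Places four disjoint contiguous (ball-shaped) masks on a compact 3-D
#' lattice: left insula (1533 voxels by default), right insula (1346), a
#' white-matter control (500) and a BA21 control (750). Within each insula
#' mask, a contiguous dorso-central cluster of voxels is annotated
#' "vitality_preferring" (the common population) and a smaller, spatially
#' separate cluster "velocity_preferring" (the rare one), in the
#' proportions given by the \linkS4class{SignalConfig}; control-ROI voxels
#' carry no annotation and never receive task signal. `scale` shrinks all
#' mask sizes proportionally for reduced-resolution cohorts.
#'
#' @param signal a \linkS4class{SignalConfig} (only the tuning fractions
#'   are used here).
#' @param scale multiplicative factor on all mask voxel counts.
#' @param roi_sizes named integer vector of mask sizes before scaling.
#' @param voxel_size_mm isotropic voxel size.
#' @param displace_seed when non-NULL, tuned-cluster centres are displaced
#'   by rounded Gaussian offsets
#'   (SD = \code{signal@cluster_displacement_sd}) before annotation --
#'   the per-subject variation used by \code{\link{simulateSubject}}.
#' @return A \linkS4class{ROISet}.
#' @export
#' @examples
#' rois <- buildGeometry()
#' vapply(rois@masks, length, integer(1))
buildGeometry <- function(signal = signalConfig(), scale = 1,
                          roi_sizes = c(left_insula = 1533L,
                                        right_insula = 1346L,
                                        ctrl_white_matter = 500L,
                                        ctrl_ba21 = 750L),
                          voxel_size_mm = 2.5,
                          displace_seed = NULL) {
  stopifnot(is(signal, "SignalConfig"))
  .assertScalarNumber(scale, "scale", positive = TRUE)
  sizes <- pmax(as.integer(round(roi_sizes * scale)), 4L)
  names(sizes) <- names(roi_sizes)
  radii <- ceiling(.ballRadius(sizes))
  margin <- 3L
  yz <- 2L * max(radii) + margin
  centers <- list()
  x_cursor <- 0L
  for (i in seq_along(sizes)) {
    x_cursor <- x_cursor + radii[i] + margin
    centers[[names(sizes)[i]]] <- c(x_cursor, ceiling(yz / 2), ceiling(yz / 2))
    x_cursor <- x_cursor + radii[i]
  }
  dims <- as.integer(c(x_cursor + margin, yz, yz))
  if (prod(dims) < sum(sizes))
    stop("requested mask sizes do not fit the lattice", call. = FALSE)
  masks <- lapply(names(sizes), function(nm)
    .ballVoxels(dims, centers[[nm]], sizes[[nm]]))
  names(masks) <- names(sizes)

  tuning <- list()
  cluster_info <- list()
  insulas <- intersect(c("left_insula", "right_insula"), names(masks))
  for (nm in insulas) {
    idx <- masks[[nm]]
    V <- length(idx)
    coords <- arrayInd(idx, dims)
    ctr <- centers[[nm]]
    r <- radii[[match(nm, names(sizes))]]
    # vitality cluster sits dorso-central (upper half), velocity ventral
    vit_center <- ctr + c(0, 0, round(r / 2))
    vel_center <- ctr + c(0, 0, -round(r / 2))
    if (!is.null(displace_seed)) {
      # displacement scales with the ROI radius, so reduced-resolution
      # cohorts keep the same relative anatomical variability
      dsd <- signal@cluster_displacement_sd * r
      dsp <- withSeed(deriveSeed(displace_seed, match(nm, insulas)), {
        list(v1 = round(rnorm(3, 0, dsd)), v2 = round(rnorm(3, 0, dsd)))
      })
      vit_center <- vit_center + dsp$v1
      vel_center <- vel_center + dsp$v2
    }
    n_vit <- round(signal@frac_vitality_voxels * V)
    n_vel <- round(signal@frac_velocity_voxels * V)
    d_vit <- colSums((t(coords) - vit_center)^2)
    d_vel <- colSums((t(coords) - vel_center)^2)
    lab <- rep("untuned", V)
    lab[order(d_vit)[seq_len(n_vit)]] <- "vitality_preferring"
    pool <- which(lab == "untuned")
    lab[pool[order(d_vel[pool])[seq_len(min(n_vel, length(pool)))]]] <-
      "velocity_preferring"
    tuning[[nm]] <- lab
    cluster_info[[nm]] <- list(vitality_center = vit_center,
                               velocity_center = vel_center)
  }
  new("ROISet", dim = dims, voxel_size_mm = voxel_size_mm, masks = masks,
      tuning = tuning, cluster_info = cluster_info)
}

# Per-voxel trial amplitudes (percent signal change) for the six
# (task, level) conditions, for every mask voxel in canonical order
# (masks concatenated in roiNames() order). Tuned deviations and level
# patterns are demeaned within each insula mask so the region-mean
# response is identical across conditions (no univariate task effect);
# task_mean_offset deliberately breaks that balance when non-zero.
.voxelAmplitudes <- function(rois, signal, seed, amp_common = 1) {
  conds <- expand.grid(level = 1:3, task = c("vitality", "velocity"),
                       stringsAsFactors = FALSE)
  cond_names <- paste(conds$task, conds$level, sep = ".")
  n_all <- sum(vapply(rois@masks, length, integer(1)))
  amp <- matrix(amp_common, n_all, nrow(conds),
                dimnames = list(NULL, cond_names))
  offset <- 0L
  for (nm in roiNames(rois)) {
    V <- length(rois@masks[[nm]])
    rows <- offset + seq_len(V)
    offset <- offset + V
    if (nm %in% names(rois@tuning)) {
      lab <- rois@tuning[[nm]]
      s <- withSeed(deriveSeed(seed, 977L, match(nm, roiNames(rois))), {
        list(jit = rnorm(V, 0, signal@pattern_jitter_sd),
             lev = matrix(rnorm(V * 3L), V, 3L))
      })
      dev_vit <- signal@delta * (lab == "vitality_preferring") * (1 + s$jit)
      dev_vel <- signal@delta * (lab == "velocity_preferring") * (1 + s$jit)
      dev_vit <- dev_vit - mean(dev_vit)
      dev_vel <- dev_vel - mean(dev_vel)
      lev_pat <- signal@level_delta *
        sweep(s$lev, 2, colMeans(s$lev), "-")
      for (ci in seq_len(nrow(conds))) {
        dev <- if (conds$task[ci] == "vitality") dev_vit else dev_vel
        amp[rows, ci] <- amp[rows, ci] + dev + lev_pat[, conds$level[ci]] +
          if (conds$task[ci] == "vitality") signal@task_mean_offset else 0
      }
    }
  }
  amp
}

#' Simulate one 4-D BOLD run
#'
#' Generates the voxel time series of one functional run: baseline plus a
#' slow sinusoidal drift, AR(1)-correlated Gaussian noise and, for every
#' trial in the design, a per-voxel response amplitude convolved with the
#' canonical HRF kernel. All amplitudes are in percent of baseline.
#' Insular voxels carry the task-tuned pattern signal of the
#' \linkS4class{SignalConfig}; control-ROI voxels receive the common
#' response only. Voxels outside every mask are left at zero (background).
#'
#' @param design a \linkS4class{RunDesign}.
#' @param rois a \linkS4class{ROISet}.
#' @param signal a \linkS4class{SignalConfig}.
#' @param noise a \linkS4class{NoiseConfig}.
#' @param seed RNG seed for this run's noise.
#' @param subject_id subject identifier recorded in the output.
#' @param amp_common common response amplitude (percent signal change)
#'   received by every mask voxel on every trial.
#' @param amplitudes optional precomputed amplitude matrix from the
#'   internal generator (used by \code{\link{simulateSubject}} to keep a
#'   subject's voxel patterns identical across runs); when NULL it is
#'   derived from `seed`.
#' @return A \linkS4class{BOLDRun}.
#' @export
simulateRun <- function(design, rois, signal = signalConfig(),
                        noise = noiseConfig(), seed = 1L,
                        subject_id = "sub-01", amp_common = 1,
                        amplitudes = NULL) {
  stopifnot(is(design, "RunDesign"), is(rois, "ROISet"),
            is(signal, "SignalConfig"), is(noise, "NoiseConfig"))
  if (is.null(amplitudes))
    amplitudes <- .voxelAmplitudes(rois, signal, seed,
                                   amp_common = amp_common)
  nt <- design@n_volumes
  idx_all <- unlist(rois@masks, use.names = FALSE)
  V <- length(idx_all)
  stopifnot(nrow(amplitudes) == V)

  kernel <- canonicalHRF(design@tr_s, design@events$duration_s[1])
  nk <- length(kernel)
  sig_pct <- matrix(0, nt, V)
  ev <- design@events
  cond <- paste(ev$task, ev$level, sep = ".")
  for (i in seq_len(nrow(ev))) {
    v0 <- floor(ev$onset_s[i] / design@tr_s) + 1L
    vols <- v0:(v0 + nk - 1L)
    sig_pct[vols, ] <- sig_pct[vols, ] +
      outer(kernel, amplitudes[, cond[i]])
  }

  noise_pct <- withSeed(deriveSeed(seed, 7L), {
    out <- matrix(0, nt, V)
    if (noise@white_sd > 0) {
      innov_sd <- noise@white_sd * sqrt(1 - noise@ar1_coeff^2)
      w <- matrix(rnorm(nt * V, sd = innov_sd), nt, V)
      out <- if (noise@ar1_coeff > 0)
        apply(w, 2, function(col)
          as.numeric(filter(col, noise@ar1_coeff, method = "recursive")))
      else w
    }
    if (noise@drift_amplitude > 0) {
      tt <- (seq_len(nt) - 1) * design@tr_s
      phase <- runif(V, 0, 2 * pi)
      period <- runif(V, 120, 240)
      out <- out + noise@drift_amplitude *
        sin(outer(tt, 2 * pi / period) + rep(phase, each = nt))
    }
    out
  })

  ts <- noise@baseline_level * (1 + (sig_pct + noise_pct) / 100)
  arr <- array(0, dim = c(rois@dim, nt))
  flat <- matrix(arr, prod(rois@dim), nt)
  flat[idx_all, ] <- t(ts)
  arr <- array(flat, dim = c(rois@dim, nt))
  new("BOLDRun", data = arr, tr_s = design@tr_s,
      subject_id = subject_id, run_index = design@run_index,
      seed = as.integer(seed))
}

#' Simulate the full four-run session of one subject
#'
#' Generates the session design, a subject-specific ROI annotation (the
#' tuned clusters displaced around their cohort-shared centres), a
#' subject-specific effect size (log-normal scaling of `delta` with
#' SD \code{signal@subject_delta_sd}), and the four BOLD runs with
#' voxel patterns held constant across runs.
#'
#' @param subject_id subject identifier.
#' @param seed per-subject seed.
#' @param rois cohort \linkS4class{ROISet} (template geometry).
#' @param signal a \linkS4class{SignalConfig}.
#' @param noise a \linkS4class{NoiseConfig}.
#' @param amp_common common response amplitude, percent signal change.
#' @return List with elements `design` (\linkS4class{ScanDesign}), `runs`
#'   (list of 4 \linkS4class{BOLDRun}), `rois` (subject-annotated
#'   \linkS4class{ROISet}) and `delta` (the subject's effect size).
#' @export
simulateSubject <- function(subject_id = "sub-01", seed = 1L,
                            rois = buildGeometry(), signal = signalConfig(),
                            noise = noiseConfig(), amp_common = 1) {
  stopifnot(is(rois, "ROISet"), is(signal, "SignalConfig"))
  design <- generateSessionDesign(subject_id, seed)
  # subject-specific tuned-cluster placement on the shared geometry
  rois_s <- rois
  if (signal@cluster_displacement_sd > 0 && length(rois@tuning)) {
    sizes <- vapply(rois@masks, length, integer(1))
    rois_s <- buildGeometry(signal = signal, scale = 1, roi_sizes = sizes,
                            voxel_size_mm = rois@voxel_size_mm,
                            displace_seed = deriveSeed(seed, 31L))
  }
  delta_s <- signal@delta *
    exp(withSeed(deriveSeed(seed, 59L), rnorm(1, 0, signal@subject_delta_sd)) -
          signal@subject_delta_sd^2 / 2)
  sig_s <- signal
  sig_s@delta <- delta_s
  amp <- .voxelAmplitudes(rois_s, sig_s, deriveSeed(seed, 83L),
                          amp_common = amp_common)
  runs <- lapply(1:4, function(r)
    simulateRun(sessionRun(design, r), rois_s, sig_s, noise,
                seed = deriveSeed(seed, 211L, r), subject_id = subject_id,
                amp_common = amp_common, amplitudes = amp))
  list(design = design, runs = runs, rois = rois_s, delta = delta_s)
}
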