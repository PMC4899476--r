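# Single-trial response estimation: a windowed GLM (one pre-response and
# five post-onset volumes) fitted per trial and voxel, and assembly of the
# labeled trials x voxels pattern matrices.

# 6-volume peristimulus window of a trial: the volume acquired at onset
# (pre-response; the kernel is zero there) plus the five following volumes.
.trialWindow <- function(onset_s, tr_s, n_volumes) {
  v0 <- floor(onset_s / tr_s) + 1L   # 1-based index of the onset volume
  vols <- v0:(v0 + 5L)
  if (vols[6L] > n_volumes)
    stop(sprintf("trial at onset %.1f s: window truncated by run end",
                 onset_s), call. = FALSE)
  vols
}

# voxels x time matrix of the mask voxels of one run
.maskTimeSeries <- function(run, voxels) {
  d <- dim(run@data)
  flat <- matrix(run@data, prod(d[1:3]), d[4])
  flat[voxels, , drop = FALSE]
}

#' Estimate per-voxel response amplitudes for one trial
#'
#' Within the trial's 6-volume window, fits by least squares a design of
#' [HRF-convolved 2 s event regressor, constant] to every voxel and scales
#' the event coefficient to percent signal change. With the default
#' \code{scale = "local"} the reference is the window's fitted constant
#' (the local baseline), which recovers embedded amplitudes exactly in the
#' noiseless limit; \code{scale = "run_mean"} divides by the voxel's
#' whole-run mean instead.
#'
#' @param run a \linkS4class{BOLDRun}.
#' @param onset_s trial onset in seconds.
#' @param voxels linear voxel indices (e.g. \code{roiMask(rois, name)}).
#' @param scale "local" or "run_mean".
#' @return Numeric vector of per-voxel betas (percent signal change).
#' @export
estimateTrialBeta <- function(run, onset_s, voxels,
                              scale = c("local", "run_mean")) {
  stopifnot(is(run, "BOLDRun"))
  scale <- match.arg(scale)
  ts <- .maskTimeSeries(run, voxels)
  .estimateBetas(ts, onset_s, run@tr_s, scale)[, 1L]
}

# core windowed GLM; ts is voxels x time, onsets a vector
.estimateBetas <- function(ts, onsets, tr_s, scale) {
  kernel <- as.numeric(canonicalHRF(tr_s, 2))
  X <- cbind(event = kernel, const = 1)
  P <- solve(crossprod(X), t(X))          # 2 x 6 projector
  n_volumes <- ncol(ts)
  run_mean <- rowMeans(ts)
  out <- matrix(NA_real_, nrow(ts), length(onsets))
  for (i in seq_along(onsets)) {
    vols <- .trialWindow(onsets[i], tr_s, n_volumes)
    B <- P %*% t(ts[, vols, drop = FALSE])  # 2 x voxels
    ref <- if (scale == "local") B[2L, ] else run_mean
    out[, i] <- ifelse(ref > 0, B[1L, ] / ref * 100, 0)
  }
  out
}

#' Assemble the labeled trial-pattern matrix for one ROI
#'
#' Estimates single-trial betas for every non-catch trial of the four runs
#' and stacks them into a voxels x trials
#' \linkS4class{TrialPatternSet} (a \linkS4class{SummarizedExperiment}
#' with a "beta" assay). Trials are ordered by (run, onset); catch trials
#' are excluded, so a default session yields 4 x 45 = 180 trials with 15
#' trials per level per run.
#'
#' @param runs list of four \linkS4class{BOLDRun}.
#' @param design the matching \linkS4class{ScanDesign}.
#' @param rois the \linkS4class{ROISet} the runs were simulated on.
#' @param roi_name which mask to extract.
#' @param scale beta normalization, see \code{\link{estimateTrialBeta}}.
#' @return A \linkS4class{TrialPatternSet}.
#' @export
buildPatternSet <- function(runs, design, rois, roi_name,
                            scale = c("local", "run_mean")) {
  scale <- match.arg(scale)
  stopifnot(is(design, "ScanDesign"), is(rois, "ROISet"))
  if (length(runs) != 4L)
    stop("four runs are required", call. = FALSE)
  voxels <- roiMask(rois, roi_name)
  beta_blocks <- vector("list", 4L)
  label_blocks <- vector("list", 4L)
  for (r in 1:4) {
    run <- runs[[r]]
    if (!is(run, "BOLDRun"))
      stop(sprintf("run %d is missing or not a BOLDRun", r), call. = FALSE)
    rd <- sessionRun(design, r)
    if (run@run_index != rd@run_index)
      stop(sprintf("run %d does not match its design", r), call. = FALSE)
    ev <- rd@events[!rd@events$is_catch, ]
    ev <- ev[order(ev$onset_s), ]
    ts <- .maskTimeSeries(run, voxels)
    beta_blocks[[r]] <- .estimateBetas(ts, ev$onset_s, rd@tr_s, scale)
    label_blocks[[r]] <- data.frame(
      task = ev$task, level = ev$level, object = ev$object,
      run_index = rd@run_index, onset_s = ev$onset_s)
  }
  beta <- do.call(cbind, beta_blocks)
  labels <- do.call(rbind, label_blocks)
  rownames(beta) <- paste0("vox", voxels)
  colnames(beta) <- sprintf("trial%03d", seq_len(ncol(beta)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    colData = S4Vectors::DataFrame(labels, row.names = colnames(beta)))
  S4Vectors::metadata(se) <- list(roi_name = roi_name,
                                  subject_id = design@subject_id,
                                  scale = scale, voxels = voxels)
  new("TrialPatternSet", se)
}
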