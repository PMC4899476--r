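# Constructors and accessors.

#' @rdname SignalConfig-class
#' @param delta,frac_vitality_voxels,frac_velocity_voxels,level_delta
#'   see the class slots.
#' @param pattern_jitter_sd,cluster_displacement_sd,subject_delta_sd
#'   see the class slots.
#' @param task_mean_offset see the class slots.
#' @return `signalConfig()` returns a validated SignalConfig.
#' @export
#' @examples
#' signalConfig(delta = 0)   # a signal-free (null) configuration
signalConfig <- function(delta = 0.60,
                         frac_vitality_voxels = 0.12,
                         frac_velocity_voxels = 0.01,
                         level_delta = 0,
                         pattern_jitter_sd = 0.3,
                         cluster_displacement_sd = 0.05,
                         subject_delta_sd = 0.25,
                         task_mean_offset = 0) {
  new("SignalConfig", delta = delta,
      frac_vitality_voxels = frac_vitality_voxels,
      frac_velocity_voxels = frac_velocity_voxels,
      level_delta = level_delta, pattern_jitter_sd = pattern_jitter_sd,
      cluster_displacement_sd = cluster_displacement_sd,
      subject_delta_sd = subject_delta_sd,
      task_mean_offset = task_mean_offset)
}

#' @rdname NoiseConfig-class
#' @param white_sd,ar1_coeff,drift_amplitude,baseline_level see the class
#'   slots.
#' @return `noiseConfig()` returns a validated NoiseConfig.
#' @export
#' @examples
#' noiseConfig(white_sd = 0)   # noise-free, for round-trip checks
noiseConfig <- function(white_sd = 1.6, ar1_coeff = 0.3,
                        drift_amplitude = 0.5, baseline_level = 100) {
  new("NoiseConfig", white_sd = white_sd, ar1_coeff = ar1_coeff,
      drift_amplitude = drift_amplitude, baseline_level = baseline_level)
}

#' @rdname ROISet-class
#' @param x a ROISet
#' @param name mask name
#' @return `roiMask()` returns the linear voxel indices of one mask;
#'   `roiNames()` the mask names; `roiTuning()` the tuning annotation of an
#'   insular mask.
#' @export
roiMask <- function(x, name) {
  stopifnot(is(x, "ROISet"))
  if (!name %in% names(x@masks))
    stop(sprintf("unknown ROI '%s'", name), call. = FALSE)
  x@masks[[name]]
}

#' @rdname ROISet-class
#' @export
roiNames <- function(x) names(x@masks)

#' @rdname ROISet-class
#' @export
roiTuning <- function(x, name) {
  stopifnot(is(x, "ROISet"))
  if (!name %in% names(x@tuning))
    stop(sprintf("no tuning annotation for ROI '%s'", name), call. = FALSE)
  x@tuning[[name]]
}

#' @rdname RunDesign-class
#' @param x a RunDesign (or ScanDesign for `sessionEvents`)
#' @return `runEvents()` returns the event table of a run.
#' @export
runEvents <- function(x) {
  stopifnot(is(x, "RunDesign"))
  x@events
}

#' @rdname ScanDesign-class
#' @param x a ScanDesign
#' @param run run index 1..4
#' @return `sessionRun()` extracts one RunDesign.
#' @export
sessionRun <- function(x, run) {
  stopifnot(is(x, "ScanDesign"), run %in% 1:4)
  x@runs[[run]]
}

#' @rdname TrialPatternSet-class
#' @param x a TrialPatternSet
#' @return `betaValues()` returns the voxels x trials beta matrix;
#'   `trialLabels()` the per-trial label data.frame.
#' @export
betaValues <- function(x) {
  stopifnot(is(x, "TrialPatternSet"))
  SummarizedExperiment::assay(x, "beta")
}

#' @rdname TrialPatternSet-class
#' @export
trialLabels <- function(x) {
  stopifnot(is(x, "TrialPatternSet"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @rdname DecodingResult-class
#' @param x a DecodingResult
#' @return `meanAccuracy()` the fold-averaged accuracy; `foldAccuracies()`
#'   the four per-fold accuracies; `chanceEstimate()` the permutation-null
#'   mean; `nullAccuracies()` the permutation null distribution;
#'   `foldWeights()` the voxels x folds signed weight matrix.
#' @export
meanAccuracy <- function(x) { stopifnot(is(x, "DecodingResult")); x@mean_accuracy }

#' @rdname DecodingResult-class
#' @export
foldAccuracies <- function(x) { stopifnot(is(x, "DecodingResult")); x@fold_accuracies }

#' @rdname DecodingResult-class
#' @export
chanceEstimate <- function(x) { stopifnot(is(x, "DecodingResult")); x@chance_estimate }

#' @rdname DecodingResult-class
#' @export
nullAccuracies <- function(x) { stopifnot(is(x, "DecodingResult")); x@null_accuracies }

#' @rdname DecodingResult-class
#' @export
foldWeights <- function(x) { stopifnot(is(x, "DecodingResult")); x@weights }

#' @rdname GroupOverlapMap-class
#' @param x a GroupOverlapMap
#' @return `overlapCounts()` returns a data.frame with per-voxel positive,
#'   negative and total overlap counts (and p-values / FDR mask when
#'   present); `fdrMask()` the logical FDR-survival mask.
#' @export
overlapCounts <- function(x) {
  stopifnot(is(x, "GroupOverlapMap"))
  out <- data.frame(
    voxel = seq_along(x@overlap_pos),
    overlap_pos = x@overlap_pos,
    overlap_neg = x@overlap_neg,
    overlap_total = x@overlap_pos + x@overlap_neg
  )
  if (length(x@p_value)) out$p_value <- x@p_value
  if (length(x@fdr_mask)) out$fdr_mask <- x@fdr_mask
  out
}

#' @rdname GroupOverlapMap-class
#' @export
fdrMask <- function(x) { stopifnot(is(x, "GroupOverlapMap")); x@fdr_mask }

#' @rdname DTWDistanceMatrix-class
#' @param x a DTWDistanceMatrix
#' @return `dtwDistances()` returns the distance matrix with
#'   "object.level" dimnames; `dtwLabels()` the label data.frame.
#' @export
dtwDistances <- function(x) {
  stopifnot(is(x, "DTWDistanceMatrix"))
  d <- x@distances
  lab <- paste(x@objects, x@levels, sep = ".")
  dimnames(d) <- list(lab, lab)
  d
}

#' @rdname DTWDistanceMatrix-class
#' @export
dtwLabels <- function(x) {
  stopifnot(is(x, "DTWDistanceMatrix"))
  data.frame(object = x@objects, level = x@levels)
}

#' @rdname VelocityTrajectory-class
#' @param x a VelocityTrajectory
#' @param mode velocity channel: "modulus" (speed), "vx", "vy" or "vz"
#' @return `trajectoryChannel()` returns the requested 1-D series;
#'   `trajectorySamples()` the full n x 3 sample matrix.
#' @export
trajectoryChannel <- function(x, mode = c("modulus", "vx", "vy", "vz")) {
  stopifnot(is(x, "VelocityTrajectory"))
  mode <- match.arg(mode)
  s <- x@samples
  switch(mode,
         modulus = sqrt(rowSums(s^2)),
         vx = s[, 1], vy = s[, 2], vz = s[, 3])
}

#' @rdname VelocityTrajectory-class
#' @export
trajectorySamples <- function(x) { stopifnot(is(x, "VelocityTrajectory")); x@samples }
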