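#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats coef convolve dgamma filter lm p.adjust pbinom predict
#'   psignrank pt quantile rnorm runif sd t.test var
#' @importFrom utils head read.delim write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Kinematics

#' VelocityTrajectory: a sampled 3-D velocity time series for one stimulus
#'
#' Holds the (vx, vy, vz) samples of one reaching action at a fixed sampling
#' rate (default 100 Hz), together with its execution time, the object moved
#' and the duration level (1--12) it instantiates.
#'
#' @slot samples numeric matrix, one row per sample, columns vx, vy, vz (m/s).
#' @slot rate_hz sampling rate in Hz.
#' @slot exec_time_ms execution time in milliseconds.
#' @slot object_label one of "bottle", "can", "jar".
#' @slot duration_level integer duration level in 1..12.
#' @export
setClass("VelocityTrajectory",
  representation(
    samples = "matrix",
    rate_hz = "numeric",
    exec_time_ms = "integer",
    object_label = "character",
    duration_level = "integer"
  )
)

setValidity("VelocityTrajectory", function(object) {
  msg <- character()
  s <- object@samples
  if (!is.numeric(s) || ncol(s) != 3L || !all(is.finite(s)))
    msg <- c(msg, "'samples' must be a finite numeric matrix with 3 columns")
  n_expect <- round(object@exec_time_ms / 1000 * object@rate_hz)
  if (nrow(s) != n_expect)
    msg <- c(msg, sprintf("sample count %d != rate x duration = %d",
                          nrow(s), n_expect))
  if (!object@object_label %in% c("bottle", "can", "jar"))
    msg <- c(msg, "'object_label' must be bottle, can or jar")
  if (object@duration_level < 1L || object@duration_level > 12L)
    msg <- c(msg, "'duration_level' must be in 1..12")
  if (length(msg)) msg else TRUE
})

#' @describeIn VelocityTrajectory compact display
#' @param object a VelocityTrajectory
#' @export
setMethod("show", "VelocityTrajectory", function(object) {
  cat(sprintf("VelocityTrajectory: %s, level %d, %d ms (%d samples @ %g Hz)\n",
              object@object_label, object@duration_level,
              object@exec_time_ms, nrow(object@samples), object@rate_hz))
})

#' DTWDistanceMatrix: pairwise dynamic-time-warping distances among stimuli
#'
#' A symmetric, zero-diagonal matrix of DTW distances among the 36 action
#' stimuli (3 objects x 12 duration levels), with the channel the distances
#' were computed on recorded in `mode`.
#'
#' @slot distances numeric square matrix of non-negative distances.
#' @slot objects character vector of object labels, one per row.
#' @slot levels integer vector of duration levels, one per row.
#' @slot mode which velocity channel was compared: "modulus", "vx", "vy", "vz".
#' @export
setClass("DTWDistanceMatrix",
  representation(
    distances = "matrix",
    objects = "character",
    levels = "integer",
    mode = "character"
  )
)

setValidity("DTWDistanceMatrix", function(object) {
  d <- object@distances
  msg <- character()
  if (nrow(d) != ncol(d)) msg <- c(msg, "'distances' must be square")
  if (length(object@objects) != nrow(d) || length(object@levels) != nrow(d))
    msg <- c(msg, "label lengths must match matrix dimension")
  if (any(d < 0)) msg <- c(msg, "distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (max(abs(d - t(d))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
  if (!object@mode %in% c("modulus", "vx", "vy", "vz"))
    msg <- c(msg, "'mode' must be one of modulus, vx, vy, vz")
  if (length(msg)) msg else TRUE
})

#' @describeIn DTWDistanceMatrix compact display
#' @param object a DTWDistanceMatrix
#' @export
setMethod("show", "DTWDistanceMatrix", function(object) {
  cat(sprintf("DTWDistanceMatrix: %d x %d (%s channel)\n",
              nrow(object@distances), ncol(object@distances), object@mode))
})

# ---------------------------------------------------------------------------
# Paradigm

#' RunDesign: the event schedule of one functional run
#'
#' One run of the event-related paradigm: 45 experimental and 5 catch video
#' events of 2 s, separated by jittered 12--16 s fixation intervals, within
#' 416 volumes at TR 2 s. Runs 1--2 carry the vitality task, runs 3--4 the
#' velocity task.
#'
#' @slot run_index run number 1..4.
#' @slot task "vitality" or "velocity".
#' @slot events data.frame with columns onset_s, duration_s, task, level,
#'   object, is_catch, question_onset_s (NA for non-catch trials).
#' @slot tr_s repetition time (s).
#' @slot n_volumes volumes acquired per run.
#' @slot initial_fixation_s initial fixation duration (s).
#' @export
setClass("RunDesign",
  representation(
    run_index = "integer",
    task = "character",
    events = "data.frame",
    tr_s = "numeric",
    n_volumes = "integer",
    initial_fixation_s = "numeric"
  )
)

setValidity("RunDesign", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("onset_s", "duration_s", "task", "level", "object",
            "is_catch", "question_onset_s")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (!object@task %in% c("vitality", "velocity"))
    msg <- c(msg, "'task' must be vitality or velocity")
  expected_task <- if (object@run_index <= 2L) "vitality" else "velocity"
  if (object@task != expected_task)
    msg <- c(msg, "runs 1-2 must be vitality, runs 3-4 velocity")
  if (sum(!ev$is_catch) != 45L || sum(ev$is_catch) != 5L)
    msg <- c(msg, "a run must hold 45 experimental + 5 catch events")
  if (any(ev$duration_s != 2.0)) msg <- c(msg, "event duration must be 2 s")
  if (is.unsorted(ev$onset_s, strictly = TRUE))
    msg <- c(msg, "onsets must be strictly increasing")
  isi <- diff(ev$onset_s) - ev$duration_s[-nrow(ev)]
  if (length(isi) && (any(isi < 12 - 1e-9) || any(isi > 16 + 1e-9)))
    msg <- c(msg, "inter-trial intervals must lie in [12, 16] s")
  if (any(xor(ev$is_catch, !is.na(ev$question_onset_s))))
    msg <- c(msg, "question_onset_s must be present iff is_catch")
  # last trial's 6-volume window must exist within the run
  last_vol <- floor(max(ev$onset_s) / object@tr_s) + 5
  if (last_vol >= object@n_volumes)
    msg <- c(msg, "event schedule does not fit within the run")
  lev <- table(ev$level[!ev$is_catch])
  if (!all(lev == 15L))
    msg <- c(msg, "each level must appear 15 times among non-catch trials")
  if (length(msg)) msg else TRUE
})

#' @describeIn RunDesign compact display
#' @param object a RunDesign
#' @export
setMethod("show", "RunDesign", function(object) {
  cat(sprintf(
    "RunDesign: run %d (%s task), %d events, %d volumes @ TR %g s\n",
    object@run_index, object@task, nrow(object@events),
    object@n_volumes, object@tr_s))
})

#' ScanDesign: the full four-run session of one subject
#'
#' @slot subject_id subject identifier.
#' @slot runs list of 4 \linkS4class{RunDesign} (vitality, vitality,
#'   velocity, velocity).
#' @slot seed master seed the session was generated from.
#' @export
setClass("ScanDesign",
  representation(subject_id = "character", runs = "list", seed = "integer")
)

setValidity("ScanDesign", function(object) {
  if (length(object@runs) != 4L) return("a session has exactly 4 runs")
  if (!all(vapply(object@runs, is, logical(1), "RunDesign")))
    return("'runs' must hold RunDesign objects")
  tasks <- vapply(object@runs, function(r) r@task, character(1))
  if (!identical(tasks, c("vitality", "vitality", "velocity", "velocity")))
    return("run tasks must be vitality, vitality, velocity, velocity")
  TRUE
})

#' @describeIn ScanDesign compact display
#' @param object a ScanDesign
#' @export
setMethod("show", "ScanDesign", function(object) {
  cat(sprintf("ScanDesign: subject %s, 4 runs (seed %d)\n",
              object@subject_id, object@seed))
})

# ---------------------------------------------------------------------------
# BOLD simulation

#' ROISet: lattice geometry, ROI masks and voxel tuning annotation
#'
#' The voxel lattice with four disjoint region-of-interest masks (left
#' insula, right insula, a white-matter control and a BA21 control) and the
#' task-tuning annotation of insular voxels ("vitality_preferring",
#' "velocity_preferring" or "untuned"). Masks are stored as linear voxel
#' indices into the lattice.
#'
#' @slot dim integer lattice dimensions (x, y, z).
#' @slot voxel_size_mm isotropic voxel size in mm.
#' @slot masks named list of integer vectors of linear voxel indices.
#' @slot tuning named list (one element per insula mask) of character
#'   vectors parallel to the mask indices.
#' @slot cluster_info list recording planted cluster centres per mask.
#' @export
setClass("ROISet",
  representation(
    dim = "integer",
    voxel_size_mm = "numeric",
    masks = "list",
    tuning = "list",
    cluster_info = "list"
  )
)

setValidity("ROISet", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "'dim' must be three positive integers")
  all_idx <- unlist(object@masks, use.names = FALSE)
  if (length(all_idx) != length(unique(all_idx)))
    msg <- c(msg, "masks must be pairwise disjoint")
  if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > prod(object@dim)))
    msg <- c(msg, "mask indices must lie inside the lattice")
  for (nm in names(object@tuning)) {
    if (!nm %in% names(object@masks)) {
      msg <- c(msg, sprintf("tuning refers to unknown mask '%s'", nm))
      next
    }
    if (length(object@tuning[[nm]]) != length(object@masks[[nm]]))
      msg <- c(msg, sprintf("tuning for '%s' must match mask length", nm))
    bad <- setdiff(unique(object@tuning[[nm]]),
                   c("vitality_preferring", "velocity_preferring", "untuned"))
    if (length(bad)) msg <- c(msg, "unknown tuning label(s)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ROISet compact display
#' @param object a ROISet
#' @export
setMethod("show", "ROISet", function(object) {
  sizes <- vapply(object@masks, length, integer(1))
  cat(sprintf("ROISet: lattice %s, voxel %g mm\n",
              paste(object@dim, collapse = "x"), object@voxel_size_mm))
  for (nm in names(sizes)) cat(sprintf("  %s: %d voxels\n", nm, sizes[nm]))
})

#' SignalConfig: task-tuned multivoxel signal parameters
#'
#' Governs the pattern signal embedded in simulated insular voxels. Tuned
#' voxels respond `delta` percent-signal-change units more strongly in their
#' preferred task; the tuned deviations are demeaned within each insula mask
#' per task so the region-mean response is task-balanced (no univariate
#' effect). `level_delta = 0` (the default) leaves the three levels within a
#' task indistinguishable, reproducing chance-level within-task decoding.
#'
#' @slot delta task-contrast amplitude, percent signal change.
#' @slot frac_vitality_voxels fraction of insular voxels preferring vitality
#'   (clustered; the common population).
#' @slot frac_velocity_voxels fraction preferring velocity (the rare one).
#' @slot level_delta amplitude of level-specific patterns (default 0).
#' @slot pattern_jitter_sd SD of multiplicative jitter on tuned amplitudes.
#' @slot cluster_displacement_sd SD of the per-subject displacement of
#'   tuned clusters around their shared centre, as a fraction of the ROI
#'   radius (scale-free anatomical variability).
#' @slot subject_delta_sd SD of the per-subject log-normal scaling of delta.
#' @slot task_mean_offset global amplitude added to every insular voxel in
#'   vitality runs; 0 by default, positive values are the univariate
#'   positive control.
#' @export
setClass("SignalConfig",
  representation(
    delta = "numeric",
    frac_vitality_voxels = "numeric",
    frac_velocity_voxels = "numeric",
    level_delta = "numeric",
    pattern_jitter_sd = "numeric",
    cluster_displacement_sd = "numeric",
    subject_delta_sd = "numeric",
    task_mean_offset = "numeric"
  ),
  prototype(
    delta = 0.60,
    frac_vitality_voxels = 0.12,
    frac_velocity_voxels = 0.01,
    level_delta = 0,
    pattern_jitter_sd = 0.3,
    cluster_displacement_sd = 0.05,
    subject_delta_sd = 0.25,
    task_mean_offset = 0
  )
)

setValidity("SignalConfig", function(object) {
  msg <- character()
  if (object@delta < 0) msg <- c(msg, "'delta' must be >= 0")
  if (object@level_delta < 0) msg <- c(msg, "'level_delta' must be >= 0")
  f <- object@frac_vitality_voxels + object@frac_velocity_voxels
  if (object@frac_vitality_voxels < 0 || object@frac_velocity_voxels < 0 ||
      f > 1)
    msg <- c(msg, "tuning fractions must be >= 0 and sum to <= 1")
  if (object@pattern_jitter_sd < 0 || object@cluster_displacement_sd < 0 ||
      object@subject_delta_sd < 0)
    msg <- c(msg, "jitter/displacement SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' NoiseConfig: additive noise model of the simulated BOLD signal
#'
#' White Gaussian noise with an AR(1) temporal kernel plus a slow sinusoidal
#' drift, riding on a constant baseline. All amplitudes are in percent of
#' baseline.
#'
#' @slot white_sd innovation SD (percent signal).
#' @slot ar1_coeff AR(1) coefficient in [0, 1).
#' @slot drift_amplitude amplitude of the slow drift (percent signal).
#' @slot baseline_level raw baseline intensity.
#' @export
setClass("NoiseConfig",
  representation(
    white_sd = "numeric",
    ar1_coeff = "numeric",
    drift_amplitude = "numeric",
    baseline_level = "numeric"
  ),
  prototype(white_sd = 1.6, ar1_coeff = 0.3, drift_amplitude = 0.5,
            baseline_level = 100)
)

setValidity("NoiseConfig", function(object) {
  msg <- character()
  if (object@white_sd < 0) msg <- c(msg, "'white_sd' must be >= 0")
  if (object@ar1_coeff < 0 || object@ar1_coeff >= 1)
    msg <- c(msg, "'ar1_coeff' must be in [0, 1)")
  if (object@drift_amplitude < 0)
    msg <- c(msg, "'drift_amplitude' must be >= 0")
  if (!is.finite(object@baseline_level) || object@baseline_level <= 0)
    msg <- c(msg, "'baseline_level' must be positive")
  if (length(msg)) msg else TRUE
})

#' BOLDRun: one simulated 4-D functional run
#'
#' @slot data 4-D numeric array (x, y, z, t); t = 416 volumes by default.
#' @slot tr_s repetition time (s).
#' @slot subject_id subject identifier.
#' @slot run_index run number 1..4.
#' @slot seed RNG seed the run was generated from.
#' @export
setClass("BOLDRun",
  representation(
    data = "array",
    tr_s = "numeric",
    subject_id = "character",
    run_index = "integer",
    seed = "integer"
  )
)

setValidity("BOLDRun", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "'data' must be a 4-D array")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "'data' must be finite")
  if (object@tr_s <= 0) msg <- c(msg, "'tr_s' must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn BOLDRun compact display
#' @param object a BOLDRun
#' @export
setMethod("show", "BOLDRun", function(object) {
  d <- dim(object@data)
  cat(sprintf("BOLDRun: subject %s run %d, %s lattice x %d volumes @ TR %g s\n",
              object@subject_id, object@run_index,
              paste(d[1:3], collapse = "x"), d[4], object@tr_s))
})

# ---------------------------------------------------------------------------
# Trial patterns (SummarizedExperiment-backed)

#' TrialPatternSet: per-trial multivoxel response patterns for one ROI
#'
#' Extends \linkS4class{SummarizedExperiment}: the "beta" assay holds the
#' voxels x trials matrix of single-trial response amplitudes (percent
#' signal change); `colData` carries the per-trial labels (task, level,
#' object, run_index); metadata records the ROI and subject. Catch trials
#' are excluded, so a default session yields 4 runs x 45 trials = 180
#' columns.
#'
#' @export
setClass("TrialPatternSet", contains = "SummarizedExperiment")

setValidity("TrialPatternSet", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("must contain a 'beta' assay")
  cd <- SummarizedExperiment::colData(object)
  need <- c("task", "level", "object", "run_index")
  if (!all(need %in% names(cd)))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  if (!all(is.finite(SummarizedExperiment::assay(object, "beta"))))
    msg <- c(msg, "beta values must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrialPatternSet compact display
#' @param object a TrialPatternSet
#' @export
setMethod("show", "TrialPatternSet", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("TrialPatternSet: %s / %s, %d voxels x %d trials\n",
              md$subject_id %||% "?", md$roi_name %||% "?",
              nrow(object), ncol(object)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Decoding

#' DecodingResult: cross-validated decoding of one contrast in one ROI
#'
#' @slot subject_id subject identifier.
#' @slot roi_name ROI the patterns came from.
#' @slot contrast contrast name, e.g. "rude_vs_fast".
#' @slot fold_accuracies accuracy of each of the four alternate-run folds.
#' @slot mean_accuracy unweighted mean of the fold accuracies.
#' @slot weights voxels x folds matrix of signed linear-SVM weights
#'   (positive = evidence for the first class, the vitality side in
#'   cross-task contrasts).
#' @slot null_accuracies permutation null accuracies (possibly empty).
#' @slot chance_estimate mean of the null accuracies (NA when no null).
#' @export
setClass("DecodingResult",
  representation(
    subject_id = "character",
    roi_name = "character",
    contrast = "character",
    fold_accuracies = "numeric",
    mean_accuracy = "numeric",
    weights = "matrix",
    null_accuracies = "numeric",
    chance_estimate = "numeric"
  )
)

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (length(object@fold_accuracies) != 4L)
    msg <- c(msg, "exactly four fold accuracies expected")
  if (any(object@fold_accuracies < 0 | object@fold_accuracies > 1))
    msg <- c(msg, "fold accuracies must lie in [0, 1]")
  if (abs(object@mean_accuracy - mean(object@fold_accuracies)) > 1e-12)
    msg <- c(msg, "mean_accuracy must equal the mean of fold_accuracies")
  if (ncol(object@weights) != 4L)
    msg <- c(msg, "weights must have one column per fold")
  if (length(msg)) msg else TRUE
})

#' @describeIn DecodingResult compact display
#' @param object a DecodingResult
#' @export
setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %s / %s / %s\n", object@subject_id,
              object@roi_name, object@contrast))
  cat(sprintf("  mean accuracy %.3f (folds: %s)\n", object@mean_accuracy,
              paste(sprintf("%.3f", object@fold_accuracies), collapse = " ")))
  if (length(object@null_accuracies))
    cat(sprintf("  permutation chance %.3f (%d permutations)\n",
                object@chance_estimate, length(object@null_accuracies)))
})

# ---------------------------------------------------------------------------
# Group maps

#' SubjectDiscriminativeMap: ranked signed voxel weights for one subject
#'
#' @slot subject_id subject identifier.
#' @slot roi_name ROI name.
#' @slot weight fold- and contrast-averaged signed weight per voxel.
#' @slot rank rank of each voxel by decreasing absolute weight (1 = most
#'   discriminative; ties broken by voxel id).
#' @slot selected logical; TRUE for the top-fraction voxels (all FALSE
#'   before selection).
#' @slot fraction the selection fraction applied (NA before selection).
#' @export
setClass("SubjectDiscriminativeMap",
  representation(
    subject_id = "character",
    roi_name = "character",
    weight = "numeric",
    rank = "integer",
    selected = "logical",
    fraction = "numeric"
  )
)

setValidity("SubjectDiscriminativeMap", function(object) {
  msg <- character()
  v <- length(object@weight)
  if (length(object@rank) != v || length(object@selected) != v)
    msg <- c(msg, "weight, rank and selected must have equal length")
  if (v && !identical(sort(object@rank), seq_len(v)))
    msg <- c(msg, "ranks must be a permutation of 1..V")
  if (!is.na(object@fraction) &&
      sum(object@selected) != round(object@fraction * v))
    msg <- c(msg, "selected count must equal round(fraction x V)")
  if (length(msg)) msg else TRUE
})

#' GroupOverlapMap: signed subject-overlap counts with null p-values
#'
#' Per voxel, the number of subjects whose individual discriminative maps
#' select it with positive (vitality-preferring) or negative
#' (velocity-preferring) sign, the tail probability of the total overlap
#' under the independence null, and the Benjamini-Hochberg FDR mask.
#'
#' @slot roi_name ROI name.
#' @slot overlap_pos integer per-voxel count of positive-sign selections.
#' @slot overlap_neg integer per-voxel count of negative-sign selections.
#' @slot n_subjects number of subjects entering the map.
#' @slot fraction selection fraction used for the individual maps.
#' @slot p_value per-voxel overlap tail probability (empty before testing).
#' @slot fdr_mask logical per-voxel FDR survival (empty before testing).
#' @slot q FDR level.
#' @slot null_method "binomial" or "monte_carlo".
#' @export
setClass("GroupOverlapMap",
  representation(
    roi_name = "character",
    overlap_pos = "integer",
    overlap_neg = "integer",
    n_subjects = "integer",
    fraction = "numeric",
    p_value = "numeric",
    fdr_mask = "logical",
    q = "numeric",
    null_method = "character"
  ),
  prototype(p_value = numeric(0), fdr_mask = logical(0), q = 0.05,
            null_method = "binomial")
)

setValidity("GroupOverlapMap", function(object) {
  msg <- character()
  if (length(object@overlap_pos) != length(object@overlap_neg))
    msg <- c(msg, "overlap count vectors must have equal length")
  tot <- object@overlap_pos + object@overlap_neg
  if (any(object@overlap_pos < 0L) || any(object@overlap_neg < 0L) ||
      any(tot > object@n_subjects))
    msg <- c(msg, "overlap counts must lie in 0..n_subjects")
  if (length(object@p_value) &&
      (length(object@p_value) != length(tot) ||
       any(object@p_value <= 0 | object@p_value > 1)))
    msg <- c(msg, "p-values must lie in (0, 1] and match voxel count")
  if (length(msg)) msg else TRUE
})

#' @describeIn GroupOverlapMap compact display
#' @param object a GroupOverlapMap
#' @export
setMethod("show", "GroupOverlapMap", function(object) {
  cat(sprintf("GroupOverlapMap: %s, %d voxels, f = %g, S = %d\n",
              object@roi_name, length(object@overlap_pos), object@fraction,
              object@n_subjects))
  if (length(object@fdr_mask))
    cat(sprintf("  FDR (q = %g, %s null): %d surviving voxels\n",
                object@q, object@null_method, sum(object@fdr_mask)))
})
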