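# Readers and writers for on-disk artifacts: NIfTI volumes and masks,
# BIDS-style event tables, trajectory CSVs and pattern-set matrices.

#' Write / read a simulated run or mask as NIfTI-1
#'
#' Volumes are written with an RAS+ affine scaled by the voxel size, so the
#' data array, dimensions and voxel size round-trip losslessly.
#'
#' @param run a \linkS4class{BOLDRun} (or plain array for masks).
#' @param path output file, conventionally ".nii" or ".nii.gz".
#' @param voxel_size_mm isotropic voxel size recorded in the header.
#' @return `writeVolume` returns `path` invisibly; `readVolume` the data
#'   array with a "voxel_size_mm" attribute.
#' @export
writeVolume <- function(run, path, voxel_size_mm = 2.5) {
  tr <- if (is(run, "BOLDRun")) run@tr_s else 1
  arr <- if (is(run, "BOLDRun")) run@data else run
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(rep(voxel_size_mm, 3), rep(tr, nd - 3))[1:nd]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, call. = FALSE))
  arr <- as.array(img)
  attr(arr, "voxel_size_mm") <- RNifti::pixdim(img)[1]
  arr
}

#' Write an ROI mask volume
#'
#' Encodes a mask (linear voxel indices on the lattice) as a binary NIfTI
#' volume.
#'
#' @param rois a \linkS4class{ROISet}.
#' @param name mask name.
#' @param path output file.
#' @export
writeMask <- function(rois, name, path) {
  stopifnot(is(rois, "ROISet"))
  arr <- array(0L, dim = rois@dim)
  arr[roiMask(rois, name)] <- 1L
  writeVolume(arr, path, rois@voxel_size_mm)
}

#' Write / read run events as a BIDS-style tab-separated table
#'
#' Columns: onset, duration, trial_type (task.level or "catch"), task,
#' level, object, is_catch.
#'
#' @param design a \linkS4class{RunDesign}.
#' @param path output .tsv file.
#' @export
writeEventsTSV <- function(design, path) {
  stopifnot(is(design, "RunDesign"))
  ev <- design@events
  out <- data.frame(
    onset = ev$onset_s, duration = ev$duration_s,
    trial_type = ifelse(ev$is_catch, "catch",
                        paste(ev$task, ev$level, sep = ".")),
    task = ev$task, level = ev$level, object = ev$object,
    is_catch = tolower(ev$is_catch))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTSV
#' @export
readEventsTSV <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("not an events table (need onset/duration/trial_type): ", path,
         call. = FALSE)
  ev$is_catch <- ev$is_catch == "true"
  ev
}

#' Write a trajectory as CSV with a JSON label sidecar
#'
#' @param traj a \linkS4class{VelocityTrajectory}.
#' @param path output .csv (columns t_s, vx, vy, vz); labels go to the
#'   matching .json sidecar.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  stopifnot(is(traj, "VelocityTrajectory"))
  n <- nrow(traj@samples)
  df <- data.frame(t_s = (seq_len(n) - 0.5) / traj@rate_hz, traj@samples)
  write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(object_label = traj@object_label,
                            duration_level = traj@duration_level,
                            exec_time_ms = traj@exec_time_ms,
                            rate_hz = traj@rate_hz),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  new("VelocityTrajectory",
      samples = as.matrix(df[, c("vx", "vy", "vz")]),
      rate_hz = meta$rate_hz, exec_time_ms = as.integer(meta$exec_time_ms),
      object_label = meta$object_label,
      duration_level = as.integer(meta$duration_level))
}

#' Write a DTW distance matrix as labeled CSV
#'
#' @param m a \linkS4class{DTWDistanceMatrix}.
#' @param path output .csv with "object.level" header row and column.
#' @export
writeDTWMatrixCSV <- function(m, path) {
  stopifnot(is(m, "DTWDistanceMatrix"))
  write.csv(dtwDistances(m), path)
  invisible(path)
}

#' Write / read a trial-pattern set as a matrix + labels CSV pair
#'
#' @param patterns a \linkS4class{TrialPatternSet}.
#' @param prefix file prefix; writes `<prefix>_beta.csv` (voxels x trials)
#'   and `<prefix>_labels.csv`.
#' @export
writePatternSet <- function(patterns, prefix) {
  stopifnot(is(patterns, "TrialPatternSet"))
  write.csv(betaValues(patterns), paste0(prefix, "_beta.csv"))
  write.csv(trialLabels(patterns), paste0(prefix, "_labels.csv"),
            row.names = FALSE)
  invisible(prefix)
}

#' @rdname writePatternSet
#' @param roi_name,subject_id metadata restored on read.
#' @export
readPatternSet <- function(prefix, roi_name = "roi", subject_id = "sub") {
  beta <- as.matrix(read.csv(paste0(prefix, "_beta.csv"), row.names = 1))
  labels <- read.csv(paste0(prefix, "_labels.csv"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    colData = S4Vectors::DataFrame(labels, row.names = colnames(beta)))
  S4Vectors::metadata(se) <- list(roi_name = roi_name,
                                  subject_id = subject_id)
  new("TrialPatternSet", se)
}
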