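# End-to-end cohort pipeline: simulate -> single-trial betas -> decoding
# -> group maps -> group statistics.

#' Pipeline configuration
#'
#' Bundles every tunable of the cohort analysis with the study's design
#' constants as defaults: 16 subjects, TR 2 s, 416 volumes, 45 + 5 trials
#' per run, 1000 permutations, selection fraction 0.5, q = 0.05,
#' alpha = 0.05. `scale` shrinks the ROI voxel counts for
#' reduced-resolution cohorts (1 = the full published sizes).
#'
#' @param n_subjects cohort size.
#' @param seed master seed; every stage derives its streams from it.
#' @param scale geometry scale factor on ROI voxel counts.
#' @param signal a \linkS4class{SignalConfig}.
#' @param noise a \linkS4class{NoiseConfig}.
#' @param svm_cost linear SVM cost.
#' @param n_perm permutations per subject-contrast for the chance level
#'   (0 skips the permutation stage; group tests then use nominal 0.5).
#' @param alpha group-test significance level.
#' @param f group-map selection fraction (0.5 or 0.35).
#' @param q FDR level.
#' @param null_method overlap null: "binomial" or "monte_carlo".
#' @param n_iter Monte Carlo iterations for the overlap null.
#' @param rois ROIs to decode; default all four masks.
#' @param contrasts contrast list; default the three cross-task plus the
#'   six within-task contrasts.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return A list of class "mvpa_config".
#' @export
pipelineConfig <- function(n_subjects = 16L, seed = 1L, scale = 1,
                           signal = signalConfig(), noise = noiseConfig(),
                           svm_cost = 1, n_perm = 0L, alpha = 0.05,
                           f = 0.5, q = 0.05,
                           null_method = c("binomial", "monte_carlo"),
                           n_iter = 10000L, rois = NULL, contrasts = NULL,
                           out_dir = NULL) {
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    scale = scale, signal = signal, noise = noise, svm_cost = svm_cost,
    n_perm = as.integer(n_perm), alpha = alpha, f = f, q = q,
    null_method = match.arg(null_method), n_iter = as.integer(n_iter),
    rois = rois, contrasts = contrasts, out_dir = out_dir),
    class = "mvpa_config")
}

#' Run the full cohort analysis
#'
#' Simulates `n_subjects` sessions, estimates single-trial betas per ROI,
#' decodes every contrast with the alternate-run cross-validation scheme,
#' runs the univariate ROI control, tests cohort accuracies against chance
#' with the exact Wilcoxon signed-rank test, and builds FDR-thresholded
#' group discriminative maps for the insular ROIs (collapsing the three
#' cross-task contrasts). Fully deterministic given the configuration.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose print stage progress with seeds and wall time.
#' @return List with `accuracies` (tidy data.frame: subject, roi,
#'   contrast, contrast_type, fold, accuracy), `mean_accuracies`,
#'   `wilcoxon`, `univariate`, `group_maps` (per insular ROI),
#'   `rois_template` (the cohort geometry with the shared planted
#'   clusters) and `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "mvpa_config"))
  t0 <- Sys.time()
  say <- function(fmt, ...) if (verbose)
    message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, "secs")),
            sprintf(fmt, ...))
  rois_template <- buildGeometry(signal = config$signal,
                                 scale = config$scale)
  roi_names <- config$rois %||% roiNames(rois_template)
  contrasts <- config$contrasts %||%
    c(crossTaskContrasts(), withinTaskContrasts())
  cross_names <- vapply(crossTaskContrasts(), `[[`, character(1), "name")

  acc_rows <- list()
  insula_results <- list()   # per subject: cross-task results per insula
  uni_rows <- list()
  say("cohort: %d subjects, scale %g, seed %d (delta = %g)",
      config$n_subjects, config$scale, config$seed, config$signal@delta)

  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("sub-%02d", s)
    subj <- simulateSubject(sid, seed = deriveSeed(config$seed, 1009L, s),
                            rois = rois_template, signal = config$signal,
                            noise = config$noise)
    tasks <- vapply(subj$runs, function(r)
      if (r@run_index <= 2L) "vitality" else "velocity", character(1))
    subj_cross <- list()
    for (nm in roi_names) {
      pat <- buildPatternSet(subj$runs, subj$design, subj$rois, nm)
      vox <- roiMask(subj$rois, nm)
      m <- vapply(subj$runs, function(r)
        mean(.maskTimeSeries(r, vox)), numeric(1))
      uni_rows[[length(uni_rows) + 1L]] <- data.frame(
        subject_id = sid, roi = nm,
        vitality_mean = mean(m[tasks == "vitality"]),
        velocity_mean = mean(m[tasks == "velocity"]))
      for (ct in contrasts) {
        res <- decodeContrast(pat, ct, svm_cost = config$svm_cost,
                              n_perm = config$n_perm,
                              seed = deriveSeed(config$seed, 4001L, s,
                                                match(ct$name, vapply(
                                                  contrasts, `[[`,
                                                  character(1), "name"))))
        type <- if (ct$name %in% cross_names) "cross_task" else "within_task"
        acc_rows[[length(acc_rows) + 1L]] <- data.frame(
          subject_id = sid, roi = nm, contrast = ct$name,
          contrast_type = type, fold = 1:4,
          accuracy = foldAccuracies(res),
          chance = chanceEstimate(res))
        if (type == "cross_task" &&
            nm %in% c("left_insula", "right_insula"))
          subj_cross[[nm]] <- c(subj_cross[[nm]], list(res))
      }
    }
    insula_results[[s]] <- subj_cross
    say("subject %s done", sid)
  }

  accuracies <- do.call(rbind, acc_rows)
  mean_acc <- stats::aggregate(accuracy ~ subject_id + roi + contrast +
                                 contrast_type, accuracies, mean)

  wil_rows <- list()
  for (key in split(mean_acc,
                    list(mean_acc$roi, mean_acc$contrast), drop = TRUE)) {
    ch <- 0.5
    w <- tryCatch(wilcoxonGroup(key$accuracy, chance = ch),
                  error = function(e) list(statistic = NA, p_value = NA))
    wil_rows[[length(wil_rows) + 1L]] <- data.frame(
      roi = key$roi[1], contrast = key$contrast[1],
      contrast_type = key$contrast_type[1],
      mean_accuracy = mean(key$accuracy), chance = ch,
      statistic = w$statistic, p_value = w$p_value)
  }
  wilcoxon <- do.call(rbind, wil_rows)
  rownames(wilcoxon) <- NULL

  univariate <- univariateROICheck(do.call(rbind, uni_rows))
  say("decoding + group statistics done")

  group_maps <- list()
  for (nm in intersect(c("left_insula", "right_insula"), roi_names)) {
    per_subject <- lapply(insula_results, `[[`, nm)
    group_maps[[nm]] <- buildGroupMap(
      per_subject, f = config$f, q = config$q,
      null = config$null_method, n_iter = config$n_iter,
      seed = deriveSeed(config$seed, 7001L, match(nm, roi_names)))
  }
  say("group maps done")

  out <- list(accuracies = accuracies, mean_accuracies = mean_acc,
              wilcoxon = wilcoxon, univariate = univariate,
              group_maps = group_maps, rois_template = rois_template,
              config = config)
  if (!is.null(config$out_dir)) .writePipelineOutputs(out, config$out_dir)
  out
}

# CSV/JSON artifact tree with provenance
.writePipelineOutputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(out$accuracies, file.path(dir, "accuracies.csv"),
            row.names = FALSE)
  write.csv(out$mean_accuracies, file.path(dir, "mean_accuracies.csv"),
            row.names = FALSE)
  write.csv(out$wilcoxon, file.path(dir, "wilcoxon.csv"), row.names = FALSE)
  write.csv(out$univariate, file.path(dir, "univariate.csv"),
            row.names = FALSE)
  for (nm in names(out$group_maps))
    write.csv(overlapCounts(out$group_maps[[nm]]),
              file.path(dir, sprintf("group_map_%s.csv", nm)),
              row.names = FALSE)
  cfg <- out$config
  prov <- list(
    seed = cfg$seed, n_subjects = cfg$n_subjects, scale = cfg$scale,
    delta = cfg$signal@delta, level_delta = cfg$signal@level_delta,
    white_sd = cfg$noise@white_sd, svm_cost = cfg$svm_cost,
    n_perm = cfg$n_perm, f = cfg$f, q = cfg$q,
    null_method = cfg$null_method,
    package_version = as.character(utils::packageVersion("insulaMVPA")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
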