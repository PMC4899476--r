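# Event-related scan design: four runs (2 vitality, 2 velocity), 45
# experimental + 5 catch trials per run, 2 s events, jittered 12-16 s
# fixation intervals, 416 volumes at TR 2 s.

#' Generate the event schedule of one functional run
#'
#' Builds one run of the paradigm: after 12 s of initial fixation, 50 video
#' events of 2 s (45 experimental, 5 catch) separated by jittered fixation
#' intervals of 12, 14 or 16 s. The 45 experimental trials cover each
#' (object x level) cell exactly 5 times (15 trials per level); event order
#' and the catch-trial slots are randomized per seed. Jitter durations form
#' a balanced multiset of \{12, 14, 16\} s permuted per seed, which keeps
#' the schedule inside the 416-volume run for every seed. Catch trials
#' carry a task question cued 500 ms after video offset.
#'
#' @param run_index run number 1..4.
#' @param task "vitality" (runs 1-2) or "velocity" (runs 3-4); inferred
#'   from `run_index` when NULL; a mismatch is an error.
#' @param seed RNG seed.
#' @return A \linkS4class{RunDesign}.
#' @export
#' @examples
#' rd <- generateRunDesign(1, seed = 7)
#' table(runEvents(rd)$level[!runEvents(rd)$is_catch])   # 15 per level
generateRunDesign <- function(run_index, task = NULL, seed = 1L) {
  pc <- paradigmConstants()
  run_index <- as.integer(run_index)
  if (!run_index %in% 1:4) stop("'run_index' must be 1..4", call. = FALSE)
  expected <- pc$run_tasks[run_index]
  if (is.null(task)) task <- expected
  if (!identical(task, expected))
    stop(sprintf("run %d carries the %s task, not '%s'",
                 run_index, expected, task), call. = FALSE)

  n <- pc$n_trials
  cells <- expand.grid(object = pc$objects, level = pc$levels,
                       stringsAsFactors = FALSE)
  out <- withSeed(seed, {
    # balanced jitter multiset: 49 gaps, counts of 12/14/16 as equal as
    # possible (the odd one out is 14 s, preserving the 14 s mean)
    n_gap <- n - 1L
    base <- n_gap %/% 3L
    isi_pool <- c(rep(pc$isi_choices_s[1], base),
                  rep(pc$isi_choices_s[2], n_gap - 2L * base),
                  rep(pc$isi_choices_s[3], base))
    isi <- sample(isi_pool)
    onsets <- pc$initial_fixation_s +
      c(0, cumsum(isi + pc$event_duration_s))
    catch_slots <- sort(sample.int(n, pc$n_catch))
    # 45 experimental trials: each cell 5x, in random order
    exp_cells <- cells[sample(rep(seq_len(nrow(cells)), 5L)), ]
    catch_cells <- cells[sample.int(nrow(cells), pc$n_catch,
                                    replace = TRUE), ]
    list(isi = isi, onsets = onsets, catch_slots = catch_slots,
         exp_cells = exp_cells, catch_cells = catch_cells)
  })

  is_catch <- seq_len(n) %in% out$catch_slots
  object <- character(n); level <- integer(n)
  object[!is_catch] <- out$exp_cells$object
  level[!is_catch] <- out$exp_cells$level
  object[is_catch] <- out$catch_cells$object
  level[is_catch] <- out$catch_cells$level
  events <- data.frame(
    onset_s = out$onsets,
    duration_s = pc$event_duration_s,
    task = task,
    level = level,
    object = object,
    is_catch = is_catch,
    question_onset_s = ifelse(
      is_catch,
      out$onsets + pc$event_duration_s + pc$question_delay_s, NA_real_)
  )
  new("RunDesign", run_index = run_index, task = task, events = events,
      tr_s = pc$tr_s, n_volumes = pc$n_volumes,
      initial_fixation_s = pc$initial_fixation_s)
}

#' Generate the full four-run session design of one subject
#'
#' Two vitality runs followed by two velocity runs (the vitality task always
#' precedes the velocity task), each randomized independently from a
#' per-run seed derived from the session seed.
#'
#' @param subject_id subject identifier string.
#' @param seed session seed.
#' @return A \linkS4class{ScanDesign}.
#' @export
#' @examples
#' sd <- generateSessionDesign("sub-01", seed = 11)
#' vapply(sd@runs, function(r) r@task, character(1))
generateSessionDesign <- function(subject_id = "sub-01", seed = 1L) {
  runs <- lapply(1:4, function(r)
    generateRunDesign(r, seed = deriveSeed(seed, 101L, r)))
  new("ScanDesign", subject_id = as.character(subject_id), runs = runs,
      seed = as.integer(seed))
}
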