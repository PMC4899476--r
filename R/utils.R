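# Internal helpers shared across modules.

# Derive a stream-specific RNG seed from a master seed. Keeps results
# reproducible while decoupling the random streams of subjects, runs and
# analysis stages. Result always fits a 32-bit signed integer.
deriveSeed <- function(seed, ...) {
  offs <- c(...)
  stopifnot(length(seed) == 1L, is.finite(seed))
  x <- as.double(seed) %% 2147483647
  for (o in offs) {
    x <- (x * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(TRUE)
}

#' Timing and design constants of the scan paradigm
#'
#' Returns the fixed constants of the event-related design emulated by the
#' package: repetition time 2 s, 416 volumes per run, 12 s initial fixation,
#' 2 s video events, jittered 12--16 s inter-stimulus intervals, 45
#' experimental plus 5 catch trials per run, 15 trials per level, four runs
#' (two vitality, then two velocity) and 16 subjects per cohort.
#'
#' @return A named list of constants.
#' @export
#' @examples
#' paradigmConstants()$n_volumes
paradigmConstants <- function() {
  list(
    tr_s = 2.0,
    n_volumes = 416L,
    initial_fixation_s = 12,
    event_duration_s = 2.0,
    isi_choices_s = c(12, 14, 16),
    n_experimental = 45L,
    n_catch = 5L,
    n_trials = 50L,
    trials_per_level = 15L,
    question_delay_s = 0.5,
    question_duration_s = 2.5,
    run_tasks = c("vitality", "vitality", "velocity", "velocity"),
    levels = 1:3,
    objects = c("bottle", "can", "jar"),
    n_subjects = 16L
  )
}
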