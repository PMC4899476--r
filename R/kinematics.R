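# Kinematic stimulus analysis: synthetic reaching velocity profiles,
# dynamic time warping among the 36 stimuli, and the logarithmic
# judgment model.

#' The twelve execution times of the behavioral stimulus set
#'
#' @return Integer vector of execution times in ms (500 to 1600 in 100 ms
#'   steps), one per duration level.
#' @export
executionTimes <- function() as.integer(seq(500L, 1600L, by = 100L))

#' Path length of the reaching action at a given execution time
#'
#' Quadratic (Lagrange) interpolation through the three calibrated stimuli,
#' whose path lengths are mean velocity times execution time:
#' 1.06 m/s x 0.6 s = 0.636 m, 0.57 x 1.0 = 0.570 m, 0.38 x 1.4 = 0.532 m.
#'
#' @param exec_time_ms execution time in milliseconds.
#' @return Path length in metres.
#' @export
#' @examples
#' stimulusPathLength(1000)   # 0.57 m, i.e. mean velocity 0.57 m/s
stimulusPathLength <- function(exec_time_ms) {
  .assertScalarNumber(exec_time_ms, "exec_time_ms", positive = TRUE)
  T <- exec_time_ms / 1000
  x <- c(0.6, 1.0, 1.4)
  y <- c(0.636, 0.570, 0.532)
  sum(vapply(1:3, function(k) {
    o <- setdiff(1:3, k)
    y[k] * prod(T - x[o]) / prod(x[k] - x[o])
  }, numeric(1)))
}

# Minimum-jerk speed profile on tau in [0, 1]; integrates to 1/30.
.minJerkShape <- function(tau) tau^2 - 2 * tau^3 + tau^4

#' Generate a bell-shaped (minimum-jerk) reaching velocity trajectory
#'
#' Produces the 3-D velocity samples of one synthetic reaching action: a
#' minimum-jerk speed profile whose time integral equals the requested path
#' length, decomposed into (vx, vy, vz) along a gently arched transport
#' path, sampled at `rate_hz` (100 Hz by default, midpoint sampling so the
#' discrete mean speed matches path_length / exec_time). A small seeded,
#' smooth perturbation differentiates objects while leaving the overall
#' bell shape intact.
#'
#' @param exec_time_ms execution time in ms, within [500, 1600].
#' @param path_length_m path length in metres; defaults to
#'   \code{stimulusPathLength(exec_time_ms)}.
#' @param seed RNG seed for the object-specific perturbation.
#' @param object_label object moved: "bottle", "can" or "jar".
#' @param duration_level duration level 1..12; by default inferred from the
#'   nearest canonical execution time.
#' @param rate_hz sampling rate in Hz.
#' @param perturbation_sd relative amplitude of the seeded smooth
#'   perturbation (fraction of peak speed).
#' @return A \linkS4class{VelocityTrajectory}.
#' @export
#' @examples
#' tr <- generateVelocityProfile(1000, seed = 1)
#' mean(trajectoryChannel(tr, "modulus"))   # ~0.57 m/s
generateVelocityProfile <- function(exec_time_ms,
                                    path_length_m = stimulusPathLength(exec_time_ms),
                                    seed = 1L,
                                    object_label = "bottle",
                                    duration_level = NULL,
                                    rate_hz = 100,
                                    perturbation_sd = 0.02) {
  .assertScalarNumber(exec_time_ms, "exec_time_ms", positive = TRUE)
  .assertScalarNumber(path_length_m, "path_length_m", positive = TRUE)
  if (exec_time_ms < 500 || exec_time_ms > 1600)
    stop("'exec_time_ms' must lie in [500, 1600]", call. = FALSE)
  if (is.null(duration_level))
    duration_level <- which.min(abs(executionTimes() - exec_time_ms))
  T <- exec_time_ms / 1000
  n <- round(exec_time_ms / 1000 * rate_hz)
  tau <- (seq_len(n) - 0.5) / n
  speed <- 30 * path_length_m / T * .minJerkShape(tau)
  if (perturbation_sd > 0) {
    coefs <- withSeed(deriveSeed(seed, match(object_label,
                                             c("bottle", "can", "jar")),
                                 duration_level),
                      rnorm(3))
    # smooth, endpoint-vanishing modulation; keeps speed non-negative
    mod <- perturbation_sd * (coefs[1] * sin(2 * pi * tau) +
                              coefs[2] * sin(3 * pi * tau) +
                              coefs[3] * sin(4 * pi * tau))
    speed <- speed * pmax(1 + mod, 0)
  }
  # transport mostly along x with a vertical arc and slight lateral sway
  elev <- 0.30 * sin(pi * tau)
  azim <- 0.08 * sin(2 * pi * tau)
  samples <- cbind(
    vx = speed * cos(elev) * cos(azim),
    vy = speed * cos(elev) * sin(azim),
    vz = speed * sin(elev)
  )
  new("VelocityTrajectory", samples = samples, rate_hz = rate_hz,
      exec_time_ms = as.integer(round(exec_time_ms)),
      object_label = object_label,
      duration_level = as.integer(duration_level))
}

#' Generate the complete 36-stimulus trajectory set
#'
#' One trajectory per (object, duration level) cell: 3 objects x 12
#' execution times from 500 to 1600 ms.
#'
#' @param seed RNG seed.
#' @param perturbation_sd passed to \code{\link{generateVelocityProfile}}.
#' @return List of 36 \linkS4class{VelocityTrajectory}, object-major order.
#' @export
generateStimulusSet <- function(seed = 1L, perturbation_sd = 0.02) {
  objects <- c("bottle", "can", "jar")
  times <- executionTimes()
  out <- vector("list", 36L)
  k <- 0L
  for (obj in objects) {
    for (lev in seq_along(times)) {
      k <- k + 1L
      out[[k]] <- generateVelocityProfile(
        times[lev], seed = seed, object_label = obj, duration_level = lev,
        perturbation_sd = perturbation_sd)
    }
  }
  out
}

#' Dynamic time warping distance between two 1-D series
#'
#' Classic dynamic-programming DTW with local cost |a_i - b_j|, boundary
#' D(1,1) = cost(1,1) and recursion over insertion, deletion and match
#' steps; returns the unnormalized terminal cumulative cost. With
#' \code{normalize = TRUE} the cost is divided by the sum of the two series
#' lengths (a common normalization for series of unequal duration; the
#' default is unnormalized).
#'
#' @param a,b non-empty finite numeric vectors.
#' @param normalize divide the terminal cost by length(a) + length(b)?
#' @return Non-negative scalar distance.
#' @export
#' @examples
#' dtwDistance(c(0, 1, 2), c(0, 2))
dtwDistance <- function(a, b, normalize = FALSE) {
  if (length(a) == 0L || length(b) == 0L)
    stop("series must be non-empty", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("series must be finite", call. = FALSE)
  n <- length(a); m <- length(b)
  # row-wise DP; the in-row recursion D[j] = c_j + min(E_j, D[j-1]) is
  # unrolled to a cummin over prefix sums so each row is vectorized
  cost1 <- abs(a[1] - b)
  D <- cumsum(cost1)
  if (n > 1L) {
    for (i in 2:n) {
      ci <- abs(a[i] - b)
      E <- pmin(D, c(Inf, D[-m]))      # min(D[i-1, j], D[i-1, j-1])
      S <- cumsum(ci)
      D <- S + cummin(E - c(0, S[-m]))
    }
  }
  d <- D[m]
  if (normalize) d <- d / (n + m)
  d
}

#' Pairwise DTW distance matrix over the 36 stimulus trajectories
#'
#' Applies \code{\link{dtwDistance}} to the selected velocity channel
#' (the speed modulus by default, or a single component) of every pair of
#' trajectories.
#'
#' @param trajs list of exactly 36 \linkS4class{VelocityTrajectory}, one per
#'   (object, duration level) combination.
#' @param mode channel to compare: "modulus", "vx", "vy" or "vz".
#' @param normalize passed to \code{\link{dtwDistance}}.
#' @return A \linkS4class{DTWDistanceMatrix}.
#' @export
pairwiseDTWMatrix <- function(trajs, mode = c("modulus", "vx", "vy", "vz"),
                              normalize = FALSE) {
  mode <- match.arg(mode)
  if (length(trajs) != 36L)
    stop("exactly 36 trajectories are required (3 objects x 12 levels)",
         call. = FALSE)
  if (!all(vapply(trajs, is, logical(1), "VelocityTrajectory")))
    stop("'trajs' must hold VelocityTrajectory objects", call. = FALSE)
  objects <- vapply(trajs, function(t) t@object_label, character(1))
  levels <- vapply(trajs, function(t) t@duration_level, integer(1))
  key <- paste(objects, levels)
  if (anyDuplicated(key))
    stop("duplicate (object, duration_level) labels", call. = FALSE)
  series <- lapply(trajs, trajectoryChannel, mode = mode)
  d <- matrix(0, 36L, 36L)
  for (i in 1:35) {
    for (j in (i + 1):36) {
      d[i, j] <- d[j, i] <- dtwDistance(series[[i]], series[[j]],
                                        normalize = normalize)
    }
  }
  new("DTWDistanceMatrix", distances = d, objects = objects,
      levels = levels, mode = mode)
}

#' Within- versus between-duration distance structure of a DTW matrix
#'
#' Tests whether stimuli sharing a duration level are mutually closer than
#' stimuli of different duration levels: the basis for pooling the three
#' objects into one average profile per execution time.
#'
#' @param m a \linkS4class{DTWDistanceMatrix}.
#' @return List with `within_mean` (mean distance over same-level pairs),
#'   `between_mean` (over different-level pairs) and `within_less`
#'   (TRUE iff within < between).
#' @export
durationGroupingCheck <- function(m) {
  stopifnot(is(m, "DTWDistanceMatrix"))
  d <- m@distances
  same <- outer(m@levels, m@levels, "==")
  ut <- upper.tri(d)
  list(
    within_mean = mean(d[ut & same]),
    between_mean = mean(d[ut & !same]),
    within_less = mean(d[ut & same]) < mean(d[ut & !same])
  )
}

# ---------------------------------------------------------------------------
# Behavioral judgments

#' Simulate vitality/velocity judgment scores across execution times
#'
#' Each subject scores each of the twelve execution times once per task.
#' The noiseless score follows a clipped logarithmic curve
#' clip(a_task + b_task * ln(exec_time_ms), 1, 5); Gaussian noise is added
#' and the result clipped back to the 1--5 scale. Defaults place the
#' velocity-task curve slightly above the vitality-task curve, matching the
#' reported group means (velocity 2.83 vs vitality 2.66) with a common
#' negative slope (longer execution = slower/gentler = lower score).
#'
#' @param a_task named numeric, intercepts for "vitality" and "velocity".
#' @param b_task named numeric, ln-time slopes for the two tasks.
#' @param noise_sd judgment noise SD (score units).
#' @param n_subjects number of simulated subjects.
#' @param seed RNG seed.
#' @return data.frame with columns subject_id, task, exec_time_ms, score.
#' @export
simulateJudgments <- function(a_task = c(vitality = 20.47, velocity = 20.64),
                              b_task = c(vitality = -2.58, velocity = -2.58),
                              noise_sd = 0.4, n_subjects = 18L, seed = 1L) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1", call. = FALSE)
  times <- executionTimes()
  grid <- expand.grid(subject_id = sprintf("sub-%02d", seq_len(n_subjects)),
                      task = c("vitality", "velocity"),
                      exec_time_ms = times, stringsAsFactors = FALSE)
  mu <- pmin(pmax(a_task[grid$task] + b_task[grid$task] *
                    log(grid$exec_time_ms), 1), 5)
  noise <- withSeed(seed, rnorm(nrow(grid), sd = noise_sd))
  grid$score <- pmin(pmax(as.numeric(mu) + noise, 1), 5)
  grid[order(grid$subject_id, grid$task, grid$exec_time_ms), ]
}

#' Fit the logarithmic judgment curve for one task
#'
#' Ordinary least squares of the mean score (over subjects) on the natural
#' log of execution time, the regression summarized in the behavioral study
#' (reported fits: R^2 = 0.94 for vitality, 0.87 for velocity).
#'
#' @param judgments data.frame as returned by
#'   \code{\link{simulateJudgments}}.
#' @param task "vitality" or "velocity".
#' @return List with `intercept`, `slope`, `r_squared` and the fitted `lm`.
#' @export
fitLogJudgment <- function(judgments, task = c("vitality", "velocity")) {
  task <- match.arg(task)
  stopifnot(is.data.frame(judgments),
            all(c("task", "exec_time_ms", "score") %in% names(judgments)))
  j <- judgments[judgments$task == task, ]
  if (length(unique(j$exec_time_ms)) < 2L)
    stop("need at least two distinct execution times", call. = FALSE)
  means <- tapply(j$score, j$exec_time_ms, mean)
  df <- data.frame(log_t = log(as.numeric(names(means))),
                   score = as.numeric(means))
  fit <- lm(score ~ log_t, data = df)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r_squared = summary(fit)$r.squared, fit = fit)
}
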