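# Linear SVM decoding with the alternate-run cross-validation scheme,
# permutation chance level, exact Wilcoxon signed-rank group inference and
# the univariate ROI control.

#' The four alternate-run cross-validation folds
#'
#' Because the two tasks live in separate runs (vitality: 1, 2; velocity:
#' 3, 4), training and testing sets each combine one run per task:
#' (1,3 | 2,4), (2,4 | 1,3), (2,3 | 1,4) and (1,4 | 2,3).
#'
#' @return List of four folds, each a list with integer vectors `train`
#'   and `test`.
#' @export
#' @examples
#' makeCVFolds()[[1]]
makeCVFolds <- function() {
  list(
    list(train = c(1L, 3L), test = c(2L, 4L)),
    list(train = c(2L, 4L), test = c(1L, 3L)),
    list(train = c(2L, 3L), test = c(1L, 4L)),
    list(train = c(1L, 4L), test = c(2L, 3L))
  )
}

#' Define a two-class decoding contrast
#'
#' @param a_task,a_level the (task, level) selector of the first class
#'   (the vitality side for cross-task contrasts; its evidence carries
#'   positive SVM weight).
#' @param b_task,b_level the second class.
#' @param name contrast label; derived from the selectors when NULL.
#' @return A list of class "mvpa_contrast".
#' @export
#' @examples
#' makeContrast("vitality", 1, "velocity", 1, "rude_vs_fast")
makeContrast <- function(a_task, a_level, b_task, b_level, name = NULL) {
  stopifnot(a_task %in% c("vitality", "velocity"),
            b_task %in% c("vitality", "velocity"),
            a_level %in% 1:3, b_level %in% 1:3)
  if (is.null(name))
    name <- sprintf("%s%d_vs_%s%d", a_task, a_level, b_task, b_level)
  structure(list(name = name,
                 class_a = list(task = a_task, level = as.integer(a_level)),
                 class_b = list(task = b_task, level = as.integer(b_level))),
            class = "mvpa_contrast")
}

#' Standard contrast sets
#'
#' `crossTaskContrasts()` returns the three same-level task contrasts
#' (rude vs fast, neutral vs medium, gentle vs slow);
#' `withinTaskContrasts()` the six level pairs within each task.
#'
#' @return List of contrasts (see \code{\link{makeContrast}}).
#' @export
crossTaskContrasts <- function() {
  list(makeContrast("vitality", 1, "velocity", 1, "rude_vs_fast"),
       makeContrast("vitality", 2, "velocity", 2, "neutral_vs_medium"),
       makeContrast("vitality", 3, "velocity", 3, "gentle_vs_slow"))
}

#' @rdname crossTaskContrasts
#' @export
withinTaskContrasts <- function() {
  vit <- c("rude", "neutral", "gentle")
  vel <- c("fast", "medium", "slow")
  out <- list()
  for (task in c("vitality", "velocity")) {
    lab <- if (task == "vitality") vit else vel
    for (i in 1:2) for (j in (i + 1):3)
      out[[length(out) + 1L]] <- makeContrast(
        task, i, task, j, sprintf("%s_vs_%s", lab[i], lab[j]))
  }
  out
}

# per-fold standardized train/test matrices and labels for one contrast;
# computed once and reused across permutations
.foldData <- function(patterns, contrast, cv) {
  lab <- trialLabels(patterns)
  X <- t(betaValues(patterns))           # trials x voxels
  in_a <- lab$task == contrast$class_a$task &
    lab$level == contrast$class_a$level
  in_b <- lab$task == contrast$class_b$task &
    lab$level == contrast$class_b$level
  lapply(cv, function(fold) {
    tr <- (in_a | in_b) & lab$run_index %in% fold$train
    te <- (in_a | in_b) & lab$run_index %in% fold$test
    y_tr <- factor(ifelse(in_a[tr], "a", "b"), levels = c("a", "b"))
    y_te <- factor(ifelse(in_a[te], "a", "b"), levels = c("a", "b"))
    if (length(unique(table(y_tr))) != 1L || nlevels(droplevels(y_tr)) != 2L)
      stop("unbalanced training classes in fold; the design is balanced",
           call. = FALSE)
    if (length(unique(table(y_te))) != 1L)
      stop("unbalanced test classes in fold", call. = FALSE)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    sdv[sdv < 1e-12] <- 1
    list(
      x_train = sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/"),
      x_test = sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/"),
      y_train = y_tr, y_test = y_te
    )
  })
}

# fit a linear SVM and return test accuracy (+ weights if asked)
.svmFoldAccuracy <- function(fd, y_train, svm_cost, want_weights = FALSE) {
  fit <- e1071::svm(fd$x_train, y_train, kernel = "linear",
                    cost = svm_cost, scale = FALSE)
  pred <- predict(fit, fd$x_test)
  acc <- mean(pred == fd$y_test)
  if (!want_weights) return(list(accuracy = acc))
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  # libsvm orients decision values toward the first training label seen;
  # flip so positive weight always means evidence for class "a"
  if (fit$labels[1L] != 1L) w <- -w
  list(accuracy = acc, weights = w)
}

#' Decode one contrast with alternate-run cross-validation
#'
#' Per fold, features are z-scored with training-set statistics, a linear
#' soft-margin SVM (cost fixed, default 1) is trained on the 15 + 15
#' training trials and evaluated on the held-out runs; the per-fold signed
#' weight vectors are retained (positive = evidence for the first class).
#' With \code{n_perm > 0} the permutation chance level is appended (see
#' \code{\link{permutationNull}}).
#'
#' @param patterns a \linkS4class{TrialPatternSet}.
#' @param contrast a contrast from \code{\link{makeContrast}}.
#' @param cv fold list from \code{\link{makeCVFolds}}.
#' @param svm_cost soft-margin cost parameter.
#' @param n_perm number of label permutations for the chance estimate
#'   (0 = skip).
#' @param seed RNG seed for the permutations.
#' @return A \linkS4class{DecodingResult}.
#' @export
decodeContrast <- function(patterns, contrast, cv = makeCVFolds(),
                           svm_cost = 1, n_perm = 0L, seed = 1L) {
  stopifnot(is(patterns, "TrialPatternSet"),
            inherits(contrast, "mvpa_contrast"))
  fds <- .foldData(patterns, contrast, cv)
  V <- nrow(betaValues(patterns))
  acc <- numeric(4L)
  W <- matrix(NA_real_, V, 4L)
  for (k in seq_along(fds)) {
    r <- .svmFoldAccuracy(fds[[k]], fds[[k]]$y_train, svm_cost,
                          want_weights = TRUE)
    acc[k] <- r$accuracy
    W[, k] <- r$weights
  }
  rownames(W) <- rownames(betaValues(patterns))
  md <- S4Vectors::metadata(patterns)
  res <- new("DecodingResult",
             subject_id = md$subject_id %||% "?",
             roi_name = md$roi_name %||% "?",
             contrast = contrast$name,
             fold_accuracies = acc, mean_accuracy = mean(acc),
             weights = W, null_accuracies = numeric(0),
             chance_estimate = NA_real_)
  if (n_perm > 0L) {
    null <- permutationNull(patterns, contrast, cv, n_perm = n_perm,
                            seed = seed, svm_cost = svm_cost,
                            .fold_data = fds)
    res@null_accuracies <- null$null_accuracies
    res@chance_estimate <- null$chance_estimate
  }
  res
}

#' Permutation null distribution of the decoding accuracy
#'
#' For each permutation the class labels of the training trials are
#' shuffled within each fold's pooled training set, the SVM is retrained,
#' and accuracy is evaluated against the intact test labels; the four fold
#' accuracies are averaged, yielding one null accuracy per permutation.
#' The chance estimate is the mean of the null distribution (expected
#' ~50\% for this balanced design).
#'
#' @inheritParams decodeContrast
#' @param n_perm number of permutations (>= 1).
#' @param .fold_data internal: precomputed fold data.
#' @return List with `null_accuracies` (length `n_perm`) and
#'   `chance_estimate`.
#' @export
permutationNull <- function(patterns, contrast, cv = makeCVFolds(),
                            n_perm = 1000L, seed = 1L, svm_cost = 1,
                            .fold_data = NULL) {
  if (n_perm < 1L) stop("'n_perm' must be >= 1", call. = FALSE)
  fds <- .fold_data %||% .foldData(patterns, contrast, cv)
  null_acc <- withSeed(seed, {
    vapply(seq_len(n_perm), function(p) {
      mean(vapply(fds, function(fd) {
        y_perm <- sample(fd$y_train)
        .svmFoldAccuracy(fd, y_perm, svm_cost)$accuracy
      }, numeric(1)))
    }, numeric(1))
  })
  list(null_accuracies = null_acc, chance_estimate = mean(null_acc))
}

#' Empirical permutation p-value
#'
#' @param observed observed accuracy.
#' @param null_accuracies permutation null distribution.
#' @return (1 + #\{null >= observed\}) / (n_perm + 1), in (0, 1].
#' @export
permutationP <- function(observed, null_accuracies) {
  (1 + sum(null_accuracies >= observed)) / (length(null_accuracies) + 1)
}

#' Exact one-sided Wilcoxon signed-rank group test
#'
#' Tests whether per-subject accuracies exceed the chance level using the
#' exact signed-rank distribution: zero differences are discarded (the
#' classic convention), absolute differences are mid-ranked, and the exact
#' null distribution of the positive-rank sum is built by convolution over
#' the (possibly tied) ranks -- valid for the n = 16 cohort and exact under
#' ties, where \code{stats::wilcox.test} falls back to a normal
#' approximation.
#'
#' @param accuracies per-subject accuracies (e.g. 16 values).
#' @param chance the chance level to test against (default 0.5).
#' @return List with `statistic` (positive-rank sum W+), `p_value`
#'   (one-sided, alternative: accuracies > chance) and `n_used` (non-zero
#'   differences).
#' @export
#' @examples
#' wilcoxonGroup(seq(0.51, 0.66, by = 0.01))$p_value   # 1 / 2^16
wilcoxonGroup <- function(accuracies, chance = 0.5) {
  d <- accuracies - chance
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero; the signed-rank test is undefined",
         call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  # exact null via generating function over doubled ranks (midranks are
  # multiples of 0.5, so doubling makes them integers)
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  probs <- numeric(total + 1L)     # index i-1 = statistic value
  probs[1L] <- 1
  for (rr in r2) {
    shifted <- c(rep(0, rr), probs[seq_len(total + 1L - rr)])
    probs <- (probs + shifted) / 2
  }
  W2 <- as.integer(round(2 * W))
  p <- sum(probs[(W2 + 1L):(total + 1L)])
  list(statistic = W, p_value = p, n_used = n)
}

#' Univariate ROI control: task difference in mean signal
#'
#' Tests, per ROI, whether the mean BOLD signal differs between vitality
#' and velocity runs across subjects (paired t-test) -- the control showing
#' that decodable pattern differences are not explained by global amplitude
#' differences between tasks.
#'
#' @param x either a list of simulated subjects (each with elements `runs`
#'   and `rois`, as returned by \code{\link{simulateSubject}}) or a
#'   data.frame with columns subject_id, roi, vitality_mean, velocity_mean.
#' @param roi_names ROIs to test (list input only); defaults to all masks.
#' @return data.frame with columns roi, mean_diff, t, df, p_value.
#' @export
univariateROICheck <- function(x, roi_names = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("subject_id", "roi", "vitality_mean", "velocity_mean")
                  %in% names(x)))
    tab <- x
  } else {
    if (length(x) < 2L)
      stop("at least two subjects are required", call. = FALSE)
    if (is.null(roi_names)) roi_names <- roiNames(x[[1]]$rois)
    rows <- list()
    for (s in seq_along(x)) {
      subj <- x[[s]]
      tasks <- vapply(subj$runs, function(r)
        if (r@run_index <= 2L) "vitality" else "velocity", character(1))
      for (nm in roi_names) {
        vox <- roiMask(subj$rois, nm)
        m <- vapply(subj$runs, function(r)
          mean(.maskTimeSeries(r, vox)), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj$runs[[1]]@subject_id,
          roi = nm,
          vitality_mean = mean(m[tasks == "vitality"]),
          velocity_mean = mean(m[tasks == "velocity"]))
      }
    }
    tab <- do.call(rbind, rows)
  }
  out <- lapply(split(tab, tab$roi), function(g) {
    if (nrow(g) < 2L)
      stop("at least two subjects are required per ROI", call. = FALSE)
    tt <- t.test(g$vitality_mean, g$velocity_mean, paired = TRUE)
    data.frame(roi = g$roi[1],
               mean_diff = mean(g$vitality_mean - g$velocity_mean),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
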