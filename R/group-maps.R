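# Group discriminative maps: per-subject ranked weight maps, signed
# subject-overlap counts, the Monte Carlo / exact binomial independence
# null, and Benjamini-Hochberg FDR thresholding.

#' Rank a subject's voxels by discriminative contribution
#'
#' Averages the signed linear-SVM weights over folds and (optionally) over
#' several contrasts -- collapsing the three cross-task contrasts into one
#' map -- then ranks voxels by decreasing absolute weight (ties broken by
#' voxel order). Positive weight marks a vitality-preferring voxel,
#' negative a velocity-preferring one. `method = "rank_vote"` instead
#' ranks voxels within each contrast and averages the ranks.
#'
#' @param results a \linkS4class{DecodingResult} or list of them (same
#'   subject and ROI, e.g. the three cross-task contrasts).
#' @param method "mean_weight" (default) or "rank_vote".
#' @return A \linkS4class{SubjectDiscriminativeMap} (nothing selected yet).
#' @export
rankDiscriminativeVoxels <- function(results,
                                     method = c("mean_weight", "rank_vote")) {
  method <- match.arg(method)
  if (is(results, "DecodingResult")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, is, logical(1), "DecodingResult")))
  for (r in results)
    if (anyNA(r@weights))
      stop("missing fold weights in a DecodingResult", call. = FALSE)
  w_per <- lapply(results, function(r) rowMeans(r@weights))
  weight <- Reduce(`+`, w_per) / length(w_per)
  score <- if (method == "mean_weight") {
    abs(weight)
  } else {
    # average the per-contrast |weight| ranks (higher = more discriminative)
    rnk <- lapply(w_per, function(w) rank(abs(w), ties.method = "first"))
    Reduce(`+`, rnk) / length(rnk)
  }
  ord <- order(-score, seq_along(score))
  rk <- integer(length(score))
  rk[ord] <- seq_along(score)
  new("SubjectDiscriminativeMap",
      subject_id = results[[1]]@subject_id,
      roi_name = results[[1]]@roi_name,
      weight = weight, rank = rk,
      selected = rep(FALSE, length(weight)), fraction = NA_real_)
}

#' Select the top fraction of most discriminative voxels
#'
#' @param map a \linkS4class{SubjectDiscriminativeMap}.
#' @param f selection fraction in (0, 1]; the study used 0.5 and 0.35.
#' @return The map with exactly round(f x V) top-ranked voxels selected.
#' @export
selectTopFraction <- function(map, f = 0.5) {
  stopifnot(is(map, "SubjectDiscriminativeMap"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1)
    stop("'f' must lie in (0, 1]", call. = FALSE)
  n_sel <- round(f * length(map@weight))
  map@selected <- map@rank <= n_sel
  map@fraction <- f
  map
}

#' Signed group overlap of individual discriminative maps
#'
#' Counts, per voxel, how many subjects selected it with positive
#' (vitality-preferring) and negative (velocity-preferring) weight sign.
#'
#' @param maps list of selected \linkS4class{SubjectDiscriminativeMap}
#'   over the same voxel space.
#' @return A \linkS4class{GroupOverlapMap} (no p-values yet; see
#'   \code{\link{overlapPValues}}).
#' @export
groupOverlap <- function(maps) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, is, logical(1), "SubjectDiscriminativeMap")))
  V <- length(maps[[1]]@weight)
  fr <- maps[[1]]@fraction
  for (m in maps) {
    if (length(m@weight) != V)
      stop("maps must share one voxel space", call. = FALSE)
    if (is.na(m@fraction))
      stop("maps must be selected first (selectTopFraction)", call. = FALSE)
  }
  pos <- integer(V); neg <- integer(V)
  for (m in maps) {
    pos <- pos + as.integer(m@selected & m@weight >= 0)
    neg <- neg + as.integer(m@selected & m@weight < 0)
  }
  new("GroupOverlapMap", roi_name = maps[[1]]@roi_name,
      overlap_pos = pos, overlap_neg = neg,
      n_subjects = length(maps), fraction = fr)
}

#' Exact binomial overlap tail probability
#'
#' Under the independence null -- each subject selects a fraction f of
#' voxels uniformly at random, unrelated across subjects -- the overlap
#' count at a voxel is Binomial(S, f). Returns P(X >= k).
#'
#' @param k observed overlap count(s), 0..S.
#' @param S number of subjects.
#' @param f selection fraction.
#' @return Exact upper-tail probability, vectorized over `k`.
#' @export
#' @examples
#' binomialOverlapPvalue(10, 16, 0.5)   # 14893/65536 ~ 0.2272
binomialOverlapPvalue <- function(k, S = 16L, f = 0.5) {
  if (any(k < 0 | k > S)) stop("'k' must lie in 0..S", call. = FALSE)
  if (f <= 0 || f > 1) stop("'f' must lie in (0, 1]", call. = FALSE)
  pbinom(k - 1, size = S, prob = f, lower.tail = FALSE)
}

#' Monte Carlo overlap null under the independence assumption
#'
#' Each iteration draws, for every one of S subjects, round(f x V) voxels
#' uniformly without replacement and tabulates per-voxel overlap counts.
#' Tail probabilities are pooled over voxels (valid because voxels are
#' exchangeable under this null):
#' p(k) = (1 + #\{iteration-voxel pairs with overlap >= k\}) /
#' (n_iter x V + 1). The per-count tail converges to the exact
#' \code{\link{binomialOverlapPvalue}} as n_iter grows.
#'
#' @param V number of voxels.
#' @param S number of subjects.
#' @param f selection fraction in (0, 1].
#' @param n_iter Monte Carlo iterations (>= 1).
#' @param seed RNG seed.
#' @param max_statistic also record, per iteration, the maximum overlap
#'   over voxels, yielding a family-wise (max-statistic) null as the
#'   `max_tail` component.
#' @return List with `tail` (named vector, tail probability of each count
#'   0..S), `iter_fraction_sd` (SD over iterations of the per-iteration
#'   voxel fraction at each count, for Monte Carlo error assessment) and,
#'   when requested, `max_tail`.
#' @export
monteCarloOverlapNull <- function(V, S = 16L, f = 0.5, n_iter = 10000L,
                                  seed = 1L, max_statistic = FALSE) {
  if (f <= 0 || f > 1) stop("'f' must lie in (0, 1]", call. = FALSE)
  if (n_iter < 1L) stop("'n_iter' must be >= 1", call. = FALSE)
  m <- round(f * V)
  counts_ge <- matrix(0, n_iter, S + 1L)   # per iter, #voxels with >= k
  max_count <- integer(n_iter)
  withSeed(seed, {
    for (it in seq_len(n_iter)) {
      ov <- integer(V)
      for (s in seq_len(S)) {
        sel <- sample.int(V, m)
        ov[sel] <- ov[sel] + 1L
      }
      tb <- tabulate(ov + 1L, nbins = S + 1L)   # counts of overlap 0..S
      counts_ge[it, ] <- rev(cumsum(rev(tb)))
      if (max_statistic) max_count[it] <- max(ov)
    }
  })
  tail <- (1 + colSums(counts_ge)) / (as.double(n_iter) * V + 1)
  names(tail) <- 0:S
  frac <- counts_ge / V
  out <- list(tail = tail,
              iter_fraction_sd = apply(frac, 2, sd),
              n_iter = n_iter, V = V, S = S, f = f)
  if (max_statistic) {
    out$max_tail <- vapply(0:S, function(k)
      (1 + sum(max_count >= k)) / (n_iter + 1), numeric(1))
    names(out$max_tail) <- 0:S
  }
  out
}

#' Attach per-voxel overlap p-values to a group map
#'
#' @param map a \linkS4class{GroupOverlapMap}.
#' @param method "binomial" (exact closed form, default) or "monte_carlo".
#' @param n_iter,seed Monte Carlo settings (ignored for "binomial").
#' @param max_statistic use the Monte Carlo maximum-overlap null (a
#'   family-wise variant; only with method = "monte_carlo").
#' @return The map with `p_value` filled in.
#' @export
overlapPValues <- function(map, method = c("binomial", "monte_carlo"),
                           n_iter = 10000L, seed = 1L,
                           max_statistic = FALSE) {
  stopifnot(is(map, "GroupOverlapMap"))
  method <- match.arg(method)
  tot <- map@overlap_pos + map@overlap_neg
  if (method == "binomial") {
    map@p_value <- binomialOverlapPvalue(tot, map@n_subjects, map@fraction)
    map@null_method <- "binomial"
  } else {
    null <- monteCarloOverlapNull(length(tot), map@n_subjects,
                                  map@fraction, n_iter = n_iter,
                                  seed = seed,
                                  max_statistic = max_statistic)
    tail <- if (max_statistic) null$max_tail else null$tail
    map@p_value <- unname(tail[as.character(tot)])
    map@null_method <- if (max_statistic) "monte_carlo_max" else "monte_carlo"
  }
  map
}

#' Benjamini-Hochberg FDR thresholding of overlap p-values
#'
#' Applies the step-up procedure at level q to the per-voxel p-values and
#' reports the smallest overlap count among surviving voxels (the study's
#' headline threshold, "at least 10 of 16 participants").
#'
#' @param map a \linkS4class{GroupOverlapMap} with p-values (or a bare
#'   numeric vector of p-values).
#' @param q FDR level.
#' @return For a map: the map with `fdr_mask` and `q` filled, plus an
#'   attribute "min_surviving_overlap". For a numeric vector: a list with
#'   `mask` and `min_surviving_overlap = NA`.
#' @export
fdrThreshold <- function(map, q = 0.05) {
  if (is.numeric(map)) {
    if (!length(map)) stop("empty p-value vector", call. = FALSE)
    return(list(mask = p.adjust(map, "BH") <= q))
  }
  stopifnot(is(map, "GroupOverlapMap"))
  if (!length(map@p_value))
    stop("attach p-values first (overlapPValues)", call. = FALSE)
  mask <- p.adjust(map@p_value, "BH") <= q
  map@fdr_mask <- mask
  map@q <- q
  tot <- map@overlap_pos + map@overlap_neg
  attr(map, "min_surviving_overlap") <-
    if (any(mask)) min(tot[mask]) else NA_integer_
  map
}

#' Voxel signs of a group map
#'
#' The sign of a group voxel is the side with the larger overlap count:
#' +1 vitality-preferring, -1 velocity-preferring, 0 tied or unselected.
#'
#' @param map a \linkS4class{GroupOverlapMap}.
#' @return Integer vector of per-voxel signs.
#' @export
groupMapSigns <- function(map) {
  stopifnot(is(map, "GroupOverlapMap"))
  sign(map@overlap_pos - map@overlap_neg)
}

#' Build a thresholded group discriminative map for one ROI
#'
#' Convenience wrapper chaining \code{\link{rankDiscriminativeVoxels}}
#' (collapsing the supplied contrasts), \code{\link{selectTopFraction}},
#' \code{\link{groupOverlap}}, \code{\link{overlapPValues}} and
#' \code{\link{fdrThreshold}}.
#'
#' @param results_by_subject list (one element per subject) of lists of
#'   \linkS4class{DecodingResult} for the contrasts to collapse.
#' @param f selection fraction (0.5 or 0.35 in the study).
#' @param q FDR level.
#' @param null "binomial" or "monte_carlo".
#' @param n_iter,seed Monte Carlo settings.
#' @return A \linkS4class{GroupOverlapMap} with FDR mask.
#' @export
buildGroupMap <- function(results_by_subject, f = 0.5, q = 0.05,
                          null = c("binomial", "monte_carlo"),
                          n_iter = 10000L, seed = 1L) {
  null <- match.arg(null)
  maps <- lapply(results_by_subject, function(res)
    selectTopFraction(rankDiscriminativeVoxels(res), f))
  map <- groupOverlap(maps)
  map <- overlapPValues(map, method = null, n_iter = n_iter, seed = seed)
  fdrThreshold(map, q)
}
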