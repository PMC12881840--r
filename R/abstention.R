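#' Per-patient sum of signed patch scores
#'
#' Aggregates patch-level signed decision values to one score per patient by
#' exact arithmetic summation. The summed score is the quantity the
#' abstention thresholds operate on.
#'
#' @param scores data.table as returned by [score_patches()] (any number of
#'   patients).
#' @return data.table with columns `patient_id`, `sum_signed`, `n_patches`.
#' @export
patient_sums <- function(scores) {
  scores <- as.data.table(scores)
  if (nrow(scores) == 0) stop("patient_sums on an empty score table")
  out <- scores[, list(sum_signed = sum(signed_score),
                       n_patches = .N), by = "patient_id"]
  if (!all(is.finite(out$sum_signed))) stop("non-finite summed score")
  setkeyv(out, "patient_id")
  out[]
}

#' Calibration set for the abstention thresholds
#'
#' Holds the per-patient summed signed scores of the calibration split: the
#' pancreas and small-intestine patients not used for classifier training,
#' plus the `o` patients with NETs of other origin.
#'
#' @param pancreas_sums,si_sums,other_sums Numeric vectors of summed signed
#'   scores.
#' @return A `calibration_set` list.
#' @export
calibration_set <- function(pancreas_sums, si_sums, other_sums) {
  stopifnot(all(is.finite(c(pancreas_sums, si_sums, other_sums))))
  structure(list(pancreas_sums = as.numeric(pancreas_sums),
                 si_sums = as.numeric(si_sums),
                 other_sums = as.numeric(other_sums)),
            class = "calibration_set")
}

#' Determine the abstention thresholds for a given capture count
#'
#' Finds a closed interval `[lower, upper]` of summed signed scores that
#' contains exactly `i` of the `o` other-origin calibration sums while
#' minimising the number of pancreas/small-intestine calibration sums inside.
#' Because the others captured by any interval are contiguous in sorted
#' order, the search enumerates the `o - i + 1` contiguous windows of `i`
#' sorted other-origin sums and takes the tightest interval
#' `[window min, window max]` for each.
#'
#' By default (matching the geometry of the latent space, where other-origin
#' cases concentrate near the decision boundary) candidate intervals must
#' contain 0 for `i >= 1`, so the three-way rule `sum < lower -> pancreas`,
#' `sum > upper -> small intestine` never contradicts the score sign. Under
#' that constraint the tightest admissible interval for a window is its hull
#' with 0, `[min(window, 0), max(window, 0)]`; windows whose extension to 0
#' would capture additional others are discarded, and if no window survives
#' the constraint is dropped with a warning. Ties between admissible windows
#' are broken by (fewest in-class sums inside, midpoint closest to 0,
#' smallest width).
#'
#' For `i = 0` the interval degenerates to `lower = upper = 0`, so confidence
#' 0 reproduces the pure binary classifier on every patient with a nonzero
#' sum.
#'
#' @param cal A [calibration_set()].
#' @param i Number of other-origin calibration patients to capture,
#'   `0 <= i <= o`.
#' @param contain_zero Require the interval to contain the decision boundary
#'   (default `TRUE`).
#' @return A `threshold_pair` list with fields `lower`, `upper`, `i`, `o`,
#'   `confidence = i/o`, `n_inclass_inside`, `contain_zero`.
#' @export
determine_thresholds <- function(cal, i, contain_zero = TRUE) {
  stopifnot(inherits(cal, "calibration_set"))
  o <- length(cal$other_sums)
  i <- as.integer(i)
  if (i < 0 || i > o)
    stop("capture count i = ", i, " outside 0..o (o = ", o, ")")

  mk <- function(lower, upper, n_in) {
    structure(list(lower = lower, upper = upper, i = i, o = o,
                   confidence = if (o > 0) i / o else 0,
                   n_inclass_inside = n_in, contain_zero = contain_zero),
              class = "threshold_pair")
  }
  inclass <- c(cal$pancreas_sums, cal$si_sums)
  count_in <- function(v, lo, hi) sum(v >= lo & v <= hi)

  if (i == 0L) return(mk(0, 0, count_in(inclass, 0, 0)))

  s <- sort(cal$other_sums)
  windows <- lapply(seq_len(o - i + 1L), function(w) c(s[w], s[w + i - 1L]))
  if (contain_zero) {
    # tightest admissible interval for a window is its hull with 0; discard
    # windows whose extension towards 0 would capture additional others
    hulls <- lapply(windows, function(wd) c(min(wd[1], 0), max(wd[2], 0)))
    cand <- Filter(function(wd) count_in(s, wd[1], wd[2]) == i, hulls)
    if (!length(cand)) {
      warning("no interval containing 0 captures exactly i = ", i,
              " other-origin sums; dropping the contain-zero constraint")
      cand <- Filter(function(wd) count_in(s, wd[1], wd[2]) == i, windows)
    }
  } else {
    cand <- Filter(function(wd) count_in(s, wd[1], wd[2]) == i, windows)
  }
  if (!length(cand))
    stop("no interval captures exactly i = ", i,
         " other-origin sums (tied values?)")

  # tie-breaks: fewest in-class sums inside, then midpoint closest to the
  # decision boundary, then smallest width. Boundary-centred windows are
  # preferred over narrow one-sided ones because other-origin cases
  # concentrate near the boundary; a width-first rule degenerates to
  # one-sided slivers at intermediate i and makes abstention erratic.
  key <- vapply(cand, function(wd)
    c(count_in(inclass, wd[1], wd[2]), abs((wd[1] + wd[2]) / 2), wd[2] - wd[1]),
    numeric(3))
  best <- do.call(order, as.data.frame(t(key)))[1]
  wd <- cand[[best]]
  mk(wd[1], wd[2], as.integer(key[1, best]))
}

#' Three-way classification with abstention
#'
#' Applies the calibrated thresholds to summed signed scores: sums inside the
#' closed interval `[lower, upper]` are labelled `uncertain`, sums below
#' `lower` pancreas, sums above `upper` small intestine.
#'
#' @param sum_signed Numeric vector of per-patient summed signed scores.
#' @param thr A `threshold_pair` from [determine_thresholds()].
#' @return Character vector in `{pancreas, small_intestine, uncertain}`.
#' @export
classify_with_abstention <- function(sum_signed, thr) {
  stopifnot(inherits(thr, "threshold_pair"), thr$lower <= thr$upper)
  ifelse(sum_signed < thr$lower, "pancreas",
         ifelse(sum_signed > thr$upper, "small_intestine", "uncertain"))
}

#' Threshold pairs for every confidence level
#'
#' Runs [determine_thresholds()] for every capture count `i = 0, ..., o`,
#' yielding the full confidence sweep `c = i/o`.
#'
#' @param cal A [calibration_set()].
#' @param contain_zero Passed through to [determine_thresholds()].
#' @return List of `o + 1` `threshold_pair`s.
#' @export
sweep_confidence <- function(cal, contain_zero = TRUE) {
  o <- length(cal$other_sums)
  lapply(0:o, function(i) determine_thresholds(cal, i, contain_zero))
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(
    "<threshold_pair> [%.4g, %.4g] i=%d/%d (confidence %.3f), %d in-class inside\n",
    x$lower, x$upper, x$i, x$o, x$confidence, x$n_inclass_inside))
  invisible(x)
}
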