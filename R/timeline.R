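#' Song timeline for one individual
#'
#' A `song_timeline` holds the ordered, non-overlapping song intervals of one
#' individual within an analysis window. Times are seconds from session start;
#' intervals are half-open `[begin, end)`, so abutting songs do not overlap and
#' durations are additive.
#'
#' @param individual_id character scalar.
#' @param intervals two-column numeric matrix (begin, end), a data.frame with
#'   columns `t_begin`/`t_end`, or NULL for an empty timeline. Overlapping or
#'   abutting intervals are merged.
#' @param window numeric length-2, the analysis window `(t0, t1)`. Intervals
#'   are clipped to the window.
#' @return object of class `song_timeline` with fields `individual_id`,
#'   `intervals` (two-column matrix), `window`.
#' @examples
#' tl <- song_timeline("RYB", rbind(c(1, 3), c(3, 5)), window = c(0, 10))
#' timeline_singing_time(tl)  # 4 seconds, the two songs merged
#' @export
song_timeline <- function(individual_id, intervals = NULL, window) {
  stopifnot(is.character(individual_id), length(individual_id) == 1L,
            length(window) == 2L, is.finite(window[1L]), is.finite(window[2L]))
  if (window[2L] < window[1L]) {
    stop("window must satisfy t0 <= t1")
  }
  if (is.data.frame(intervals)) {
    intervals <- cbind(intervals$t_begin, intervals$t_end)
  }
  iv <- clip_intervals(normalize_intervals(intervals), as.numeric(window))
  structure(
    list(individual_id = individual_id, intervals = iv,
         window = as.numeric(window)),
    class = "song_timeline"
  )
}

#' @export
print.song_timeline <- function(x, ...) {
  cat(sprintf("<song_timeline> %s: %d songs, %.1f s singing in window [%g, %g)\n",
              x$individual_id, nrow(x$intervals), timeline_singing_time(x),
              x$window[1L], x$window[2L]))
  invisible(x)
}

#' Total singing time of a timeline (seconds)
#' @param x a `song_timeline`.
#' @export
timeline_singing_time <- function(x) {
  intervals_length(x$intervals)
}

#' Duty cycle of a timeline
#'
#' Fraction of the analysis window during which the individual sings.
#' @param x a `song_timeline`.
#' @export
timeline_duty_cycle <- function(x) {
  w <- diff(x$window)
  if (w <= 0) {
    return(0)
  }
  timeline_singing_time(x) / w
}

stopifnot_same_window <- function(x, y) {
  if (!isTRUE(all.equal(x$window, y$window, tolerance = 1e-12))) {
    stop("timelines must share the same analysis window")
  }
}

#' Binary singing series
#'
#' A 0/1 indicator of singing at a fixed bin width, the discretization used by
#' the transfer-entropy analysis.
#'
#' @param bits integer vector of 0/1 values.
#' @param bin bin width in seconds.
#' @param t0 start time of the first bin.
#' @return object of class `binary_series`.
#' @export
binary_series <- function(bits, bin = 0.5, t0 = 0) {
  stopifnot(length(bits) >= 1L, bin > 0, all(bits %in% c(0L, 1L)))
  structure(list(bits = as.integer(bits), bin = bin, t0 = t0),
            class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf("<binary_series> %d bins of %g s from t0=%g (duty %.3f)\n",
              length(x$bits), x$bin, x$t0, mean(x$bits)))
  invisible(x)
}

#' Binarize a song timeline
#'
#' Assigns bin `i` (covering `[t0 + i*bin, t0 + (i+1)*bin)`) the value 1 iff
#' some song interval contains the bin midpoint. The midpoint rule gives an
#' unbiased duty cycle; only full bins inside the window are emitted.
#'
#' @param timeline a `song_timeline`.
#' @param bin bin width in seconds (default 0.5).
#' @return a `binary_series`.
#' @examples
#' tl <- song_timeline("b", rbind(c(1.0, 2.2)), window = c(0, 3))
#' binarize(tl)$bits  # 0 0 1 1 0 0
#' @export
binarize <- function(timeline, bin = 0.5) {
  stopifnot(inherits(timeline, "song_timeline"), bin > 0)
  w <- timeline$window
  n <- floor((w[2L] - w[1L]) / bin + 1e-9)
  if (n < 1L) {
    stop("window shorter than one bin")
  }
  mids <- w[1L] + (seq_len(n) - 0.5) * bin
  bits <- as.integer(points_in_union(mids, timeline$intervals))
  binary_series(bits, bin = bin, t0 = w[1L])
}

#' Compare a localized timeline against an annotated one
#'
#' Decomposes the shared window into true-positive, false-positive,
#' true-negative, and false-negative durations by exact interval sweep, and
#' derives accuracy, true-positive rate, and false-positive rate:
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, `tpr = TP/(TP+FN)`, `fpr = FP/(FP+TN)`.
#'
#' @param localized `song_timeline` produced by the localization pipeline.
#' @param annotated `song_timeline` from human annotation (ground truth).
#' @return list of class `evaluation_result` with fields `tp`, `fp`, `tn`,
#'   `fn` (seconds) and `accuracy`, `tpr`, `fpr`.
#' @export
evaluate_timeline <- function(localized, annotated) {
  stopifnot(inherits(localized, "song_timeline"),
            inherits(annotated, "song_timeline"))
  stopifnot_same_window(localized, annotated)
  w <- diff(localized$window)
  tp <- intersect_length(localized$intervals, annotated$intervals)
  fp <- intervals_length(localized$intervals) - tp
  fn <- intervals_length(annotated$intervals) - tp
  tn <- w - tp - fp - fn
  res <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = if (w > 0) (tp + tn) / w else NA_real_,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_
  )
  class(res) <- "evaluation_result"
  res
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> TP %.1f FP %.1f TN %.1f FN %.1f s | acc %.3f tpr %.3f fpr %.3f\n",
    x$tp, x$fp, x$tn, x$fn, x$accuracy, x$tpr, x$fpr))
  invisible(x)
}

#' Complement of a timeline within its window
#' @keywords internal
complement_timeline <- function(x) {
  w <- x$window
  iv <- x$intervals
  pts <- c(w[1L], as.vector(t(iv)), w[2L])
  comp <- matrix(pts, ncol = 2L, byrow = TRUE)
  song_timeline(x$individual_id, comp, window = w)
}
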