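# Interval algebra on half-open [begin, end) intervals.
#
# Intervals are represented as numeric matrices with two columns (begin, end).
# All exported timeline operations are exact interval sweeps, never gridded.

#' Normalize a set of intervals
#'
#' Sorts intervals by begin time and merges overlapping or abutting ones, so
#' the result is a disjoint, sorted union. Zero- or negative-length intervals
#' are dropped.
#'
#' @param x numeric matrix with two columns (begin, end), or NULL/empty.
#' @return numeric matrix with two columns, possibly 0 rows.
#' @keywords internal
normalize_intervals <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  x <- matrix(as.numeric(x), ncol = 2L)
  x <- x[x[, 2L] > x[, 1L], , drop = FALSE]
  if (nrow(x) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  x <- x[order(x[, 1L], x[, 2L]), , drop = FALSE]
  n <- nrow(x)
  if (n == 1L) {
    return(x)
  }
  # interval i starts a new block iff begin_i > running max of earlier ends
  ce <- cummax(x[, 2L])
  starts_block <- c(TRUE, x[-1L, 1L] > ce[-n])
  first <- which(starts_block)
  last <- c(first[-1L] - 1L, n)
  cbind(x[first, 1L], ce[last], deparse.level = 0L)
}

#' Total length of a normalized interval union
#' @keywords internal
intervals_length <- function(x) {
  if (nrow(x) == 0L) 0 else sum(x[, 2L] - x[, 1L])
}

#' Clip a normalized interval union to a window
#' @keywords internal
clip_intervals <- function(x, window) {
  if (nrow(x) == 0L) {
    return(x)
  }
  b <- pmax(x[, 1L], window[1L])
  e <- pmin(x[, 2L], window[2L])
  keep <- e > b
  cbind(b[keep], e[keep], deparse.level = 0L)
}

# Membership of points in a normalized union under half-open semantics:
# t is inside iff it falls in some [b, e). findInterval() against the
# flattened boundary vector gives an odd index exactly in that case
# (t == b lands on the begin boundary -> inside; t == e -> outside).
points_in_union <- function(t, x) {
  if (nrow(x) == 0L) {
    return(rep(FALSE, length(t)))
  }
  findInterval(t, as.vector(t(x))) %% 2L == 1L
}

# Cumulative coverage C(t) = measure of the union lying before time t,
# evaluated at a vector of times. Exact, no grid.
cumulative_coverage <- function(t, x) {
  if (nrow(x) == 0L) {
    return(rep(0, length(t)))
  }
  n <- nrow(x)
  v <- as.vector(t(x))                  # b1 e1 b2 e2 ...
  cumlens <- cumsum(x[, 2L] - x[, 1L])
  cum_at <- numeric(2L * n)             # coverage before each boundary
  cum_at[seq(1L, 2L * n, by = 2L)] <- c(0, cumlens[-n])
  cum_at[seq(2L, 2L * n, by = 2L)] <- cumlens
  i <- findInterval(t, v)
  out <- numeric(length(t))
  pos <- i > 0L
  out[pos] <- cum_at[i[pos]]
  inside <- pos & i %% 2L == 1L         # t falls within interval ceiling(i/2)
  out[inside] <- out[inside] + (t[inside] - v[i[inside]])
  out
}

#' Length of the intersection of two normalized unions
#' @keywords internal
intersect_length <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L) {
    return(0)
  }
  sum(cumulative_coverage(x[, 2L], y) - cumulative_coverage(x[, 1L], y))
}

#' Intersection of two normalized unions as intervals
#' @keywords internal
intersect_intervals <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  out <- vector("list", nrow(x))
  j <- 1L
  for (i in seq_len(nrow(x))) {
    b <- pmax(x[i, 1L], y[, 1L])
    e <- pmin(x[i, 2L], y[, 2L])
    keep <- e > b
    if (any(keep)) {
      out[[j]] <- cbind(b[keep], e[keep], deparse.level = 0L)
      j <- j + 1L
    }
  }
  if (j == 1L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  do.call(rbind, out[seq_len(j - 1L)])
}
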