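# Interaction inference between pairs of song timelines.
#
# The question throughout: do two territorial birds time their songs to avoid
# (or seek) overlap, and is the influence directional? The null model is the
# gap shuffle: a surrogate timeline that keeps every song's duration and
# order but permutes the nonsinging-interval durations, preserving the duty
# cycle and bout structure while destroying the relative timing between the
# two birds. All p-values are Monte-Carlo proportions under that null with
# strict inequalities, so ties count against significance.

#' Vacant / overlapped / solo decomposition of a timeline pair
#'
#' Partitions the shared window into time where neither bird sings (vacant),
#' both sing (overlapped), and exactly one sings (solo), by exact interval
#' sweep. The three parts sum to the window length.
#'
#' @param X,Y `song_timeline`s on the same window.
#' @return list of class `pair_decomposition`: `duration`, `vacant`,
#'   `overlapped`, `solo` (seconds).
#' @examples
#' w <- c(0, 10)
#' X <- song_timeline("a", rbind(c(0, 4)), w)
#' Y <- song_timeline("b", rbind(c(3, 6)), w)
#' decompose_pair(X, Y)  # vacant 4, overlapped 1, solo 5
#' @export
decompose_pair <- function(X, Y) {
  stopifnot(inherits(X, "song_timeline"), inherits(Y, "song_timeline"))
  stopifnot_same_window(X, Y)
  w <- diff(X$window)
  lx <- intervals_length(X$intervals)
  ly <- intervals_length(Y$intervals)
  ov <- intersect_length(X$intervals, Y$intervals)
  res <- list(duration = w, vacant = w - (lx + ly - ov), overlapped = ov,
              solo = lx + ly - 2 * ov)
  class(res) <- "pair_decomposition"
  res
}

#' @export
print.pair_decomposition <- function(x, ...) {
  cat(sprintf(
    "<pair_decomposition> duration %.1f = vacant %.1f + overlapped %.1f + solo %.1f s\n",
    x$duration, x$vacant, x$overlapped, x$solo))
  invisible(x)
}

#' Gap-shuffle surrogate timeline
#'
#' Keeps song durations and their order; permutes the multiset of
#' nonsinging-interval durations (including the leading and trailing gaps
#' within the window) uniformly at random. Total window length, total singing
#' time, and the song-duration sequence are preserved exactly.
#'
#' Uses R's global random stream: seed with `set.seed()` (the randomization
#' tests below do this for you via their `seed` argument).
#'
#' @param X a `song_timeline`.
#' @return a `song_timeline`.
#' @export
shuffle_gaps <- function(X) {
  stopifnot(inherits(X, "song_timeline"))
  iv <- X$intervals
  n <- nrow(iv)
  if (n == 0L) {
    return(X)
  }
  w <- X$window
  d <- iv[, 2L] - iv[, 1L]
  gaps <- c(iv[, 1L], w[2L]) - c(w[1L], iv[, 2L])
  g <- gaps[sample.int(n + 1L)]
  b <- w[1L] + cumsum(g[seq_len(n)]) + c(0, cumsum(d[-n]))
  song_timeline(X$individual_id, cbind(b, b + d), window = w)
}

rand_test_result <- function(observed, null_values, p_value, n_rand, seed) {
  structure(list(observed = observed, expected = mean(null_values),
                 p_value = p_value, n_rand = n_rand, seed = seed,
                 null_values = null_values),
            class = "rand_test_result")
}

#' @export
print.rand_test_result <- function(x, ...) {
  cat(sprintf(
    "<rand_test_result> observed %.4g, expected %.4g (n_rand %d), p = %.4f\n",
    x$observed, x$expected, x$n_rand, x$p_value))
  invisible(x)
}

#' Solo-duration randomization test
#'
#' Tests whether the pair's solo singing duration (time exactly one bird
#' sings) departs from chance. Both timelines are gap-shuffled independently
#' in each of `n_rand` null draws; the p-value is the proportion of null solo
#' durations strictly larger than the observed one. Two-tailed reading:
#' overlap avoidance if p < .025 (observed solo unusually long), active
#' overlap if p > .975.
#'
#' @param X,Y `song_timeline`s on the same window.
#' @param n_rand number of null draws (default 10000).
#' @param seed integer seed.
#' @return a `rand_test_result` (`observed`, `expected`, `p_value`, and the
#'   null draws in `null_values`).
#' @export
solo_test <- function(X, Y, n_rand = 10000L, seed = 1L) {
  stopifnot_same_window(X, Y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  observed <- decompose_pair(X, Y)$solo
  nulls <- vapply(seq_len(n_rand), function(i) {
    decompose_pair(shuffle_gaps(X), shuffle_gaps(Y))$solo
  }, 0)
  rand_test_result(observed, nulls, mean(nulls > observed), n_rand, seed)
}

#' Active-overlap duration of a target against a reference
#'
#' Sums, over every song of the target `X` whose onset falls while the
#' reference `Y` is singing, the co-singing time during that song. This
#' attributes all co-singing seconds during a later-starting song to the bird
#' that started it, including any accrued after the reference's current song
#' ends and a new reference song begins.
#'
#' With the default `"union"` attribution, a later-starting song collects all
#' its co-singing seconds, including any accrued against reference songs that
#' begin after it; the two directed durations can then jointly exceed the
#' pair's total overlapped time. The `"onset_song"` alternative counts only
#' co-singing with the reference song that contained the onset; under it the
#' two directions never exceed the total overlap, with equality when every
#' overlapped second lies inside some later-starting song.
#'
#' @param X target `song_timeline` (the potential overlapper/avoider).
#' @param Y reference `song_timeline`.
#' @param attribution `"union"` (default) or `"onset_song"`, see Details.
#' @return seconds.
#' @examples
#' w <- c(0, 10)
#' X <- song_timeline("x", rbind(c(2, 5)), w)
#' Y <- song_timeline("y", rbind(c(1, 3)), w)
#' active_overlap_duration(X, Y)  # 1: onset 2 lies inside [1, 3)
#' active_overlap_duration(Y, X)  # 0
#' @export
active_overlap_duration <- function(X, Y,
                                    attribution = c("union", "onset_song")) {
  attribution <- match.arg(attribution)
  stopifnot_same_window(X, Y)
  iv <- X$intervals
  yv <- Y$intervals
  if (nrow(iv) == 0L || nrow(yv) == 0L) {
    return(0)
  }
  pos <- findInterval(iv[, 1L], as.vector(t(yv)))
  onset_in <- pos %% 2L == 1L
  if (!any(onset_in)) {
    return(0)
  }
  if (attribution == "union") {
    sum(cumulative_coverage(iv[onset_in, 2L], yv) -
          cumulative_coverage(iv[onset_in, 1L], yv))
  } else {
    ysong <- (pos[onset_in] + 1L) %/% 2L      # index of onset-containing song
    sum(pmin(iv[onset_in, 2L], yv[ysong, 2L]) - iv[onset_in, 1L])
  }
}

#' Asymmetric active-overlap randomization test
#'
#' Tests whether the target `X` begins songs during the reference `Y`'s songs
#' less (avoidance) or more (active overlap) than chance. Null draws
#' gap-shuffle `X` only, keeping `Y` fixed; the p-value is the proportion of
#' null active-overlap durations strictly smaller than the observed one.
#' Two-tailed reading: `X` avoided overlapping `Y` if p < .025, actively
#' overlapped if p > .975.
#'
#' @inheritParams solo_test
#' @inheritParams active_overlap_duration
#' @param X target timeline (shuffled under the null).
#' @param Y reference timeline (held fixed).
#' @return a `rand_test_result`; `expected` is the null-mean overlap.
#' @export
asymmetric_overlap_test <- function(X, Y, n_rand = 10000L, seed = 1L,
                                    attribution = c("union", "onset_song")) {
  attribution <- match.arg(attribution)
  stopifnot_same_window(X, Y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  observed <- active_overlap_duration(X, Y, attribution)
  nulls <- vapply(seq_len(n_rand), function(i) {
    active_overlap_duration(shuffle_gaps(X), Y, attribution)
  }, 0)
  rand_test_result(observed, nulls, mean(nulls < observed), n_rand, seed)
}

#' Plug-in transfer entropy between binary series
#'
#' Transfer entropy from source `Y` to sink `X` with history lengths `k`
#' (sink) and `l` (source), in bits:
#' \deqn{TE_{Y \to X}(k, l) = \sum p(x_{t+1}, x_t^k, y_t^l)
#'   \log_2 \frac{p(x_{t+1} | x_t^k, y_t^l)}{p(x_{t+1} | x_t^k)}}
#' where \eqn{x_t^k = (x_{t-k+1}, \ldots, x_t)}. Probabilities are empirical
#' frequencies over all valid t (the plug-in estimator); zero-probability
#' outcomes contribute 0. TE is nonnegative and zero when `X`'s next state is
#' conditionally independent of `Y`'s past given `X`'s own past.
#'
#' @param X sink `binary_series`.
#' @param Y source `binary_series` (same length and bin).
#' @param k,l history lengths (bins), defaults 1. With 0.5 s bins, one bin
#'   spans the typical pause between consecutive songs' notes.
#' @return transfer entropy in bits (nonnegative scalar).
#' @export
transfer_entropy <- function(X, Y, k = 1L, l = 1L) {
  stopifnot(inherits(X, "binary_series"), inherits(Y, "binary_series"),
            k >= 1L, l >= 1L)
  if (length(X$bits) != length(Y$bits) || !isTRUE(all.equal(X$bin, Y$bin))) {
    stop("series must share length and bin width")
  }
  x <- X$bits
  y <- Y$bits
  n <- length(x)
  m <- max(k, l)
  if (n <= m) {
    stop("series too short for history lengths k=", k, ", l=", l)
  }
  ts <- seq.int(m, n - 1L)              # indices t with full histories
  pow2 <- function(j) 2L^(seq_len(j) - 1L)
  hist_code <- function(v, j, t) {
    # code of (v[t-j+1], ..., v[t]) as an integer in [0, 2^j)
    out <- integer(length(t))
    for (s in seq_len(j)) {
      out <- out + v[t - s + 1L] * pow2(s)[s]
    }
    out
  }
  xk <- hist_code(x, k, ts)
  yl <- hist_code(y, l, ts)
  xn <- x[ts + 1L]
  # joint cell codes
  c_xk <- xk
  c_xkyl <- xk + 2L^k * yl
  c_xnxk <- xn + 2L * xk
  c_full <- xn + 2L * xk + 2L^(k + 1L) * yl
  cnt <- function(code, size) tabulate(code + 1L, nbins = size)
  n_full <- cnt(c_full, 2L^(k + l + 1L))
  n_xkyl <- cnt(c_xkyl, 2L^(k + l))
  n_xnxk <- cnt(c_xnxk, 2L^(k + 1L))
  n_xk <- cnt(c_xk, 2L^k)
  N <- length(ts)
  full_codes <- which(n_full > 0L) - 1L
  xn_c <- full_codes %% 2L
  xk_c <- (full_codes %/% 2L) %% 2L^k
  yl_c <- full_codes %/% 2L^(k + 1L)
  nf <- n_full[full_codes + 1L]
  te <- sum(nf / N * log2(
    (nf / n_xkyl[xk_c + 2L^k * yl_c + 1L]) /
      (n_xnxk[xn_c + 2L * xk_c + 1L] / n_xk[xk_c + 1L])
  ))
  max(te, 0)
}

#' Transfer-entropy randomization test
#'
#' Tests for directional influence from the source bird to the sink bird.
#' The observed statistic is `transfer_entropy(binarize(sink),
#' binarize(source))`. Null draws gap-shuffle the *source timeline* at the
#' interval level, re-binarize, and recompute TE, preserving the source's
#' bout structure. One-tailed: p is the proportion of null TEs strictly
#' larger than the observed TE.
#'
#' @param sink `song_timeline` of the receiving bird (X).
#' @param source `song_timeline` of the potentially influencing bird (Y).
#' @param k,l history lengths in bins.
#' @param bin binarization width in seconds (default 0.5).
#' @param n_rand number of null draws.
#' @param seed integer seed.
#' @return a `rand_test_result`; `expected` is the null-mean TE.
#' @export
te_test <- function(sink, source, k = 1L, l = 1L, bin = 0.5,
                    n_rand = 10000L, seed = 1L) {
  stopifnot_same_window(sink, source)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bx <- binarize(sink, bin = bin)
  observed <- transfer_entropy(bx, binarize(source, bin = bin), k = k, l = l)
  nulls <- vapply(seq_len(n_rand), function(i) {
    transfer_entropy(bx, binarize(shuffle_gaps(source), bin = bin),
                     k = k, l = l)
  }, 0)
  rand_test_result(observed, nulls, mean(nulls > observed), n_rand, seed)
}

#' Session-level bootstrap of an interaction effect
#'
#' Resamples sessions with replacement and recomputes the mean per-session
#' effect, giving a percentile confidence interval and a two-sided sign
#' bootstrap p-value `p = min(1, 2 * min(P*(stat <= 0), P*(stat >= 0)))`.
#' Sessions are the only exchangeable units once per-session observed and
#' null-expected statistics are in hand.
#'
#' Effects:
#' \describe{
#'   \item{expected_minus_observed}{`expected - observed` per session (e.g.
#'     null-mean overlap minus observed overlap; positive = avoidance).
#'     Needs columns `observed`, `expected`.}
#'   \item{te_minus_ternd}{`observed - expected` per session (TE minus
#'     null-mean TE; positive = directional influence). Needs columns
#'     `observed`, `expected`.}
#'   \item{obs_exp_ratio_diff}{difference of observed/expected ratios between
#'     two individuals, `observed_a/expected_a - observed_b/expected_b` per
#'     session. Needs columns `observed_a`, `expected_a`, `observed_b`,
#'     `expected_b`.}
#' }
#'
#' @param values data.frame with one row per session (>= 2 rows).
#' @param effect effect type, see Details.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return list of class `bootstrap_result`: `mean`, `ci95` (2.5/97.5
#'   percentiles), `p_value`, `n_boot`.
#' @export
bootstrap_effect <- function(values,
                             effect = c("expected_minus_observed",
                                        "te_minus_ternd",
                                        "obs_exp_ratio_diff"),
                             n_boot = 10000L, seed = 1L) {
  effect <- match.arg(effect)
  if (nrow(values) < 2L) {
    stop("bootstrap needs at least 2 sessions")
  }
  e <- switch(effect,
    expected_minus_observed = values$expected - values$observed,
    te_minus_ternd = values$observed - values$expected,
    obs_exp_ratio_diff = values$observed_a / values$expected_a -
      values$observed_b / values$expected_b
  )
  if (anyNA(e)) {
    stop("effect values contain NA (check required columns for ", effect, ")")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(e)
  stat <- vapply(seq_len(n_boot), function(i) {
    mean(e[sample.int(n, n, replace = TRUE)])
  }, 0)
  p <- min(1, 2 * min(mean(stat <= 0), mean(stat >= 0)))
  res <- list(mean = mean(stat),
              ci95 = unname(stats::quantile(stat, c(0.025, 0.975))),
              p_value = p, n_boot = n_boot, seed = seed)
  class(res) <- "bootstrap_result"
  res
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> mean %.4g, 95%% CI [%.4g, %.4g], p = %.4f (n_boot %d)\n",
    x$mean, x$ci95[1L], x$ci95[2L], x$p_value, x$n_boot))
  invisible(x)
}

#' Solo duration implied by the decomposition conservation law
#'
#' Given a window duration and its vacant and overlapped parts, the solo part
#' is determined: `solo = duration - vacant - overlapped`.
#'
#' @param duration,vacant,overlapped seconds.
#' @return solo seconds.
#' @export
solo_from_decomposition <- function(duration, vacant, overlapped) {
  duration - vacant - overlapped
}
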