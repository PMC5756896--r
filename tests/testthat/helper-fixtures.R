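# Shared test fixtures and independent oracles.
#
# Oracles here are deliberately naive (grids, enumeration, brute force) and
# never call the code paths they check.

# circular distance between two angles in degrees
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# random valid song timeline: n songs with positive gaps inside the window
random_timeline <- function(id = "x", window = c(0, 100), n_songs = 8) {
  w <- diff(window)
  # draw 2n+1 positive segment lengths summing to w: gap song gap song ... gap
  lens <- stats::rexp(2L * n_songs + 1L) + 1e-3
  lens <- lens / sum(lens) * w
  bounds <- window[1L] + cumsum(lens)
  b <- c(window[1L], bounds)[seq(2L, 2L * n_songs, by = 2L)]
  e <- bounds[seq(2L, 2L * n_songs, by = 2L)]
  song_timeline(id, cbind(b, e), window = window)
}

# 1 ms grid oracle for pairwise decomposition
grid_decompose <- function(X, Y, dt = 0.001) {
  w <- X$window
  t <- seq(w[1L] + dt / 2, w[2L], by = dt)
  inx <- grid_in(t, X$intervals)
  iny <- grid_in(t, Y$intervals)
  c(vacant = sum(!inx & !iny) * dt,
    overlapped = sum(inx & iny) * dt,
    solo = sum(xor(inx, iny)) * dt)
}

grid_in <- function(t, iv) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) {
    out <- out | (t >= iv[i, 1L] & t < iv[i, 2L])
  }
  out
}

# brute-force per-song active overlap: onset inside Y, co-singing on a grid
grid_active_overlap <- function(X, Y, dt = 0.001) {
  iv <- X$intervals
  total <- 0
  for (i in seq_len(nrow(iv))) {
    if (!grid_in(iv[i, 1L], Y$intervals)) next
    t <- seq(iv[i, 1L] + dt / 2, iv[i, 2L], by = dt)
    t <- t[t < iv[i, 2L]]
    total <- total + sum(grid_in(t, Y$intervals)) * dt
  }
  total
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1L) {
    return(matrix(1L))
  }
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

# rebuild a timeline from a specific gap ordering (independent of
# shuffle_gaps): songs keep durations/order, gaps g in the given order
timeline_from_gaps <- function(X, g) {
  iv <- X$intervals
  d <- iv[, 2L] - iv[, 1L]
  n <- length(d)
  b <- X$window[1L] + cumsum(g[seq_len(n)]) + c(0, cumsum(d[-n]))
  song_timeline(X$individual_id, cbind(b, b + d), window = X$window)
}

timeline_gaps <- function(X) {
  iv <- X$intervals
  c(iv[, 1L], X$window[2L]) - c(X$window[1L], iv[, 2L])
}

# exhaustive-outcome transfer entropy oracle: loops over all history
# patterns, counting occurrences naively
te_oracle <- function(x, y, k = 1L, l = 1L) {
  n <- length(x)
  m <- max(k, l)
  ts <- seq.int(m, n - 1L)
  pat_x <- expand.grid(rep(list(0:1), k))
  pat_y <- expand.grid(rep(list(0:1), l))
  N <- length(ts)
  te <- 0
  for (xn in 0:1) {
    for (i in seq_len(nrow(pat_x))) {
      for (j in seq_len(nrow(pat_y))) {
        # pattern px = (x_{t-k+1},...,x_t): pat row stored most-recent-first
        px <- as.integer(pat_x[i, ])
        py <- as.integer(pat_y[j, ])
        n_full <- 0L; n_xkyl <- 0L; n_xnxk <- 0L; n_xk <- 0L
        for (t in ts) {
          mx <- all(x[t - seq_len(k) + 1L] == px)
          my <- all(y[t - seq_len(l) + 1L] == py)
          if (mx) n_xk <- n_xk + 1L
          if (mx && my) n_xkyl <- n_xkyl + 1L
          if (mx && x[t + 1L] == xn) n_xnxk <- n_xnxk + 1L
          if (mx && my && x[t + 1L] == xn) n_full <- n_full + 1L
        }
        if (n_full > 0L) {
          te <- te + n_full / N *
            log2((n_full / n_xkyl) / (n_xnxk / n_xk))
        }
      }
    }
  }
  te
}

# standard three-array test geometry (spacings 40-60 m, like a field layout)
test_geometry <- function() {
  array_geometry(c("1", "2", "3"), x = c(0, 60, 30), y = c(0, 0, 40))
}

noiseless_noise <- function() {
  observation_noise(azimuth_sd = 0, begin_jitter_max = 0, end_jitter_sd = 0,
                    miss_prob = 0, clutter_rate = 0)
}

# small two-bird scenario used by several pipeline tests
demo_config <- function(seed = 42, window = c(0, 300), suppression = 1,
                        mode = "independent", n_rand = 200) {
  list(
    seed = seed,
    window = window,
    scenario = list(
      birds = list(
        list(individual_id = "RYB", post_xy = c(15, 8), gap_mean = 4,
             movement_radius = 2),
        list(individual_id = "RGY", post_xy = c(45, 30), gap_mean = 5)
      ),
      interaction = c(list(mode = mode, suppression = suppression),
                      if (mode != "independent") {
                        list(targets = list(c("RGY", "RYB")))
                      }),
      noise = list(azimuth_sd = 1, begin_jitter_max = 0.5,
                   end_jitter_sd = 0.1, miss_prob = 0.02, clutter_rate = 0.5)
    ),
    geometry = list(list(array_id = "1", x = 0, y = 0),
                    list(array_id = "2", x = 60, y = 0),
                    list(array_id = "3", x = 30, y = 40)),
    posts = list(list(individual_id = "RYB", center_xy = c(15, 8), radius = 15),
                 list(individual_id = "RGY", center_xy = c(45, 30), radius = 10)),
    n_rand = n_rand, n_boot = 500
  )
}
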