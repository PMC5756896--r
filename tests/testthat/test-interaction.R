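test_that("decompose_pair: hand case and conservation on random timelines", {
  w <- c(0, 10)
  X <- song_timeline("x", rbind(c(0, 4)), w)
  Y <- song_timeline("y", rbind(c(3, 6)), w)
  d <- decompose_pair(X, Y)
  expect_equal(c(d$vacant, d$overlapped, d$solo), c(4, 1, 5))
  expect_error(decompose_pair(X, song_timeline("y", NULL, c(0, 20))),
               "window")

  set.seed(101)
  for (rep in 1:50) {
    A <- random_timeline("a", c(0, 120), sample(1:15, 1))
    B <- random_timeline("b", c(0, 120), sample(1:15, 1))
    d <- decompose_pair(A, B)
    expect_equal(d$vacant + d$overlapped + d$solo, d$duration,
                 tolerance = 1e-9)
    expect_true(all(c(d$vacant, d$overlapped, d$solo) >= -1e-12))
    g <- grid_decompose(A, B)
    expect_equal(d$overlapped, unname(g["overlapped"]), tolerance = 2e-3)
    expect_equal(d$solo, unname(g["solo"]), tolerance = 4e-3)
  }
})

test_that("shuffle_gaps preserves songs and window and permutes gaps", {
  set.seed(111)
  X <- random_timeline("x", c(0, 60), 7)
  d0 <- sort(X$intervals[, 2L] - X$intervals[, 1L])
  for (rep in 1:50) {
    S <- shuffle_gaps(X)
    expect_equal(S$window, X$window)
    expect_equal(timeline_singing_time(S), timeline_singing_time(X),
                 tolerance = 1e-9)
    expect_equal(nrow(S$intervals), nrow(X$intervals))
    expect_equal(S$intervals[, 2L] - S$intervals[, 1L],
                 X$intervals[, 2L] - X$intervals[, 1L], tolerance = 1e-9)
    expect_equal(sort(timeline_gaps(S)), sort(timeline_gaps(X)),
                 tolerance = 1e-9)
  }
  # single song with gaps (2, 5): only two arrangements exist
  X1 <- song_timeline("x", rbind(c(2, 5)), c(0, 10))
  seen <- replicate(50, shuffle_gaps(X1)$intervals[1L, 1L])
  expect_true(all(seen %in% c(2, 5)))
  expect_equal(sort(unique(seen)), c(2, 5))
  # zero-gap timeline: one song filling the window is a fixed point
  Xf <- song_timeline("x", rbind(c(0, 10)), c(0, 10))
  expect_equal(shuffle_gaps(Xf)$intervals, Xf$intervals)
})

test_that("gap orderings are uniform (chi-squared at alpha = .01)", {
  # 2 songs -> 3 gaps -> 6 orderings
  X <- song_timeline("x", rbind(c(1, 2), c(5, 6)), c(0, 10))
  set.seed(121)
  n <- 10000L
  key <- replicate(n, paste(signif(timeline_gaps(shuffle_gaps(X)), 10),
                            collapse = "|"))
  counts <- table(key)
  expect_equal(length(counts), 6L)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("active_overlap_duration: hand cases and brute-force oracle", {
  w <- c(0, 10)
  X <- song_timeline("x", rbind(c(2, 5)), w)
  Y <- song_timeline("y", rbind(c(1, 3)), w)
  expect_equal(active_overlap_duration(X, Y), 1)
  expect_equal(active_overlap_duration(Y, X), 0)
  D1 <- song_timeline("x", rbind(c(0, 2)), w)
  D2 <- song_timeline("y", rbind(c(5, 7)), w)
  expect_equal(active_overlap_duration(D1, D2), 0)

  set.seed(131)
  for (rep in 1:25) {
    A <- random_timeline("a", c(0, 60), sample(1:10, 1))
    B <- random_timeline("b", c(0, 60), sample(1:10, 1))
    expect_equal(active_overlap_duration(A, B), grid_active_overlap(A, B),
                 tolerance = 3e-3)
    # each direction alone never exceeds the total co-singing time, and
    # onset-song attribution never exceeds union attribution
    tot <- decompose_pair(A, B)$overlapped
    expect_lte(active_overlap_duration(A, B), tot + 1e-9)
    expect_lte(active_overlap_duration(A, B, "onset_song"),
               active_overlap_duration(A, B) + 1e-12)
    # onset-song attribution partitions the overlap: directions never
    # jointly exceed it
    expect_lte(active_overlap_duration(A, B, "onset_song") +
                 active_overlap_duration(B, A, "onset_song"), tot + 1e-9)
  }
})

test_that("directed onset-song overlaps sum to the total when all onsets are inside", {
  w <- c(0, 20)
  # Y sings [2, 10); X starts at 4 inside Y; Y's second song starts inside X
  X <- song_timeline("x", rbind(c(4, 14)), w)
  Y <- song_timeline("y", rbind(c(2, 10), c(12, 16)), w)
  tot <- decompose_pair(X, Y)$overlapped
  expect_equal(active_overlap_duration(X, Y, "onset_song") +
                 active_overlap_duration(Y, X, "onset_song"),
               tot, tolerance = 1e-9)
  # union attribution double-counts the co-singing inside Y's second song
  expect_equal(active_overlap_duration(X, Y) + active_overlap_duration(Y, X),
               tot + 2, tolerance = 1e-9)
})

test_that("solo_test flags X = Y as active overlap and is deterministic", {
  w <- c(0, 60)
  X <- song_timeline("x", rbind(c(2, 6), c(10, 13), c(20, 24), c(30, 37),
                                c(41, 44), c(50, 53)), w)
  r1 <- solo_test(X, X, n_rand = 400, seed = 5)
  expect_equal(r1$observed, 0)
  expect_gt(r1$p_value, 0.975)   # observed solo is the minimum possible
  r2 <- solo_test(X, X, n_rand = 400, seed = 5)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$null_values, r2$null_values)
})

test_that("asymmetric test reports zero observed for a hard avoider", {
  sim <- simulate_timelines(
    list(bird_spec("drv", c(30, 10), gap_mean = 3),
         bird_spec("avd", c(0, 40), gap_mean = 3)),
    interaction_spec("avoider", suppression = 0,
                     targets = list(c("avd", "drv"))),
    c(0, 600), seed = 33)
  r <- asymmetric_overlap_test(sim$timelines$avd, sim$timelines$drv,
                               n_rand = 500, seed = 7)
  expect_equal(r$observed, 0)
  expect_lt(r$p_value, 0.025)
})

test_that("Monte-Carlo p matches exact enumeration on few-gap timelines", {
  w <- c(0, 30)
  X <- song_timeline("x", rbind(c(1, 5), c(9, 12), c(16, 22), c(26, 28)), w)
  Y <- song_timeline("y", rbind(c(3, 8), c(13, 18), c(24, 27)), w)
  gx <- timeline_gaps(X)   # 5 gaps
  gy <- timeline_gaps(Y)   # 4 gaps
  px <- all_perms(length(gx))
  py <- all_perms(length(gy))

  # exact solo test p: all pairs of gap orderings of X and Y
  obs_solo <- decompose_pair(X, Y)$solo
  solos <- outer(seq_len(nrow(px)), seq_len(nrow(py)),
                 Vectorize(function(i, j) {
                   decompose_pair(timeline_from_gaps(X, gx[px[i, ]]),
                                  timeline_from_gaps(Y, gy[py[j, ]]))$solo
                 }))
  p_exact_solo <- mean(solos > obs_solo)
  n_rand <- 2000L
  mc <- solo_test(X, Y, n_rand = n_rand, seed = 17)
  band <- 3 * sqrt(p_exact_solo * (1 - p_exact_solo) / n_rand)
  expect_lt(abs(mc$p_value - p_exact_solo), band + 1e-12)

  # exact asymmetric test p: orderings of X's gaps only
  obs_ao <- active_overlap_duration(X, Y)
  aos <- vapply(seq_len(nrow(px)), function(i) {
    active_overlap_duration(timeline_from_gaps(X, gx[px[i, ]]), Y)
  }, 0)
  p_exact_ao <- mean(aos < obs_ao)
  mca <- asymmetric_overlap_test(X, Y, n_rand = n_rand, seed = 19)
  band_a <- 3 * sqrt(p_exact_ao * (1 - p_exact_ao) / n_rand)
  expect_lt(abs(mca$p_value - p_exact_ao), band_a + 1e-12)
})

test_that("transfer entropy: closed forms, oracle, and invariances", {
  # constant sink -> exactly zero
  set.seed(141)
  Yb <- binary_series(rbinom(300, 1, 0.5))
  expect_identical(transfer_entropy(binary_series(rep(1L, 300)), Yb), 0)

  # X_{t+1} = Y_t with fair i.i.d. Y: TE -> 1 bit
  y <- rbinom(10000, 1, 0.5)
  x <- c(0L, y[-length(y)])
  te <- transfer_entropy(binary_series(x), binary_series(y))
  expect_lt(abs(te - 1), 0.02)

  # exhaustive-outcome oracle on short series, several k and l
  set.seed(151)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    x <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, 0.5)
    k <- sample(1:2, 1)
    l <- sample(1:2, 1)
    got <- transfer_entropy(binary_series(x), binary_series(y), k, l)
    expect_lt(abs(got - te_oracle(x, y, k, l)), 1e-12)
    expect_gte(got, 0)
    # invariant under joint 0<->1 relabeling
    flip <- transfer_entropy(binary_series(1L - x), binary_series(1L - y),
                             k, l)
    expect_equal(got, flip, tolerance = 1e-12)
  }
  expect_error(transfer_entropy(binary_series(c(0L, 1L)),
                                binary_series(c(0L, 1L)), k = 2L),
               "too short")
})

test_that("te_test is deterministic under a seed and directional on avoiders", {
  sim <- simulate_timelines(
    list(bird_spec("drv", c(30, 10), gap_mean = 4),
         bird_spec("avd", c(0, 40), gap_mean = 4)),
    interaction_spec("avoider", suppression = 0,
                     targets = list(c("avd", "drv"))),
    c(0, 600), seed = 55)
  r1 <- te_test(sink = sim$timelines$avd, source = sim$timelines$drv,
                n_rand = 300, seed = 9)
  r2 <- te_test(sink = sim$timelines$avd, source = sim$timelines$drv,
                n_rand = 300, seed = 9)
  expect_equal(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05)    # driver -> avoider influence detected
})

test_that("bootstrap_effect: degenerate, null, and enumeration behavior", {
  # all sessions share effect 3.0
  v <- data.frame(observed = c(1, 2, 5), expected = c(4, 5, 8))
  b <- bootstrap_effect(v, "expected_minus_observed", n_boot = 500, seed = 3)
  expect_equal(b$mean, 3)
  expect_equal(unname(b$ci95), c(3, 3))
  expect_equal(b$p_value, 0)
  expect_error(bootstrap_effect(v[1, , drop = FALSE]), "at least 2")

  # 3-session toy: resample means match exhaustive enumeration probabilities
  v3 <- data.frame(observed = c(0, 0, 0), expected = c(1, 2, 4))
  b3 <- bootstrap_effect(v3, "expected_minus_observed", n_boot = 20000,
                         seed = 11)
  e <- c(1, 2, 4)
  enum <- expand.grid(i = 1:3, j = 1:3, k = 1:3)
  enum_means <- (e[enum$i] + e[enum$j] + e[enum$k]) / 3
  expect_equal(b3$mean, mean(enum_means), tolerance = 0.02)
  expect_equal(unname(b3$ci95[1L]),
               unname(stats::quantile(enum_means, 0.025)), tolerance = 0.35)

  # ratio-difference effect uses the four-column layout
  vr <- data.frame(observed_a = c(2, 3, 4), expected_a = c(2, 3, 4),
                   observed_b = c(1, 1, 1), expected_b = c(2, 2, 2))
  br <- bootstrap_effect(vr, "obs_exp_ratio_diff", n_boot = 500, seed = 13)
  expect_equal(br$mean, 0.5, tolerance = 1e-9)

  # symmetric-about-zero effects are rarely declared significant
  set.seed(161)
  hits <- 0L
  for (rep in 1:100) {
    e <- sample(c(-2, -1, 1, 2))
    vv <- data.frame(observed = rep(0, 4), expected = e)
    bb <- bootstrap_effect(vv, "expected_minus_observed", n_boot = 400,
                           seed = rep)
    if (bb$p_value <= 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})

test_that("Monte-Carlo tests reproduce exactly under fixed seeds", {
  set.seed(171)
  A <- random_timeline("a", c(0, 80), 6)
  B <- random_timeline("b", c(0, 80), 8)
  expect_identical(solo_test(A, B, 200, seed = 2)$null_values,
                   solo_test(A, B, 200, seed = 2)$null_values)
  expect_identical(asymmetric_overlap_test(A, B, 200, seed = 2)$null_values,
                   asymmetric_overlap_test(A, B, 200, seed = 2)$null_values)
})
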