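# Synthetic soundscape: ground-truth song timelines with controllable
# interaction structure, plus the noisy per-array DOA events those songs
# would produce. Every downstream stage of the pipeline can therefore be
# exercised and validated with no field recordings.
#
# The generative model per bird is an alternating renewal process:
# lognormal song durations, exponential gaps (constant onset hazard). The
# interaction mechanism modulates a waiting bird's onset hazard while any
# attended bird sings; ongoing songs are never truncated, so the song-length
# distribution is independent of the interaction. Simulation runs on a
# discrete 0.05 s grid, ten times finer than the 0.5 s analysis bin.

SIM_DT <- 0.05

#' Specification of one simulated bird
#'
#' @param individual_id character scalar.
#' @param post_xy song-post location `(x, y)` in meters.
#' @param song_meanlog,song_sdlog lognormal parameters of song duration
#'   (seconds). Defaults give median ~3 s songs, typical of a loud
#'   territorial warbler.
#' @param gap_mean mean of the exponential nonsinging gap (seconds).
#' @param movement_radius each song's true location is scattered uniformly in
#'   a disk of this radius around the post (meters); 0 = stationary.
#' @return object of class `bird_spec`.
#' @export
bird_spec <- function(individual_id, post_xy,
                      song_meanlog = log(3), song_sdlog = 0.4,
                      gap_mean = 5, movement_radius = 0) {
  stopifnot(length(post_xy) == 2L, song_sdlog > 0, gap_mean > 0,
            movement_radius >= 0)
  structure(list(individual_id = individual_id,
                 post_xy = as.numeric(post_xy),
                 song_meanlog = song_meanlog, song_sdlog = song_sdlog,
                 gap_mean = gap_mean, movement_radius = movement_radius),
            class = "bird_spec")
}

#' Specification of the interaction structure
#'
#' `suppression` multiplies a waiting bird's song-onset hazard while any bird
#' it attends to is singing: 0 is a hard avoider (never starts during the
#' other's song), 1 is independence, >1 is an active overlapper. `targets`
#' lists directed pairs `(attender, attended)`.
#'
#' @param mode `"independent"`, `"avoider"`, or `"overlapper"`.
#' @param suppression nonnegative hazard multiplier; must be 1 when
#'   `mode == "independent"`.
#' @param targets list of character pairs `c(attender, attended)`.
#' @return object of class `interaction_spec`.
#' @export
interaction_spec <- function(mode = c("independent", "avoider", "overlapper"),
                             suppression = 1, targets = list()) {
  mode <- match.arg(mode)
  stopifnot(suppression >= 0)
  if (mode == "independent" && suppression != 1) {
    stop("independent mode requires suppression = 1")
  }
  if (mode == "avoider" && suppression >= 1) {
    stop("avoider mode requires suppression < 1")
  }
  if (mode == "overlapper" && suppression <= 1) {
    stop("overlapper mode requires suppression > 1")
  }
  structure(list(mode = mode, suppression = suppression, targets = targets),
            class = "interaction_spec")
}

#' Specification of observation noise for DOA generation
#'
#' @param azimuth_sd s.d. of i.i.d. Gaussian noise on each track frame's
#'   azimuth (degrees).
#' @param begin_jitter_max detected begins are delayed by `U(0, max)` seconds,
#'   emulating missed quiet introductory notes.
#' @param end_jitter_sd Gaussian jitter of detected ends (seconds); ends of
#'   loud terminal notes are detected well, so this is small.
#' @param miss_prob probability that a given array misses a given song.
#' @param clutter_rate spurious events per minute per array.
#' @param clutter_dur length-2 range of clutter event durations (seconds).
#' @return object of class `observation_noise`.
#' @export
observation_noise <- function(azimuth_sd = 2, begin_jitter_max = 2,
                              end_jitter_sd = 0.3, miss_prob = 0.05,
                              clutter_rate = 1, clutter_dur = c(0.5, 3)) {
  stopifnot(azimuth_sd >= 0, begin_jitter_max >= 0, end_jitter_sd >= 0,
            miss_prob >= 0, miss_prob <= 1, clutter_rate >= 0,
            length(clutter_dur) == 2L, all(clutter_dur >= 0))
  structure(list(azimuth_sd = azimuth_sd, begin_jitter_max = begin_jitter_max,
                 end_jitter_sd = end_jitter_sd, miss_prob = miss_prob,
                 clutter_rate = clutter_rate,
                 clutter_dur = as.numeric(clutter_dur)),
            class = "observation_noise")
}

#' Simulate ground-truth song timelines
#'
#' Each bird alternates exponential gaps and lognormal songs on a 0.05 s grid.
#' While any attended bird is singing, a waiting bird's per-step onset
#' probability is multiplied by the interaction's `suppression`; ongoing songs
#' are never cut short. Each song gets a true location scattered uniformly in
#' a disk of `movement_radius` around the bird's post.
#'
#' @param birds list of `bird_spec`.
#' @param interaction an `interaction_spec`.
#' @param window analysis window `(t0, t1)` seconds.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `timelines` (named list of `song_timeline`) and `songs`
#'   (data.frame `individual,t_begin,t_end,x,y`, one row per song).
#' @examples
#' birds <- list(bird_spec("A", c(30, 10)), bird_spec("B", c(70, 45)))
#' sim <- simulate_timelines(birds, interaction_spec("independent"),
#'                           window = c(0, 600), seed = 1)
#' sapply(sim$timelines, timeline_duty_cycle)
#' @export
simulate_timelines <- function(birds, interaction, window, seed) {
  stopifnot(all(vapply(birds, inherits, TRUE, "bird_spec")),
            inherits(interaction, "interaction_spec"),
            length(window) == 2L)
  ids <- vapply(birds, function(b) b$individual_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate individual_id among birds")
  }
  n_steps <- max(0L, floor((window[2L] - window[1L]) / SIM_DT + 1e-9))
  nb <- length(birds)
  # attends[i, j] = TRUE if bird i modulates its onsets by bird j's singing
  attends <- matrix(FALSE, nb, nb, dimnames = list(ids, ids))
  for (p in interaction$targets) {
    if (!all(p %in% ids)) {
      stop("interaction target references unknown individual: ",
           paste(p, collapse = " -> "))
    }
    attends[p[1L], p[2L]] <- TRUE
  }
  sup <- interaction$suppression

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  base_p <- vapply(birds, function(b) -expm1(-SIM_DT / b$gap_mean), 0)
  # deterministic sub-step phase per bird: onsets of different birds never
  # coincide, so "began while the other was singing" is unambiguous under
  # half-open interval semantics; birds are evaluated in phase order and see
  # same-step earlier onsets as already active
  phase <- (seq_len(nb) - 1L) * SIM_DT / (2 * nb)
  singing_left <- rep(0L, nb)       # remaining steps of current song
  songs <- vector("list", nb)
  for (i in seq_len(nb)) songs[[i]] <- list()
  cur_start <- rep(NA_real_, nb)
  cur_end <- rep(NA_real_, nb)
  if (n_steps > 0L) {
    for (s in seq_len(n_steps)) {
      t_now <- window[1L] + (s - 1L) * SIM_DT
      active <- singing_left > 0L
      for (i in seq_len(nb)) {
        if (active[i]) next
        p <- base_p[i]
        if (any(attends[i, ] & active)) {
          p <- min(1, p * sup)
        }
        if (stats::runif(1) < p) {
          dur <- stats::rlnorm(1, birds[[i]]$song_meanlog,
                               birds[[i]]$song_sdlog)
          n_song <- max(1L, round(dur / SIM_DT))
          singing_left[i] <- n_song
          cur_start[i] <- t_now + phase[i]
          cur_end[i] <- cur_start[i] + n_song * SIM_DT
          active[i] <- TRUE
        }
      }
      ended <- singing_left == 1L
      singing_left[singing_left > 0L] <- singing_left[singing_left > 0L] - 1L
      for (i in which(ended)) {
        songs[[i]][[length(songs[[i]]) + 1L]] <- c(cur_start[i], cur_end[i])
      }
    }
    # close songs still running at the window end
    for (i in which(singing_left > 0L)) {
      songs[[i]][[length(songs[[i]]) + 1L]] <-
        c(cur_start[i], min(cur_end[i], window[2L]))
    }
  }

  song_rows <- list()
  timelines <- vector("list", nb)
  names(timelines) <- ids
  for (i in seq_len(nb)) {
    iv <- if (length(songs[[i]])) do.call(rbind, songs[[i]]) else NULL
    ns <- if (is.null(iv)) 0L else nrow(iv)
    if (ns) {
      r <- birds[[i]]$movement_radius * sqrt(stats::runif(ns))
      th <- stats::runif(ns, 0, 2 * pi)
      song_rows[[i]] <- data.frame(
        individual = ids[i],
        t_begin = iv[, 1L], t_end = pmin(iv[, 2L], window[2L]),
        x = birds[[i]]$post_xy[1L] + r * cos(th),
        y = birds[[i]]$post_xy[2L] + r * sin(th),
        stringsAsFactors = FALSE
      )
    }
    timelines[[i]] <- song_timeline(ids[i], iv, window = window)
  }
  songs_df <- if (length(song_rows)) {
    out <- do.call(rbind, song_rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(individual = character(0), t_begin = numeric(0),
               t_end = numeric(0), x = numeric(0), y = numeric(0),
               stringsAsFactors = FALSE)
  }
  list(timelines = timelines, songs = songs_df)
}

#' Generate noisy per-array DOA events from simulated songs
#'
#' For each (song, array) pair not missed, emits one DOA event whose begin is
#' delayed by `U(0, begin_jitter_max)`, whose end carries Gaussian jitter plus
#' a fixed +0.6 s silence-detection tail (which spatial localization later
#' removes), and whose azimuth track is sampled at `dt` with i.i.d. Gaussian
#' noise around the true bearing from the array to the song's location.
#' Clutter events arrive as a Poisson process per array with uniform azimuths,
#' independent across arrays, so clutter rarely triangulates consistently.
#'
#' @param songs data.frame `individual,t_begin,t_end,x,y` as produced by
#'   [simulate_timelines()].
#' @param geometry an `array_geometry`.
#' @param noise an `observation_noise`.
#' @param window recording window `(t0, t1)` (bounds clutter arrivals).
#' @param seed integer seed.
#' @param dt azimuth track frame step (seconds), default 0.2.
#' @param end_tail fixed silence-detection tail added to detected ends
#'   (seconds), default 0.6.
#' @return a `doa_events` table.
#' @export
generate_doa_streams <- function(songs, geometry, noise, window, seed,
                                 dt = 0.2, end_tail = 0.6) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(noise, "observation_noise"), nrow(geometry) >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  rows <- list()
  make_track <- function(array_id, event_id, tb, te, bearing_fun) {
    te <- max(te, tb + dt)              # at least one frame
    tt <- seq(tb, te, by = dt)
    az <- (bearing_fun(length(tt))) %% 360
    data.frame(array_id = array_id, event_id = event_id, t = tt,
               azimuth = az, t_begin = tb, t_end = te,
               stringsAsFactors = FALSE)
  }

  for (a in seq_len(nrow(geometry))) {
    aid <- geometry$array_id[a]
    ax <- geometry$x[a]
    ay <- geometry$y[a]
    if (nrow(songs)) {
      for (k in seq_len(nrow(songs))) {
        if (stats::runif(1) < noise$miss_prob) next
        tb <- songs$t_begin[k] + stats::runif(1, 0, noise$begin_jitter_max)
        te <- songs$t_end[k] + stats::rnorm(1, 0, noise$end_jitter_sd) +
          end_tail
        true_bearing <- atan2(songs$y[k] - ay, songs$x[k] - ax) * 180 / pi
        eid <- sprintf("%s_%04d", songs$individual[k], k)
        rows[[length(rows) + 1L]] <- make_track(
          aid, eid, tb, te,
          function(n) true_bearing + stats::rnorm(n, 0, noise$azimuth_sd))
      }
    }
    n_clutter <- stats::rpois(1, noise$clutter_rate *
                                (window[2L] - window[1L]) / 60)
    if (n_clutter > 0L) {
      for (k in seq_len(n_clutter)) {
        tb <- stats::runif(1, window[1L], window[2L])
        te <- tb + stats::runif(1, noise$clutter_dur[1L],
                                noise$clutter_dur[2L])
        az0 <- stats::runif(1, 0, 360)
        rows[[length(rows) + 1L]] <- make_track(
          aid, sprintf("clutter_%s_%03d", aid, k), tb, te,
          function(n) az0 + stats::rnorm(n, 0, noise$azimuth_sd))
      }
    }
  }
  df <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(array_id = character(0), event_id = character(0),
               t = numeric(0), azimuth = numeric(0), t_begin = numeric(0),
               t_end = numeric(0), stringsAsFactors = FALSE)
  }
  doa_events(df)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
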