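# End-to-end orchestration: simulate -> localize -> timelines -> evaluate ->
# interact, as one seeded, configured, logged run. Every stage writes a
# self-describing delimited table so each stage is also runnable standalone
# on the previous stage's files.

#' Run configuration
#'
#' Validates and normalizes a run configuration (an R list or a JSON file).
#' Top-level fields:
#' \describe{
#'   \item{seed}{integer; drives every random stage.}
#'   \item{window}{recording window `(t0, t1)` seconds.}
#'   \item{scenario}{synthetic scenario: `birds` (list of [bird_spec()]
#'     fields), `interaction` ([interaction_spec()] fields), `noise`
#'     ([observation_noise()] fields).}
#'   \item{geometry}{list of `(array_id, x, y)` or a geometry config path.}
#'   \item{localization}{[localization_params()] fields (optional).}
#'   \item{posts}{list of `(individual_id, center_xy, radius)`; defaults to
#'     each bird's post with a 15 m radius.}
#'   \item{analysis_windows}{list of `(t0, t1)` bouts, non-empty and
#'     non-overlapping; defaults to the whole window.}
#'   \item{te}{`k`, `l`, `bin` (defaults 1, 1, 0.5).}
#'   \item{n_rand, n_boot}{randomization/bootstrap draws (defaults 10000).}
#' }
#'
#' @param config list or path to a JSON config file.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) {
    stop("config$seed is required")
  }
  if (is.null(config$window) || length(config$window) != 2L) {
    stop("config$window must be (t0, t1)")
  }
  config$window <- as.numeric(config$window)
  if (diff(config$window) <= 0) {
    stop("config$window must have positive length")
  }
  if (is.null(config$scenario)) {
    stop("config$scenario is required (synthetic runs only)")
  }
  if (is.null(config$analysis_windows)) {
    config$analysis_windows <- list(config$window)
  }
  aw <- lapply(config$analysis_windows, as.numeric)
  if (!length(aw)) {
    stop("analysis_windows must be non-empty")
  }
  for (w in aw) {
    if (length(w) != 2L || diff(w) <= 0) {
      stop("each analysis window must be (t0, t1) with t0 < t1")
    }
  }
  ord <- order(vapply(aw, `[`, 0, 1L))
  aw <- aw[ord]
  if (length(aw) > 1L) {
    b <- vapply(aw, `[`, 0, 1L)
    e <- vapply(aw, `[`, 0, 2L)
    if (any(b[-1L] < e[-length(e)])) {
      stop("analysis windows must not overlap")
    }
  }
  config$analysis_windows <- aw
  if (is.null(config$te)) {
    config$te <- list()
  }
  config$te <- utils::modifyList(list(k = 1L, l = 1L, bin = 0.5), config$te)
  if (is.null(config$n_rand)) config$n_rand <- 10000L
  if (is.null(config$n_boot)) config$n_boot <- 10000L
  class(config) <- c("run_config", "list")
  config
}

config_birds <- function(config) {
  lapply(config$scenario$birds, function(b) {
    do.call(bird_spec, b)
  })
}

config_geometry <- function(config) {
  g <- config$geometry
  if (is.character(g)) {
    return(read_geometry(g))
  }
  array_geometry(vapply(g, function(a) as.character(a$array_id), ""),
                 vapply(g, function(a) as.numeric(a$x), 0),
                 vapply(g, function(a) as.numeric(a$y), 0))
}

config_posts <- function(config, birds) {
  if (!is.null(config$posts)) {
    lapply(config$posts, function(p) {
      song_post(p$individual_id, as.numeric(p$center_xy), p$radius)
    })
  } else {
    lapply(birds, function(b) song_post(b$individual_id, b$post_xy, 15))
  }
}

#' Run the full pipeline
#'
#' Simulates a soundscape, triangulates sources, assembles per-individual
#' timelines, scores them against the simulated ground truth, and runs the
#' interaction analyses per bout. Identical config and seed give identical
#' outputs. All outputs land in `out_dir`:
#' `songs_true.csv`, `doa_events.csv`, `sources.csv`, `timelines.csv`,
#' `evaluation.csv`, `partitioning.csv` (vacant/overlapped/solo + solo test),
#' `asymmetric_overlap.csv`, `transfer_entropy.csv`, `bootstrap.csv`,
#' `manifest.json`.
#'
#' @param config a `run_config`, list, or JSON path.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return the run manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  config <- run_config(config)
  t_start <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) {
    if (!quiet) message(sprintf(...))
  }
  stage_times <- c()
  timed <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  seed <- as.integer(config$seed)
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, name)
    path
  }

  # stage 1: simulate ground truth + DOA streams
  birds <- config_birds(config)
  inter <- do.call(interaction_spec, config$scenario$interaction)
  noise <- do.call(observation_noise,
                   if (is.null(config$scenario$noise)) list()
                   else config$scenario$noise)
  geom <- config_geometry(config)
  sim <- timed("simulate",
               simulate_timelines(birds, inter, config$window, seed = seed))
  emit(sim$songs, "songs_true.csv")
  doa <- timed("doa", generate_doa_streams(sim$songs, geom, noise,
                                           config$window, seed = seed + 1L))
  emit(doa, "doa_events.csv")
  log_msg("simulate: %d birds, %d true songs, %d DOA rows",
          length(birds), nrow(sim$songs), nrow(doa))

  # stage 2: localize
  lp <- do.call(localization_params,
                if (is.null(config$localization)) list()
                else config$localization)
  sources <- timed("localize", triangulate(doa, geom, lp))
  emit(sources, "sources.csv")
  log_msg("localize: %d sources accepted", nrow(sources))

  # stage 3: timelines via song posts
  posts <- config_posts(config, birds)
  asn <- timed("timelines", assign_to_posts(sources, posts, config$window))
  tl_rows <- do.call(rbind, lapply(asn$timelines, function(tl) {
    if (nrow(tl$intervals) == 0L) {
      return(NULL)
    }
    data.frame(individual = tl$individual_id, t_begin = tl$intervals[, 1L],
               t_end = tl$intervals[, 2L], stringsAsFactors = FALSE)
  }))
  if (is.null(tl_rows)) {
    tl_rows <- data.frame(individual = character(0), t_begin = numeric(0),
                          t_end = numeric(0))
  }
  emit(tl_rows, "timelines.csv")
  log_msg("timelines: %d sources assigned, %d unassigned, %s dropped",
          nrow(sources) - nrow(asn$unassigned), nrow(asn$unassigned),
          paste(asn$dropped, collapse = "/"))

  # stage 4: evaluate localized vs true timelines
  eval_rows <- do.call(rbind, lapply(names(asn$timelines), function(id) {
    ev <- evaluate_timeline(asn$timelines[[id]], sim$timelines[[id]])
    data.frame(individual = id, tp = ev$tp, fp = ev$fp, tn = ev$tn,
               fn = ev$fn, accuracy = ev$accuracy, tpr = ev$tpr,
               fpr = ev$fpr, stringsAsFactors = FALSE)
  }))
  eval_path <- timed("evaluate", emit(eval_rows, "evaluation.csv"))
  log_msg("evaluate: accuracy %s",
          paste(sprintf("%s=%.3f", eval_rows$individual, eval_rows$accuracy),
                collapse = ", "))

  # stage 5: interaction analyses per bout, on the localized timelines of the
  # first two posts
  pair <- if (!is.null(config$pair)) {
    as.character(config$pair)
  } else {
    vapply(posts[1:2], function(p) p$individual_id, "")
  }
  interact <- timed("interact", {
    part_rows <- list()
    asym_rows <- list()
    te_rows <- list()
    for (s in seq_along(config$analysis_windows)) {
      w <- config$analysis_windows[[s]]
      Xw <- song_timeline(pair[1L], asn$timelines[[pair[1L]]]$intervals, w)
      Yw <- song_timeline(pair[2L], asn$timelines[[pair[2L]]]$intervals, w)
      dec <- decompose_pair(Xw, Yw)
      st <- solo_test(Xw, Yw, n_rand = config$n_rand, seed = seed + 100L + s)
      part_rows[[s]] <- data.frame(
        session = s, duration = dec$duration, vacant = dec$vacant,
        overlapped = dec$overlapped, solo = dec$solo,
        solo_rnd = st$expected, p = st$p_value)
      for (d in 1:2) {
        tgt <- if (d == 1L) Yw else Xw    # target = potential avoider
        ref <- if (d == 1L) Xw else Yw
        at <- asymmetric_overlap_test(tgt, ref, n_rand = config$n_rand,
                                      seed = seed + 200L + 10L * s + d)
        asym_rows[[length(asym_rows) + 1L]] <- data.frame(
          session = s, reference = ref$individual_id,
          target = tgt$individual_id, observed = at$observed,
          expected = at$expected, p = at$p_value)
        tt <- te_test(sink = tgt, source = ref, k = config$te$k,
                      l = config$te$l, bin = config$te$bin,
                      n_rand = config$n_rand, seed = seed + 300L + 10L * s + d)
        te_rows[[length(te_rows) + 1L]] <- data.frame(
          session = s, source = ref$individual_id, sink = tgt$individual_id,
          te = tt$observed, te_rnd = tt$expected, p = tt$p_value)
      }
    }
    list(part = do.call(rbind, part_rows), asym = do.call(rbind, asym_rows),
         te = do.call(rbind, te_rows))
  })
  emit(interact$part, "partitioning.csv")
  emit(interact$asym, "asymmetric_overlap.csv")
  emit(interact$te, "transfer_entropy.csv")
  log_msg("interact: %d bouts analyzed", nrow(interact$part))

  boot_rows <- NULL
  if (length(config$analysis_windows) >= 2L) {
    boot_rows <- do.call(rbind, lapply(unique(interact$asym$target),
                                       function(id) {
      v <- interact$asym[interact$asym$target == id, ]
      b <- bootstrap_effect(v, "expected_minus_observed",
                            n_boot = config$n_boot, seed = seed + 400L)
      data.frame(effect = "expected_minus_observed", individual = id,
                 mean = b$mean, ci_lo = b$ci95[1L], ci_hi = b$ci95[2L],
                 p = b$p_value, stringsAsFactors = FALSE)
    }))
    te_boot <- do.call(rbind, lapply(unique(interact$te$sink), function(id) {
      v <- interact$te[interact$te$sink == id, ]
      names(v)[names(v) == "te"] <- "observed"
      names(v)[names(v) == "te_rnd"] <- "expected"
      b <- bootstrap_effect(v, "te_minus_ternd", n_boot = config$n_boot,
                            seed = seed + 401L)
      data.frame(effect = "te_minus_ternd", individual = id, mean = b$mean,
                 ci_lo = b$ci95[1L], ci_hi = b$ci95[2L], p = b$p_value,
                 stringsAsFactors = FALSE)
    }))
    boot_rows <- rbind(boot_rows, te_boot)
    emit(boot_rows, "bootstrap.csv")
  }

  config_path <- file.path(out_dir, "config.json")
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, pretty = 2L), config_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("songscape")),
    seed = seed,
    config_md5 = unname(tools::md5sum(config_path)),
    outputs = outputs,
    stage_seconds = as.list(stage_times),
    total_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = 2L), tmp)
  file.rename(tmp, manifest_path)
  invisible(manifest)
}
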