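# Spatial localization of songs from multi-array DOA events.
#
# At the heart is bearing-only triangulation: each array's DOA defines a half
# line from the array toward the sound; a consistent triple of events (one
# per array) yields three pairwise intersections whose centroid is the
# estimated 2D location. Spatiotemporal gates reject triples built from
# different sounds: all three pairwise intersection distances must be <= R,
# all begin times within DB of each other, all end times within DE. DB is
# large because songs open with quiet introductory notes that arrays may miss
# by different amounts; DE is small because the loud terminal notes give a
# sharp, consistent end. The accepted source's duration is taken from the
# member event of the array nearest the centroid (the cleanest recording),
# minus a fixed end correction for the silence-detection tail.

#' Localization parameters
#'
#' @param DT DOA frame step (seconds).
#' @param R maximum pairwise distance among the three ray intersections
#'   (meters).
#' @param DB maximum spread of member-event begin times (seconds).
#' @param DE maximum spread of member-event end times (seconds).
#' @param end_correction seconds subtracted from the accepted source's end,
#'   compensating the detector's trailing-silence requirement.
#' @return object of class `localization_params`.
#' @export
localization_params <- function(DT = 0.2, R = 15, DB = 6.0, DE = 1.0,
                                end_correction = 0.6) {
  stopifnot(DT > 0, R > 0, DB > 0, DE > 0, end_correction > 0)
  structure(list(DT = DT, R = R, DB = DB, DE = DE,
                 end_correction = end_correction),
            class = "localization_params")
}

#' Intersect two half lines
#'
#' Each half line starts at `origin` and extends toward `azimuth` (degrees,
#' math convention: counterclockwise from +x). Returns the unique point lying
#' on both half lines (non-negative ray parameter on both), or `NULL` when
#' the rays are parallel (within 1e-9 rad) or the line intersection falls
#' behind either origin.
#'
#' @param origin1,origin2 numeric length-2 `(x, y)` in meters.
#' @param azimuth1,azimuth2 degrees.
#' @return numeric length-2 point, or `NULL`.
#' @examples
#' intersect_rays(c(0, 0), 0, c(5, -5), 90)  # c(5, 0)
#' intersect_rays(c(0, 0), 0, c(5, 5), 90)   # NULL: second ray points away
#' @export
intersect_rays <- function(origin1, azimuth1, origin2, azimuth2) {
  a1 <- azimuth1 * pi / 180
  a2 <- azimuth2 * pi / 180
  u1 <- c(cos(a1), sin(a1))
  u2 <- c(cos(a2), sin(a2))
  det <- u1[1L] * u2[2L] - u1[2L] * u2[1L]   # sin of the angle between rays
  if (abs(det) < 1e-9) {
    return(NULL)
  }
  d <- origin2 - origin1
  t1 <- (d[1L] * u2[2L] - d[2L] * u2[1L]) / det
  t2 <- (d[1L] * u1[2L] - d[2L] * u1[1L]) / det
  if (t1 < 0 || t2 < 0) {
    return(NULL)
  }
  origin1 + t1 * u1
}

#' Triangulate localized sources from per-array DOA events
#'
#' Enumerates candidate triples (one event from each of three distinct
#' arrays) whose begin times all lie within `DB` and end times within `DE` of
#' each other. Each candidate's three pairwise half-line intersections are
#' computed from the events' track-mean bearings; the candidate is rejected
#' if any intersection is missing or the maximum pairwise distance among the
#' three points exceeds `R`. Surviving candidates are processed greedily in
#' ascending maximum intersection distance (ties: earlier begin, then
#' lexicographic event ids), and each event may belong to at most one
#' accepted source. An accepted source is placed at the centroid of its three
#' intersections; its times come from the member event of the array closest
#' to the centroid, with `end_correction` subtracted from the end.
#'
#' @param events a `doa_events` table.
#' @param geometry an `array_geometry` with at least 3 arrays.
#' @param params a `localization_params`.
#' @return data.frame of class `localized_sources`: columns `x`, `y`,
#'   `t_begin`, `t_end`, `max_dist`, `max_begin_spread`, `max_end_spread`,
#'   `member_events` (semicolon-joined `array:event` ids).
#' @export
triangulate <- function(events, geometry, params = localization_params()) {
  stopifnot(inherits(events, "doa_events"),
            inherits(geometry, "array_geometry"),
            inherits(params, "localization_params"))
  if (nrow(geometry) < 3L) {
    stop("triangulation requires at least 3 arrays")
  }
  ev <- doa_event_summary(events)
  ev <- ev[ev$array_id %in% geometry$array_id, , drop = FALSE]
  empty <- data.frame(x = numeric(0), y = numeric(0), t_begin = numeric(0),
                      t_end = numeric(0), max_dist = numeric(0),
                      max_begin_spread = numeric(0),
                      max_end_spread = numeric(0),
                      member_events = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("localized_sources", "data.frame")
  if (nrow(ev) == 0L) {
    return(empty)
  }
  ev <- ev[order(ev$t_begin), , drop = FALSE]
  by_array <- split(seq_len(nrow(ev)), ev$array_id)
  arr_xy <- rbind(geometry$x, geometry$y)
  colnames(arr_xy) <- geometry$array_id

  cands <- list()
  triples <- utils::combn(sort(geometry$array_id), 3L, simplify = FALSE)
  for (tri in triples) {
    ia <- by_array[[tri[1L]]]
    ib <- by_array[[tri[2L]]]
    ic <- by_array[[tri[3L]]]
    if (is.null(ia) || is.null(ib) || is.null(ic)) next
    for (i in ia) {
      # begin gate prunes the search: |tb_i - tb_j| <= DB for all pairs
      jb <- ib[abs(ev$t_begin[ib] - ev$t_begin[i]) <= params$DB]
      if (!length(jb)) next
      jc <- ic[abs(ev$t_begin[ic] - ev$t_begin[i]) <= params$DB]
      if (!length(jc)) next
      for (j in jb) {
        kc <- jc[abs(ev$t_begin[jc] - ev$t_begin[j]) <= params$DB]
        for (k in kc) {
          idx <- c(i, j, k)
          te <- ev$t_end[idx]
          end_spread <- max(te) - min(te)
          if (end_spread > params$DE) next
          tb <- ev$t_begin[idx]
          o <- list(arr_xy[, ev$array_id[i]], arr_xy[, ev$array_id[j]],
                    arr_xy[, ev$array_id[k]])
          b <- ev$bearing[idx]
          p12 <- intersect_rays(o[[1L]], b[1L], o[[2L]], b[2L])
          if (is.null(p12)) next
          p13 <- intersect_rays(o[[1L]], b[1L], o[[3L]], b[3L])
          if (is.null(p13)) next
          p23 <- intersect_rays(o[[2L]], b[2L], o[[3L]], b[3L])
          if (is.null(p23)) next
          dmax <- max(sqrt(sum((p12 - p13)^2)), sqrt(sum((p12 - p23)^2)),
                      sqrt(sum((p13 - p23)^2)))
          if (dmax > params$R) next
          cen <- (p12 + p13 + p23) / 3
          d_arr <- vapply(o, function(xy) sqrt(sum((xy - cen)^2)), 0)
          nearest <- idx[which.min(d_arr)]
          cands[[length(cands) + 1L]] <- list(
            idx = idx, cen = cen, dmax = dmax,
            begin_spread = max(tb) - min(tb), end_spread = end_spread,
            t_begin = ev$t_begin[nearest],
            t_end = ev$t_end[nearest] - params$end_correction,
            members = paste(ev$array_id[idx], ev$event_id[idx],
                            sep = ":", collapse = ";"),
            key = paste(sort(paste(ev$array_id[idx], ev$event_id[idx])),
                        collapse = "|")
          )
        }
      }
    }
  }
  if (!length(cands)) {
    return(empty)
  }
  ord <- order(vapply(cands, `[[`, 0, "dmax"),
               vapply(cands, `[[`, 0, "t_begin"),
               vapply(cands, `[[`, "", "key"))
  used <- rep(FALSE, nrow(ev))
  out <- list()
  for (c_ in cands[ord]) {
    if (any(used[c_$idx])) next
    if (c_$t_end <= c_$t_begin) next    # degenerate after end correction
    used[c_$idx] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      x = c_$cen[1L], y = c_$cen[2L], t_begin = c_$t_begin, t_end = c_$t_end,
      max_dist = c_$dmax, max_begin_spread = c_$begin_spread,
      max_end_spread = c_$end_spread, member_events = c_$members,
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$t_begin, res$t_end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("localized_sources", "data.frame")
  res
}

#' Read / write localized source tables
#' @param path CSV path.
#' @export
read_sources <- function(path) {
  df <- utils::read.csv(path, colClasses = c(member_events = "character"))
  class(df) <- c("localized_sources", "data.frame")
  df
}

#' @rdname read_sources
#' @param sources a `localized_sources` data.frame.
#' @export
write_sources <- function(sources, path) {
  utils::write.csv(as.data.frame(sources), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Observed-vs-localized distance analysis
#'
#' Walks each observed interval in 1 s ticks; at each tick inside the
#' interval, measures the distance from the observed location to the nearest
#' localized source active at that tick (`t_begin <= tick < t_end`). Ticks
#' with no active source are skipped. The summary restricts to distances
#' below `max_dist` (default 30 m), separating true localizations of the
#' observed bird's song from sources at other posts.
#'
#' @param observed an `annotation_set` whose records carry `x`, `y`.
#' @param sources a `localized_sources` data.frame.
#' @param tick sampling step (seconds), default 1.
#' @param max_dist summary restriction (meters), default 30.
#' @return list with `distances` (data.frame `individual,t,distance`) and
#'   `summary` (per individual plus `"all"`: n, mean, sd of distances below
#'   `max_dist`) and `histogram` (counts in 2 m bins over all distances).
#' @export
observed_localized_distances <- function(observed, sources, tick = 1.0,
                                         max_dist = 30) {
  stopifnot(inherits(observed, "annotation_set"),
            all(c("x", "y") %in% names(observed)))
  rows <- list()
  for (r in seq_len(nrow(observed))) {
    ticks <- seq(ceiling(observed$t_begin[r] / tick) * tick,
                 observed$t_end[r], by = tick)
    ticks <- ticks[ticks < observed$t_end[r]]
    for (tt in ticks) {
      act <- sources$t_begin <= tt & tt < sources$t_end
      if (!any(act)) next
      d <- sqrt((sources$x[act] - observed$x[r])^2 +
                  (sources$y[act] - observed$y[r])^2)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = observed$individual[r], t = tt, distance = min(d),
        stringsAsFactors = FALSE
      )
    }
  }
  distances <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(individual = character(0), t = numeric(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  }
  summ_one <- function(d) {
    d <- d[d < max_dist]
    data.frame(n = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               sd = if (length(d) > 1L) stats::sd(d) else NA_real_)
  }
  groups <- split(distances$distance, distances$individual)
  summary <- do.call(rbind, c(
    lapply(groups, summ_one),
    list(all = summ_one(distances$distance))
  ))
  summary <- cbind(individual = rownames(summary), summary,
                   stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  breaks <- seq(0, ceiling(max(c(distances$distance, 2)) / 2) * 2, by = 2)
  histogram <- if (nrow(distances)) {
    h <- graphics::hist(distances$distance, breaks = breaks, plot = FALSE)
    data.frame(lo = utils::head(h$breaks, -1L), hi = h$breaks[-1L],
               count = h$counts)
  } else {
    data.frame(lo = numeric(0), hi = numeric(0), count = integer(0))
  }
  list(distances = distances, summary = summary, histogram = histogram)
}
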