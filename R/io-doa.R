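# DOA (direction-of-arrival) event streams.
#
# One DOA event is a sound localized by one array: an identifier, begin/end
# times, and an azimuth track sampled at the localization frame step DT
# (0.2 s by default). The on-disk form is a delimited long table with one row
# per (event, frame):
#
#   array_id,event_id,t,azimuth,t_begin,t_end
#
# In memory a `doa_events` object is that same long data.frame, validated and
# sorted, with azimuths always in the internal math convention, degrees in
# [0, 360).

#' Construct a validated DOA event table
#'
#' @param df data.frame with columns `array_id`, `event_id`, `t`, `azimuth`,
#'   `t_begin`, `t_end`; one row per track frame.
#' @return object of class `doa_events` (a data.frame), rows sorted by
#'   `(array_id, event_id, t)`.
#' @export
doa_events <- function(df) {
  need <- c("array_id", "event_id", "t", "azimuth", "t_begin", "t_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  df <- df[need]
  df$array_id <- as.character(df$array_id)
  df$event_id <- as.character(df$event_id)
  for (col in c("t", "azimuth", "t_begin", "t_end")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (nrow(df)) {
    df$azimuth <- df$azimuth %% 360
    df <- df[order(df$array_id, df$event_id, df$t), , drop = FALSE]
    rownames(df) <- NULL
    key <- paste(df$array_id, df$event_id, sep = "\r")
    for (k in unique(key)) {
      rows <- df[key == k, ]
      if (rows$t_begin[1L] >= rows$t_end[1L]) {
        stop("event ", rows$event_id[1L], " (array ", rows$array_id[1L],
             "): t_begin >= t_end")
      }
      if (any(diff(rows$t) <= 0)) {
        stop("event ", rows$event_id[1L], " (array ", rows$array_id[1L],
             "): track times not strictly increasing")
      }
      if (rows$t[1L] < rows$t_begin[1L] - 1e-9 ||
          rows$t[nrow(rows)] > rows$t_end[1L] + 1e-9) {
        stop("event ", rows$event_id[1L], " (array ", rows$array_id[1L],
             "): track times outside [t_begin, t_end]")
      }
    }
  }
  class(df) <- c("doa_events", "data.frame")
  df
}

#' Read / write DOA event tables
#'
#' @param path CSV file with header `array_id,event_id,t,azimuth,t_begin,t_end`.
#' @param convention azimuth convention of the file; compass azimuths are
#'   converted to the internal math convention on load.
#' @return `read_doa_events()`: a `doa_events` data.frame (math convention).
#' @export
read_doa_events <- function(path, convention = "math_ccw_from_east") {
  stopifnot(convention %in% AZIMUTH_CONVENTIONS)
  df <- utils::read.csv(path, colClasses = c(array_id = "character",
                                             event_id = "character"))
  if (nrow(df) && convention == "compass_cw_from_north") {
    df$azimuth <- compass_to_math(df$azimuth)
  }
  doa_events(df)
}

#' @rdname read_doa_events
#' @param events a `doa_events` object.
#' @export
write_doa_events <- function(events, path) {
  stopifnot(inherits(events, "doa_events"))
  df <- as.data.frame(events)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a DOA event table to one row per event
#'
#' Collapses each event's azimuth track to a single bearing (circular mean).
#'
#' @param events a `doa_events` object.
#' @return data.frame with one row per event: `array_id`, `event_id`,
#'   `t_begin`, `t_end`, `bearing` (degrees, math convention).
#' @export
doa_event_summary <- function(events) {
  stopifnot(inherits(events, "doa_events"))
  if (!nrow(events)) {
    return(data.frame(array_id = character(0), event_id = character(0),
                      t_begin = numeric(0), t_end = numeric(0),
                      bearing = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste(events$array_id, events$event_id, sep = "\r")
  idx <- !duplicated(key)
  rad <- events$azimuth * pi / 180
  s <- rowsum(sin(rad), key, reorder = FALSE)[, 1L]
  c_ <- rowsum(cos(rad), key, reorder = FALSE)[, 1L]
  bearing <- (atan2(s, c_) * 180 / pi) %% 360
  out <- data.frame(
    array_id = events$array_id[idx],
    event_id = events$event_id[idx],
    t_begin = events$t_begin[idx],
    t_end = events$t_end[idx],
    stringsAsFactors = FALSE
  )
  out$bearing <- bearing[match(key[idx], unique(key))]
  rownames(out) <- NULL
  out
}

#' Bearing of one DOA event
#'
#' Circular mean of the event's azimuth track, optionally restricted to a time
#' window. The circular mean is the angle of the mean unit vector, so tracks
#' that straddle 0/360 average correctly.
#'
#' @param track data.frame with columns `t` and `azimuth` (degrees).
#' @param t_window optional `(t0, t1)`; only frames with `t0 <= t <= t1` are
#'   used. An empty restriction is an error.
#' @return bearing in degrees, `[0, 360)`.
#' @examples
#' event_bearing(data.frame(t = c(0, 0.2), azimuth = c(350, 10)))  # 0, not 180
#' @export
event_bearing <- function(track, t_window = NULL) {
  stopifnot(nrow(track) >= 1L)
  az <- track$azimuth
  if (!is.null(t_window)) {
    keep <- track$t >= t_window[1L] & track$t <= t_window[2L]
    if (!any(keep)) {
      stop("no track frames inside the requested window")
    }
    az <- az[keep]
  }
  rad <- az * pi / 180
  (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
}
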