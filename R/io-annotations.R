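# Human annotations: per-individual song intervals, optionally with an
# observed (x, y) location per interval.
#
# Two dialects are supported:
#   * interval_table -- CSV `individual,t_begin,t_end[,x,y]`
#   * textgrid       -- Praat TextGrid (long text format), one interval tier
#                      per individual; non-empty labels mark songs
#
# Per-individual intervals are merged at load time when they overlap or abut:
# a bird cannot overlap itself, and half-open interval semantics make merged
# durations additive.

#' Annotation set
#'
#' @param records data.frame with columns `individual`, `t_begin`, `t_end` and
#'   optionally `x`, `y` (observed location of each interval, meters).
#' @param window analysis window `(t0, t1)`; defaults to the record span.
#' @return object of class `annotation_set`: the records data.frame (merged
#'   per individual, sorted) with attribute `window`.
#' @export
annotation_set <- function(records, window = NULL) {
  need <- c("individual", "t_begin", "t_end")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(records$t_begin >= records$t_end)
  if (length(bad)) {
    stop("t_begin >= t_end at row ", bad[1L])
  }
  has_xy <- all(c("x", "y") %in% names(records))
  if (is.null(window)) {
    window <- if (nrow(records)) {
      c(min(records$t_begin), max(records$t_end))
    } else {
      c(0, 0)
    }
  }
  out <- lapply(split(records, records$individual), function(r) {
    iv <- normalize_intervals(cbind(r$t_begin, r$t_end))
    d <- data.frame(individual = r$individual[1L],
                    t_begin = iv[, 1L], t_end = iv[, 2L],
                    stringsAsFactors = FALSE)
    if (has_xy) {
      # after a merge the location of the earliest constituent is kept
      i <- findInterval(d$t_begin, sort(r$t_begin))
      ord <- order(r$t_begin)
      d$x <- r$x[ord][i]
      d$y <- r$y[ord][i]
    }
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(individual = character(0), t_begin = numeric(0),
                      t_end = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, window = as.numeric(window),
            class = c("annotation_set", "data.frame"))
}

#' Read annotations from a table or Praat TextGrid
#'
#' @param path file path.
#' @param dialect `"interval_table"` (CSV `individual,t_begin,t_end[,x,y]`) or
#'   `"textgrid"` (Praat long format; each interval tier is an individual,
#'   intervals with non-empty labels are songs).
#' @param window optional analysis window; defaults to file metadata
#'   (TextGrid xmin/xmax) or the record span.
#' @return an `annotation_set`.
#' @export
read_annotations <- function(path, dialect = c("interval_table", "textgrid"),
                             window = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "interval_table") {
    df <- utils::read.csv(path, colClasses = c(individual = "character"))
    annotation_set(df, window = window)
  } else {
    tg <- parse_textgrid(path)
    if (is.null(window)) {
      window <- tg$window
    }
    annotation_set(tg$records, window = window)
  }
}

#' @rdname read_annotations
#' @param annotations an `annotation_set`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  utils::write.csv(as.data.frame(annotations), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Minimal Praat TextGrid (long format) reader: interval tiers only.
parse_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num_after <- function(x) {
    as.numeric(sub(".*=\\s*", "", x))
  }
  str_after <- function(x) {
    m <- regmatches(x, regexpr('"[^"]*"', x))
    if (length(m)) substr(m, 2L, nchar(m) - 1L) else ""
  }
  g_xmin <- num_after(grep("^\\s*xmin\\s*=", lines, value = TRUE)[1L])
  g_xmax <- num_after(grep("^\\s*xmax\\s*=", lines, value = TRUE)[1L])
  item_at <- grep("^\\s*item\\s*\\[[0-9]+\\]", lines)
  if (!length(item_at)) {
    stop("no tiers found in TextGrid: ", path)
  }
  bounds <- c(item_at, length(lines) + 1L)
  recs <- list()
  for (i in seq_along(item_at)) {
    chunk <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    cls <- str_after(grep("^\\s*class\\s*=", chunk, value = TRUE)[1L])
    if (!identical(cls, "IntervalTier")) {
      next
    }
    tier_name <- str_after(grep("^\\s*name\\s*=", chunk, value = TRUE)[1L])
    iv_at <- grep("^\\s*intervals\\s*\\[[0-9]+\\]", chunk)
    if (!length(iv_at)) {
      next
    }
    ib <- c(iv_at, length(chunk) + 1L)
    for (j in seq_along(iv_at)) {
      blk <- chunk[ib[j]:(ib[j + 1L] - 1L)]
      txt <- str_after(grep("^\\s*text\\s*=", blk, value = TRUE)[1L])
      if (!nzchar(trimws(txt))) {
        next
      }
      recs[[length(recs) + 1L]] <- data.frame(
        individual = tier_name,
        t_begin = num_after(grep("^\\s*xmin\\s*=", blk, value = TRUE)[1L]),
        t_end = num_after(grep("^\\s*xmax\\s*=", blk, value = TRUE)[1L]),
        stringsAsFactors = FALSE
      )
    }
  }
  records <- if (length(recs)) {
    do.call(rbind, recs)
  } else {
    data.frame(individual = character(0), t_begin = numeric(0),
               t_end = numeric(0), stringsAsFactors = FALSE)
  }
  list(records = records, window = c(g_xmin, g_xmax))
}

#' Timeline of one individual from an annotation set
#'
#' @param annotations an `annotation_set`.
#' @param individual_id which individual.
#' @param window analysis window; defaults to the set's window.
#' @return a `song_timeline`.
#' @export
annotation_timeline <- function(annotations, individual_id, window = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (is.null(window)) {
    window <- attr(annotations, "window")
  }
  r <- annotations[annotations$individual == individual_id, , drop = FALSE]
  song_timeline(individual_id, cbind(r$t_begin, r$t_end), window = window)
}
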