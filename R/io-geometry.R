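# Array geometry: positions of the microphone arrays in one shared planar
# frame, plus the azimuth convention of the DOA streams they produce.
#
# Internal convention is always mathematical: degrees counterclockwise from
# +x (east). Compass azimuths (clockwise from north) are converted at the
# file boundary only.

AZIMUTH_CONVENTIONS <- c("math_ccw_from_east", "compass_cw_from_north")

#' Construct an array geometry
#'
#' @param array_id character vector of unique array identifiers.
#' @param x,y array positions in meters, one shared planar frame.
#' @return object of class `array_geometry`: a data.frame with columns
#'   `array_id`, `x`, `y`. Positions are always stored in the internal
#'   math convention (azimuths counterclockwise from east).
#' @examples
#' geom <- array_geometry(c("1", "2", "3"), x = c(0, 60, 30), y = c(0, 0, 40))
#' @export
array_geometry <- function(array_id, x, y) {
  array_id <- as.character(array_id)
  if (anyDuplicated(array_id)) {
    stop("duplicate array_id: ",
         paste(unique(array_id[duplicated(array_id)]), collapse = ", "))
  }
  if (length(array_id) < 2L) {
    stop("at least 2 arrays required (3 for triangulation)")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("array coordinates must be finite")
  }
  stopifnot(length(x) == length(array_id), length(y) == length(array_id))
  structure(data.frame(array_id = array_id, x = as.numeric(x),
                       y = as.numeric(y), stringsAsFactors = FALSE),
            class = c("array_geometry", "data.frame"))
}

#' Convert compass azimuths to the internal math convention
#'
#' Compass azimuths run clockwise from north; internal azimuths run
#' counterclockwise from east. The conversion `90 - a (mod 360)` is an
#' involution, so the same formula maps back.
#'
#' @param azimuth degrees.
#' @return degrees in `[0, 360)`.
#' @export
compass_to_math <- function(azimuth) {
  (90 - azimuth) %% 360
}

#' @rdname compass_to_math
#' @export
math_to_compass <- function(azimuth) {
  (90 - azimuth) %% 360
}

#' Read / write an array geometry config
#'
#' The geometry config is a versioned JSON document:
#' ```
#' {
#'   "format": 1,
#'   "azimuth_convention": "math_ccw_from_east",
#'   "arrays": [ {"array_id": "1", "x": 0, "y": 0}, ... ]
#' }
#' ```
#' `azimuth_convention` declares the convention of the DOA files this geometry
#' accompanies; `read_doa_events()` uses it to convert compass azimuths to the
#' internal math convention on load. `write_geometry()` emits canonical JSON so
#' that write -> read -> write is byte-identical.
#'
#' @param path file path.
#' @return `read_geometry()`: an `array_geometry` with attribute
#'   `azimuth_convention`.
#' @export
read_geometry <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$format) || doc$format != 1) {
    stop("unsupported geometry format version: ", deparse(doc$format))
  }
  conv <- doc$azimuth_convention
  if (is.null(conv) || !conv %in% AZIMUTH_CONVENTIONS) {
    stop("azimuth_convention must be one of: ",
         paste(AZIMUTH_CONVENTIONS, collapse = ", "))
  }
  arr <- doc$arrays
  if (is.null(arr) || nrow(arr) == 0L) {
    stop("geometry config lists no arrays")
  }
  for (col in c("array_id", "x", "y")) {
    if (is.null(arr[[col]]) || anyNA(arr[[col]])) {
      stop("missing coordinate or id in geometry config: column ", col)
    }
  }
  geom <- array_geometry(arr$array_id, arr$x, arr$y)
  attr(geom, "azimuth_convention") <- conv
  geom
}

#' @rdname read_geometry
#' @param geometry an `array_geometry`.
#' @param azimuth_convention convention to declare in the file.
#' @export
write_geometry <- function(geometry, path,
                           azimuth_convention = attr(geometry, "azimuth_convention")) {
  if (is.null(azimuth_convention)) {
    azimuth_convention <- "math_ccw_from_east"
  }
  stopifnot(inherits(geometry, "array_geometry"),
            azimuth_convention %in% AZIMUTH_CONVENTIONS)
  doc <- list(
    format = 1L,
    azimuth_convention = azimuth_convention,
    arrays = data.frame(array_id = geometry$array_id,
                        x = geometry$x, y = geometry$y,
                        stringsAsFactors = FALSE)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2L)
  writeLines(json, path)
  invisible(path)
}
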