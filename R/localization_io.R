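#' @title Localization tables
#' @description
#' A localization table is the pipeline's universal currency: one row per
#' detected single-molecule emission event, with x/y coordinates in
#' nanometres (image convention: origin top-left, y increasing downward),
#' the acquisition frame index, and the fitted localization uncertainty
#' in nanometres.  Tables are plain `data.frame`s of class `loc_table`
#' carrying the channel, the field extent and a provenance tag as
#' attributes, so that every base-R data-frame verb keeps working.
#' @name loc_table
NULL

.LOC_CHANNELS <- c("A_af647", "B_pagfp")

#' Construct a localization table
#'
#' @param x,y Numeric coordinates in nm; finite and non-negative.
#' @param frame Positive integer acquisition frame indices.
#' @param uncertainty Positive localization precisions in nm.
#' @param channel `"A_af647"` (Alexa Fluor 647 anti-CBM3a) or
#'   `"B_pagfp"` (photoactivatable GFP-dockerin).
#' @param field_extent Numeric `(width, height)` in nm.  Defaults to the
#'   bounding box of the coordinates (the origin is always included).
#' @param provenance Free-text source tag.
#' @return A `data.frame` of class `loc_table` with columns
#'   `x`, `y`, `frame`, `uncertainty`.
#' @export
loc_table <- function(x = numeric(), y = numeric(),
                      frame = integer(), uncertainty = numeric(),
                      channel = c("A_af647", "B_pagfp"),
                      field_extent = NULL, provenance = "") {
  channel <- match.arg(channel)
  n <- length(x)
  if (length(y) != n || length(frame) != n || length(uncertainty) != n)
    stop("x, y, frame and uncertainty must have equal length", call. = FALSE)
  x <- as.numeric(x); y <- as.numeric(y)
  uncertainty <- as.numeric(uncertainty)
  if (n > 0) {
    if (any(!is.finite(x)) || any(!is.finite(y)))
      stop("coordinates must be finite", call. = FALSE)
    if (any(x < 0) || any(y < 0))
      stop("coordinates must be >= 0 (origin top-left convention)",
           call. = FALSE)
    if (any(!is.finite(frame)) || any(frame < 1) || any(frame != round(frame)))
      stop("frame must be a positive integer", call. = FALSE)
    if (any(!is.finite(uncertainty)) || any(uncertainty <= 0))
      stop("uncertainty must be > 0", call. = FALSE)
  }
  frame <- as.integer(round(frame))
  if (is.null(field_extent)) {
    field_extent <- if (n > 0) c(max(x), max(y)) else c(0, 0)
  }
  field_extent <- as.numeric(field_extent)
  if (length(field_extent) != 2 || any(!is.finite(field_extent)) ||
      any(field_extent < 0))
    stop("field_extent must be two finite non-negative lengths (nm)",
         call. = FALSE)
  if (n > 0 && (any(x > field_extent[1]) || any(y > field_extent[2])))
    stop("all coordinates must lie within field_extent", call. = FALSE)
  out <- data.frame(x = x, y = y, frame = frame, uncertainty = uncertainty)
  structure(out,
            channel = channel,
            field_extent = field_extent,
            provenance = as.character(provenance)[1],
            class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  fe <- attr(x, "field_extent")
  cat(sprintf("<loc_table> %d localizations, channel %s, field %.1f x %.1f nm\n",
              nrow(x), attr(x, "channel"), fe[1], fe[2]))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# rebuild a loc_table from a row subset, keeping metadata
.subset_loc_table <- function(table, keep) {
  df <- as.data.frame(table)[keep, c("x", "y", "frame", "uncertainty"),
                             drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            channel = attr(table, "channel"),
            field_extent = attr(table, "field_extent"),
            provenance = attr(table, "provenance"),
            class = c("loc_table", "data.frame"))
}

.loc_xy <- function(table) cbind(table$x, table$y)

# ThunderSTORM-style header names; the only supported dialect.
.TS_COLS <- c(x = "x [nm]", y = "y [nm]", frame = "frame",
              uncertainty = "uncertainty [nm]")

#' Read a localization table from delimited text
#'
#' Reads a comma-separated localization table in the ThunderSTORM-style
#' dialect, whose header must name at least the columns
#' `"x [nm]"`, `"y [nm]"`, `"frame"` and `"uncertainty [nm]"`.  Extra
#' columns are ignored.  Rows are kept in file order.
#'
#' @param path Path to an existing file.
#' @param channel Channel tag to attach, see [loc_table()].
#' @param dialect Only `"thunderstorm_csv"` is supported.
#' @param field_extent Optional `(width, height)` in nm; inferred as the
#'   coordinate bounding box when absent.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, channel = c("A_af647", "B_pagfp"),
                               dialect = "thunderstorm_csv",
                               field_extent = NULL) {
  channel <- match.arg(channel)
  dialect <- match.arg(dialect, "thunderstorm_csv")
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    stop("empty localization file (no header): ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character",
                         stringsAsFactors = FALSE)
  missing <- setdiff(unname(.TS_COLS), names(raw))
  if (length(missing) > 0)
    stop("localization file is missing required column(s): ",
         paste0('"', missing, '"', collapse = ", "), call. = FALSE)
  num <- lapply(.TS_COLS, function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    bad <- c(bad, which(is.na(raw[[col]]) | !nzchar(raw[[col]])))
    if (length(bad) > 0)
      # +1 for the header row -> actual line number in the file
      stop(sprintf("non-numeric value in column \"%s\" at line %d of %s",
                   col, min(bad) + 1L, path), call. = FALSE)
    v
  })
  loc_table(x = num$x, y = num$y, frame = num$frame,
            uncertainty = num$uncertainty, channel = channel,
            field_extent = field_extent, provenance = path)
}

#' Write a localization table to delimited text
#'
#' Writes the ThunderSTORM-style dialect read by [read_localizations()];
#' the round trip write-then-read reproduces the table record for record.
#'
#' @param table A [loc_table()].
#' @param path Output path.
#' @param dialect Only `"thunderstorm_csv"` is supported.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, dialect = "thunderstorm_csv") {
  dialect <- match.arg(dialect, "thunderstorm_csv")
  stopifnot(inherits(table, "loc_table"))
  out <- data.frame(
    a = sprintf("%.4f", table$x),
    b = sprintf("%.4f", table$y),
    c = as.integer(table$frame),
    d = sprintf("%.4f", table$uncertainty),
    check.names = FALSE)
  names(out) <- unname(.TS_COLS)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write localization file: ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' Filter localizations by precision
#'
#' Keeps exactly the records whose fitted uncertainty is less than or
#' equal to `max_uncertainty` (inclusive boundary), preserving order.
#'
#' @param table A [loc_table()].
#' @param max_uncertainty Positive threshold in nm.
#' @return The filtered [loc_table()].
#' @export
filter_by_uncertainty <- function(table, max_uncertainty) {
  stopifnot(inherits(table, "loc_table"))
  if (!is.numeric(max_uncertainty) || length(max_uncertainty) != 1 ||
      !is.finite(max_uncertainty) || max_uncertainty <= 0)
    stop("max_uncertainty must be a single positive number (nm)",
         call. = FALSE)
  .subset_loc_table(table, table$uncertainty <= max_uncertainty)
}

#' Acquisition geometry
#'
#' Camera geometry of the acquisition: physical pixel size, field size in
#' pixels and the number of frames.  The default mirrors a 100 nm pixel,
#' a usable 256 x 256 pixel field (25.6 x 25.6 um) and 15,000 frames per
#' channel.
#'
#' @param pixel_size nm per pixel, > 0.
#' @param field_pixels Integer `(width, height)` in pixels.
#' @param n_frames Number of acquisition frames, > 0.
#' @export
acquisition_geometry <- function(pixel_size = 100,
                                 field_pixels = c(256L, 256L),
                                 n_frames = 15000L) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive length (nm)", call. = FALSE)
  field_pixels <- as.integer(field_pixels)
  if (length(field_pixels) != 2 || any(field_pixels <= 0))
    stop("field_pixels must be two positive integers", call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (length(n_frames) != 1 || n_frames <= 0)
    stop("n_frames must be a positive integer", call. = FALSE)
  structure(list(pixel_size = as.numeric(pixel_size),
                 field_pixels = field_pixels, n_frames = n_frames),
            class = "acquisition_geometry")
}

#' Convert a pixel count to physical length
#'
#' @param n_pixels Non-negative pixel count (vectorized).
#' @param geometry An [acquisition_geometry()].
#' @return Length in nm: `n_pixels * pixel_size`.
#' @examples
#' pixels_to_length(256, acquisition_geometry(pixel_size = 100)) # 25600 nm
#' @export
pixels_to_length <- function(n_pixels, geometry = acquisition_geometry()) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (!is.numeric(n_pixels) || any(!is.finite(n_pixels)) || any(n_pixels < 0))
    stop("n_pixels must be non-negative", call. = FALSE)
  n_pixels * geometry$pixel_size
}
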