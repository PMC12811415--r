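#' @title Regions of interest
#' @description
#' Polygonal regions of interest stratify a field into single bacterial
#' cells, groups of cells, substrate (Avicel) particles, or composite
#' particle-with-cells regions, so that clustering runs only inside the
#' region that matters.  Boundary points count as inside; when several
#' ROIs share an edge, a localization is assigned to the ROI that comes
#' first in the ROI list, which makes partitions conserve counts.
#' @name roi_selection
NULL

.ROI_CATEGORIES <- c("single_cell", "multiple_cells", "particle",
                     "particle_with_cells")

# signed polygon area (shoelace), nm^2
.shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# do segments p1-p2 and p3-p4 properly intersect (interiors cross)?
.seg_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.is_simple_polygon <- function(v) {
  nv <- nrow(v)
  for (i in seq_len(nv)) {
    a1 <- v[i, ]; a2 <- v[if (i == nv) 1 else i + 1, ]
    for (j in seq_len(nv)) {
      if (abs(i - j) <= 1 || (i == 1 && j == nv) || (i == nv && j == 1))
        next
      b1 <- v[j, ]; b2 <- v[if (j == nv) 1 else j + 1, ]
      if (.seg_cross(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

#' Construct a region of interest
#'
#' @param vertices Matrix (or 2-column object) of >= 3 polygon vertices
#'   in nm, in order; the polygon must be simple with positive area.
#' @param category One of `"single_cell"`, `"multiple_cells"`,
#'   `"particle"`, `"particle_with_cells"`.
#' @param id Identifier string.
#' @export
roi <- function(vertices, category = "single_cell", id = "roi") {
  category <- match.arg(category, .ROI_CATEGORIES)
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) < 2 || nrow(v) < 3 || any(!is.finite(v)))
    stop("vertices must be >= 3 finite (x, y) points", call. = FALSE)
  v <- v[, 1:2, drop = FALSE]
  if (!.is_simple_polygon(v))
    stop("polygon must be simple (non-self-intersecting)", call. = FALSE)
  if (abs(.shoelace(v)) <= 0)
    stop("degenerate polygon: zero area", call. = FALSE)
  structure(list(vertices = v, category = category,
                 id = as.character(id)[1]),
            class = "roi")
}

# vectorized point-in-polygon, boundary inclusive.
# Even-odd crossing rule plus an explicit on-segment test so that points
# exactly on an edge or vertex always count as inside.
.point_in_polygon <- function(px, py, v) {
  n <- length(px)
  nv <- nrow(v)
  inside <- logical(n)
  boundary <- logical(n)
  scale <- max(abs(v), 1)
  tol <- 1e-9 * scale
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    # on-segment: zero cross product and within the segment's bbox
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on <- abs(cross) <= tol * max(abs(xj - xi) + abs(yj - yi), 1) &
      px >= pmin(xi, xj) - tol & px <= pmax(xi, xj) + tol &
      py >= pmin(yi, yj) - tol & py <= pmax(yi, yj) + tol
    boundary <- boundary | on
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | boundary
}

#' Restrict a localization table to an ROI
#'
#' Keeps exactly the localizations whose coordinates lie inside or on
#' the boundary of the ROI polygon, preserving order.
#'
#' @param table A [loc_table()].
#' @param roi A [roi()].
#' @return The clipped [loc_table()].
#' @export
clip_to_roi <- function(table, roi) {
  stopifnot(inherits(table, "loc_table"), inherits(roi, "roi"))
  keep <- .point_in_polygon(table$x, table$y, roi$vertices)
  .subset_loc_table(table, keep)
}

#' Assign localizations to the first containing ROI
#'
#' @param table A [loc_table()].
#' @param rois List of [roi()] objects; earlier ROIs win ties on shared
#'   boundaries.
#' @return Character vector of ROI ids (NA where no ROI contains the
#'   point), one per localization.
#' @export
assign_rois <- function(table, rois) {
  stopifnot(inherits(table, "loc_table"))
  out <- rep(NA_character_, nrow(table))
  for (r in rois) {
    stopifnot(inherits(r, "roi"))
    hit <- is.na(out) & .point_in_polygon(table$x, table$y, r$vertices)
    out[hit] <- r$id
  }
  out
}

#' Count, area and density of an ROI
#'
#' @param table A [loc_table()].
#' @param roi A [roi()].
#' @return List with `count`, `area_um2` (shoelace formula) and
#'   `density_per_um2 = count / area`.
#' @export
roi_summary <- function(table, roi) {
  stopifnot(inherits(roi, "roi"))
  area_um2 <- abs(.shoelace(roi$vertices)) / 1e6
  if (area_um2 <= 0) stop("zero-area polygon", call. = FALSE)
  count <- nrow(clip_to_roi(table, roi))
  list(count = count, area_um2 = area_um2,
       density_per_um2 = count / area_um2)
}

#' Read ROI definitions from a sidecar file
#'
#' The sidecar is a CSV with columns `roi_id`, `category`, `vertex`,
#' `x`, `y` (coordinates in nm), one row per vertex, vertices ordered by
#' the `vertex` column within each ROI.  ROI order in the file defines
#' the tie-break priority used by [assign_rois()].
#'
#' @param path Sidecar path.
#' @return List of [roi()] objects.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "category", "vertex", "x", "y")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("ROI file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ids <- unique(raw$roi_id)
  lapply(ids, function(id) {
    part <- raw[raw$roi_id == id, , drop = FALSE]
    part <- part[order(part$vertex), , drop = FALSE]
    roi(cbind(part$x, part$y), category = part$category[1], id = id)
  })
}

#' Write ROI definitions to a sidecar file
#'
#' @param rois List of [roi()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  rows <- do.call(rbind, lapply(rois, function(r) {
    data.frame(roi_id = r$id, category = r$category,
               vertex = seq_len(nrow(r$vertices)),
               x = r$vertices[, 1], y = r$vertices[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
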