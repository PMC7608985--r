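#' Spatial calibration of a digitized section
#'
#' @param um_per_px micrometers per pixel at which the image was digitized;
#'   must be positive.
#' @return A `calibration` object.
#' @export
calibration <- function(um_per_px) {
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L ||
      is.na(um_per_px) || um_per_px <= 0)
    stop("`um_per_px` must be a single positive number")
  structure(list(um_per_px = as.numeric(um_per_px)), class = "calibration")
}

#' Cyst diameter range of interest
#'
#' The recognizer keeps only regions whose equivalent-circle diameter lies
#' in `[dmin, dmax]`. The range can be given in pixels or micrometers; a
#' micrometer range is converted to pixels at construction using the
#' calibration.
#'
#' @param dmin,dmax minimum and maximum diameters, `0 < dmin < dmax`.
#' @param unit `"px"` (default) or `"um"`.
#' @param cal a [calibration()]; required when `unit = "um"`.
#' @return A `diameter_range` object with `dmin`/`dmax` in pixels.
#' @export
diameter_range <- function(dmin, dmax, unit = c("px", "um"), cal = NULL) {
  unit <- match.arg(unit)
  if (!is.numeric(dmin) || !is.numeric(dmax) || is.na(dmin) || is.na(dmax))
    stop("`dmin` and `dmax` must be numbers")
  if (unit == "um") {
    if (!inherits(cal, "calibration"))
      stop("a calibration is required to convert micrometers to pixels")
    dmin <- dmin / cal$um_per_px
    dmax <- dmax / cal$um_per_px
  }
  if (!(dmin > 0 && dmin < dmax))
    stop("require 0 < dmin < dmax")
  structure(list(dmin = as.numeric(dmin), dmax = as.numeric(dmax)),
            class = "diameter_range")
}

#' Equivalent-circle diameter of an area
#'
#' @param area_px region area in pixels.
#' @return `2 * sqrt(area_px / pi)`, in pixels.
#' @export
equiv_diameter <- function(area_px) 2 * sqrt(area_px / pi)

# Internal constructor. `region` is the filled pixel-index set the polygon
# rasterizes to; area is its cardinality so that polygon- and mask-derived
# areas agree exactly.
new_cyst_contour <- function(id, polygon, origin, region) {
  stopifnot(origin %in% c("auto", "manual", "derived"))
  storage.mode(polygon) <- "double"
  colnames(polygon) <- c("x", "y")
  area <- length(region)
  structure(
    list(id = as.integer(id), polygon = polygon, origin = origin,
         region = as.integer(region), area_px = area,
         equiv_diameter_px = equiv_diameter(area)),
    class = "cyst_contour")
}

#' Construct a cyst contour from a polygon
#'
#' @param id unique integer identifier.
#' @param polygon n x 2 matrix of (x, y) vertices, 0-based, x = column.
#' @param width,height dimensions of the image the contour lives in.
#' @param origin provenance: `"auto"` (recognizer), `"manual"` (drawn) or
#'   `"derived"` (produced by an edit).
#' @return A `cyst_contour` whose `area_px` is the filled pixel count of
#'   the polygon and whose `equiv_diameter_px` is `2 * sqrt(area / pi)`.
#' @export
cyst_contour <- function(id, polygon, width, height, origin = "manual") {
  polygon <- as_polygon(polygon)
  if (!polygon_in_bounds(polygon, width, height))
    stop("polygon vertices must lie inside the image")
  region <- region_from_mask(cpp_fill_polygon(polygon, as.integer(width),
                                              as.integer(height)))
  if (length(region) == 0L) stop("polygon encloses no pixels")
  new_cyst_contour(id, polygon, origin, region)
}

#' Container of recognized cysts for one image
#'
#' Holds the image dimensions, organ type, calibration and the list of
#' cyst contours, together with a replayable edit log (see
#' [edit_log()]).
#'
#' @param width,height image dimensions in pixels.
#' @param organ `"kidney"` or `"liver"`.
#' @param cal a [calibration()].
#' @param cysts list of `cyst_contour` objects with unique ids.
#' @return A `cyst_set`.
#' @export
cyst_set <- function(width, height, organ = c("kidney", "liver"),
                     cal = calibration(1), cysts = list()) {
  organ <- match.arg(organ)
  stopifnot(width >= 1, height >= 1, inherits(cal, "calibration"))
  ids <- vapply(cysts, function(c) c$id, integer(1))
  if (anyDuplicated(ids)) stop("cyst ids must be unique")
  names(cysts) <- as.character(ids)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         organ = organ, calibration = cal, cysts = cysts,
         next_id = if (length(ids)) max(ids) + 1L else 1L,
         log = list(), cursor = 0L,
         initial = cysts, initial_next_id = if (length(ids)) max(ids) + 1L else 1L),
    class = "cyst_set")
}

set_ids <- function(set) {
  as.integer(vapply(set$cysts, function(c) c$id, integer(1), USE.NAMES = FALSE))
}

get_cyst <- function(set, id) {
  c <- set$cysts[[as.character(id)]]
  if (is.null(c)) stop("no cyst with id ", id)
  c
}

#' Diameters of all cysts in a set
#'
#' @param set a [cyst_set()].
#' @param unit `"px"` or `"um"` (converted with the set's calibration).
#' @return Numeric vector of equivalent-circle diameters.
#' @export
cyst_diameters <- function(set, unit = c("px", "um")) {
  unit <- match.arg(unit)
  d <- vapply(set$cysts, function(c) c$equiv_diameter_px, numeric(1),
              USE.NAMES = FALSE)
  if (unit == "um") d <- d * set$calibration$um_per_px
  d
}

# Union of all filled cyst regions as a logical H x W matrix.
cyst_union_mask <- function(set) {
  acc <- logical(set$height * set$width)
  for (c in set$cysts) acc[c$region] <- TRUE
  matrix(acc, set$height, set$width)
}

#' @export
print.cyst_contour <- function(x, ...) {
  cat(sprintf("<cyst_contour #%d %s: area %d px, equiv diameter %.1f px, %d vertices>\n",
              x$id, x$origin, x$area_px, x$equiv_diameter_px, nrow(x$polygon)))
  invisible(x)
}

#' @export
print.cyst_set <- function(x, ...) {
  cat(sprintf("<cyst_set: %d cysts on %d x %d px %s section, %.3g um/px, %d edits>\n",
              length(x$cysts), x$width, x$height, x$organ,
              x$calibration$um_per_px, length(x$log)))
  invisible(x)
}

#' @export
summary.cyst_set <- function(object, ...) {
  d <- cyst_diameters(object)
  org <- table(vapply(object$cysts, function(c) c$origin, character(1)))
  out <- list(n_cysts = length(object$cysts),
              cystic_index = cystic_index(object),
              diameter_summary = if (length(d)) summary(d) else NULL,
              origins = org, n_edits = length(object$log))
  class(out) <- "summary.cyst_set"
  out
}

#' @export
print.summary.cyst_set <- function(x, ...) {
  cat(sprintf("Cysts: %d   Cystic index: %.2f%%   Edits applied: %d\n",
              x$n_cysts, x$cystic_index, x$n_edits))
  if (!is.null(x$diameter_summary)) {
    cat("Equivalent diameters (px):\n")
    print(x$diameter_summary)
  }
  if (length(x$origins)) {
    cat("Origins: ",
        paste(names(x$origins), as.integer(x$origins), sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Plot a cyst set as polygon outlines
#'
#' Draws every cyst contour in image coordinates (origin top-left),
#' optionally over a greyscale background image.
#'
#' @param x a [cyst_set()].
#' @param background optional [grey_image()] backdrop.
#' @param col outline color, recycled per cyst.
#' @param ... passed to [graphics::polygon()].
#' @export
plot.cyst_set <- function(x, background = NULL, col = "blue", ...) {
  graphics::plot(NA, xlim = c(0, x$width - 1), ylim = c(x$height - 1, 0),
                 xlab = "x (px)", ylab = "y (px)", asp = 1,
                 main = sprintf("%d cysts (%s)", length(x$cysts), x$organ))
  if (!is.null(background)) {
    graphics::rasterImage(as_grey_matrix(background) / 255,
                          0, x$height - 1, x$width - 1, 0)
  }
  col <- rep_len(col, max(1L, length(x$cysts)))
  for (i in seq_along(x$cysts)) {
    p <- x$cysts[[i]]$polygon
    graphics::polygon(p[, 1], p[, 2], border = col[i], ...)
  }
  invisible(x)
}
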