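# Geometry helpers shared by segmentation, editing and quantification.
# Coordinates are 0-based with x = column and y = row; a polygon is an
# n x 2 numeric matrix of vertices at pixel centres.

#' Rasterize a closed polygon into a binary mask
#'
#' The filled region is the even-odd interior of the polygon plus all
#' pixels crossed by its edges, so boundary pixels always belong to the
#' region. When the polygon is the traced outer border of a mask component
#' this reproduces the component with its interior holes filled.
#'
#' @param polygon n x 2 numeric matrix of (x, y) vertices, 0-based.
#' @param width,height raster dimensions in pixels.
#' @return A [binary_mask()] of the given dimensions.
#' @export
rasterize_polygon <- function(polygon, width, height) {
  polygon <- as_polygon(polygon)
  binary_mask(cpp_fill_polygon(polygon, as.integer(width), as.integer(height)))
}

as_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 1L || anyNA(polygon))
    stop("a polygon must be an n x 2 matrix of (x, y) vertices")
  storage.mode(polygon) <- "double"
  colnames(polygon) <- c("x", "y")
  polygon
}

# Segment intersection test for the simple-polygon check. Shared endpoints
# between consecutive edges are allowed; any other contact is an
# intersection.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# TRUE when the closed polygon has >= 3 distinct vertices and no two
# non-adjacent edges touch.
is_simple_polygon <- function(polygon) {
  n <- nrow(polygon)
  if (n < 3L) return(FALSE)
  if (nrow(unique(polygon)) < 3L) return(FALSE)
  idx <- function(k) (k - 1L) %% n + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (they share a vertex by construction)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(polygon[i, ], polygon[idx(i + 1L), ],
                         polygon[j, ], polygon[idx(j + 1L), ])) return(FALSE)
    }
  }
  TRUE
}

polygon_in_bounds <- function(polygon, width, height) {
  all(polygon[, 1] >= 0 & polygon[, 1] <= width - 1 &
        polygon[, 2] >= 0 & polygon[, 2] <= height - 1)
}

# Region representation: 1-based linear indices into an H x W matrix
# (column-major, index = x * H + y + 1).
region_from_mask <- function(mask) which(as.vector(mask))

mask_from_region <- function(region, width, height) {
  m <- matrix(FALSE, height, width)
  m[region] <- TRUE
  m
}
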