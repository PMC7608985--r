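#' Extract the green channel of an RGB image
#'
#' Cyst lumens are nearly unstained and therefore bright in the green
#' channel of an H&E section, which gives the best lumen/tissue contrast of
#' the three channels; segmentation operates on it.
#'
#' @param image an [rgb_image()].
#' @return A [grey_image()] with the same dimensions.
#' @export
extract_green <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  a <- unclass(image)
  grey_image(matrix(a[, , 2], dim(a)[1], dim(a)[2]))
}

#' Threshold a grey image at its global mean level
#'
#' The mean grey level is kept as a real number (no rounding); a pixel is
#' foreground iff its value strictly exceeds the mean, so a constant image
#' yields an empty mask.
#'
#' @param grey a [grey_image()].
#' @return A list with `mask` (a [binary_mask()]) and `mean_level` (the
#'   arithmetic mean of all pixels).
#' @export
global_mean_threshold <- function(grey) {
  stopifnot(inherits(grey, "grey_image"))
  m <- as_grey_matrix(grey)
  mu <- mean(m)
  list(mask = binary_mask(m > mu), mean_level = mu)
}

#' Refine a threshold mask by 1-D k-means on pixel intensities
#'
#' Runs Lloyd's algorithm with k = 2 on the grey values, initializing the
#' cluster assignment from `init` (foreground/background labels). Iteration
#' stops when both centroids move by less than 0.5 grey levels or after 10
#' iterations. The returned foreground is the cluster with the higher final
#' centroid. A degenerate initialization (all pixels one label) is returned
#' unchanged.
#'
#' @param grey a [grey_image()].
#' @param init a [binary_mask()] of matching dimensions.
#' @param tol centroid movement tolerance in grey levels.
#' @param max_iter iteration cap.
#' @return A [binary_mask()].
#' @export
kmeans_refine <- function(grey, init, tol = 0.5, max_iter = 10L) {
  stopifnot(inherits(grey, "grey_image"), inherits(init, "binary_mask"))
  if (!all(dim(grey) == dim(init)))
    stop("`init` dimensions must match `grey`")
  x <- as.vector(as_grey_matrix(grey))
  lab <- as.vector(as_mask_matrix(init))
  if (all(lab) || !any(lab)) return(init)

  c_fg <- mean(x[lab]); c_bg <- mean(x[!lab])
  for (it in seq_len(max_iter)) {
    d_fg <- abs(x - c_fg); d_bg <- abs(x - c_bg)
    # ties join the brighter cluster
    new_lab <- if (c_fg >= c_bg) d_fg <= d_bg else d_fg < d_bg
    if (all(new_lab) || !any(new_lab)) break
    lab <- new_lab
    n_fg <- mean(x[lab]); n_bg <- mean(x[!lab])
    moved <- max(abs(n_fg - c_fg), abs(n_bg - c_bg))
    c_fg <- n_fg; c_bg <- n_bg
    if (moved < tol) break
  }
  fg <- if (c_fg >= c_bg) lab else !lab
  binary_mask(matrix(fg, nrow(grey), ncol(grey)))
}

#' Disk structuring element
#'
#' Binary disk of the given diameter: an odd-sized square grid whose pixels
#' lie within Euclidean distance `diameter / 2` of the centre. At diameter
#' 3 this is the full 3 x 3 neighbourhood.
#'
#' @param diameter disk diameter in pixels (>= 1).
#' @return A 0/1 matrix usable as a morphology kernel.
#' @export
disk_kernel <- function(diameter) {
  stopifnot(diameter >= 1)
  s <- 2L * (as.integer(diameter) %/% 2L) + 1L
  ctr <- (s + 1L) / 2
  d2 <- outer(seq_len(s) - ctr, seq_len(s) - ctr,
              function(i, j) i * i + j * j)
  (d2 <= (diameter / 2)^2) * 1
}

#' Remove small noise regions by morphological opening
#'
#' Opens the refined mask with a disk structuring element. For liver images
#' the disk diameter is fixed at 3 px; for kidney images it is
#' `max(3, round(dmin))` px so that structures smaller than the smallest
#' cyst of interest are removed. Opening is anti-extensive: the result is a
#' subset of the input foreground.
#'
#' @param mask a [binary_mask()].
#' @param organ `"kidney"` or `"liver"`.
#' @param range a [diameter_range()]; only `dmin` is used (kidney).
#' @return A [binary_mask()].
#' @export
denoise_open <- function(mask, organ = c("kidney", "liver"), range = NULL) {
  organ <- match.arg(organ)
  stopifnot(inherits(mask, "binary_mask"))
  d <- 3
  if (organ == "kidney") {
    if (is.null(range)) stop("kidney opening requires a diameter range")
    d <- max(3, round(range$dmin))
  }
  if (nrow(mask) < d || ncol(mask) < d)
    return(binary_mask(matrix(FALSE, nrow(mask), ncol(mask))))
  kern <- disk_kernel(d)
  out <- EBImage::opening(as_mask_matrix(mask) * 1, kern)
  binary_mask(matrix(as.vector(out) > 0.5, nrow(mask), ncol(mask)))
}

#' Extract cyst contours from a binary mask
#'
#' One contour per 8-connected foreground component, tracing the outer
#' border only (Suzuki-Abe border following). Interior holes are not
#' traced: a cyst's filled region includes any enclosed background (lumen
#' debris does not reduce cyst size), so `area_px` of an annulus counts the
#' hole.
#'
#' @param mask a [binary_mask()].
#' @return List of `cyst_contour` objects with `origin = "auto"`, ids
#'   assigned in raster-scan order of the components.
#' @export
extract_contours <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- as_mask_matrix(mask)
  labels <- cpp_label_components(m, 8L)
  n <- attr(labels, "n")
  out <- vector("list", n)
  for (k in seq_len(n)) {
    poly <- cpp_trace_outer_border(labels, k)
    storage.mode(poly) <- "double"
    colnames(poly) <- c("x", "y")
    region <- region_from_mask(cpp_fill_polygon(poly, ncol(m), nrow(m)))
    out[[k]] <- new_cyst_contour(k, poly, "auto", region)
  }
  out
}

#' Keep only cysts whose diameter lies in a range
#'
#' @param cysts list of `cyst_contour` objects.
#' @param range a [diameter_range()] in pixels.
#' @return The cysts with `dmin <= equiv_diameter_px <= dmax`, order and
#'   ids preserved.
#' @export
filter_by_diameter <- function(cysts, range) {
  stopifnot(inherits(range, "diameter_range"))
  keep <- vapply(cysts, function(c)
    c$equiv_diameter_px >= range$dmin && c$equiv_diameter_px <= range$dmax,
    logical(1))
  cysts[keep]
}

#' Automatic cyst recognition
#'
#' Runs the full six-step recognition pipeline on an RGB histology image:
#' green-channel extraction, global mean thresholding, two-cluster k-means
#' refinement of the threshold mask, morphological opening (organ-specific
#' structuring element), outer-border contour extraction and diameter
#' filtering.
#'
#' @param image an [rgb_image()].
#' @param organ `"kidney"` or `"liver"`; selects the opening element.
#' @param range a [diameter_range()] in pixels.
#' @param cal a [calibration()] recorded in the result.
#' @return A list of class `cyst_recognition` with elements `cyst_set` (a
#'   [cyst_set()] of the accepted cysts) and `trace` (the intermediate
#'   rasters: `green`, `mean_level`, `thresholded`, `kmeans_refined`,
#'   `opened`).
#' @export
recognize_cysts <- function(image, organ = c("kidney", "liver"), range,
                            cal = calibration(1)) {
  organ <- match.arg(organ)
  stopifnot(inherits(image, "rgb_image"), inherits(range, "diameter_range"))
  green <- extract_green(image)
  th <- global_mean_threshold(green)
  ik <- kmeans_refine(green, th$mask)
  io <- denoise_open(ik, organ, range)
  contours <- filter_by_diameter(extract_contours(io), range)
  # reissue consecutive ids in detection order
  contours <- lapply(seq_along(contours), function(i) {
    c <- contours[[i]]; c$id <- i; c
  })
  set <- cyst_set(img_width(image), img_height(image), organ, cal, contours)
  set$range <- range
  trace <- structure(
    list(green = green, mean_level = th$mean_level, thresholded = th$mask,
         kmeans_refined = ik, opened = io),
    class = "segmentation_trace")
  structure(list(cyst_set = set, trace = trace), class = "cyst_recognition")
}

#' @export
print.cyst_recognition <- function(x, ...) {
  cat(sprintf("<cyst_recognition: %d cysts, mean grey level %.2f>\n",
              length(x$cyst_set$cysts), x$trace$mean_level))
  invisible(x)
}

#' Write the intermediate rasters of a recognition run as PNG masks
#'
#' @param trace a `segmentation_trace`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trace <- function(trace, dir) {
  stopifnot(inherits(trace, "segmentation_trace"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  png::writePNG(as_grey_matrix(trace$green) / 255, file.path(dir, "IG.png"))
  write_mask_png(trace$thresholded, file.path(dir, "IB.png"))
  write_mask_png(trace$kmeans_refined, file.path(dir, "Ik.png"))
  write_mask_png(trace$opened, file.path(dir, "Io.png"))
  invisible(dir)
}
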