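#' Multi-scale local binary pattern configuration
#'
#' Each scale is a (radius R, neighbours P) pair. With the rotation-
#' invariant uniform mapping each scale contributes P + 2 histogram bins
#' (P + 1 uniform rotation classes plus one non-uniform bin), so the
#' default three scales (1,8), (2,16), (3,24) give a 54-dimensional
#' feature vector.
#'
#' @param scales list of `c(R, P)` pairs; `R >= 1` integer, `P >= 4`.
#' @return An `lbp_config` with a `feature_length` field.
#' @export
lbp_config <- function(scales = list(c(1, 8), c(2, 16), c(3, 24))) {
  for (s in scales) {
    if (length(s) != 2L || s[1] < 1 || s[1] != round(s[1]) || s[2] < 4)
      stop("each scale must be c(R, P) with integer R >= 1 and P >= 4")
  }
  structure(list(scales = scales,
                 feature_length = sum(vapply(scales, function(s) s[2] + 2,
                                             numeric(1)))),
            class = "lbp_config")
}

# Bilinear sample of grey matrix g (0-based x, y vectors). Offsets within
# 1e-8 of an integer are snapped so that the axial neighbours of small
# radii are read exactly.
bilinear_sample <- function(g, x, y) {
  x <- ifelse(abs(x - round(x)) < 1e-8, round(x), x)
  y <- ifelse(abs(y - round(y)) < 1e-8, round(y), y)
  x0 <- floor(x); y0 <- floor(y)
  wx <- x - x0; wy <- y - y0
  # the +1 cells carry zero weight when the offset is exactly integral;
  # clamp them so weight-zero reads at the raster edge stay in bounds
  x1 <- pmin(x0 + 1, ncol(g) - 1); y1 <- pmin(y0 + 1, nrow(g) - 1)
  at <- function(xx, yy) g[cbind(yy + 1L, xx + 1L)]
  (1 - wx) * (1 - wy) * at(x0, y0) +
    wx * (1 - wy) * at(x1, y0) +
    (1 - wx) * wy * at(x0, y1) +
    wx * wy * at(x1, y1)
}

# riu2 codes for a set of region pixels at one (R, P) scale.
# Returns integer labels in 0..P+1 (P+1 = non-uniform).
lbp_riu2_codes <- function(g, px, py, R, P) {
  n <- length(px)
  centre <- g[cbind(py + 1L, px + 1L)]
  bits <- matrix(FALSE, n, P)
  for (k in 0:(P - 1)) {
    ang <- 2 * pi * k / P
    nx <- px + R * cos(ang)
    ny <- py - R * sin(ang)
    # the 1e-6 guard keeps the >= tie convention immune to rounding of
    # the bilinear weights (a flat neighbourhood must yield an all-ones
    # pattern)
    bits[, k + 1L] <- bilinear_sample(g, nx, ny) >= centre - 1e-6
  }
  trans <- integer(n)
  for (k in seq_len(P)) {
    k2 <- if (k == P) 1L else k + 1L
    trans <- trans + (bits[, k] != bits[, k2])
  }
  ones <- rowSums(bits)
  ifelse(trans <= 2L, ones, P + 1L)
}

#' Rotation-invariant uniform LBP histogram features of a region
#'
#' For each configured (R, P) scale, every region pixel whose full circular
#' neighbourhood of radius R lies inside the image receives a
#' rotation-invariant uniform LBP code (neighbour >= centre sets the bit;
#' non-integer neighbour positions are sampled by bilinear interpolation;
#' patterns with more than two circular bit transitions share the
#' non-uniform bin). Each scale's P + 2 bin histogram is normalized to sum
#' to one and the blocks are concatenated in the configured scale order.
#'
#' @param grey a [grey_image()] (typically the luminance version of the
#'   RGB image, see [to_grey()]).
#' @param region a `cyst_contour`, a logical mask, or an n x 2 matrix of
#'   0-based (x, y) pixel coordinates; the descriptor is accumulated over
#'   these pixels.
#' @param config an [lbp_config()].
#' @return Numeric feature vector of length `config$feature_length` (54
#'   for the default scales).
#' @export
compute_lbp_features <- function(grey, region, config = lbp_config()) {
  stopifnot(inherits(grey, "grey_image"), inherits(config, "lbp_config"))
  g <- as_grey_matrix(grey)
  H <- nrow(g); W <- ncol(g)
  if (inherits(region, "cyst_contour")) {
    idx <- region$region
    py <- (idx - 1L) %% H
    px <- (idx - 1L) %/% H
  } else if (is.logical(region) && is.matrix(region)) {
    if (!all(dim(region) == dim(g)))
      stop("region mask dimensions must match the image")
    idx <- which(region)
    py <- (idx - 1L) %% H
    px <- (idx - 1L) %/% H
  } else {
    coords <- as.matrix(region)
    if (ncol(coords) != 2L) stop("region coordinates must be an n x 2 matrix")
    px <- as.integer(coords[, 1]); py <- as.integer(coords[, 2])
  }
  if (length(px) == 0L) stop("region-unsupported: region contains no pixels")

  feats <- numeric(0)
  for (s in config$scales) {
    R <- s[1]; P <- s[2]
    m <- ceiling(R)
    ok <- px >= m & px <= W - 1L - m & py >= m & py <= H - 1L - m
    if (!any(ok))
      stop("region-unsupported: no pixel has a full radius-", R,
           " neighbourhood inside the image")
    codes <- lbp_riu2_codes(g, px[ok], py[ok], R, P)
    h <- tabulate(codes + 1L, nbins = P + 2L)
    feats <- c(feats, h / sum(h))
  }
  feats
}
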