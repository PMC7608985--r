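#' Cystic index of a cyst set
#'
#' Percentage of the section area occupied by cyst lumens:
#' `100 * |union of filled cyst regions| / denominator`. Overlapping cysts
#' are counted once (union, not sum), so the index cannot exceed 100. The
#' denominator is the whole image area unless a tissue mask restricts it.
#'
#' @param set a [cyst_set()].
#' @param tissue_mask optional logical matrix (or [binary_mask()])
#'   delimiting the tissue; when supplied, both numerator and denominator
#'   are restricted to it.
#' @return Cystic index in percent.
#' @export
cystic_index <- function(set, tissue_mask = NULL) {
  stopifnot(inherits(set, "cyst_set"))
  total <- as.numeric(set$width) * set$height
  if (total <= 0) stop("image has zero area")
  u <- cyst_union_mask(set)
  if (!is.null(tissue_mask)) {
    tm <- as_mask_matrix(tissue_mask)
    if (!all(dim(tm) == dim(u))) stop("tissue mask dimensions must match")
    if (!any(tm)) stop("tissue mask is empty")
    return(100 * sum(u & tm) / sum(tm))
  }
  100 * sum(u) / total
}

#' Number of cysts in a set
#'
#' @param set a [cyst_set()].
#' @return Integer count.
#' @export
count_cysts <- function(set) length(set$cysts)

#' ImageJ-style global-threshold cystic index
#'
#' The baseline most labs use: threshold the image and report the
#' foreground fraction as the cystic index. Here the threshold is the
#' global mean of the green channel, so the value equals the foreground
#' fraction of the pipeline's initial threshold mask - every bright
#' structure (vessels, ducts, tubules, specks) counts as cyst, which is
#' why this baseline overestimates.
#'
#' @param image an [rgb_image()].
#' @return Foreground percentage of the mean-thresholded green channel.
#' @export
imagej_style_ci <- function(image) {
  th <- global_mean_threshold(extract_green(image))
  100 * mean(th$mask)
}

#' Cyst size profile (diameter histogram)
#'
#' Counts cysts per equivalent-diameter bin: five half-open bins
#' `[k*w, (k+1)*w)` for `k = 0..4` plus an overflow bin for diameters of
#' `5*w` and above (printed as `> 5w`, mirroring the usual presentation
#' with the default 100 px width). Counts always sum to the number of
#' cysts.
#'
#' @param set a [cyst_set()].
#' @param bin_width bin width in pixels (default 100).
#' @return A `size_profile`: integer vector of 6 counts with bin labels.
#' @export
size_profile <- function(set, bin_width = 100) {
  if (bin_width <= 0) stop("bin_width must be positive")
  d <- cyst_diameters(set)
  bin <- pmin(floor(d / bin_width), 5)
  counts <- tabulate(bin + 1L, nbins = 6L)
  labs <- c(sprintf("[%g,%g)", (0:4) * bin_width, (1:5) * bin_width),
            sprintf(">%g", 5 * bin_width))
  structure(counts, names = labs, bin_width = bin_width,
            class = "size_profile")
}

#' @export
print.size_profile <- function(x, ...) {
  cat("Cyst diameter profile (px):\n")
  print(structure(as.integer(x), names = names(x)))
  invisible(x)
}

#' Severity class from the cystic index
#'
#' Organ-specific cut points: kidney mild below 35%, cystic 35-55%
#' (inclusive), severely cystic above 55%; liver mild below 5%, cystic
#' 5-15% (inclusive), severely cystic above 15%.
#'
#' @param ci cystic index in percent, in [0, 100].
#' @param organ `"kidney"` or `"liver"`.
#' @return One of `"mild_cystic"`, `"cystic"`, `"severely_cystic"`.
#' @export
classify_severity <- function(ci, organ = c("kidney", "liver")) {
  organ <- match.arg(organ)
  if (!is.numeric(ci) || is.na(ci) || ci < 0 || ci > 100)
    stop("cystic index must lie in [0, 100]")
  cuts <- if (organ == "kidney") c(35, 55) else c(5, 15)
  if (ci < cuts[1]) "mild_cystic"
  else if (ci <= cuts[2]) "cystic"
  else "severely_cystic"
}

#' Full quantitative result for one image
#'
#' @param set a [cyst_set()].
#' @param image_id identifier written to the CSV export.
#' @param bin_width size-profile bin width in pixels.
#' @param supervised whether the set has been supervised (any edits
#'   applied); defaults to `TRUE` when the edit log is non-empty.
#' @return A `quant_result` bundling calibration, dimensions, cystic
#'   index, cyst count, size profile and severity class.
#' @export
quant_result <- function(set, image_id = "image", bin_width = 100,
                         supervised = length(set$log) > 0) {
  ci <- cystic_index(set)
  structure(list(image_id = image_id,
                 um_per_px = set$calibration$um_per_px,
                 width_px = set$width, height_px = set$height,
                 cystic_index = ci,
                 n_cysts = count_cysts(set),
                 profile = size_profile(set, bin_width),
                 severity = classify_severity(ci, set$organ),
                 organ = set$organ,
                 supervised = isTRUE(supervised)),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("Image %s (%s, %s): CI %.2f%% [%s], %d cysts\n",
              x$image_id, x$organ,
              if (x$supervised) "supervised" else "automated",
              x$cystic_index, x$severity, x$n_cysts))
  print(x$profile)
  invisible(x)
}

#' Export quantification results as CSV
#'
#' One row per image: image id, calibration, dimensions, cystic index,
#' cyst count, then one column per size-profile bin. UTF-8,
#' comma-separated, `.` decimal mark.
#'
#' @param results list of [quant_result()] objects (may be empty: a
#'   header-only file is written).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(results, path) {
  nbins <- if (length(results)) length(results[[1]]$profile) else 6L
  bw <- if (length(results)) attr(results[[1]]$profile, "bin_width") else 100
  bin_cols <- c(sprintf("d_%g_%g", (0:(nbins - 2)) * bw, (1:(nbins - 1)) * bw),
                sprintf("d_over_%g", (nbins - 1) * bw))
  header <- c("image_id", "um_per_px", "width_px", "height_px",
              "cystic_index_pct", "n_cysts", bin_cols)
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "quant_result"))
    data.frame(r$image_id, r$um_per_px, r$width_px, r$height_px,
               r$cystic_index, r$n_cysts,
               matrix(as.integer(r$profile), nrow = 1))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(matrix(nrow = 0, ncol = length(header)))
  names(df) <- header
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  write.table(df, utf8, sep = ",", dec = ".", row.names = FALSE,
              qmethod = "double")
  invisible(path)
}
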