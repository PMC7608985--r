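# Seeded synthetic H&E-like histology with exact ground truth. The
# generator emulates what segmentation relies on: bright (high green)
# elliptical cyst lumens on darker eosin-stained tissue, optional tiny
# cysts below the primary size range, and bright non-cyst distractors
# (tubules, bile ducts, vessels) whose speckled texture separates them
# from smooth lumens at LBP scales of 1-3 px.

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic histology image
#'
#' @param width,height image size in pixels.
#' @param organ `"kidney"` or `"liver"`.
#' @param n_cysts number of primary cysts.
#' @param cyst_d_range equivalent-diameter range (uniform) of primary
#'   cysts, px.
#' @param n_small_cysts number of true cysts below the primary size range.
#' @param small_d_range diameter range of the small cysts, px.
#' @param n_tubules,n_ducts,n_vessels numbers of bright non-cyst
#'   distractors.
#' @param tubule_d_range,duct_d_range,vessel_d_range their diameter
#'   ranges, px.
#' @param tissue_rgb,lumen_rgb base colors (8-bit RGB); the lumen green
#'   value must exceed the tissue green value by at least `green_margin`.
#' @param green_margin required lumen-tissue green-channel contrast.
#' @param noise_sd additive Gaussian noise, grey levels.
#' @param speckle_amplitude distractor texture amplitude (uniform +/-),
#'   grey levels.
#' @param tissue_speckle tissue texture amplitude, grey levels.
#' @param min_separation minimum gap between object boundaries, px.
#' @param seed mandatory integer seed; the generator is deterministic
#'   given the spec.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(width = 1020, height = 768,
                         organ = c("kidney", "liver"),
                         n_cysts = 12, cyst_d_range = c(18, 60),
                         n_small_cysts = 0, small_d_range = c(6, 10),
                         n_tubules = 0, tubule_d_range = c(6, 12),
                         n_ducts = 0, duct_d_range = c(8, 14),
                         n_vessels = 0, vessel_d_range = c(10, 18),
                         tissue_rgb = c(205, 150, 180),
                         lumen_rgb = c(244, 242, 245),
                         green_margin = 60,
                         noise_sd = 4, speckle_amplitude = 40,
                         tissue_speckle = 6, min_separation = 8,
                         seed) {
  organ <- match.arg(organ)
  if (missing(seed)) stop("a seed is mandatory")
  if (lumen_rgb[2] - tissue_rgb[2] < green_margin)
    stop("lumen green must exceed tissue green by at least the margin")
  spec <- list(width = width, height = height, organ = organ,
               n_cysts = n_cysts, cyst_d_range = cyst_d_range,
               n_small_cysts = n_small_cysts, small_d_range = small_d_range,
               n_tubules = n_tubules, tubule_d_range = tubule_d_range,
               n_ducts = n_ducts, duct_d_range = duct_d_range,
               n_vessels = n_vessels, vessel_d_range = vessel_d_range,
               tissue_rgb = tissue_rgb, lumen_rgb = lumen_rgb,
               green_margin = green_margin, noise_sd = noise_sd,
               speckle_amplitude = speckle_amplitude,
               tissue_speckle = tissue_speckle,
               min_separation = min_separation, seed = as.integer(seed))
  class(spec) <- "fixture_spec"
  spec
}

# Ellipse pixel membership over its bounding box; returns linear indices
# into the H x W raster.
ellipse_region <- function(cx, cy, a, b, theta, width, height) {
  x0 <- max(0L, floor(cx - a)); x1 <- min(width - 1L, ceiling(cx + a))
  y0 <- max(0L, floor(cy - a)); y1 <- min(height - 1L, ceiling(cy + a))
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(rep(xs - cx, each = length(ys)), length(ys))
  dy <- matrix(rep(ys - cy, times = length(xs)), length(ys))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  hit <- which(u * u + v * v <= 1, arr.ind = TRUE)
  (xs[hit[, 2]]) * height + ys[hit[, 1]] + 1L
}

place_objects <- function(spec) {
  counts <- c(cyst = spec$n_cysts, small_cyst = spec$n_small_cysts,
              tubule = spec$n_tubules, duct = spec$n_ducts,
              vessel = spec$n_vessels)
  ranges <- list(cyst = spec$cyst_d_range, small_cyst = spec$small_d_range,
                 tubule = spec$tubule_d_range, duct = spec$duct_d_range,
                 vessel = spec$vessel_d_range)
  ecc <- c(cyst = 1.15, small_cyst = 1.1, tubule = 1.0, duct = 1.6,
           vessel = 1.3)
  n_total <- sum(counts)
  budget <- 10L * n_total
  placed <- list()
  for (cls in names(counts)) {
    for (k in seq_len(counts[[cls]])) {
      repeat {
        if (budget <= 0L)
          stop("infeasible packing: could not place all objects")
        budget <- budget - 1L
        d <- runif(1, ranges[[cls]][1], ranges[[cls]][2])
        s <- runif(1, 1, ecc[[cls]])
        a <- d / 2 * s; b <- d / 2 / s
        theta <- runif(1, 0, pi)
        margin <- a + 4
        if (2 * margin >= spec$width || 2 * margin >= spec$height)
          stop("object of diameter ", round(d), " does not fit the image")
        cx <- runif(1, margin, spec$width - 1 - margin)
        cy <- runif(1, margin, spec$height - 1 - margin)
        ok <- TRUE
        for (p in placed) {
          if (sqrt((cx - p$cx)^2 + (cy - p$cy)^2) <
              a + p$a + spec$min_separation) { ok <- FALSE; break }
        }
        if (ok) {
          placed <- c(placed, list(list(class = cls, d = d, cx = cx,
                                        cy = cy, a = a, b = b,
                                        theta = theta)))
          break
        }
      }
    }
  }
  placed
}

#' Generate a synthetic histology image with ground truth
#'
#' Deterministic under the spec's seed: the same spec yields a
#' bit-identical image and truth. Cyst lumens are smooth bright ellipses;
#' distractors are equally bright but carry speckle texture; everything
#' sits on speckled tissue with additive Gaussian noise.
#'
#' @param spec a [fixture_spec()].
#' @return List with `image` (an [rgb_image()]) and `truth`: `cysts` and
#'   `small_cysts` ([cyst_set()] objects with exact regions),
#'   `distractors` (list of class-labelled regions), `diameters`, and
#'   `objects` (raw placement parameters).
#' @export
generate_histology_image <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    objects <- place_objects(spec)

    ch <- lapply(1:3, function(i) matrix(spec$tissue_rgb[i], H, W))
    speck <- matrix(rnorm(H * W, 0, spec$tissue_speckle), H, W)
    for (i in 1:3) ch[[i]] <- ch[[i]] + speck

    for (obj in objects) {
      idx <- ellipse_region(obj$cx, obj$cy, obj$a, obj$b, obj$theta, W, H)
      smooth <- obj$class %in% c("cyst", "small_cyst")
      tex <- if (smooth) 0 else runif(length(idx), -spec$speckle_amplitude,
                                      spec$speckle_amplitude)
      for (i in 1:3) ch[[i]][idx] <- spec$lumen_rgb[i] + tex
    }
    for (i in 1:3) {
      ch[[i]] <- ch[[i]] + matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
      ch[[i]] <- pmin(255, pmax(0, round(ch[[i]])))
    }
    image <- rgb_image(array(c(ch[[1]], ch[[2]], ch[[3]]), c(H, W, 3)))

    mk_set <- function(cls) {
      objs <- Filter(function(o) o$class == cls, objects)
      cysts <- lapply(seq_along(objs), function(i) {
        o <- objs[[i]]
        idx <- ellipse_region(o$cx, o$cy, o$a, o$b, o$theta, W, H)
        m <- mask_from_region(idx, W, H)
        labels <- cpp_label_components(m, 8L)
        poly <- cpp_trace_outer_border(labels, 1L)
        storage.mode(poly) <- "double"
        new_cyst_contour(i, poly, "manual", idx)
      })
      cyst_set(W, H, spec$organ, calibration(1), cysts)
    }
    distractors <- lapply(
      Filter(function(o) o$class %in% c("tubule", "duct", "vessel"), objects),
      function(o) list(class = o$class, d = o$d,
                       region = ellipse_region(o$cx, o$cy, o$a, o$b,
                                               o$theta, W, H)))
    truth <- list(
      cysts = mk_set("cyst"),
      small_cysts = mk_set("small_cyst"),
      distractors = distractors,
      diameters = vapply(Filter(function(o) o$class == "cyst", objects),
                         function(o) o$d, numeric(1)),
      objects = objects)
    list(image = image, truth = truth)
  })
}

#' Generate a labelled LBP training set from recognizer candidates
#'
#' Emulates how the original training data were collected: small training
#' images (true small cysts plus tubule/duct distractors on speckled
#' tissue) are segmented with the fine 3-px opening, and every candidate
#' contour the recognizer proposes becomes a sample - `true_cyst` when it
#' covers a planted small cyst, `false_positive` otherwise (textured
#' distractors and spurious threshold blobs over tissue alike). Classes
#' are balanced by subsampling the majority class. Features are computed
#' by [compute_lbp_features()] on the grey version of each image.
#'
#' @param spec a [fixture_spec()] supplying the appearance parameters
#'   (colors, noise, speckle); its object counts are ignored.
#' @param n_per_class samples per class (>= 20).
#' @param seed integer seed (independent of `spec$seed`).
#' @param config an [lbp_config()].
#' @return List with `features` (matrix), `labels` (factor) and
#'   `provenance` (character).
#' @export
generate_lbp_training_set <- function(spec, n_per_class, seed,
                                      config = lbp_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (n_per_class < 20) stop("n_per_class must be at least 20")
  n_dist <- n_per_class %/% 2L       # textured distractor candidates
  n_blob <- n_per_class - n_dist     # spurious tissue blobs
  with_seed(seed, {
    tf <- list(); fd <- list(); fb <- list()
    imgs <- 0L
    while ((length(tf) < n_per_class || length(fd) < n_dist ||
            length(fb) < n_blob) && imgs < 80L) {
      imgs <- imgs + 1L
      tspec <- fixture_spec(
        width = 400, height = 400, organ = spec$organ,
        n_cysts = 0, n_small_cysts = 10, small_d_range = c(6, 12),
        n_tubules = 4, tubule_d_range = spec$tubule_d_range,
        n_ducts = 4, duct_d_range = spec$duct_d_range,
        tissue_rgb = spec$tissue_rgb, lumen_rgb = spec$lumen_rgb,
        green_margin = spec$green_margin, noise_sd = spec$noise_sd,
        speckle_amplitude = spec$speckle_amplitude,
        tissue_speckle = spec$tissue_speckle,
        min_separation = spec$min_separation,
        seed = sample.int(2^30, 1))
      gen <- generate_histology_image(tspec)
      green <- extract_green(gen$image)
      th <- global_mean_threshold(green)
      io <- denoise_open(kmeans_refine(green, th$mask), "liver")
      cands <- filter_by_diameter(extract_contours(io),
                                  diameter_range(3, 18))
      truemask <- logical(400L * 400L)
      for (cy in gen$truth$small_cysts$cysts) truemask[cy$region] <- TRUE
      distmask <- logical(400L * 400L)
      for (d in gen$truth$distractors) distmask[d$region] <- TRUE
      grey <- to_grey(gen$image)
      for (cy in cands) {
        f <- tryCatch(compute_lbp_features(grey, cy, config),
                      error = function(e) NULL)
        if (is.null(f)) next
        if (sum(truemask[cy$region]) > 0.5 * cy$area_px) {
          if (length(tf) < n_per_class) tf <- c(tf, list(f))
        } else if (sum(distmask[cy$region]) > 0.5 * cy$area_px) {
          if (length(fd) < n_dist) fd <- c(fd, list(f))
        } else {
          fb <- c(fb, list(f))
        }
      }
    }
    if (length(tf) < n_per_class || length(fd) < n_dist ||
        length(fb) < n_blob)
      stop("could not harvest enough candidates of both classes")
    fb <- fb[sample(length(fb), n_blob)]
    feats <- do.call(rbind, c(tf, fd, fb))
    dimnames(feats) <- NULL
    labels <- rep(c("true_cyst", "false_positive"),
                  c(n_per_class, n_per_class))
    list(features = feats, labels = canonical_labels(labels),
         provenance = c(rep("recognized_small_cyst", n_per_class),
                        rep("recognized_distractor", n_dist),
                        rep("recognized_tissue_blob", n_blob)))
  })
}

#' Generate a linearly separable Gaussian feature set
#'
#' Two spherical Gaussian classes in feature space whose means are
#' `separation` standard deviations apart - a sanity-check dataset for
#' the classifier training machinery.
#'
#' @param n total number of samples (split evenly).
#' @param dim feature dimension.
#' @param separation distance between class means in units of the
#'   within-class standard deviation.
#' @param seed integer seed.
#' @return List with `features` and `labels`.
#' @export
generate_blob_dataset <- function(n = 400, dim = 54, separation = 6, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  with_seed(seed, {
    n1 <- n %/% 2L; n2 <- n - n1
    mu <- rep(separation / sqrt(dim), dim)
    x1 <- matrix(rnorm(n1 * dim), n1, dim)
    x2 <- matrix(rnorm(n2 * dim), n2, dim) +
      matrix(mu, n2, dim, byrow = TRUE)
    list(features = rbind(x1, x2),
         labels = canonical_labels(rep(c("true_cyst", "false_positive"),
                                       c(n1, n2))))
  })
}

# Independent tally of the error-accounting rules, written directly from
# the rule list (one FP per deleted/modified automatic detection, one FN
# per added cyst, split = 1 FP + 2 FN, merge of k = k FP + 1 FN,
# complete = 1 FP + 1 FN, remove_inner = 1 FP per removed detection,
# small-cyst pass = 1 FN per accepted cyst). Used as the oracle for
# counts_from_log.
tally_rules <- function(n_auto_untouched, log) {
  fp <- 0L; fn <- 0L
  for (r in log) {
    if (r$kind == "delete") fp <- fp + sum(r$target_origins == "auto")
    if (r$kind == "add") fn <- fn + 1L
    if (r$kind == "complete") { fp <- fp + 1L; fn <- fn + 1L }
    if (r$kind == "split") { fp <- fp + 1L; fn <- fn + 2L }
    if (r$kind == "merge") { fp <- fp + length(r$target_ids); fn <- fn + 1L }
    if (r$kind == "remove_inner") fp <- fp + length(r$target_ids)
    if (r$kind == "add_smaller") fn <- fn + length(r$created_ids)
  }
  list(tp = n_auto_untouched, fp = fp, fn = fn)
}

#' Generate a random but replayable supervision scenario
#'
#' Builds a small automatic cyst set (axis-aligned squares on a grid),
#' applies a random sequence of supervision edits, and returns the
#' expected error counts computed by an independent rule-by-rule tally -
#' an oracle for [counts_from_log()].
#'
#' @param seed integer seed.
#' @param n_ops number of random edits (2-8 drawn if `NULL`).
#' @return List with `initial` (the automatic [cyst_set()]), `final` (the
#'   supervised set), `log` (its edit records) and `expected` (an
#'   [eval_counts()] from the independent tally).
#' @export
generate_edit_scenario <- function(seed, n_ops = NULL) {
  with_seed(seed, {
    W <- 220L; H <- 220L
    pitch <- 22L; side <- 12L
    slots <- expand.grid(gx = 0:8, gy = 0:8)
    slots <- slots[sample(nrow(slots)), ]
    n0 <- sample(6:10, 1)
    sq <- function(x0, y0, s) {
      rbind(c(x0, y0), c(x0 + s - 1, y0), c(x0 + s - 1, y0 + s - 1),
            c(x0, y0 + s - 1))
    }
    used <- 0L
    take_slot <- function() {
      used <<- used + 1L
      c(4L + slots$gx[used] * pitch, 4L + slots$gy[used] * pitch)
    }
    cysts <- lapply(seq_len(n0), function(i) {
      p <- take_slot()
      cyst_contour(i, sq(p[1], p[2], side), W, H, "manual")
    })
    # mark as automatic detections
    cysts <- lapply(cysts, function(c) { c$origin <- "auto"; c })
    initial <- cyst_set(W, H, "kidney", calibration(1), cysts)

    set <- initial
    if (is.null(n_ops)) n_ops <- sample(2:8, 1)
    for (k in seq_len(n_ops)) {
      ids <- set_ids(set)
      choices <- c("add", if (length(ids) >= 1) c("delete", "complete",
                                                  "split", "inner"),
                   if (length(ids) >= 2) "merge")
      op <- sample(choices, 1)
      if (op == "add") {
        p <- take_slot()
        set <- add_cyst(set, sq(p[1], p[2], side))
      } else if (op == "delete") {
        set <- delete_cyst(set, sample(ids, 1))
      } else if (op == "complete") {
        id <- sample(ids, 1)
        cy <- get_cyst(set, id)
        b <- range_box(cy)
        poly <- sq(max(0, b[1] - 1), max(0, b[3] - 1),
                   min(min(W, H) - 1, b[2] - b[1] + 3))
        if (polygon_in_bounds(as_polygon(poly), W, H))
          set <- complete_cyst(set, id, poly)
      } else if (op == "split") {
        id <- sample(ids, 1)
        cy <- get_cyst(set, id)
        b <- range_box(cy)
        if (b[2] - b[1] >= 5) {
          cx <- floor((b[1] + b[2]) / 2)
          set <- tryCatch(
            split_cyst(set, id, rbind(c(cx, max(0, b[3] - 1)),
                                      c(cx, min(H - 1, b[4] + 1)))),
            error = function(e) set)
        }
      } else if (op == "merge") {
        pick <- sample(ids, 2)
        set <- tryCatch(merge_cysts(set, pick), error = function(e) set)
      } else if (op == "inner") {
        id <- sample(ids, 1)
        cy <- get_cyst(set, id)
        if (cy$origin == "auto") {
          b <- range_box(cy)
          poly <- sq(b[1] - 2, b[3] - 2, b[2] - b[1] + 5)
          if (polygon_in_bounds(as_polygon(poly), W, H)) {
            set <- add_cyst(set, poly)
            container <- max(set_ids(set))
            set <- remove_inner_cysts(set, container)
          }
        }
      }
    }
    log <- edit_log(set)
    touched <- unlist(lapply(log, function(r) r$target_ids))
    untouched <- sum(!set_ids(initial) %in% touched)
    tal <- tally_rules(untouched, log)
    list(initial = initial, final = set, log = log,
         expected = eval_counts(tal$tp, tal$fp, tal$fn))
  })
}

# bounding box (x0, x1, y0, y1) of a cyst's region
range_box <- function(cy) {
  # region indices are column-major into an H x W matrix; recover coords
  # from the polygon instead (cheap and exact for these fixtures)
  c(min(cy$polygon[, 1]), max(cy$polygon[, 1]),
    min(cy$polygon[, 2]), max(cy$polygon[, 2]))
}
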