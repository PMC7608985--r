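# Supervision edits. Every operation appends exactly one self-contained
# edit record (targets removed, created contours carried in full), so the
# final cyst set is a pure function of the initial set and the log, and
# undo/redo only move a cursor.

new_edit_record <- function(kind, target_ids, target_origins, created,
                            payload = NULL) {
  structure(list(kind = kind,
                 target_ids = as.integer(target_ids),
                 target_origins = as.character(target_origins),
                 created = created,
                 created_ids = vapply(created, function(c) c$id, integer(1)),
                 payload = payload),
            class = "edit_record")
}

apply_record <- function(cysts, rec) {
  if (length(rec$target_ids))
    cysts <- cysts[!names(cysts) %in% as.character(rec$target_ids)]
  for (c in rec$created) cysts[[as.character(c$id)]] <- c
  cysts
}

# Append a record: any redo tail beyond the cursor is discarded.
push_record <- function(set, rec) {
  set$log <- c(set$log[seq_len(set$cursor)], list(rec))
  set$cursor <- length(set$log)
  set$cysts <- apply_record(set$cysts, rec)
  if (length(rec$created_ids))
    set$next_id <- max(set$next_id, max(rec$created_ids) + 1L)
  set
}

validate_new_polygon <- function(set, polygon) {
  polygon <- as_polygon(polygon)
  if (!is_simple_polygon(polygon))
    stop("polygon must be simple with at least 3 distinct vertices")
  if (!polygon_in_bounds(polygon, set$width, set$height))
    stop("polygon must lie inside the image")
  polygon
}

#' Delete a cyst
#'
#' @param set a [cyst_set()].
#' @param id id of the cyst to remove.
#' @return The edited set, with one edit record appended.
#' @export
delete_cyst <- function(set, id) {
  cy <- get_cyst(set, id)
  push_record(set, new_edit_record("delete", id, cy$origin, list()))
}

#' Manually draw a new cyst
#'
#' @param set a [cyst_set()].
#' @param polygon simple polygon (n x 2, >= 3 distinct vertices) inside
#'   the image.
#' @return The edited set; the new cyst has `origin = "manual"` and a
#'   fresh id.
#' @export
add_cyst <- function(set, polygon) {
  polygon <- validate_new_polygon(set, polygon)
  cy <- cyst_contour(set$next_id, polygon, set$width, set$height, "manual")
  push_record(set, new_edit_record("add", integer(0), character(0), list(cy)))
}

#' Replace a cyst's outline (the Complete tool)
#'
#' Retires the target detection and creates a fresh `derived` cyst with
#' the supplied polygon. For error accounting this counts as one false
#' positive plus one false negative regardless of how much the geometry
#' changed.
#'
#' @param set a [cyst_set()].
#' @param id id of the cyst being completed.
#' @param polygon replacement outline.
#' @return The edited set.
#' @export
complete_cyst <- function(set, id, polygon) {
  old <- get_cyst(set, id)
  polygon <- validate_new_polygon(set, polygon)
  cy <- cyst_contour(set$next_id, polygon, set$width, set$height, "derived")
  push_record(set, new_edit_record("complete", id, old$origin, list(cy)))
}

#' Split one cyst in two along a polyline
#'
#' The cyst's filled region is cut by the 1-px rasterized polyline
#' (removed from both children); the remainder must fall apart into
#' exactly two pieces, which become two `derived` cysts. Children are
#' relabelled with 4-connectivity so that a thin 8-connected cut line
#' separates them.
#'
#' @param set a [cyst_set()].
#' @param id cyst to split.
#' @param polyline n x 2 matrix of (x, y) vertices crossing the cyst from
#'   boundary to boundary.
#' @return The edited set.
#' @export
split_cyst <- function(set, id, polyline) {
  old <- get_cyst(set, id)
  polyline <- as_polygon(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 vertices")
  cut <- cpp_draw_polyline(polyline, set$width, set$height)
  m <- mask_from_region(old$region, set$width, set$height)
  if (!any(m & cut)) stop("polyline does not cross the cyst interior")
  remainder <- m & !cut
  labels <- cpp_label_components(remainder, 4L)
  n <- attr(labels, "n")
  if (n != 2L)
    stop("polyline must bisect the cyst into exactly 2 parts (got ", n, ")")
  created <- lapply(1:2, function(k) {
    poly <- cpp_trace_outer_border(labels, k)
    storage.mode(poly) <- "double"
    region <- region_from_mask(cpp_fill_polygon(poly, set$width, set$height))
    new_cyst_contour(set$next_id + k - 1L, poly, "derived", region)
  })
  push_record(set, new_edit_record("split", id, old$origin, created,
                                   payload = list(polyline = polyline)))
}

#' Merge several cysts into one
#'
#' Takes the union of the filled regions. If the union is already a single
#' 8-connected component it is used as is (so merging overlapping cysts
#' gives exactly the union); otherwise the union is closed with a disk of
#' diameter `2 * gap_tolerance` to bridge small separations and must then
#' form a single component. The outer contour of the result becomes one
#' `derived` cyst; the originals are retired.
#'
#' @param set a [cyst_set()].
#' @param ids at least two cyst ids.
#' @param gap_tolerance bridging half-width in pixels.
#' @return The edited set.
#' @export
merge_cysts <- function(set, ids, gap_tolerance = 8) {
  if (length(ids) < 2L) stop("merge needs at least 2 cyst ids")
  parts <- lapply(ids, function(id) get_cyst(set, id))
  acc <- logical(set$height * set$width)
  for (p in parts) acc[p$region] <- TRUE
  m <- matrix(acc, set$height, set$width)
  labels <- cpp_label_components(m, 8L)
  if (attr(labels, "n") > 1L) {
    closed <- EBImage::closing(m * 1, disk_kernel(2 * gap_tolerance))
    m <- matrix(as.vector(closed) > 0.5, set$height, set$width)
    labels <- cpp_label_components(m, 8L)
    if (attr(labels, "n") != 1L)
      stop("cysts are too far apart to merge (", attr(labels, "n"),
           " components after bridging)")
  }
  poly <- cpp_trace_outer_border(labels, 1L)
  storage.mode(poly) <- "double"
  region <- region_from_mask(cpp_fill_polygon(poly, set$width, set$height))
  cy <- new_cyst_contour(set$next_id, poly, "derived", region)
  push_record(set, new_edit_record(
    "merge", ids, vapply(parts, function(p) p$origin, character(1)),
    list(cy), payload = list(gap_tolerance = gap_tolerance)))
}

#' Remove automatic detections inside a manually drawn cyst
#'
#' Deletes every `auto`-origin cyst whose filled region lies entirely
#' inside the filled region of the manual container cyst.
#'
#' @param set a [cyst_set()].
#' @param container_id id of a cyst with `origin = "manual"`.
#' @return The edited set (unchanged geometry if nothing is inside, but an
#'   edit record is still appended).
#' @export
remove_inner_cysts <- function(set, container_id) {
  container <- get_cyst(set, container_id)
  if (container$origin != "manual")
    stop("container must be a manually drawn cyst")
  inside <- logical(set$height * set$width)
  inside[container$region] <- TRUE
  victims <- Filter(function(c) {
    c$id != container$id && c$origin == "auto" && all(inside[c$region])
  }, set$cysts)
  ids <- vapply(victims, function(c) c$id, integer(1), USE.NAMES = FALSE)
  push_record(set, new_edit_record(
    "remove_inner", ids, rep("auto", length(ids)), list(),
    payload = list(container_id = container$id)))
}

#' Automatically add very small cysts below the primary size range
#'
#' Re-runs the segmentation pipeline with the fine (3 px, liver-style)
#' opening regardless of organ, keeps candidate contours inside
#' `small_range` that do not overlap any existing cyst, and accepts those
#' the texture classifier labels `true_cyst`. Accepted cysts are appended
#' with `origin = "derived"`. A second consecutive run adds nothing, since
#' previously added cysts exclude their candidates by overlap.
#'
#' @param set a [cyst_set()] (typically the result of [recognize_cysts()];
#'   `small_range$dmax` must not exceed the primary `dmin` when the set
#'   records one).
#' @param image the source [rgb_image()].
#' @param model a trained `cyst_classifier`.
#' @param small_range a [diameter_range()] for the small cysts.
#' @return The edited set.
#' @export
add_smaller_cysts <- function(set, image, model, small_range) {
  if (!inherits(model, "cyst_classifier")) stop("model must be trained")
  stopifnot(inherits(image, "rgb_image"), inherits(small_range, "diameter_range"))
  if (!is.null(set$range) && small_range$dmax > set$range$dmin)
    stop("small_range$dmax must not exceed the primary dmin")
  green <- extract_green(image)
  th <- global_mean_threshold(green)
  ik <- kmeans_refine(green, th$mask)
  io <- denoise_open(ik, "liver")     # fine 3-px opening for tiny cysts
  cands <- filter_by_diameter(extract_contours(io), small_range)

  existing <- logical(set$height * set$width)
  for (c in set$cysts) existing[c$region] <- TRUE
  cands <- Filter(function(c) !any(existing[c$region]), cands)

  grey <- to_grey(image)
  created <- list()
  nid <- set$next_id
  for (c in cands) {
    feats <- tryCatch(compute_lbp_features(grey, c, model$lbp_config),
                      error = function(e) NULL)
    if (is.null(feats)) next
    if (as.character(predict(model, matrix(feats, nrow = 1))) == "true_cyst") {
      c$id <- nid
      c$origin <- "derived"
      created <- c(created, list(c))
      nid <- nid + 1L
    }
  }
  push_record(set, new_edit_record(
    "add_smaller", integer(0), character(0), created,
    payload = list(small_range = small_range)))
}

#' Undo / redo the most recent edit
#'
#' Moves the edit-log cursor and recomputes the cyst list by replaying the
#' records before it; records themselves are never mutated.
#'
#' @param set a [cyst_set()].
#' @return The set with the cursor moved.
#' @export
undo_edit <- function(set) {
  if (set$cursor < 1L) stop("nothing to undo")
  set$cursor <- set$cursor - 1L
  replay_to_cursor(set)
}

#' @rdname undo_edit
#' @export
redo_edit <- function(set) {
  if (set$cursor >= length(set$log)) stop("nothing to redo")
  set$cursor <- set$cursor + 1L
  replay_to_cursor(set)
}

replay_to_cursor <- function(set) {
  cysts <- set$initial
  for (k in seq_len(set$cursor)) cysts <- apply_record(cysts, set$log[[k]])
  set$cysts <- cysts
  ids <- c(set$initial_next_id - 1L,
           unlist(lapply(set$log[seq_len(set$cursor)],
                         function(r) r$created_ids)))
  set$next_id <- max(ids) + 1L
  set
}

#' Replay an edit log against an initial cyst set
#'
#' @param initial a [cyst_set()] (its own log, if any, is ignored).
#' @param log list of edit records.
#' @return The final [cyst_set()] obtained by applying every record in
#'   order.
#' @export
replay_edits <- function(initial, log) {
  stopifnot(inherits(initial, "cyst_set"))
  out <- initial
  out$initial <- initial$cysts
  out$initial_next_id <- initial$next_id
  out$log <- log
  out$cursor <- length(log)
  replay_to_cursor(out)
}

#' @export
print.edit_record <- function(x, ...) {
  cat(sprintf("<edit %s: targets [%s] -> created [%s]>\n", x$kind,
              paste(x$target_ids, collapse = ","),
              paste(x$created_ids, collapse = ",")))
  invisible(x)
}

#' The edit log of a cyst set
#'
#' @param set a [cyst_set()].
#' @return List of edit records (all of them, including any undone tail
#'   past the cursor).
#' @export
edit_log <- function(set) set$log
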