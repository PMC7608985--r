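# Annotation XML: lossless round trip of the cyst set (polygons, origins,
# ids, organ, calibration, dimensions) and its edit log. The dialect is
# package-defined:
#
#   <cyst_annotation version="1" organ=".." width=".." height=".."
#                    um_per_px=".." next_id=".." cursor="..">
#     <cysts> <cyst id=".." origin=".."> <vertex x=".." y=".."/>... </cyst> </cysts>
#     <edits> <edit kind=".." ...> <target id=".." origin=".."/>
#             <created> <cyst .../> </created> <payload..../> </edit> </edits>
#   </cyst_annotation>

fmt_num <- function(x) sprintf("%.17g", x)

xml_add_cyst <- function(parent, cy) {
  node <- xml2::xml_add_child(parent, "cyst", id = as.character(cy$id),
                              origin = cy$origin)
  for (k in seq_len(nrow(cy$polygon)))
    xml2::xml_add_child(node, "vertex",
                        x = fmt_num(cy$polygon[k, 1]),
                        y = fmt_num(cy$polygon[k, 2]))
  node
}

xml_read_cyst <- function(node, width, height) {
  vs <- xml2::xml_find_all(node, "./vertex")
  poly <- cbind(x = as.numeric(xml2::xml_attr(vs, "x")),
                y = as.numeric(xml2::xml_attr(vs, "y")))
  id <- as.integer(xml2::xml_attr(node, "id"))
  origin <- xml2::xml_attr(node, "origin")
  if (is.na(id) || !origin %in% c("auto", "manual", "derived"))
    stop("malformed <cyst> element")
  region <- region_from_mask(cpp_fill_polygon(poly, width, height))
  new_cyst_contour(id, as_polygon(poly), origin, region)
}

xml_add_polyline <- function(parent, name, pl) {
  node <- xml2::xml_add_child(parent, name)
  for (k in seq_len(nrow(pl)))
    xml2::xml_add_child(node, "vertex", x = fmt_num(pl[k, 1]),
                        y = fmt_num(pl[k, 2]))
  node
}

#' Export a cyst set (and its edit log) as annotation XML
#'
#' @param set a [cyst_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_annotations_xml <- function(set, path) {
  stopifnot(inherits(set, "cyst_set"))
  doc <- xml2::xml_new_root("cyst_annotation", version = "1",
                            organ = set$organ,
                            width = as.character(set$width),
                            height = as.character(set$height),
                            um_per_px = fmt_num(set$calibration$um_per_px),
                            next_id = as.character(set$next_id),
                            initial_next_id = as.character(set$initial_next_id),
                            cursor = as.character(set$cursor))
  cysts_node <- xml2::xml_add_child(doc, "initial_cysts")
  for (cy in set$initial) xml_add_cyst(cysts_node, cy)
  edits_node <- xml2::xml_add_child(doc, "edits")
  for (rec in set$log) {
    e <- xml2::xml_add_child(edits_node, "edit", kind = rec$kind)
    for (k in seq_along(rec$target_ids))
      xml2::xml_add_child(e, "target",
                          id = as.character(rec$target_ids[k]),
                          origin = rec$target_origins[k])
    created <- xml2::xml_add_child(e, "created")
    for (cy in rec$created) xml_add_cyst(created, cy)
    if (!is.null(rec$payload$polyline))
      xml_add_polyline(e, "polyline", rec$payload$polyline)
    if (!is.null(rec$payload$gap_tolerance))
      xml2::xml_add_child(e, "gap_tolerance",
                          fmt_num(rec$payload$gap_tolerance))
    if (!is.null(rec$payload$container_id))
      xml2::xml_add_child(e, "container",
                          id = as.character(rec$payload$container_id))
    if (!is.null(rec$payload$small_range))
      xml2::xml_add_child(e, "small_range",
                          dmin = fmt_num(rec$payload$small_range$dmin),
                          dmax = fmt_num(rec$payload$small_range$dmax))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a cyst set from annotation XML
#'
#' Reconstructs the initial cysts, replays the edit log and restores the
#' undo cursor, so the returned set is exactly the exported one.
#'
#' @param path annotation XML file written by [export_annotations_xml()].
#' @return A [cyst_set()].
#' @export
import_annotations_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "cyst_annotation")
    stop("not a cyst annotation file")
  width <- as.integer(xml2::xml_attr(doc, "width"))
  height <- as.integer(xml2::xml_attr(doc, "height"))
  organ <- xml2::xml_attr(doc, "organ")
  cal <- calibration(as.numeric(xml2::xml_attr(doc, "um_per_px")))
  cursor <- as.integer(xml2::xml_attr(doc, "cursor"))

  initial <- lapply(xml2::xml_find_all(doc, "./initial_cysts/cyst"),
                    xml_read_cyst, width = width, height = height)
  set <- cyst_set(width, height, organ, cal, initial)
  set$initial_next_id <- as.integer(xml2::xml_attr(doc, "initial_next_id"))

  log <- lapply(xml2::xml_find_all(doc, "./edits/edit"), function(e) {
    kind <- xml2::xml_attr(e, "kind")
    targets <- xml2::xml_find_all(e, "./target")
    created <- lapply(xml2::xml_find_all(e, "./created/cyst"),
                      xml_read_cyst, width = width, height = height)
    payload <- NULL
    pl <- xml2::xml_find_first(e, "./polyline")
    if (!inherits(pl, "xml_missing")) {
      vs <- xml2::xml_find_all(pl, "./vertex")
      payload$polyline <- as_polygon(
        cbind(as.numeric(xml2::xml_attr(vs, "x")),
              as.numeric(xml2::xml_attr(vs, "y"))))
    }
    gt <- xml2::xml_find_first(e, "./gap_tolerance")
    if (!inherits(gt, "xml_missing"))
      payload$gap_tolerance <- as.numeric(xml2::xml_text(gt))
    cn <- xml2::xml_find_first(e, "./container")
    if (!inherits(cn, "xml_missing"))
      payload$container_id <- as.integer(xml2::xml_attr(cn, "id"))
    sr <- xml2::xml_find_first(e, "./small_range")
    if (!inherits(sr, "xml_missing"))
      payload$small_range <- diameter_range(
        as.numeric(xml2::xml_attr(sr, "dmin")),
        as.numeric(xml2::xml_attr(sr, "dmax")))
    new_edit_record(kind, as.integer(xml2::xml_attr(targets, "id")),
                    xml2::xml_attr(targets, "origin"), created, payload)
  })
  set$log <- log
  set$cursor <- cursor
  set$next_id <- as.integer(xml2::xml_attr(doc, "next_id"))
  replayed <- replay_to_cursor(set)
  replayed$next_id <- as.integer(xml2::xml_attr(doc, "next_id"))
  replayed
}
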