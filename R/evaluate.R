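#' Detection error counts
#'
#' True positives are automatic detections the supervisor left untouched;
#' false positives are detections the supervisor deleted or modified;
#' false negatives are cysts the supervisor had to add. `NA = TP + FP` is
#' the number of automatic detections and `NS = TP + FN` the number of
#' cysts after supervision.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return An `eval_counts` with derived `n_auto` (NA) and `n_supervised`
#'   (NS).
#' @export
eval_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0) || anyNA(c(tp, fp, fn)))
    stop("counts must be non-negative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 n_auto = as.integer(tp + fp),
                 n_supervised = as.integer(tp + fn)),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("<eval_counts: TP %d, FP %d, FN %d (NA %d, NS %d)>\n",
              x$tp, x$fp, x$fn, x$n_auto, x$n_supervised))
  invisible(x)
}

#' Tally detection errors from an edit log
#'
#' Applies the error-accounting rules to the supervision record: a split
#' counts one false positive (the wrong detection, like a deletion) and
#' two false negatives (the two cysts added); a merge of k cysts counts k
#' false positives and one false negative; completing an outline counts
#' one of each; deleting an automatic detection or removing detections
#' inside a manual cyst counts false positives; manually adding a cyst
#' counts a false negative. True positives are the initial automatic
#' detections never targeted by any edit. Cysts accepted by the automatic
#' small-cyst pass are counted as false negatives by default (they were
#' missed by the primary recognition); `add_smaller_counts_as = "fp"`
#' switches to counting them as false positives instead.
#'
#' @param initial_auto the [cyst_set()] produced by [recognize_cysts()]
#'   before supervision.
#' @param log list of edit records, or a supervised [cyst_set()] (its
#'   active records up to the cursor are used).
#' @param add_smaller_counts_as `"fn"` (default) or `"fp"`.
#' @return An [eval_counts()].
#' @export
counts_from_log <- function(initial_auto, log,
                            add_smaller_counts_as = c("fn", "fp")) {
  add_smaller_counts_as <- match.arg(add_smaller_counts_as)
  stopifnot(inherits(initial_auto, "cyst_set"))
  if (inherits(log, "cyst_set")) log <- log$log[seq_len(log$cursor)]
  auto_ids <- vapply(initial_auto$cysts, function(c) c$id, integer(1),
                     USE.NAMES = FALSE)
  auto_ids <- auto_ids[vapply(initial_auto$cysts,
                              function(c) c$origin == "auto", logical(1),
                              USE.NAMES = FALSE)]
  touched <- integer(0)
  fp <- 0L; fn <- 0L
  for (rec in log) {
    touched <- c(touched, rec$target_ids)
    switch(rec$kind,
      delete = { fp <- fp + sum(rec$target_origins == "auto") },
      add = { fn <- fn + 1L },
      complete = { fp <- fp + 1L; fn <- fn + 1L },
      split = { fp <- fp + 1L; fn <- fn + 2L },
      merge = { fp <- fp + length(rec$target_ids); fn <- fn + 1L },
      remove_inner = { fp <- fp + length(rec$target_ids) },
      add_smaller = {
        k <- length(rec$created_ids)
        if (add_smaller_counts_as == "fn") fn <- fn + k else fp <- fp + k
      },
      stop("unknown edit kind: ", rec$kind))
  }
  tp <- sum(!auto_ids %in% touched)
  eval_counts(tp, fp, fn)
}

#' Detection sensitivity
#'
#' `Se = 100 * TP / (TP + FN)`: the percentage of true cysts the
#' automatic recognition found.
#'
#' @param counts an [eval_counts()].
#' @return Sensitivity in percent.
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  if (counts$n_supervised == 0) stop("undefined: no supervised cysts (NS = 0)")
  100 * counts$tp / (counts$tp + counts$fn)
}

#' Detection specificity
#'
#' `Sp = (1 - FP / NA) * 100`: the percentage of automatic detections
#' that were real cysts.
#'
#' @param counts an [eval_counts()].
#' @return Specificity in percent.
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  if (counts$n_auto == 0) stop("undefined: no automatic detections (NA = 0)")
  (1 - counts$fp / counts$n_auto) * 100
}

#' Percentage of cysts deleted and added during supervision
#'
#' `PCD = 100 * FP / NA` (so `Sp = 100 - PCD` identically) and
#' `PCA = 100 * FN / NS`.
#'
#' @param counts an [eval_counts()].
#' @return Named numeric vector `c(pcd = , pca = )`.
#' @export
pcd_pca <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  if (counts$n_auto == 0 || counts$n_supervised == 0)
    stop("undefined: zero NA or NS")
  c(pcd = 100 * counts$fp / counts$n_auto,
    pca = 100 * counts$fn / counts$n_supervised)
}

#' All derived detection metrics at once
#'
#' @param counts an [eval_counts()].
#' @param ... lists of [eval_counts()] may be aggregated first with
#'   [aggregate_counts()].
#' @return List with `se`, `sp`, `pcd`, `pca` (percent).
#' @export
eval_metrics <- function(counts, ...) {
  p <- pcd_pca(counts)
  list(se = sensitivity(counts), sp = specificity(counts),
       pcd = unname(p["pcd"]), pca = unname(p["pca"]))
}

#' Aggregate error counts across images
#'
#' Micro-average: counts are summed before computing metrics.
#'
#' @param counts_list list of [eval_counts()].
#' @return A single [eval_counts()].
#' @export
aggregate_counts <- function(counts_list) {
  eval_counts(sum(vapply(counts_list, function(c) c$tp, integer(1))),
              sum(vapply(counts_list, function(c) c$fp, integer(1))),
              sum(vapply(counts_list, function(c) c$fn, integer(1))))
}

#' Match detections against ground truth by region overlap
#'
#' Greedy one-to-one matching: each detected cyst is matched to the
#' unmatched ground-truth cyst with the highest intersection-over-union,
#' provided it reaches the threshold.
#'
#' @param detected,truth [cyst_set()] objects on the same raster.
#' @param iou_threshold minimum intersection-over-union for a match.
#' @return List with `tp`, `fp`, `fn`, `recall`, `precision` and the
#'   match index pairs.
#' @export
detection_stats <- function(detected, truth, iou_threshold = 0.5) {
  det <- unname(detected$cysts); tru <- unname(truth$cysts)
  matched <- logical(length(tru))
  pairs <- NULL
  for (i in seq_along(det)) {
    best <- 0; best_j <- 0L
    ri <- det[[i]]$region
    for (j in seq_along(tru)) {
      if (matched[j]) next
      rj <- tru[[j]]$region
      inter <- length(intersect(ri, rj))
      if (inter == 0) next
      iou <- inter / (length(ri) + length(rj) - inter)
      if (iou > best) { best <- iou; best_j <- j }
    }
    if (best >= iou_threshold) {
      matched[best_j] <- TRUE
      pairs <- rbind(pairs, c(detected = i, truth = best_j))
    }
  }
  tp <- sum(matched)
  list(tp = tp, fp = length(det) - tp, fn = length(tru) - tp,
       recall = if (length(tru)) tp / length(tru) else NA_real_,
       precision = if (length(det)) tp / length(det) else NA_real_,
       matches = pairs)
}

#' System Usability Scale score of one respondent
#'
#' Ten items on a 1-5 scale; odd items are positively worded (response
#' minus one), even items negatively worded (five minus response); the
#' adjusted sum is scaled by 2.5 to 0-100. The adjective bands are:
#' below 25 "worst imaginable"; 25-39 "worst imaginable to poor"; 39-52
#' "poor to ok"; 52-73 "ok to good"; 73-85 "good to excellent"; 85-100
#' "excellent to best imaginable" (boundary scores take the upper band).
#'
#' @param responses integer vector of 10 responses, each in 1..5, in item
#'   order.
#' @return List with `score` (0-100) and `adjective`.
#' @export
sus_score <- function(responses) {
  if (length(responses) != 10L || anyNA(responses) ||
      any(responses < 1 | responses > 5) || any(responses != round(responses)))
    stop("responses must be 10 integers in 1..5")
  odd <- responses[c(1, 3, 5, 7, 9)] - 1
  even <- 5 - responses[c(2, 4, 6, 8, 10)]
  score <- 2.5 * sum(odd, even)
  list(score = score, adjective = sus_adjective(score))
}

#' @rdname sus_score
#' @param score a SUS score in [0, 100].
#' @export
sus_adjective <- function(score) {
  if (score < 0 || score > 100) stop("score must lie in [0, 100]")
  if (score < 25) "worst imaginable"
  else if (score < 39) "worst imaginable to poor"
  else if (score < 52) "poor to ok"
  else if (score < 73) "ok to good"
  else if (score < 85) "good to excellent"
  else "excellent to best imaginable"
}
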