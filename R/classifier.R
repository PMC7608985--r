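#' Cohen's kappa from a 2 x 2 confusion matrix
#'
#' Chance-corrected agreement, `(p_o - p_e) / (1 - p_e)`, where `p_o` is
#' the observed agreement (diagonal fraction) and `p_e` the agreement
#' expected from the marginals. Returns 0 when `p_e = 1` (fully degenerate
#' marginals).
#'
#' @param confusion 2 x 2 matrix of counts (rows: truth, columns:
#'   prediction).
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(2L, 2L))) stop("confusion must be 2 x 2")
  n <- sum(confusion)
  if (n <= 0) stop("confusion table is empty")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) return(0)
  (po - pe) / (1 - pe)
}

#' Hyper-parameter grid for the RBF-SVM
#'
#' Candidate values are powers of two: `C = 2^i` for `i` in
#' `C_exponents` and `gamma = 2^j` for `j` in `gamma_exponents`.
#'
#' @param C_exponents integer exponents for the regularization parameter.
#' @param gamma_exponents integer exponents for the RBF kernel width.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed controlling the data split and fold
#'   assignment.
#' @return A `grid_search_config`.
#' @export
grid_search_config <- function(C_exponents = seq(-5, 15, by = 2),
                               gamma_exponents = seq(-13, 3, by = 2),
                               folds = 4L, seed = 1L) {
  if (length(C_exponents) < 1L || length(gamma_exponents) < 1L)
    stop("grids must be non-empty")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(C_exponents = as.integer(C_exponents),
                 gamma_exponents = as.integer(gamma_exponents),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "grid_search_config")
}

# Labels are canonicalized to a factor with levels true_cyst /
# false_positive.
canonical_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("true_cyst", "false_positive"))
  if (length(bad))
    stop("labels must be 'true_cyst' or 'false_positive'; found: ",
         paste(bad, collapse = ", "))
  factor(labels, levels = c("true_cyst", "false_positive"))
}

# Stratified assignment of n samples to groups with the given proportions
# (within each class, after a seeded shuffle).
stratified_split <- function(labels, props) {
  grp <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    cuts <- floor(cumsum(props) * length(idx))
    start <- 1L
    for (g in seq_along(props)) {
      if (cuts[g] >= start) grp[idx[start:cuts[g]]] <- g
      start <- cuts[g] + 1L
    }
    if (start <= length(idx)) grp[idx[start:length(idx)]] <- length(props)
  }
  grp
}

svm_fit <- function(x, y, C, gamma) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

confusion_2x2 <- function(truth, pred) {
  table(factor(truth, levels = levels(truth)),
        factor(pred, levels = levels(truth)))
}

# Mean CV kappa of one grid cell over precomputed fold ids.
cv_kappa <- function(x, y, fold_id, folds, C, gamma) {
  ks <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- svm_fit(x[tr, , drop = FALSE], y[tr], C, gamma)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    ks[f] <- cohen_kappa(confusion_2x2(y[!tr], pred))
  }
  ks
}

#' Train the small-cyst texture classifier
#'
#' Grid-searched RBF-SVM discriminating true small cysts from false
#' positives (tubules, ducts, vessels) on LBP texture features. The data
#' are split 50% train / 25% validation / 25% test by a seeded stratified
#' shuffle; hyper-parameters are selected by `folds`-fold cross-validated
#' mean Cohen kappa over the pooled train+validation samples; ties are
#' broken towards smaller `C`, then smaller `gamma`. The winner is refit
#' on the pool and evaluated once on the untouched test quarter.
#'
#' @param features numeric matrix, one row per sample (54 columns for the
#'   default LBP configuration).
#' @param labels vector of `"true_cyst"` / `"false_positive"`.
#' @param grid a [grid_search_config()].
#' @param lbp an [lbp_config()] recorded with the model and reused by
#'   [classify_candidates()].
#' @return A `cyst_classifier` with the fitted SVM, the chosen `C` and
#'   `gamma`, and a training report (per-fold kappas of the winner, the
#'   full CV kappa grid, held-out test kappa and accuracy).
#' @export
train_small_cyst_classifier <- function(features, labels,
                                        grid = grid_search_config(),
                                        lbp = lbp_config()) {
  features <- as.matrix(features)
  y <- canonical_labels(labels)
  if (nrow(features) != length(y)) stop("features/labels length mismatch")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (length(y) < 2L * grid$folds)
    stop("need at least ", 2L * grid$folds, " samples")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(grid$seed)

  split <- stratified_split(y, c(0.5, 0.25, 0.25))
  pool <- split != 3L
  xp <- features[pool, , drop = FALSE]; yp <- y[pool]
  xt <- features[!pool, , drop = FALSE]; yt <- y[!pool]
  fold_id <- stratified_split(yp, rep(1 / grid$folds, grid$folds))

  cells <- expand.grid(Ci = grid$C_exponents, gi = grid$gamma_exponents)
  cells <- cells[order(cells$Ci, cells$gi), ]
  cv_mean <- numeric(nrow(cells))
  best <- 1L; best_folds <- NULL
  for (r in seq_len(nrow(cells))) {
    ks <- cv_kappa(xp, yp, fold_id, grid$folds,
                   2^cells$Ci[r], 2^cells$gi[r])
    cv_mean[r] <- mean(ks)
    if (r == 1L || cv_mean[r] > cv_mean[best] + 1e-12) {
      best <- r; best_folds <- ks
    }
  }
  C <- 2^cells$Ci[best]; gamma <- 2^cells$gi[best]
  fit <- svm_fit(xp, yp, C, gamma)
  pred <- predict(fit, xt)
  conf <- confusion_2x2(yt, pred)

  report <- list(
    cv_grid = data.frame(C_exp = cells$Ci, gamma_exp = cells$gi,
                         mean_kappa = cv_mean),
    fold_kappas = best_folds,
    cv_kappa = cv_mean[best],
    test_kappa = cohen_kappa(conf),
    test_accuracy = sum(diag(conf)) / sum(conf),
    test_confusion = conf,
    n_train = sum(split == 1L), n_validation = sum(split == 2L),
    n_test = sum(split == 3L))

  structure(list(model = fit, C = C, gamma = gamma, grid = grid,
                 lbp_config = lbp, report = report),
            class = "cyst_classifier")
}

#' @export
print.cyst_classifier <- function(x, ...) {
  cat(sprintf(
    "<cyst_classifier: RBF SVM, C = 2^%g, gamma = 2^%g, CV kappa %.3f, test kappa %.3f, test accuracy %.3f>\n",
    log2(x$C), log2(x$gamma), x$report$cv_kappa, x$report$test_kappa,
    x$report$test_accuracy))
  invisible(x)
}

#' Predict labels for a feature matrix
#'
#' @param object a `cyst_classifier`.
#' @param newdata numeric feature matrix (rows = samples).
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.cyst_classifier <- function(object, newdata, ...) {
  predict(object$model, as.matrix(newdata))
}

#' Partition candidate cysts into accepted and rejected
#'
#' Computes the LBP descriptor of each candidate region on the grey image
#' and routes candidates predicted `true_cyst` to the accepted set,
#' everything else to the rejected set. Candidates whose region does not
#' support the descriptor (too small or too close to the image border) are
#' rejected with a warning. Ids are preserved; the two sets partition the
#' input.
#'
#' @param candidates a [cyst_set()].
#' @param grey a [grey_image()] (luminance version of the source image).
#' @param model a trained `cyst_classifier`.
#' @return List with `accepted` and `rejected` cyst sets.
#' @export
classify_candidates <- function(candidates, grey, model) {
  stopifnot(inherits(candidates, "cyst_set"), inherits(grey, "grey_image"))
  if (!inherits(model, "cyst_classifier")) stop("model must be trained")
  keep <- logical(length(candidates$cysts))
  for (i in seq_along(candidates$cysts)) {
    cy <- candidates$cysts[[i]]
    feats <- tryCatch(
      compute_lbp_features(grey, cy, model$lbp_config),
      error = function(e) {
        warning("candidate ", cy$id, " rejected: ", conditionMessage(e))
        NULL
      })
    keep[i] <- !is.null(feats) &&
      as.character(predict(model, matrix(feats, nrow = 1))) == "true_cyst"
  }
  subset_set <- function(set, which) {
    out <- set
    out$cysts <- set$cysts[which]
    out$log <- list(); out$cursor <- 0L
    out$initial <- out$cysts
    out
  }
  list(accepted = subset_set(candidates, keep),
       rejected = subset_set(candidates, !keep))
}

#' Persist a trained classifier
#'
#' Writes a versioned archive containing the SVM parameters and support
#' data, the grid and LBP configurations and the training report.
#'
#' @param model a `cyst_classifier`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "cyst_classifier"))
  saveRDS(list(format = "cystquant_classifier", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cystquant_classifier"))
    stop("not a cystquant classifier archive")
  obj$model
}
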