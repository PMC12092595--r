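#' Train a reference-based cell-type classifier
#'
#' Multinomial logistic regression with an L2 (ridge) penalty on the
#' log-normalized reference matrix, the standard reference-based annotation
#' route for imaging-based spatial panels. The penalty strength is selected
#' by stratified k-fold cross-validated multinomial deviance over
#' `strength_grid`; folds are assigned per class from `seed`, so the fit is
#' deterministic. Features are not standardized, mirroring the usual
#' scikit-learn-style setup on log-normalized input.
#'
#' @param ref lognorm-layer [count_matrix()] of reference cells.
#' @param labels cell-type label per reference cell (character or factor).
#' @param cv_folds stratified folds (default 5); every class must have at
#'   least this many members.
#' @param strength_grid penalty (lambda) grid; default 10 log-spaced values.
#' @param seed RNG seed for fold assignment.
#' @return Object of class `isgt_classifier`: gene ids, class labels,
#'   class x gene weight matrix, intercepts, selected strength, CV table.
#' @export
train_classifier <- function(ref, labels, cv_folds = 5L,
                             strength_grid = 10^seq(-4, 1, length.out = 10),
                             seed = 1L) {
  require_layer(ref, "lognorm", "train_classifier")
  labels <- as.character(labels)
  if (length(labels) != n_cells(ref)) {
    stop_("labels length must equal the number of reference cells")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_("need at least 2 classes")
  tab <- table(labels)
  if (any(tab < cv_folds)) {
    small <- names(tab)[tab < cv_folds]
    stop_("class(es) ", paste(small, collapse = ", "), " have fewer members ",
          "than cv_folds = ", cv_folds, "; use a smaller cv_folds")
  }
  if (any(strength_grid <= 0)) stop_("strength_grid values must be positive")

  # stratified fold assignment, deterministic from the seed
  foldid <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in classes) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    f
  })

  x <- dense_counts(ref)
  y <- factor(labels, levels = classes)
  lambda <- sort(unique(strength_grid), decreasing = TRUE)
  if (length(lambda) > 1L) {
    cvfit <- glmnet::cv.glmnet(x, y, family = "multinomial", alpha = 0,
                               lambda = lambda, foldid = foldid,
                               type.measure = "deviance",
                               standardize = FALSE)
    chosen <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
    cv_table <- data.frame(strength = cvfit$lambda, deviance = cvfit$cvm)
  } else {
    fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    chosen <- lambda
    cv_table <- data.frame(strength = lambda, deviance = NA_real_)
  }
  co <- coef(fit, s = chosen)
  weights <- t(vapply(classes, function(cl) as.numeric(co[[cl]])[-1],
                      numeric(n_genes(ref))))
  intercepts <- vapply(classes, function(cl) as.numeric(co[[cl]])[1],
                       numeric(1))
  dimnames(weights) <- list(classes, gene_ids(ref))
  structure(list(gene_ids = gene_ids(ref), class_labels = classes,
                 weights = weights, intercepts = intercepts,
                 regularization_strength = chosen,
                 cv_folds = cv_folds, strength_grid = strength_grid,
                 foldid = foldid, seed = seed, cv_table = cv_table),
            class = "isgt_classifier")
}

#' @export
print.isgt_classifier <- function(x, ...) {
  cat(sprintf("isgt_classifier: %d classes x %d genes, lambda = %g (%d-fold CV)\n",
              length(x$class_labels), length(x$gene_ids),
              x$regularization_strength, x$cv_folds))
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.isgt_classifier <- function(object, ...) {
  cbind(`(Intercept)` = object$intercepts, object$weights)
}

softmax_rows <- function(eta) {
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

#' Predict cell types from a trained classifier
#'
#' Genes are aligned by identifier: columns are reordered to the model's
#' feature space, model genes missing from the query are imputed as 0 on
#' the lognorm scale (with a warning giving the fraction), extra genes are
#' dropped. Fewer than 50% of model genes present is treated as a
#' feature-space mismatch and is an error. Ties at the probability argmax
#' go to the first class in class-label order.
#'
#' @param object an `isgt_classifier`.
#' @param newdata a lognorm-layer [count_matrix()].
#' @param ... unused.
#' @return data.frame with `cell_id`, predicted `cell_type`, and one
#'   probability column `p_<class>` per class (rows sum to 1).
#' @export
predict.isgt_classifier <- function(object, newdata, ...) {
  require_layer(newdata, "lognorm", "predict")
  gid <- gene_ids(newdata)
  present <- object$gene_ids %in% gid
  frac <- mean(present)
  if (frac < 0.5) {
    stop_(sprintf("only %.0f%% of model genes present in the query; feature spaces do not match",
                  100 * frac))
  }
  if (frac < 1) {
    warning(sprintf("%d of %d model genes absent from the query; imputed as 0 (%.1f%%)",
                    sum(!present), length(present), 100 * mean(!present)),
            call. = FALSE)
  }
  x <- matrix(0, n_cells(newdata), length(object$gene_ids),
              dimnames = list(cell_ids(newdata), object$gene_ids))
  common <- object$gene_ids[present]
  x[, common] <- dense_counts(newdata)[, common, drop = FALSE]
  eta <- x %*% t(object$weights) +
    matrix(object$intercepts, nrow(x), length(object$intercepts), byrow = TRUE)
  prob <- softmax_rows(eta)
  colnames(prob) <- object$class_labels
  pred <- object$class_labels[max.col(prob, ties.method = "first")]
  out <- data.frame(cell_id = cell_ids(newdata), cell_type = pred,
                    stringsAsFactors = FALSE)
  probs <- as.data.frame(prob)
  names(probs) <- paste0("p_", object$class_labels)
  cbind(out, probs)
}

#' Serialize / restore a classifier as JSON
#'
#' @param model an `isgt_classifier`.
#' @param path JSON file path.
#' @return `path` (writer) or the restored `isgt_classifier` (reader).
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "isgt_classifier"))
  payload <- list(gene_ids = model$gene_ids, class_labels = model$class_labels,
                  weights = model$weights, intercepts = unname(model$intercepts),
                  regularization_strength = model$regularization_strength,
                  cv_folds = model$cv_folds,
                  strength_grid = model$strength_grid, seed = model$seed)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- matrix(as.numeric(p$weights), nrow = length(p$class_labels),
              dimnames = list(p$class_labels, p$gene_ids))
  structure(list(gene_ids = p$gene_ids, class_labels = p$class_labels,
                 weights = w,
                 intercepts = stats::setNames(as.numeric(p$intercepts),
                                              p$class_labels),
                 regularization_strength = p$regularization_strength,
                 cv_folds = p$cv_folds, strength_grid = p$strength_grid,
                 foldid = NULL, seed = p$seed, cv_table = NULL),
            class = "isgt_classifier")
}
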