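# Minimum-distance-to-mean (MDM) classification on the SPD manifold.

#' Fit an MDM classifier
#'
#' Stores one Karcher-mean prototype per class.  Class order is the factor
#' level order of `labels` (or order of first appearance for character
#' input); it determines deterministic tie-breaking at prediction time.
#'
#' @param feats list of SPD feature matrices (sample covariance or DCCA).
#' @param labels class label per feature; at least 2 classes, at least one
#'   example each.
#' @param reference optional SPD reference matrix (e.g. the training-set
#'   Karcher mean) stored for later recentering schemes.
#' @param ... passed to [karcher_mean()].
#' @return object of class `mdm_model` with elements `prototypes` (named
#'   list), `classes`, and `reference`.
#' @export
mdm_fit <- function(feats, labels, reference = NULL, ...) {
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels, levels = unique(labels))
  if (length(feats) != length(labels)) stop("feats and labels lengths differ", call. = FALSE)
  classes <- levels(labels)
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts == 0L))
    stop("empty class: ", paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
  prototypes <- lapply(classes, function(cl) karcher_mean(feats[labels == cl], ...))
  names(prototypes) <- classes
  structure(list(prototypes = prototypes, classes = classes, reference = reference),
            class = "mdm_model")
}

#' Predict with an MDM classifier
#'
#' The predicted class is the one whose prototype is nearest in AIRM
#' distance; exact ties go to the first class in the model's declared order.
#' Per-class pseudo-probabilities are the softmax of negative distances
#' (temperature 1), a bounded monotone map consistent with the decision rule.
#'
#' @param model an `mdm_model`.
#' @param C SPD feature matrix of matching dimension.
#' @return list with `label`, `distances` (named), and `probabilities`
#'   (named, summing to 1).
#' @export
mdm_predict <- function(model, C) {
  if (!inherits(model, "mdm_model")) stop("not an mdm_model", call. = FALSE)
  if (!all(dim(C) == dim(model$prototypes[[1L]])))
    stop("dimension mismatch with model prototypes", call. = FALSE)
  d <- vapply(model$prototypes, function(P) airm_distance(C, P), numeric(1))
  e <- exp(-(d - min(d)))   # shift-invariant softmax, numerically safe
  p <- e / sum(e)
  list(label = model$classes[which.min(d)], distances = d, probabilities = p)
}
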