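# Cov-CSP-LDA baseline decoder: common spatial patterns from class-mean
# covariance matrices, log-variance features, two-class LDA.

#' Fit common spatial patterns from two class-mean covariance matrices
#'
#' Solves the generalized eigenproblem `C1 w = lambda (C1 + C2) w` (so the
#' generalized eigenvalues lie in \[0, 1\]), ranks filters by discriminability
#' `|lambda - 0.5|` in descending order (ties broken by original index), and
#' keeps the top `n_filters`.  Selected filters satisfy
#' `w' (C1 + C2) w = 1`.
#'
#' @param class_means named list of exactly two SPD matrices (the per-class
#'   mean covariance matrices; arithmetic or Riemannian class means may be
#'   supplied).
#' @param n_filters number of filters to keep (default 3, the most
#'   discriminative ones).
#' @return object of class `csp_filters` with `filters` (n_filters x
#'   n_channels, rows are spatial filters) and `eigenvalues`.
#' @export
csp_fit <- function(class_means, n_filters = 3L) {
  if (length(class_means) != 2L) stop("exactly 2 classes required", call. = FALSE)
  C1 <- class_means[[1L]]; C2 <- class_means[[2L]]
  if (!all(dim(C1) == dim(C2))) stop("dimension mismatch", call. = FALSE)
  n <- nrow(C1)
  if (n_filters > n) stop("n_filters exceeds channel count", call. = FALSE)
  Ctot <- .symmetrize(C1 + C2)
  ev <- eigen(Ctot, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .spd_eps * max(ev))
    stop("composite covariance is singular", call. = FALSE)
  Wh <- spd_invsqrt(Ctot)
  e <- eigen(.symmetrize(Wh %*% C1 %*% Wh), symmetric = TRUE)
  lambda <- e$values                       # in [0, 1]
  ord <- order(-abs(lambda - 0.5), seq_along(lambda))
  keep <- ord[seq_len(n_filters)]
  filters <- t(Wh %*% e$vectors[, keep, drop = FALSE])  # rows are filters
  structure(list(filters = filters, eigenvalues = lambda[keep]),
            class = "csp_filters")
}

#' Log-variance CSP features of one epoch covariance matrix
#'
#' @param C SPD epoch covariance matrix.
#' @param filters a `csp_filters` object.
#' @return numeric vector `log(w' C w)` per selected filter.
#' @export
csp_features <- function(C, filters) {
  W <- filters$filters
  if (ncol(W) != nrow(C)) stop("dimension mismatch", call. = FALSE)
  v <- rowSums((W %*% C) * W)
  if (any(v <= 0)) stop("non-positive projected variance", call. = FALSE)
  log(v)
}

#' Fit a two-class linear discriminant on feature vectors
#'
#' Standard pooled-covariance LDA.  A singular pooled covariance is repaired
#' with a relative ridge of 1e-6 (with a warning).  Prediction is by the sign
#' of the linear discriminant; ties go to the first class in level order.
#'
#' @param X n_obs x n_features matrix.
#' @param labels two-class labels, at least 2 examples per class.
#' @return object of class `lda_model`.
#' @export
lda_fit <- function(X, labels) {
  X <- as.matrix(X)
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels, levels = unique(labels))
  classes <- levels(labels)
  if (length(classes) != 2L) stop("exactly 2 classes required", call. = FALSE)
  if (any(table(labels) < 2L)) stop("need >= 2 examples per class", call. = FALSE)
  X1 <- X[labels == classes[1L], , drop = FALSE]
  X2 <- X[labels == classes[2L], , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  Sw <- ((nrow(X1) - 1) * stats::cov(X1) + (nrow(X2) - 1) * stats::cov(X2)) /
    (nrow(X) - 2)
  if (rcond(Sw) < 1e-12) {
    warning("singular pooled covariance; applying relative ridge 1e-6")
    Sw <- Sw + diag(1e-6 * mean(diag(Sw)), ncol(X))
  }
  w <- solve(Sw, m1 - m2)
  b <- sum(w * (m1 + m2)) / 2
  structure(list(w = w, b = b, classes = classes), class = "lda_model")
}

#' Predict with a fitted two-class LDA
#'
#' @param model an `lda_model`.
#' @param X n_obs x n_features matrix (or a single feature vector).
#' @return character vector of predicted labels.
#' @export
lda_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  score <- drop(as.matrix(X) %*% model$w) - model$b
  ifelse(score >= 0, model$classes[1L], model$classes[2L])
}
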