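# Affine-invariant Riemannian geometry on SPD matrices, covariance
# estimation, and recentering (domain adaptation).

#' Geodesic between two SPD matrices
#'
#' `P1^{1/2} (P1^{-1/2} P2 P1^{-1/2})^t P1^{1/2}` for `t` in \[0, 1\]; `t = 0`
#' returns `P1`, `t = 1` returns `P2`, `t = 0.5` the geometric midpoint.
#'
#' @param P1,P2 SPD matrices of equal dimension.
#' @param t position along the path, in \[0, 1\] (no extrapolation).
#' @return SPD matrix on the geodesic.
#' @export
geodesic <- function(P1, P2, t) {
  if (length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("t must be a single value in [0, 1]", call. = FALSE)
  if (!all(dim(P1) == dim(P2))) stop("dimension mismatch", call. = FALSE)
  h <- spd_sqrt(P1)
  hi <- spd_invsqrt(P1)
  .symmetrize(h %*% spd_powm(hi %*% P2 %*% hi, t) %*% h)
}

#' Affine-invariant Riemannian (AIRM) distance
#'
#' Frobenius norm of the matrix logarithm of `P1^{-1/2} P2 P1^{-1/2}`
#' (the congruence-symmetric evaluation of `||log(P1^{-1} P2)||_F`).
#' Invariant under congruence transforms `P -> W P W'`.
#'
#' @param P1,P2 SPD matrices of equal dimension.
#' @return nonnegative scalar distance.
#' @export
airm_distance <- function(P1, P2) {
  if (!all(dim(P1) == dim(P2))) stop("dimension mismatch", call. = FALSE)
  assert_spd(P1, "P1"); assert_spd(P2, "P2")
  hi <- spd_invsqrt(P1)
  ev <- eigen(.symmetrize(hi %*% P2 %*% hi), symmetric = TRUE,
              only.values = TRUE)$values
  sqrt(sum(log(pmax(ev, .spd_eps))^2))
}

#' Karcher (Riemannian) mean of a set of SPD matrices
#'
#' Fixed-point iteration `P <- P^{1/2} exp(mean_i log(P^{-1/2} C_i P^{-1/2}))
#' P^{1/2}` from the arithmetic-mean initialization, stopped when the
#' Frobenius norm of the mean tangent vector drops below `tol`.  The result
#' minimizes the sum of squared AIRM distances to the set.
#'
#' @param mats non-empty list of SPD matrices of common dimension.
#' @param tol convergence tolerance on the mean tangent-vector norm.
#' @param max_iter maximum number of fixed-point iterations; if reached
#'   without convergence an error of class `dccabci_convergence_failure` is
#'   signalled carrying the last iterate in its `iterate` field.
#' @return SPD matrix with attributes `converged` and `iterations`.
#' @export
karcher_mean <- function(mats, tol = 1e-8, max_iter = 50L) {
  if (length(mats) == 0L) stop("empty set", call. = FALSE)
  n <- nrow(mats[[1L]])
  if (!all(vapply(mats, function(m) all(dim(m) == c(n, n)), logical(1))))
    stop("matrices have differing dimensions", call. = FALSE)
  if (length(mats) == 1L)
    return(structure(.symmetrize(unclass(mats[[1L]])), converged = TRUE, iterations = 0L))
  P <- Reduce(`+`, mats) / length(mats)
  for (it in seq_len(max_iter)) {
    h <- spd_sqrt(P); hi <- spd_invsqrt(P)
    S <- matrix(0, n, n)
    for (C in mats) S <- S + spd_logm(hi %*% C %*% hi)
    S <- S / length(mats)
    if (frob(S) < tol)
      return(structure(P, converged = TRUE, iterations = it))
    P <- .symmetrize(h %*% sym_expm(S) %*% h)
  }
  cnd <- structure(
    class = c("dccabci_convergence_failure", "error", "condition"),
    list(message = sprintf("Karcher mean did not converge in %d iterations", max_iter),
         call = sys.call(-1), iterate = P))
  stop(cnd)
}

#' Ledoit-Wolf shrinkage sample covariance of an epoch
#'
#' Analytic convex combination `(1 - lambda) S + lambda (tr(S)/n) I` of the
#' sample covariance with a scaled identity target, with the shrinkage
#' intensity estimated from the data (guaranteed in \[0, 1\]).  The result is
#' positive definite even when channels outnumber samples.
#'
#' @param X channels x samples numeric matrix with at least 2 samples.
#' @return SPD matrix with attributes `source = "scm"` and `lambda`.
#' @export
shrinkage_scm <- function(X) {
  if (!is.matrix(X) || ncol(X) < 2L)
    stop("need a channels x samples matrix with >= 2 samples", call. = FALSE)
  n <- nrow(X); T <- ncol(X)
  Xc <- X - rowMeans(X)
  S <- tcrossprod(Xc) / T
  mu <- sum(diag(S)) / n
  d2 <- frob(S - diag(mu, n))^2
  if (d2 <= 0) {
    lambda <- 0
  } else {
    # mean squared Frobenius distance of per-sample outer products to S
    b2bar <- 0
    for (t in seq_len(T)) {
      xt <- Xc[, t]
      b2bar <- b2bar + frob(tcrossprod(xt) - S)^2
    }
    b2bar <- b2bar / T^2
    lambda <- min(b2bar, d2) / d2
  }
  C <- (1 - lambda) * S + lambda * diag(mu, n)
  structure(.symmetrize(C), source = "scm", lambda = lambda)
}

#' Trace normalization of an SPD matrix
#'
#' @param C SPD matrix with positive trace.
#' @return `C / trace(C)`; idempotent, removes any global scale factor (such
#'   as the window-averaging convention of the DCCA estimator).
#' @export
trace_normalize <- function(C) {
  tr <- sum(diag(C))
  if (!is.finite(tr) || tr <= 0) stop("trace must be positive", call. = FALSE)
  out <- C / tr
  attributes(out) <- attributes(C)
  out
}

#' Recenter (rebias) an SPD matrix with respect to a reference
#'
#' `R^{-1/2} C R^{-1/2}`: congruence transform aligning the distribution of
#' covariance features across sessions.  Rebiasing a set by its own Karcher
#' mean moves that mean to the identity; AIRM pairwise distances are
#' preserved.
#'
#' @param C SPD matrix to recenter.
#' @param R SPD reference matrix of the same dimension.
#' @return SPD matrix.
#' @export
rebias <- function(C, R) {
  if (!all(dim(C) == dim(R))) stop("dimension mismatch", call. = FALSE)
  hi <- spd_invsqrt(R)
  .symmetrize(hi %*% C %*% hi)
}

#' Initialize an adaptive recentering reference
#'
#' Causally updates the recentering reference as test epochs arrive, starting
#' from the training-set reference.  Two variants are provided:
#' \describe{
#'   \item{`"as_printed"`}{the first test matrix is rebiased with the training
#'     reference and the reference then resets to that first test matrix;
#'     each subsequent matrix `C_i` (1-based `i >= 2`) is rebiased with the
#'     current reference, which afterwards moves along the geodesic toward
#'     `C_i` with step `1/(i - 1)`.}
#'   \item{`"running_mean"`}{the reference starts at the training reference
#'     and moves toward each incoming matrix with step `1/i` after rebiasing
#'     it (a streaming Riemannian running mean seeded by the training data).}
#' }
#' In both variants the rebias of `C_i` happens before the reference update,
#' so no future epoch ever influences an earlier prediction.
#'
#' @param R_train SPD training-set reference (typically the Karcher mean of
#'   the training features).
#' @param variant `"as_printed"` (default) or `"running_mean"`.
#' @return an object of class `adaptive_reference`.
#' @export
adaptive_reference <- function(R_train, variant = c("as_printed", "running_mean")) {
  variant <- match.arg(variant)
  assert_spd(R_train, "R_train")
  structure(list(R = R_train, count = 0L, variant = variant),
            class = "adaptive_reference")
}

#' Absorb one incoming matrix into an adaptive reference
#'
#' @param state an [adaptive_reference()] state.
#' @param C incoming SPD matrix.
#' @return list with the updated `state` and `rebiased`, the recentered
#'   version of `C` (computed with the reference as it stood before this
#'   matrix updated it, preserving temporal causality).
#' @export
adaptive_reference_step <- function(state, C) {
  if (!inherits(state, "adaptive_reference")) stop("not an adaptive_reference", call. = FALSE)
  if (!all(dim(C) == dim(state$R))) stop("dimension mismatch", call. = FALSE)
  i <- state$count + 1L
  out <- rebias(C, state$R)
  if (state$variant == "as_printed") {
    state$R <- if (i == 1L) .symmetrize(unclass(C))
               else geodesic(state$R, C, 1 / (i - 1))
  } else {
    state$R <- geodesic(state$R, C, 1 / i)
  }
  state$count <- i
  list(state = state, rebiased = out)
}
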