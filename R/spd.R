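# Symmetric-eigendecomposition matrix functions for SPD matrices.
# All spectral functions floor eigenvalues at .spd_eps so that log/sqrt/power
# stay finite on numerically near-singular inputs.

.spd_eps <- 1e-12

.symmetrize <- function(P) (P + t(P)) / 2

.spd_eigen <- function(P, floor_eps = .spd_eps) {
  e <- eigen(.symmetrize(P), symmetric = TRUE)
  e$values <- pmax(e$values, floor_eps)
  e
}

.spd_fun <- function(P, f) {
  e <- .spd_eigen(P)
  .symmetrize(e$vectors %*% (f(e$values) * t(e$vectors)))
}

spd_sqrt    <- function(P) .spd_fun(P, sqrt)
spd_invsqrt <- function(P) .spd_fun(P, function(v) 1 / sqrt(v))
spd_logm    <- function(P) .spd_fun(P, log)
spd_powm    <- function(P, t) .spd_fun(P, function(v) v^t)

# exp of a symmetric (not necessarily PD) matrix
sym_expm <- function(S) {
  e <- eigen(.symmetrize(S), symmetric = TRUE)
  .symmetrize(e$vectors %*% (exp(e$values) * t(e$vectors)))
}

frob <- function(M) sqrt(sum(M * M))

#' Test whether a matrix is symmetric positive definite
#'
#' @param P square numeric matrix.
#' @param tol symmetry tolerance (absolute, on `P - t(P)`).
#' @return `TRUE` if `P` is symmetric within `tol` and all eigenvalues are
#'   strictly positive.
#' @export
is_spd <- function(P, tol = 1e-10) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) return(FALSE)
  if (max(abs(P - t(P))) > tol) return(FALSE)
  ev <- eigen(.symmetrize(P), symmetric = TRUE, only.values = TRUE)$values
  all(ev > 0)
}

assert_spd <- function(P, what = "matrix") {
  if (!is_spd(P)) stop(sprintf("%s is not symmetric positive definite", what),
                       call. = FALSE)
  invisible(P)
}
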