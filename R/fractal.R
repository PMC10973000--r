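# Detrended cross-correlation analysis (DCCA), detrended fluctuation
# analysis (DFA), and the detrended cross-correlation coefficient (DCCC).
#
# At scale s the series is cut into windows of s samples (sliding: step 1,
# K = N - s + 1 windows; nonoverlap: K = floor(N/s) windows).  In each window
# a straight line is fitted to each series by OLS and the covariance of the
# residuals is formed; the per-window values are then averaged with the
# 1/(K - 1) convention (a pure scale factor; for the single-window edge case
# K = 1 the lone window value is returned).  For classification features the
# cumulative-sum (profile) step is omitted and residual covariance is taken
# on the native signal; for DFA the profile step is applied.

#' Scale specification for detrended (cross-)correlation analysis
#'
#' @param s detrending window length in samples (integer, at least 4 so the
#'   linear detrend leaves two residual degrees of freedom).
#' @param mode `"sliding"` (step-1 overlapping windows, the streaming-capable
#'   variant and the classification default) or `"nonoverlap"`.
#' @param integrate logical; apply the cumulative-sum profile step before
#'   detrending.  `FALSE` for covariance features, `TRUE` for DFA.
#' @return an object of class `scale_spec`.
#' @export
scale_spec <- function(s, mode = c("sliding", "nonoverlap"), integrate = FALSE) {
  mode <- match.arg(mode)
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 4L)
    stop("scale s must be a single integer >= 4", call. = FALSE)
  structure(list(s = s, mode = mode, integrate = isTRUE(integrate)),
            class = "scale_spec")
}

#' Cumulative-sum profile of a series
#'
#' @param x numeric vector.
#' @return `cumsum(x)`; errors on empty input.
#' @export
integrate_profile <- function(x) {
  if (length(x) < 1L) stop("empty input", call. = FALSE)
  cumsum(x)
}

# Residual-forming projector M = I - H for the design [1, t], t = 1..s.
# M is idempotent and symmetric; cached per s.
.projector_cache <- new.env(parent = emptyenv())

detrend_projector <- function(s) {
  key <- as.character(s)
  M <- .projector_cache[[key]]
  if (!is.null(M)) return(M)
  t <- seq_len(s)
  X <- cbind(1, t)
  H <- X %*% solve(crossprod(X), t(X))
  M <- diag(s) - H
  .projector_cache[[key]] <- M
  M
}

#' Detrended covariance of a single window
#'
#' Fits independent OLS lines to `xw` and `yw` against the sample index and
#' returns the covariance of the residuals with 1/(s - 1) normalization.
#'
#' @param xw,yw numeric windows of equal length `s >= 4`.
#' @return scalar detrended covariance.
#' @export
detrended_cov_window <- function(xw, yw) {
  s <- length(xw)
  if (length(yw) != s) stop("window lengths differ", call. = FALSE)
  if (s < 4L) stop("window length must be >= 4", call. = FALSE)
  M <- detrend_projector(s)
  sum((M %*% xw) * (M %*% yw)) / (s - 1)
}

# Window start indices (1-based) for a series of length N under `spec`.
.window_starts <- function(N, spec) {
  s <- spec$s
  if (N < s) stop("series shorter than scale s", call. = FALSE)
  if (spec$mode == "sliding") {
    seq_len(N - s + 1L)
  } else {
    K <- N %/% s
    if (K < 2L)
      stop("nonoverlap mode needs at least 2 windows (N >= 2s)", call. = FALSE)
    seq(1L, by = s, length.out = K)
  }
}

# rank-2 detrending helper: M = I - Xd (Xd'Xd)^{-1} Xd' for the design
# Xd = [1, t]; applying M as W - Xd (P2 W) costs O(sK) instead of O(s^2 K)
.detrend_lowrank <- function(s) {
  t <- seq_len(s)
  Xd <- cbind(1, t)
  list(Xd = Xd, P2 = solve(crossprod(Xd), t(Xd)))
}

# Core computation shared by dcca_pair / dcca_matrix / dfa_exponent:
# returns the raw (unrepaired) matrix of detrended covariances for an
# n_channels x N input, entry (i,j) = F^2_ij(s).
#
# With the linear detrend, each window's residual cross-product is
#   x' M y = x'y - (Xd'x)' (Xd'Xd)^{-1} (Xd'y),   Xd = [1, t],
# so summing over windows needs only (i) the window-multiplicity-weighted
# Gram matrix of the raw signal (the x'y part: sample t falls in w_t
# windows) and (ii) the per-window moving sums u = sum(x) and first moments
# v = sum(a * x), reducing the cost to O(nN + K n^2) without forming any
# window matrix.
.dcca_raw <- function(X, spec) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  n <- nrow(X)
  N <- ncol(X)
  s <- spec$s
  if (spec$integrate) {
    X <- t(apply(X, 1L, cumsum))
    if (n == 1L) X <- matrix(X, nrow = 1L)  # apply() drops dims for n = 1
  }
  starts <- .window_starts(N, spec)
  K <- length(starts)

  # window multiplicity of each sample
  w <- if (spec$mode == "sliding") {
    pmin(seq_len(N), s, K, N - seq_len(N) + 1L)
  } else {
    c(rep(1, K * s), rep(0, N - K * s))
  }
  F0 <- (X * rep(w, each = n)) %*% t(X)

  # per-window sums and first moments via cumulative sums
  cs <- cbind(0, t(apply(X, 1L, cumsum)))                 # n x (N+1)
  ct <- cbind(0, t(apply(X * rep(seq_len(N), each = n), 1L, cumsum)))
  if (n == 1L) { cs <- matrix(cs, 1L); ct <- matrix(ct, 1L) }
  U <- cs[, starts + s, drop = FALSE] - cs[, starts, drop = FALSE]  # n x K
  V <- ct[, starts + s, drop = FALSE] - ct[, starts, drop = FALSE] -
    (rep(starts - 1L, each = n) * U)
  a <- seq_len(s)
  A <- matrix(c(s, sum(a), sum(a), sum(a^2)), 2L)
  Ai <- solve(A)
  corr <- Ai[1L, 1L] * tcrossprod(U) +
    Ai[1L, 2L] * (tcrossprod(U, V) + tcrossprod(V, U)) +
    Ai[2L, 2L] * tcrossprod(V)
  F2 <- (F0 - corr) / ((s - 1) * max(K - 1L, 1L))
  attr(F2, "n_windows") <- K
  F2
}

#' Detrended covariance of a pair of series at one scale
#'
#' @param x,y numeric vectors of equal length `N >= s`.
#' @param spec a [scale_spec()].
#' @return scalar `F^2(s)`; with `x` identical to `y` this is the squared DFA
#'   fluctuation of `x` under the same spec.
#' @export
dcca_pair <- function(x, y, spec) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  F2 <- .dcca_raw(rbind(x, y), spec)
  F2[1L, 2L]
}

#' Pairwise DCCA matrix of a multichannel epoch
#'
#' Computes the matrix of pairwise detrended covariances of all channels.
#' The result is symmetric positive semi-definite by construction (a Gram
#' matrix of residual windows); if the smallest eigenvalue is not strictly
#' positive (rank-deficient input, e.g. duplicated channels) a ridge of
#' `ridge * mean(diag)` is added to the diagonal and the repair is recorded
#' in the `"repair"` attribute of the result.
#'
#' @param X channels x samples numeric matrix with at least 2 channels.
#' @param spec a [scale_spec()]; classification default is
#'   `scale_spec(s, "sliding", integrate = FALSE)`.
#' @param ridge relative ridge used for the degeneracy repair.
#' @return an SPD matrix with attributes `source = "dcca"`, `scale`, and
#'   `repair` (`NA` if no repair was needed).
#' @export
dcca_matrix <- function(X, spec, ridge = 1e-10) {
  if (!is.matrix(X) || nrow(X) < 2L)
    stop("need a channels x samples matrix with >= 2 channels", call. = FALSE)
  F2 <- .dcca_raw(X, spec)
  d <- diag(F2)
  if (any(d <= 0))
    stop("degenerate input: channel(s) with zero detrended fluctuation: ",
         paste(which(d <= 0), collapse = ", "), call. = FALSE)
  K <- attr(F2, "n_windows")
  F2 <- unclass(F2); attr(F2, "n_windows") <- NULL
  repair <- NA_real_
  ev_min <- min(eigen(.symmetrize(F2), symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    repair <- ridge * mean(d)
    F2 <- F2 + diag(repair, nrow(F2))
  }
  structure(.symmetrize(F2), source = "dcca", scale = spec$s,
            n_windows = K, repair = repair)
}

#' DFA scaling exponent of a univariate series
#'
#' Computes the detrended fluctuation `F(s) = sqrt(F^2(s))` of the
#' cumulative-sum profile at each requested scale and regresses
#' `log F(s)` on `log s` (natural logarithms; the slope is base-invariant).
#' An exponent near 0.5 indicates white noise, larger values persistent
#' long-range correlation.
#'
#' @param x numeric series.
#' @param scales integer vector of at least 3 scales, all `<= length(x)`.
#' @param mode window mode, `"nonoverlap"` (the traditional DFA convention,
#'   default) or `"sliding"`.
#' @return list with `alpha` (the exponent), `scales`, `fluctuation` (per-scale
#'   `F(s)`), and `fit` (intercept, slope, r.squared of the log-log OLS).
#' @export
dfa_exponent <- function(x, scales = 2^(4:8),
                         mode = c("nonoverlap", "sliding")) {
  mode <- match.arg(mode)
  scales <- sort(as.integer(scales))
  if (length(scales) < 3L) stop("need at least 3 scales", call. = FALSE)
  if (max(scales) > length(x)) stop("largest scale exceeds series length", call. = FALSE)
  F2 <- vapply(scales, function(s)
    dcca_pair(x, x, scale_spec(s, mode, integrate = TRUE)), numeric(1))
  if (any(F2 <= 0))
    stop("degenerate input: zero fluctuation at scale(s) ",
         paste(scales[F2 <= 0], collapse = ", "), call. = FALSE)
  Fs <- sqrt(F2)
  lx <- log(scales); ly <- log(Fs)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  list(alpha = unname(fit$coefficients[2L]), scales = scales,
       fluctuation = Fs,
       fit = c(intercept = unname(fit$coefficients[1L]),
               slope = unname(fit$coefficients[2L]), r.squared = r2))
}

#' Detrended cross-correlation coefficient (DCCC)
#'
#' `F^2_xy(s) / (F_x(s) * F_y(s))`, bounded in \[-1, 1\] like an ordinary
#' correlation coefficient.  Tiny numerical overshoots (< 1e-10) are clipped;
#' larger overshoots raise an error.
#'
#' @inheritParams dcca_pair
#' @return scalar in \[-1, 1\].
#' @export
dccc <- function(x, y, spec) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  F2 <- .dcca_raw(rbind(x, y), spec)
  if (any(diag(F2) <= 0))
    stop("degenerate input: zero self-fluctuation", call. = FALSE)
  r <- F2[1L, 2L] / sqrt(F2[1L, 1L] * F2[2L, 2L])
  if (abs(r) > 1 + 1e-10)
    stop("DCCC overshoot beyond numerical tolerance: ", r, call. = FALSE)
  min(1, max(-1, r))
}
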