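# Band-pass filtering (zero-phase offline, causal state-carrying online),
# sliding-window epoching, and EOG amplitude gating.

#' Band-pass filter specification
#'
#' Butterworth band-pass design (coefficients from \pkg{signal}).  The
#' offline path uses 3rd order 8--30 Hz zero-phase (forward--backward, zero
#' group delay, effective order doubled); the online path uses 2nd order
#' causal filtering with state carried across packets.
#'
#' @param order filter order of the underlying band-pass design.
#' @param low_hz,high_hz passband edges, `0 < low < high < rate/2`.
#' @param rate sampling rate in Hz.
#' @param mode `"zero_phase"` or `"causal"`.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(order = 3L, low_hz = 8, high_hz = 30, rate = 512,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate / 2))
    stop("need 0 < low_hz < high_hz < rate/2", call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / (rate / 2), type = "pass")
  structure(list(order = order, low_hz = low_hz, high_hz = high_hz,
                 rate = rate, mode = mode, b = bf$b, a = bf$a),
            class = "filter_spec")
}

# Direct-form-II-transposed IIR filter with explicit state, so that
# packet-wise filtering equals one-shot filtering exactly.
.iir <- function(b, a, x, zi = NULL) {
  nb <- length(b); na <- length(a)
  nz <- max(nb, na) - 1L
  b <- c(b, rep(0, nz + 1L - nb)) / a[1L]
  a <- c(a, rep(0, nz + 1L - na)) / a[1L]
  z <- if (is.null(zi)) rep(0, nz) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (nz > 1L)
      z[seq_len(nz - 1L)] <- b[2L:nz] * xi + z[2L:nz] - a[2L:nz] * yi
    z[nz] <- b[nz + 1L] * xi - a[nz + 1L] * yi
    y[i] <- yi
  }
  list(y = y, state = z)
}

# odd (point-mirrored) edge extension, as customary before zero-phase passes
.reflect_pad <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
}

#' Band-pass filter a multichannel signal
#'
#' Zero-phase mode applies the filter forward and backward over the whole
#' signal with odd reflect padding (transients outside the signal).  Causal
#' mode filters forward-only from zero initial state; use
#' [causal_filter()] to carry state across packets in streaming use.
#'
#' @param X channels x samples numeric matrix (a vector is treated as one
#'   channel).
#' @param spec a [filter_spec()].
#' @return filtered matrix of the same shape.
#' @export
bandpass <- function(X, spec) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  if (any(!is.finite(X))) stop("non-finite samples", call. = FALSE)
  out <- X
  # reflect pad spanning several periods of the low cutoff so edge
  # transients decay inside the padding
  p <- as.integer(ceiling(16 * spec$rate / spec$low_hz))
  for (c in seq_len(nrow(X))) {
    x <- X[c, ]
    if (spec$mode == "zero_phase") {
      xp <- .reflect_pad(x, p)
      y <- rev(.iir0(spec$b, spec$a, rev(.iir0(spec$b, spec$a, xp))))
      np <- (length(xp) - length(x)) / 2
      out[c, ] <- y[(np + 1L):(np + length(x))]
    } else {
      out[c, ] <- .iir(spec$b, spec$a, x)$y
    }
  }
  if (vec) drop(out) else out
}

#' Causally filter a packet, carrying filter state
#'
#' Filtering a signal packet-by-packet through this function yields exactly
#' the same output as filtering it in one shot.
#'
#' @param X channels x samples packet.
#' @param spec a [filter_spec()] (mode is ignored; filtering is causal).
#' @param state previous state as returned by this function, or `NULL` to
#'   start from rest.
#' @return list with `signal` (filtered packet) and `state`.
#' @export
causal_filter <- function(X, spec, state = NULL) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1L)
  out <- X
  st <- vector("list", nrow(X))
  for (c in seq_len(nrow(X))) {
    r <- .iir(spec$b, spec$a, X[c, ], zi = if (is.null(state)) NULL else state[[c]])
    out[c, ] <- r$y
    st[[c]] <- r$state
  }
  list(signal = if (vec) drop(out) else out, state = st)
}

#' Cut a signal into fixed-length sliding epochs
#'
#' Windows are 0-based half-open `[start, start + win)` in samples, start at
#' 0, advance by `step_s * rate` samples (which must be an integer), and only
#' fully contained windows are emitted:
#' `floor((N - win) / step) + 1` epochs.
#'
#' @param X channels x samples matrix.
#' @param rate sampling rate in Hz.
#' @param win_s epoch length in seconds (default 1 s).
#' @param step_s step between epoch starts in seconds (default 62.5 ms).
#' @return list of channels x win matrices, each with attribute
#'   `start_sample` (0-based).
#' @export
epochize <- function(X, rate, win_s = 1, step_s = 0.0625) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  N <- ncol(X)
  win <- win_s * rate
  step <- step_s * rate
  if (abs(win - round(win)) > 1e-9 || abs(step - round(step)) > 1e-9)
    stop("win_s * rate and step_s * rate must be integers", call. = FALSE)
  win <- as.integer(round(win)); step <- as.integer(round(step))
  if (N < win) stop("signal shorter than one epoch", call. = FALSE)
  starts <- seq(0L, N - win, by = step)
  lapply(starts, function(st) {
    e <- X[, (st + 1L):(st + win), drop = FALSE]
    attr(e, "start_sample") <- st
    e
  })
}

#' EOG artifact gate
#'
#' Keeps an epoch unless the absolute EOG amplitude strictly surpasses the
#' threshold (an epoch exactly at the threshold is kept).
#'
#' @param eog numeric vector or matrix of EOG samples in microvolts.
#' @param threshold_uv rejection threshold in microvolts (default 320).
#' @return `TRUE` to keep, `FALSE` to reject.
#' @export
eog_gate <- function(eog, threshold_uv = 320) {
  max(abs(eog)) <= threshold_uv
}
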