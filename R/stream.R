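# Streaming (real-time) sliding-window DCCA.
#
# With the scale fixed, the residual-forming projector M = I - H is a
# constant s x s matrix, so every incoming sample closes exactly one new
# window (the last s samples) and contributes W M W' to the running sum of
# per-window residual cross-products.  The per-sample cost is therefore
# independent of the number of samples seen, and the state holds only the
# last s samples per channel plus the n x n accumulator, matching the
# bounded-memory contract of real-time use.  After n samples the emitted
# matrix equals the batch sliding-window computation on the same data up to
# floating-point roundoff.

#' Initialize a streaming DCCA state
#'
#' @param n_channels number of channels of the incoming signal.
#' @param spec a [scale_spec()]; must have `mode = "sliding"` (the step-1
#'   window recursion is only defined for sliding windows).
#' @return an object of class `dcca_stream`.
#' @export
stream_init <- function(n_channels, spec) {
  if (!inherits(spec, "scale_spec")) stop("spec must be a scale_spec", call. = FALSE)
  if (spec$mode != "sliding")
    stop("streaming DCCA is only defined for sliding windows", call. = FALSE)
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("need at least one channel", call. = FALSE)
  structure(list(
    n_channels = n_channels,
    spec = spec,
    lr = .detrend_lowrank(spec$s),
    buffer = matrix(0, n_channels, spec$s),  # ring buffer, last s samples
    pos = 0L,                                # ring write position
    count = 0L,                              # samples seen
    cum = if (spec$integrate) numeric(n_channels) else NULL,
    S = matrix(0, n_channels, n_channels)    # sum over windows of W M W'
  ), class = "dcca_stream")
}

#' Feed a packet of samples into a streaming DCCA state
#'
#' @param state a `dcca_stream` from [stream_init()].
#' @param packet channels x m matrix (or a vector for a single sample) of new
#'   samples.
#' @return list with the updated `state`, `matrix` (the current DCCA matrix,
#'   or `NULL` while fewer than `s` samples have been seen), and `degenerate`
#'   (`TRUE` if some channel has zero detrended fluctuation so far, e.g. a
#'   constant channel, in which case `matrix` is `NULL`).
#' @export
stream_update <- function(state, packet) {
  if (!inherits(state, "dcca_stream")) stop("not a dcca_stream state", call. = FALSE)
  if (!is.matrix(packet)) packet <- matrix(packet, nrow = state$n_channels)
  if (nrow(packet) != state$n_channels)
    stop("packet has ", nrow(packet), " channels, state expects ",
         state$n_channels, call. = FALSE)
  s <- state$spec$s
  lr <- state$lr
  for (j in seq_len(ncol(packet))) {
    x <- packet[, j]
    if (!is.null(state$cum)) {            # profile step, running cumulative sum
      state$cum <- state$cum + x
      x <- state$cum
    }
    state$pos <- state$pos %% s + 1L
    state$buffer[, state$pos] <- x
    state$count <- state$count + 1L
    if (state$count >= s) {
      # window in chronological order: positions pos+1..s, 1..pos
      ord <- c(seq_len(s)[-seq_len(state$pos)], seq_len(state$pos))
      W <- state$buffer[, ord, drop = FALSE]
      R <- W - tcrossprod(W %*% t(lr$P2), lr$Xd)   # W M, via the rank-2 form
      state$S <- state$S + tcrossprod(R, W)
    }
  }
  if (state$count < s)
    return(list(state = state, matrix = NULL, degenerate = FALSE))
  K <- state$count - s + 1L
  F2 <- .symmetrize(state$S) / ((s - 1) * max(K - 1L, 1L))
  # a channel whose detrended fluctuation is zero relative to its amplitude
  # (e.g. constant input) makes the matrix degenerate
  amp2 <- rowMeans(state$buffer^2)
  if (any(diag(F2) <= 1e-10 * pmax(amp2, .Machine$double.xmin)))
    return(list(state = state, matrix = NULL, degenerate = TRUE))
  list(state = state,
       matrix = structure(F2, source = "dcca", scale = s, n_windows = K),
       degenerate = FALSE)
}
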