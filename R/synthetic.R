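# Synthetic two-class motor-imagery EEG sessions with the statistical
# structure the decoder assumes: band-limited oscillatory activity mixed
# across channels with class-dependent contralateral variance reduction
# (ERD emulation at C3/C4), 1/f-type fractional-Gaussian-noise background,
# optional slow polynomial drifts, and optional between-session covariance
# shifts realized as a random congruence transform.

# zero-state causal IIR via compiled stats::filter (exact zero-state output)
.iir0 <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x) / a[1L]
  yma <- stats::filter(xp, b, method = "convolution", sides = 1L)
  yma <- yma[nb:length(yma)]
  if (length(a) > 1L)
    yma <- stats::filter(yma, -a[-1L] / a[1L], method = "recursive")
  as.numeric(yma)
}

.zero_phase0 <- function(b, a, x) {
  p <- 12L * (max(length(a), length(b)) - 1L)
  xp <- .reflect_pad(x, p)
  p <- (length(xp) - length(x)) / 2   # may have been clipped for short x
  y <- rev(.iir0(b, a, rev(.iir0(b, a, xp))))
  y[(p + 1L):(p + length(x))]
}

# variance gain of the zero-phase band-pass (energy of its impulse response)
.zp_gain <- function(b, a, n = 4096L) {
  h <- .zero_phase0(b, a, c(rep(0, n / 2), 1, rep(0, n / 2)))
  sum(h^2)
}

#' Fractional Gaussian noise by circulant embedding (Davies--Harte)
#'
#' Generates a stationary Gaussian series with the exact autocovariance of
#' fractional Gaussian noise with Hurst parameter `H` and unit variance,
#' using the circulant embedding of the covariance into a 2n circulant whose
#' eigenvalues are obtained by FFT.  If the embedding has (numerically)
#' negative eigenvalues they are clipped to zero with a warning.
#'
#' @param n series length.
#' @param H Hurst exponent in (0, 1); `H = 0.5` gives white noise,
#'   `H > 0.5` persistent long-range correlation.
#' @param seed optional integer seed; the same seed gives bit-identical
#'   output without disturbing the caller's RNG stream.
#' @return numeric vector of length `n`.
#' @export
fgn <- function(n, H, seed = NULL) {
  if (H <= 0 || H >= 1) stop("H must lie in (0, 1)", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  m <- 2L * n
  row <- c(g[1:n], g[n + 1], g[n:2])        # circulant first row, length 2n
  lam <- Re(stats::fft(row))
  if (any(lam < 0)) {
    if (min(lam) < -1e-8)
      warning("circulant embedding not nonnegative definite; clipping eigenvalues")
    lam <- pmax(lam, 0)
  }
  W <- complex(length.out = m)
  W[1] <- sqrt(lam[1]) * stats::rnorm(1)
  W[n + 1] <- sqrt(lam[n + 1]) * stats::rnorm(1)
  a <- stats::rnorm(n - 1); b <- stats::rnorm(n - 1)
  W[2:n] <- sqrt(lam[2:n] / 2) * complex(real = a, imaginary = b)
  W[m:(n + 2)] <- Conj(W[2:n])
  x <- Re(stats::fft(W)) / sqrt(m)
  x[1:n]
}

#' Specification of a synthetic motor-imagery session
#'
#' Defaults emulate the recording structure of a 22-channel, 512 Hz
#' two-class session: four runs of 20 trials (balanced left/right), 6.5 s
#' of active imagery per trial separated by 2 s rests.  Oscillatory activity
#' is band-limited (8--30 Hz) Gaussian noise mixed across channels; the left
#' class reduces oscillatory variance at C4 (and partially at FC6/CP6), the
#' right class at C3 (FC5/CP5), emulating contralateral event-related
#' desynchronization.  A per-channel fractional Gaussian noise background
#' adds 1/f-type broadband activity.  Optional per-channel random cubic
#' polynomial drifts span each trial (local non-stationarities that local
#' detrending removes but whole-epoch sample covariance does not), and an
#' optional random congruence transform emulates between-session covariance
#' shifts.
#'
#' @param n_channels,rate,channels montage and sampling rate.
#' @param classes the two class labels.
#' @param n_runs,trials_per_run,trial_s,rest_s trial layout.
#' @param osc_band,osc_amp oscillatory band (Hz) and source amplitude (SD).
#' @param bg_hurst,bg_amp Hurst exponent and amplitude of the background.
#' @param erd_gain variance multiplier at the contralateral channel
#'   (C4 for left, C3 for right).
#' @param neighbor_gain variance multiplier at its immediate neighbours.
#' @param mix_strength off-diagonal strength of the fixed channel mixing.
#' @param drift_order,drift_amp polynomial drift order and SD (0 disables).
#' @param shift_strength magnitude of the between-session congruence
#'   transform `W = I + shift_strength * G/sqrt(n)`.
#' @param subject_seed seed of subject-level structure (channel mixing),
#'   shared between sessions of the same subject.
#' @return object of class `session_spec`.
#' @export
session_spec <- function(n_channels = 22L, rate = 512,
                         channels = NULL,
                         classes = c("left", "right"),
                         n_runs = 4L, trials_per_run = 20L,
                         trial_s = 6.5, rest_s = 2,
                         osc_band = c(8, 30), osc_amp = 1,
                         bg_hurst = 0.7, bg_amp = 0.5,
                         erd_gain = 0.5, neighbor_gain = 0.75,
                         mix_strength = 0.3,
                         drift_order = 3L, drift_amp = 0,
                         shift_strength = 0.25,
                         subject_seed = 1L) {
  if (is.null(channels)) {
    std22 <- c("F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
               "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1", "CP2", "CP6",
               "P7", "P3", "Pz", "P4")
    channels <- if (n_channels == 22L) std22
                else paste0("CH", seq_len(n_channels))
  }
  stopifnot(length(channels) == n_channels, length(classes) == 2L)
  structure(as.list(environment()), class = "session_spec")
}

# per-class oscillatory variance gains over channels
.class_gains <- function(spec) {
  g <- stats::setNames(rep(1, spec$n_channels), spec$channels)
  gl <- g; gr <- g
  contra <- function(g, main, nb, spec) {
    if (main %in% names(g)) g[main] <- spec$erd_gain
    nb <- intersect(nb, names(g))
    g[nb] <- spec$neighbor_gain
    g
  }
  gl <- contra(gl, "C4", c("FC6", "CP6"), spec)   # left MI: right hemisphere
  gr <- contra(gr, "C3", c("FC5", "CP5"), spec)   # right MI: left hemisphere
  out <- list(gl, gr)
  names(out) <- spec$classes
  out
}

#' Generate a synthetic motor-imagery session
#'
#' @param spec a [session_spec()].
#' @param seed integer seed of the session-level randomness (noise, trial
#'   order, drifts, shift); together with `spec` it fully determines the
#'   output.
#' @param apply_shift apply the between-session congruence transform
#'   (typically `FALSE` for the first and `TRUE` for a second session of the
#'   same subject).
#' @return object of class `mi_session`: list with `signal` (channels x
#'   samples), `rate`, `channels`, `labels` (per-trial factor), `onsets`
#'   (0-based trial onset samples), `trial_len` (samples), `class_cov`
#'   (ground-truth oscillatory-plus-background covariance per class, before
#'   any shift), `mixing`, `shift` (the transform or `NULL`), `spec`, `seed`.
#' @export
generate_session <- function(spec, seed, apply_shift = FALSE) {
  stopifnot(inherits(spec, "session_spec"))
  n <- spec$n_channels
  rate <- spec$rate
  trial_len <- as.integer(round(spec$trial_s * rate))
  rest_len <- as.integer(round(spec$rest_s * rate))
  n_trials <- spec$n_runs * spec$trials_per_run

  set.seed(spec$subject_seed)
  B <- diag(n) + spec$mix_strength * matrix(stats::rnorm(n * n), n) / sqrt(n)

  set.seed(seed)
  labels <- factor(unlist(lapply(seq_len(spec$n_runs), function(r)
    sample(rep(spec$classes, length.out = spec$trials_per_run)))),
    levels = spec$classes)

  bf <- signal::butter(3, spec$osc_band / (rate / 2), type = "pass")
  gain <- sqrt(.zp_gain(bf$b, bf$a))
  gains <- .class_gains(spec)

  seg_len <- trial_len + rest_len
  N <- n_trials * seg_len
  X <- matrix(0, n, N)
  onsets <- integer(n_trials)
  for (tr in seq_len(n_trials)) {
    a0 <- (tr - 1L) * seg_len            # 0-based segment start
    onsets[tr] <- a0
    src <- matrix(stats::rnorm(n * seg_len), n, seg_len)
    for (c in seq_len(n)) src[c, ] <- .zero_phase0(bf$b, bf$a, src[c, ]) / gain
    g <- gains[[as.character(labels[tr])]]
    amp <- sqrt(g) * spec$osc_amp
    seg <- B %*% (amp * src)
    # rest portion: baseline (no ERD) oscillation
    if (rest_len > 0L) {
      rest_idx <- (trial_len + 1L):seg_len
      seg[, rest_idx] <- B %*% (spec$osc_amp * src[, rest_idx, drop = FALSE])
    }
    if (spec$drift_amp > 0) {
      u <- seq(-1, 1, length.out = trial_len)
      U <- outer(u, 0:spec$drift_order, `^`)
      cf <- matrix(stats::rnorm(n * (spec$drift_order + 1L)), spec$drift_order + 1L, n)
      D <- U %*% cf                       # trial_len x n
      D <- t(D) / pmax(apply(D, 2L, stats::sd), 1e-12) * spec$drift_amp
      seg[, seq_len(trial_len)] <- seg[, seq_len(trial_len)] + D
    }
    X[, a0 + seq_len(seg_len)] <- seg
  }
  for (c in seq_len(n)) X[c, ] <- X[c, ] + spec$bg_amp * fgn(N, spec$bg_hurst)

  class_cov <- lapply(gains, function(g)
    .symmetrize(spec$osc_amp^2 * B %*% (g * t(B))) + diag(spec$bg_amp^2, n))

  W <- NULL
  if (apply_shift && spec$shift_strength > 0) {
    W <- diag(n) + spec$shift_strength * matrix(stats::rnorm(n * n), n) / sqrt(n)
    X <- W %*% X
  }
  dimnames(X) <- list(spec$channels, NULL)
  structure(list(signal = X, rate = rate, channels = spec$channels,
                 labels = labels, onsets = onsets, trial_len = trial_len,
                 class_cov = class_cov, mixing = B, shift = W,
                 spec = spec, seed = seed),
            class = "mi_session")
}

#' Inject stereotyped blink transients into an EOG channel
#'
#' Adds raised-cosine deflections of the given amplitude at Poisson-process
#' times.
#'
#' @param eog numeric EOG series (microvolts).
#' @param rate sampling rate in Hz.
#' @param rate_per_min expected number of blinks per minute.
#' @param amplitude_uv peak deflection in microvolts.
#' @param duration_s blink duration (default 0.3 s).
#' @param seed optional seed (isolated from the caller's RNG stream).
#' @return list with `signal` and `onsets` (0-based sample indices).
#' @export
inject_blinks <- function(eog, rate, rate_per_min, amplitude_uv,
                          duration_s = 0.3, seed = NULL) {
  if (amplitude_uv <= 0) stop("amplitude must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(eog)
  minutes <- n / rate / 60
  k <- stats::rpois(1L, rate_per_min * minutes)
  if (k == 0L) return(list(signal = eog, onsets = integer(0)))
  len <- as.integer(round(duration_s * rate))
  pulse <- amplitude_uv * (1 - cos(2 * pi * seq_len(len) / (len + 1))) / 2
  onsets <- sort(sample.int(max(n - len, 1L), k, replace = TRUE)) - 1L
  for (o in onsets) {
    idx <- (o + 1L):min(o + len, n)
    eog[idx] <- eog[idx] + pulse[seq_along(idx)]
  }
  list(signal = eog, onsets = onsets)
}

#' Covariance or DCCA features for a list of epochs
#'
#' Convenience wrapper turning raw epochs into classifier-ready SPD feature
#' matrices: Ledoit--Wolf shrinkage sample covariance (`"scm"`) or a DCCA
#' matrix at the given scale (`"dcca"`), optionally trace-normalized
#' (default, removing global scale conventions).
#'
#' @param epochs list of channels x samples matrices.
#' @param estimator `"dcca"` or `"scm"`.
#' @param scale DCCA detrending scale in samples (default 128).
#' @param trace_norm trace-normalize each feature (default `TRUE`).
#' @return list of SPD matrices.
#' @export
epoch_features <- function(epochs, estimator = c("dcca", "scm"), scale = 128L,
                           trace_norm = TRUE) {
  estimator <- match.arg(estimator)
  spec <- if (estimator == "dcca") scale_spec(scale, "sliding", integrate = FALSE)
  lapply(epochs, function(e) {
    C <- if (estimator == "dcca") dcca_matrix(e, spec) else shrinkage_scm(e)
    if (trace_norm) trace_normalize(C) else C
  })
}
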