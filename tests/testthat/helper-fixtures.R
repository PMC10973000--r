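# Shared fixtures: random SPD matrices, tangent-space perturbed SPD samples,
# and small epoched synthetic sessions (all generated in code, seeded).

rand_spd <- function(n, scale = 1) {
  A <- matrix(stats::rnorm(n * n), n)
  scale * (crossprod(A) / n + diag(n) * 0.5)
}

# SPD samples scattered around a prototype via tangent-space Gaussian noise
spd_around <- function(P, k, sd = 0.05) {
  h <- dccabci:::spd_sqrt(P)
  lapply(seq_len(k), function(i) {
    E <- matrix(stats::rnorm(nrow(P)^2, sd = sd), nrow(P))
    h %*% dccabci:::sym_expm((E + t(E)) / 2) %*% h
  })
}

# brute-force sliding/nonoverlap DCCA oracle via per-window lm() fits
dcca_brute <- function(x, y, s, mode = "sliding", integrate = FALSE) {
  if (integrate) { x <- cumsum(x); y <- cumsum(y) }
  N <- length(x)
  starts <- if (mode == "sliding") 1:(N - s + 1) else seq(1, by = s, length.out = N %/% s)
  t <- 1:s
  f <- vapply(starts, function(k) {
    rx <- stats::resid(stats::lm(x[k:(k + s - 1)] ~ t))
    ry <- stats::resid(stats::lm(y[k:(k + s - 1)] ~ t))
    sum(rx * ry) / (s - 1)
  }, numeric(1))
  sum(f) / max(length(starts) - 1, 1)
}

# epochs + labels from a generated session (non-overlapping 1-s epochs keep
# unit tests fast; the step is a test-size choice, not a pipeline default)
session_epochs <- function(ses, step_s = 1) {
  eps <- list(); labs <- character(0); trial_id <- integer(0)
  for (i in seq_along(ses$onsets)) {
    seg <- ses$signal[, (ses$onsets[i] + 1):(ses$onsets[i] + ses$trial_len),
                      drop = FALSE]
    e <- epochize(seg, ses$rate, 1, step_s)
    eps <- c(eps, e)
    labs <- c(labs, rep(as.character(ses$labels[i]), length(e)))
    trial_id <- c(trial_id, rep(i, length(e)))
  }
  list(epochs = eps, labels = labs, trial_id = trial_id)
}

# train-on-session-1 / replay-on-session-2 pipeline used by the benchmark
# tests; returns sample-wise kappa on the test session
two_session_kappa <- function(seed, drift_amp, estimator,
                              adaptation = "adaptive", scale = 128) {
  sp <- session_spec(n_runs = 1, trials_per_run = 20, drift_amp = drift_amp,
                     subject_seed = seed)
  tr <- generate_session(sp, 10 * seed + 1)
  te <- generate_session(sp, 10 * seed + 2, apply_shift = TRUE)
  etr <- session_epochs(tr); ete <- session_epochs(te)
  ftr <- epoch_features(etr$epochs, estimator, scale)
  fte <- epoch_features(ete$epochs, estimator, scale)
  R <- karcher_mean(ftr)
  model <- mdm_fit(lapply(ftr, rebias, R = R), etr$labels, reference = R)
  rep_ <- pseudo_online_replay(fte, model, adaptation,
                               reference = if (adaptation == "rebias") karcher_mean(fte))
  cohen_kappa(confusion_table(ete$labels, rep_$labels, model$classes))
}
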