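# Post-hoc analyses: detrended cross-correlation coefficient (DCCC)
# connectivity networks contrasted between classes, and per-channel DFA
# scaling-exponent topography.

# normality-routed paired test: Lilliefors on the paired differences picks
# the paired t-test (normal at the 0.05 level) or the Wilcoxon signed-rank
# test; with fewer than 4 pairs normality cannot be assessed and the t-test
# is used.
.paired_auto_test <- function(a, b) {
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate paired differences: identical data are indistinguishable
    # (p = 1); a perfectly constant nonzero shift is maximal evidence
    return(list(test = "none", p = if (all(d == 0)) 1 else 0))
  }
  normal <- TRUE
  if (length(d) >= 4L)
    normal <- nortest::lillie.test(d)$p.value >= 0.05
  if (normal) {
    list(test = "t", p = stats::t.test(a, b, paired = TRUE)$p.value)
  } else {
    list(test = "wilcoxon",
         p = suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))$p.value)
  }
}

#' Mean DCCC connectivity network of a set of epochs
#'
#' Computes the detrended cross-correlation coefficient matrix of every
#' epoch at the given scale (no profile step, matching the covariance-mode
#' convention) and averages over epochs.  The diagonal is 1 by construction.
#'
#' @param epochs list of channels x samples matrices (typically the epochs
#'   of one class, restricted to correctly delivered trials).
#' @param spec a [scale_spec()] (default: sliding, `s = 128`).
#' @return symmetric n x n matrix of mean coefficients in \[-1, 1\].
#' @export
dccc_network <- function(epochs, spec = scale_spec(128L, "sliding")) {
  if (length(epochs) < 1L) stop("need at least one epoch", call. = FALSE)
  acc <- NULL
  for (e in epochs) {
    F2 <- .dcca_raw(e, spec)
    d <- diag(F2)
    if (any(d <= 0)) stop("degenerate channel: zero self-fluctuation", call. = FALSE)
    D <- F2 / sqrt(outer(d, d))
    D <- pmin(pmax(D, -1), 1)      # first argument keeps the matrix shape
    acc <- if (is.null(acc)) D else acc + D
  }
  out <- .symmetrize(acc / length(epochs))
  diag(out) <- 1
  dimnames(out) <- dimnames(epochs[[1L]])[c(1L, 1L)]
  out
}

#' Contrast per-connection DCCC between two classes across subjects
#'
#' For every channel pair, the paired per-subject coefficients of the two
#' classes are compared with a paired t-test or Wilcoxon signed-rank test
#' (selected by a Lilliefors normality test on the differences; p-values are
#' deliberately not adjusted for multiple comparisons -- the analysis is
#' exploratory).  Significant connections are sorted into three exhaustive,
#' mutually exclusive categories from the group-mean coefficient signs:
#' positive in both classes, negative in both, or sign-flipping.
#'
#' @param nets_a,nets_b lists (one element per subject, paired) of n x n
#'   DCCC networks from [dccc_network()].
#' @param alpha significance level (default 0.05, unadjusted).
#' @return data frame with one row per connection: channel indices/names,
#'   mean coefficient per class, test used, p-value, significance flag, and
#'   category (`"positive_both"`, `"negative_both"`, `"sign_flip"`, or `NA`
#'   for non-significant connections).
#' @export
contrast_connections <- function(nets_a, nets_b, alpha = 0.05) {
  ns <- length(nets_a)
  if (ns != length(nets_b)) stop("subject lists must be paired", call. = FALSE)
  if (ns < 3L) stop("need at least 3 subjects", call. = FALSE)
  n <- nrow(nets_a[[1L]])
  chan <- rownames(nets_a[[1L]])
  if (is.null(chan)) chan <- paste0("ch", seq_len(n))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    a <- vapply(nets_a, function(m) m[i, j], numeric(1))
    b <- vapply(nets_b, function(m) m[i, j], numeric(1))
    tst <- .paired_auto_test(a, b)
    sig <- tst$p < alpha
    ma <- mean(a); mb <- mean(b)
    cat_ <- if (!isTRUE(sig)) NA_character_
            else if (ma > 0 && mb > 0) "positive_both"
            else if (ma < 0 && mb < 0) "negative_both"
            else "sign_flip"
    data.frame(i = i, j = j, channel_i = chan[i], channel_j = chan[j],
               mean_a = ma, mean_b = mb, test = tst$test, p = tst$p,
               significant = sig, category = cat_)
  })
  do.call(rbind, res)
}

#' Per-channel DFA topography and class contrast
#'
#' Computes, per subject and class, the channel-wise DFA scaling exponent
#' (cumulative-sum profile, dyadic scales) averaged over epochs, then
#' contrasts the two classes channel-by-channel with the normality-routed
#' paired test.  Epochs are expected broadband-filtered (e.g. 1--45 Hz).
#'
#' @param epochs_a,epochs_b lists over subjects (paired); each element is a
#'   list of channels x samples epoch matrices of that subject and class.
#' @param scales DFA scales in samples (default dyadic 16--256; epochs must
#'   be at least `max(scales)` samples long).
#' @param alpha significance level for the per-channel contrast.
#' @return list with `exponents_a`, `exponents_b` (subjects x channels
#'   matrices of mean exponents) and `contrast` (data frame: channel, mean
#'   exponent per class, test, p, significance).
#' @export
dfa_topography <- function(epochs_a, epochs_b, scales = 2^(4:8), alpha = 0.05) {
  ns <- length(epochs_a)
  if (ns != length(epochs_b)) stop("subject lists must be paired", call. = FALSE)
  subj_mean <- function(eps) {
    al <- vapply(eps, function(e)
      apply(e, 1L, function(x) dfa_exponent(x, scales)$alpha),
      numeric(nrow(eps[[1L]])))
    rowMeans(matrix(al, nrow = nrow(eps[[1L]])))
  }
  A <- t(vapply(epochs_a, subj_mean, numeric(nrow(epochs_a[[1L]][[1L]]))))
  B <- t(vapply(epochs_b, subj_mean, numeric(nrow(epochs_b[[1L]][[1L]]))))
  chan <- rownames(epochs_a[[1L]][[1L]])
  if (is.null(chan)) chan <- paste0("ch", seq_len(ncol(A)))
  contrast <- do.call(rbind, lapply(seq_len(ncol(A)), function(c) {
    tst <- .paired_auto_test(A[, c], B[, c])
    data.frame(channel = chan[c], mean_a = mean(A[, c]), mean_b = mean(B[, c]),
               test = tst$test, p = tst$p, significant = tst$p < alpha)
  }))
  colnames(A) <- chan; colnames(B) <- chan
  list(exponents_a = A, exponents_b = B, contrast = contrast)
}
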