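# Performance metrics: sample-wise accuracy, Cohen's kappa, binomial chance
# level, bar dynamics, command-delivery metrics, and group-level statistics.

#' Confusion table from true and predicted labels
#'
#' @param truth,pred label vectors of equal length.
#' @param classes class set fixing row/column order (default: union of the
#'   observed labels).
#' @return k x k integer matrix, rows = truth, columns = prediction.
#' @export
confusion_table <- function(truth, pred, classes = NULL) {
  if (is.null(classes)) classes <- union(unique(truth), unique(pred))
  table(factor(truth, levels = classes), factor(pred, levels = classes),
        dnn = c("truth", "pred"))
}

#' Classification accuracy from a confusion table
#'
#' @param ct square confusion matrix (truth in rows), or a length-4 vector
#'   `c(TP, TN, FP, FN)`.
#' @return fraction of correct predictions.
#' @export
accuracy <- function(ct) {
  if (is.null(dim(ct)) && length(ct) == 4L)
    ct <- matrix(c(ct[1L], ct[4L], ct[3L], ct[2L]), 2L, 2L)
  tot <- sum(ct)
  if (tot <= 0) stop("empty confusion table", call. = FALSE)
  sum(diag(as.matrix(ct))) / tot
}

#' Cohen's kappa from a confusion table
#'
#' `(p_o - p_e) / (1 - p_e)` with marginal-product expected agreement.
#' Degenerate marginals with `p_e = 1` raise an error (kappa undefined).
#'
#' @inheritParams accuracy
#' @return kappa in \[-1, 1\].
#' @seealso [kappa_band()] for the Landis--Koch performance band.
#' @export
cohen_kappa <- function(ct) {
  if (is.null(dim(ct)) && length(ct) == 4L)
    ct <- matrix(c(ct[1L], ct[4L], ct[3L], ct[2L]), 2L, 2L)
  ct <- as.matrix(ct)
  n <- sum(ct)
  if (n <= 0) stop("empty confusion table", call. = FALSE)
  po <- sum(diag(ct)) / n
  pe <- sum(rowSums(ct) * colSums(ct)) / n^2
  if (abs(1 - pe) < 1e-12)
    stop("degenerate marginals: expected agreement is 1, kappa undefined",
         call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Landis-Koch performance band of a kappa value
#'
#' @param kappa numeric kappa value(s).
#' @return factor with levels random, poor, fair, moderate, substantial,
#'   perfect (bands (-1,0\], (0,0.2\], (0.2,0.4\], (0.4,0.6\], (0.6,0.8\],
#'   (0.8,1\]).
#' @export
kappa_band <- function(kappa) {
  cut(kappa, breaks = c(-1.000001, 0, 0.2, 0.4, 0.6, 0.8, 1),
      labels = c("random", "poor", "fair", "moderate", "substantial", "perfect"))
}

#' Binomial chance level for classification accuracy
#'
#' The smallest accuracy `k*/n` whose binomial cumulative probability under
#' uniform guessing reaches `1 - alpha` (inverse-CDF convention); accuracies
#' above it are unlikely to arise by chance at level `alpha`.
#'
#' @param n_trials number of evaluated trials/epochs (vectorized).
#' @param n_classes number of classes (default 2).
#' @param alpha confidence level (default 0.001).
#' @return chance-level threshold as a fraction in \[0, 1\].
#' @export
chance_level <- function(n_trials, n_classes = 2L, alpha = 0.001) {
  if (any(n_trials < 1L)) stop("n_trials must be >= 1", call. = FALSE)
  stats::qbinom(1 - alpha, n_trials, 1 / n_classes) / n_trials
}

#' Bar dynamics of a set of trials
#'
#' Percentage of evidence-update steps, across all trials, in which the
#' accumulated evidence was strictly on the side of the true class
#' (evidence exactly at 0.5 counts as not-correct).
#'
#' @param outcomes list of `trial_outcome` objects from [run_trial()].
#' @return percentage in \[0, 100\].
#' @export
bar_dynamics <- function(outcomes) {
  n_steps <- sum(vapply(outcomes, function(o) o$n_updates, numeric(1)))
  if (n_steps < 1) stop("no active epochs", call. = FALSE)
  n_corr <- sum(vapply(outcomes, function(o) o$n_correct_direction, numeric(1)))
  100 * n_corr / n_steps
}

#' Command-delivery metrics of a set of trials
#'
#' Computes completed-trial accuracy (`acc_comp`), approximate accuracy
#' including timeouts resolved by the final bar direction (`acc_approx`,
#' with no direction counting as an error), the number of timeouts, Cohen's
#' kappa on the completed-trial confusion table, and the timeout-normalized
#' kappa `kappa * (1 - n_timeouts / n_total)`.
#'
#' @param outcomes list of `trial_outcome` objects.
#' @param classes class set for the confusion tables (default: classes
#'   observed among the truths).
#' @return list with `n_total`, `n_timeouts`, `acc_comp`, `acc_approx`,
#'   `kappa`, `kappa_norm`, and `confusion` (completed trials).
#' @export
command_metrics <- function(outcomes, classes = NULL) {
  if (length(outcomes) < 1L) stop("no trials", call. = FALSE)
  truth <- vapply(outcomes, function(o) o$truth, character(1))
  delivered <- vapply(outcomes, function(o) o$delivered, character(1))
  final_dir <- vapply(outcomes, function(o)
    if (is.na(o$final_direction)) "<none>" else o$final_direction, character(1))
  if (is.null(classes)) classes <- unique(truth)
  is_to <- delivered == "timeout"
  n_total <- length(outcomes)
  n_timeouts <- sum(is_to)
  approx_cmd <- ifelse(is_to, final_dir, delivered)
  acc_approx <- mean(approx_cmd == truth)
  if (all(is_to)) {
    acc_comp <- NA_real_; kap <- NA_real_; kap_norm <- NA_real_; ct <- NULL
  } else {
    ct <- confusion_table(truth[!is_to], delivered[!is_to], classes)
    acc_comp <- accuracy(ct)
    kap <- cohen_kappa(ct)
    kap_norm <- kap * (1 - n_timeouts / n_total)
  }
  list(n_total = n_total, n_timeouts = n_timeouts,
       acc_comp = acc_comp, acc_approx = acc_approx,
       kappa = kap, kappa_norm = kap_norm, confusion = ct)
}

#' Group-level statistics across decoding pipelines
#'
#' Friedman test for a main effect across at least three paired conditions,
#' pairwise Wilcoxon signed-rank tests, Benjamini--Hochberg FDR adjustment,
#' and per-condition Lilliefors normality tests.
#'
#' @param tab subjects x conditions numeric matrix (complete, paired) with
#'   column names identifying the conditions.
#' @return list with `friedman_p`, `pairwise` (data frame: condition pair,
#'   raw and BH-adjusted p), and `normality` (data frame: condition,
#'   Lilliefors p, normal flag at 0.05; `NA` when n < 4).
#' @export
group_stats <- function(tab) {
  tab <- as.matrix(tab)
  if (ncol(tab) < 3L) stop("Friedman test needs >= 3 paired conditions", call. = FALSE)
  if (anyNA(tab)) stop("table must be complete", call. = FALSE)
  if (is.null(colnames(tab))) colnames(tab) <- paste0("cond", seq_len(ncol(tab)))
  fr <- stats::friedman.test(tab)
  prs <- utils::combn(colnames(tab), 2L)
  pw <- apply(prs, 2L, function(pr) {
    d <- tab[, pr[1L]] - tab[, pr[2L]]
    if (all(d == 0)) stop("Wilcoxon signed-rank undefined: all differences zero",
                          call. = FALSE)
    suppressWarnings(stats::wilcox.test(tab[, pr[1L]], tab[, pr[2L]],
                                        paired = TRUE))$p.value
  })
  pairwise <- data.frame(cond1 = prs[1L, ], cond2 = prs[2L, ],
                         p = pw, p_adj = stats::p.adjust(pw, method = "BH"))
  normality <- data.frame(
    cond = colnames(tab),
    lilliefors_p = apply(tab, 2L, function(x) {
      if (length(x) < 4L || stats::sd(x) == 0) NA_real_
      else nortest::lillie.test(x)$p.value
    })
  )
  normality$normal <- normality$lilliefors_p >= 0.05
  list(friedman_p = fr$p.value, pairwise = pairwise, normality = normality)
}
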