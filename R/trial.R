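# Online trial protocol: exponentially smoothed evidence accumulation,
# per-class decision thresholds, timeout handling, and pseudo-online replay.

#' Exponentially smoothed evidence update
#'
#' `(1 - alpha) * prev + alpha * p_inst`: the accumulated evidence is a
#' contraction toward the instantaneous classifier probability and stays in
#' \[0, 1\].
#'
#' @param prev previous accumulated probability, in \[0, 1\].
#' @param p_inst instantaneous classifier probability, in \[0, 1\].
#' @param alpha smoothing factor (default 0.05).
#' @return updated probability.
#' @export
evidence_update <- function(prev, p_inst, alpha = 0.05) {
  (1 - alpha) * prev + alpha * p_inst
}

#' Online trial protocol configuration
#'
#' @param classes character vector of the two class labels, in declared
#'   order; the evidence variable is the accumulated probability of
#'   `classes[1]`.
#' @param threshold named numeric vector of per-class decision thresholds in
#'   (0.5, 1\] (default 0.7 for both; sample-wise and normalized
#'   command-delivery metrics do not depend on the threshold choice).
#' @param timeout_s trial timeout in seconds (default 7).
#' @param update_period_s evidence update period in seconds (default 62.5 ms).
#' @param alpha smoothing factor of [evidence_update()] (default 0.05).
#' @return object of class `trial_protocol`.
#' @export
trial_protocol <- function(classes = c("left", "right"),
                           threshold = c(0.7, 0.7),
                           timeout_s = 7, update_period_s = 0.0625,
                           alpha = 0.05) {
  if (length(classes) != 2L) stop("exactly 2 classes", call. = FALSE)
  if (length(threshold) == 1L) threshold <- rep(threshold, 2L)
  if (is.null(names(threshold))) names(threshold) <- classes
  if (any(threshold <= 0.5 | threshold > 1))
    stop("thresholds must lie in (0.5, 1]", call. = FALSE)
  if (timeout_s <= 0) stop("timeout must be positive", call. = FALSE)
  structure(list(classes = classes, threshold = threshold[classes],
                 timeout_s = timeout_s, update_period_s = update_period_s,
                 alpha = alpha,
                 max_updates = as.integer(round(timeout_s / update_period_s))),
            class = "trial_protocol")
}

#' Run one trial of the online protocol
#'
#' Evidence starts at the uniform value 0.5 and is updated once per period
#' with the incoming instantaneous probability of `classes[1]`.  The trial
#' terminates at the first update where the evidence strictly surpasses a
#' class threshold (the accumulated probability of `classes[1]` above
#' `threshold[1]`, or of `classes[2]`, i.e. `1 - evidence`, above
#' `threshold[2]`), or times out after `timeout_s` (or when the stream is
#' exhausted), recording the final bar direction (evidence exactly at 0.5 at
#' timeout counts as no direction, i.e. as an error in approximate accuracy).
#'
#' @param probs numeric vector of instantaneous probabilities of
#'   `classes[1]`, one per update period.
#' @param truth true class label of the trial.
#' @param protocol a [trial_protocol()].
#' @return object of class `trial_outcome`: list with `truth`, `delivered`
#'   (a class label or `"timeout"`), `timeout`, `final_direction`, `trace`
#'   (evidence after each update), `n_updates`, `n_correct_direction`
#'   (updates with evidence strictly on the true side), and `duration_s`.
#' @export
run_trial <- function(probs, truth, protocol) {
  if (length(probs) < 1L) stop("empty probability stream", call. = FALSE)
  cl <- protocol$classes
  if (!truth %in% cl) stop("truth is not one of the protocol classes", call. = FALSE)
  n <- min(length(probs), protocol$max_updates)
  ev <- 0.5
  trace <- numeric(n)
  delivered <- "timeout"
  k_stop <- n
  for (k in seq_len(n)) {
    ev <- evidence_update(ev, probs[k], protocol$alpha)
    trace[k] <- ev
    if (ev > protocol$threshold[[1L]]) { delivered <- cl[1L]; k_stop <- k; break }
    if (1 - ev > protocol$threshold[[2L]]) { delivered <- cl[2L]; k_stop <- k; break }
  }
  trace <- trace[seq_len(k_stop)]
  final_dir <- if (ev > 0.5) cl[1L] else if (ev < 0.5) cl[2L] else NA_character_
  toward <- if (truth == cl[1L]) trace > 0.5 else trace < 0.5
  structure(list(
    truth = truth,
    delivered = delivered,
    timeout = identical(delivered, "timeout"),
    final_direction = final_dir,
    trace = trace,
    n_updates = k_stop,
    n_correct_direction = sum(toward),
    duration_s = k_stop * protocol$update_period_s
  ), class = "trial_outcome")
}

#' Pseudo-online replay of a test session
#'
#' Replays causally ordered test feature matrices through an MDM model under
#' one of three recentering schemes: `"none"` (plain prediction),
#' `"rebias"` (fixed reference), or `"adaptive"` (causal
#' [adaptive_reference_step()] updates seeded by the model's training
#' reference).  Optionally groups the per-epoch probabilities into trials and
#' runs the full threshold/timeout protocol.
#'
#' @param feats list of SPD feature matrices in temporal order.
#' @param model an `mdm_model`.
#' @param adaptation `"none"`, `"rebias"`, or `"adaptive"`.
#' @param reference SPD reference matrix, required for `"rebias"`; for
#'   `"adaptive"` the model's stored training reference is used.
#' @param variant adaptive-reference variant, see [adaptive_reference()].
#' @param trial_id optional integer vector assigning each epoch to a trial;
#'   with `protocol` and `truths` this also produces [run_trial()] outcomes.
#' @param protocol optional [trial_protocol()].
#' @param truths optional per-trial true labels (named or ordered by unique
#'   `trial_id`).
#' @return list with `labels` (per-epoch predictions), `prob1` (per-epoch
#'   probability of the model's first class), and `outcomes` (list of
#'   `trial_outcome`, or `NULL`).
#' @export
pseudo_online_replay <- function(feats, model,
                                 adaptation = c("none", "rebias", "adaptive"),
                                 reference = NULL,
                                 variant = c("as_printed", "running_mean"),
                                 trial_id = NULL, protocol = NULL, truths = NULL) {
  adaptation <- match.arg(adaptation)
  variant <- match.arg(variant)
  if (adaptation == "rebias" && is.null(reference))
    stop("rebias scheme needs a reference matrix", call. = FALSE)
  if (adaptation == "adaptive") {
    if (is.null(model$reference))
      stop("adaptive scheme needs a model with a training reference", call. = FALSE)
    st <- adaptive_reference(model$reference, variant)
  }
  n <- length(feats)
  labels <- character(n)
  prob1 <- numeric(n)
  for (i in seq_len(n)) {
    C <- feats[[i]]
    if (adaptation == "rebias") {
      C <- rebias(C, reference)
    } else if (adaptation == "adaptive") {
      r <- adaptive_reference_step(st, C)
      st <- r$state
      C <- r$rebiased
    }
    pr <- mdm_predict(model, C)
    labels[i] <- pr$label
    prob1[i] <- pr$probabilities[[1L]]
  }
  outcomes <- NULL
  if (!is.null(trial_id) && !is.null(protocol) && !is.null(truths)) {
    ids <- unique(trial_id)
    if (is.null(names(truths))) names(truths) <- as.character(ids)
    outcomes <- lapply(ids, function(id)
      run_trial(prob1[trial_id == id], truths[[as.character(id)]], protocol))
  }
  list(labels = labels, prob1 = prob1, outcomes = outcomes)
}
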