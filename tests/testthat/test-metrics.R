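# Accuracy, Cohen's kappa, chance level, bar dynamics, command metrics,
# group statistics.

test_that("accuracy from counts and tables", {
  expect_equal(accuracy(c(5, 5, 0, 0)), 1)
  expect_equal(accuracy(c(0, 0, 5, 5)), 0)
  expect_equal(accuracy(c(44, 46, 4, 6)), 0.90)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("Cohen's kappa: perfect, independent, and hand-expanded tables", {
  expect_equal(cohen_kappa(matrix(c(30, 0, 0, 20), 2)), 1)
  # prediction independent of truth (rank-1 table) gives 0
  expect_equal(cohen_kappa(outer(c(30, 20), c(0.4, 0.6))), 0, tolerance = 1e-12)
  # hand expansion: po = 0.85, pe = 0.5*0.45 + 0.5*0.55 = 0.5
  ct <- matrix(c(40, 5, 10, 45), 2)     # truth rows: (40,10 | 5,45)
  po <- 85 / 100
  pe <- (50 * 45 + 50 * 55) / 100^2
  expect_equal(cohen_kappa(ct), (po - pe) / (1 - pe))
  expect_error(cohen_kappa(matrix(c(10, 0, 0, 0), 2)), "undefined")
  expect_equal(as.character(kappa_band(c(-0.5, 0.1, 0.45, 0.95))),
               c("random", "poor", "moderate", "perfect"))
})

test_that("binomial chance level reproduces the inverse-CDF convention", {
  expect_equal(chance_level(100), 0.65)
  expect_equal(chance_level(94), 62 / 94)     # 65.96%
  expect_equal(chance_level(69), 47 / 69)     # 68.12%
  # decreasing with sample size on a dyadic grid (integer quantization makes
  # strict monotonicity over consecutive n false, e.g. n = 10 vs 11)
  cl <- chance_level(c(10, 20, 40, 80, 160, 320, 640))
  expect_true(all(diff(cl) < 0))
  expect_gt(chance_level(94), chance_level(100))
})

test_that("bar dynamics counts strictly-correct evidence steps", {
  pr <- trial_protocol(threshold = 0.999, alpha = 0.05)
  good <- run_trial(rep(1, 50), "left", pr)
  expect_equal(bar_dynamics(list(good)), 100)
  flat <- run_trial(rep(0.5, 50), "left", pr)
  expect_equal(bar_dynamics(list(flat)), 0)      # exactly 0.5 is not-correct
  expect_equal(bar_dynamics(list(good, flat)), 50)
})

test_that("command metrics reproduce the timeout-normalized kappa identities", {
  pr <- trial_protocol(threshold = 0.7)
  mk_outcomes <- function(n_correct, n_timeout) {
    cls <- rep(c("left", "right"), length.out = n_correct)
    good <- lapply(cls, function(tr)
      run_trial(if (tr == "left") rep(1, 112) else rep(0, 112), tr, pr))
    idle <- lapply(rep(c("left", "right"), length.out = n_timeout),
                   function(tr) run_trial(rep(0.5, 112), tr, pr))
    c(good, idle)
  }
  cm <- command_metrics(mk_outcomes(94, 6))
  expect_equal(cm$acc_comp, 1)
  expect_equal(cm$kappa, 1)
  expect_equal(cm$kappa_norm, 0.94)
  cm2 <- command_metrics(mk_outcomes(81, 19))
  expect_equal(cm2$kappa_norm, 0.81)
  # no timeouts: kappa_norm equals kappa
  cm3 <- command_metrics(mk_outcomes(40, 0))
  expect_equal(cm3$kappa_norm, cm3$kappa)
  expect_equal(cm3$n_timeouts, 0)
})

test_that("|kappa_norm| <= |kappa| with equality iff there are no timeouts", {
  # scaling by (1 - timeouts/total) contracts kappa toward zero, from either
  # sign, so the magnitude never grows
  for (kap in c(-0.6, 0.3, 0.9)) {
    for (f in c(0, 0.2, 0.5)) {
      kn <- kap * (1 - f)
      expect_lte(abs(kn), abs(kap))
      if (f == 0) expect_equal(kn, kap)
    }
  }
})

test_that("group statistics: Friedman, BH adjustment, degenerate inputs", {
  set.seed(81)
  tab <- cbind(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  gs <- group_stats(tab + 0)
  expect_true(gs$friedman_p >= 0 && gs$friedman_p <= 1)
  expect_equal(nrow(gs$pairwise), 3)
  expect_true(all(gs$pairwise$p_adj >= gs$pairwise$p - 1e-12))
  # identical columns: zero statistic (p in the no-effect region) -- shift
  # slightly to avoid all-zero Wilcoxon differences
  expect_error(group_stats(cbind(a = 1:5, b = 1:5, c = 1:5)), "zero")
  expect_error(group_stats(cbind(a = 1:5, b = 2:6)), ">= 3")
})
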