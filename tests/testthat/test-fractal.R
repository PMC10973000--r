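# Detrended cross-correlation analysis: window-level oracle values,
# agreement with a brute-force per-window OLS implementation, matrix
# contracts, DFA self-consistency, and DCCC bounds.

test_that("profile integration is the cumulative sum", {
  expect_equal(integrate_profile(c(1, 1, 1)), c(1, 2, 3))
  expect_equal(integrate_profile(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(integrate_profile(c(1, -1, 2)), c(1, 0, 2))
  expect_error(integrate_profile(numeric(0)), "empty")
})

test_that("single-window detrended covariance matches hand OLS", {
  # exact line fully removed
  expect_equal(detrended_cov_window(1:4, 1:4), 0, tolerance = 1e-12)
  # residuals of [1,-1,1,-1] are (0.4,-1.2,1.2,-0.4): sum r^2 / 3 = 16/15
  expect_equal(detrended_cov_window(c(1, -1, 1, -1), c(1, -1, 1, -1)), 16 / 15)
  expect_equal(detrended_cov_window(c(1, -1, 1, -1), -c(1, -1, 1, -1)), -16 / 15)
  expect_error(detrended_cov_window(1:4, 1:5), "differ")
  expect_error(detrended_cov_window(1:3, 1:3), ">= 4")
  expect_error(scale_spec(3), ">= 4")
})

test_that("dcca_pair agrees with the brute-force window-loop oracle", {
  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(90); y <- rnorm(90)
    for (mode in c("sliding", "nonoverlap")) {
      for (intg in c(FALSE, TRUE)) {
        expect_equal(dcca_pair(x, y, scale_spec(16, mode, integrate = intg)),
                     dcca_brute(x, y, 16, mode, integrate = intg),
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(dcca_pair(rnorm(10), rnorm(10), scale_spec(16)), "shorter")
  # nonoverlap needs at least two windows
  expect_error(dcca_pair(rnorm(20), rnorm(20), scale_spec(16, "nonoverlap")),
               "2 windows")
})

test_that("lines produce zero detrended covariance and x=x reduces to DFA", {
  t <- 1:200
  expect_equal(dcca_pair(2 * t + 1, -0.5 * t + 3, scale_spec(16)), 0,
               tolerance = 1e-18)
  set.seed(12)
  x <- rnorm(300)
  for (s in c(8, 32)) {
    spec <- scale_spec(s, "nonoverlap", integrate = TRUE)
    expect_identical(dcca_pair(x, x, spec),
                     dcca_pair(x, x, spec))  # same code path by construction
    f <- dfa_exponent(x, scales = c(8, 16, 32))
    expect_equal(f$fluctuation[f$scales == s]^2, dcca_pair(x, x, spec),
                 tolerance = 1e-12)
  }
})

test_that("independent white noise has near-zero mean cross-covariance", {
  set.seed(13)
  v <- replicate(60, {
    x <- rnorm(1024); y <- rnorm(1024)
    dcca_pair(x, y, scale_spec(64))
  })
  expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
})

test_that("dcca_matrix is symmetric positive definite and repairs rank deficiency", {
  set.seed(14)
  X <- matrix(rnorm(6 * 400), 6)
  M <- dcca_matrix(X, scale_spec(32))
  expect_lt(max(abs(M - t(M))), 1e-10)
  expect_gt(min(eigen(M, TRUE, TRUE)$values), 0)
  expect_true(is.na(attr(M, "repair")))
  expect_equal(M[2, 5], dcca_pair(X[2, ], X[5, ], scale_spec(32)),
               tolerance = 1e-12)
  # duplicated channel: raw matrix rank-deficient, repaired output SPD with
  # off-diagonal equal to the (pre-repair) diagonal
  X2 <- rbind(X[1, ], X[1, ])
  M2 <- dcca_matrix(X2, scale_spec(32))
  expect_false(is.na(attr(M2, "repair")))
  expect_true(is_spd(unclass(M2)))
  expect_equal(M2[1, 2], M2[1, 1] - attr(M2, "repair"), tolerance = 1e-12)
  # constant channel: all residuals vanish -> degenerate error
  expect_error(dcca_matrix(rbind(X[1, ], rep(1, 400)), scale_spec(32)),
               "degenerate")
})

test_that("white-noise DCCA matrices are diagonal-dominated", {
  set.seed(15)
  worst <- replicate(10, {
    X <- matrix(rnorm(22 * 512), 22)
    M <- dcca_matrix(X, scale_spec(128))
    max(abs(M[upper.tri(M)])) / min(diag(M))
  })
  expect_lt(max(worst), 0.5)
})

test_that("DFA recovers the Hurst exponent of fGn and flags degenerate input", {
  set.seed(16)
  a5 <- vapply(1:40, function(i) dfa_exponent(fgn(4096, 0.5), 2^(4:8))$alpha,
               numeric(1))
  a8 <- vapply(1:40, function(i) dfa_exponent(fgn(4096, 0.8), 2^(4:8))$alpha,
               numeric(1))
  expect_gt(mean(a5), 0.45); expect_lt(mean(a5), 0.55)
  expect_gt(mean(a8), 0.75); expect_lt(mean(a8), 0.85)
  expect_error(dfa_exponent(rep(1, 512), 2^(4:6)), "degenerate")
  expect_error(dfa_exponent(rnorm(512), c(16, 32)), "3 scales")
})

test_that("DCCC is bounded, exact for (anti)identical series, and affine-invariant", {
  set.seed(17)
  x <- rnorm(600); y <- rnorm(600)
  spec <- scale_spec(64)
  expect_identical(dccc(x, x, spec), 1)
  expect_identical(dccc(x, -x, spec), -1)
  r <- dccc(x, y, spec)
  expect_gte(r, -1); expect_lte(r, 1)
  expect_equal(dccc(x, 3.7 * y + 2, spec), r, tolerance = 1e-10)
  expect_equal(dccc(0.2 * x - 5, y, spec), r, tolerance = 1e-10)
  expect_error(dccc(x, rep(0, 600), spec), "degenerate")
  v <- replicate(50, dccc(rnorm(1024), rnorm(1024), scale_spec(128)))
  expect_true(all(v >= -1 & v <= 1))
  expect_lt(abs(mean(v)), 0.05)
})

test_that("the window-average convention is a pure scale factor under trace normalization", {
  set.seed(18)
  X <- matrix(rnorm(5 * 300), 5)
  M <- dcca_matrix(X, scale_spec(32))
  expect_equal(unclass(trace_normalize(M)), unclass(trace_normalize(M * 7.3)),
               tolerance = 1e-12, ignore_attr = TRUE)
})
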