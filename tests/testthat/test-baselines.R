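# Cov-CSP-LDA baseline: closed-form CSP, feature properties, LDA vs the
# MASS reference implementation, and the linear two-source benchmark.

test_that("CSP on 2x2 diagonal class means matches the closed form", {
  f <- csp_fit(list(a = diag(c(4, 1)), b = diag(c(1, 4))), n_filters = 2)
  expect_equal(sort(f$eigenvalues), c(0.2, 0.8), tolerance = 1e-10)
  # filters are axis-aligned and normalized so w'(C1+C2)w = 1
  Ctot <- diag(c(5, 5))
  expect_equal(diag(f$filters %*% Ctot %*% t(f$filters)), rep(1, 2),
               tolerance = 1e-10)
  # both filters are axis-aligned (exactly one nonzero weight each, on
  # different axes)
  nz <- abs(f$filters) > 1e-8
  expect_equal(rowSums(nz), c(1, 1))
  expect_equal(colSums(nz), c(1, 1))
})

test_that("identical class means yield deterministic index-ordered filters", {
  set.seed(51)
  C <- rand_spd(4)
  f1 <- csp_fit(list(a = C, b = C), n_filters = 3)
  f2 <- csp_fit(list(a = C, b = C), n_filters = 3)
  expect_equal(f1$filters, f2$filters)
  expect_equal(f1$eigenvalues, rep(0.5, 3), tolerance = 1e-8)
})

test_that("log-variance features: identity case and scaling additivity", {
  set.seed(52)
  f <- csp_fit(list(a = rand_spd(4), b = rand_spd(4)), n_filters = 3)
  v <- csp_features(diag(4), f)
  expect_equal(v, log(rowSums(f$filters^2)), tolerance = 1e-10)
  C <- rand_spd(4)
  expect_equal(csp_features(5 * C, f) - csp_features(C, f), rep(log(5), 3),
               tolerance = 1e-10)
})

test_that("two-class LDA matches MASS::lda predictions and is affine-stable", {
  skip_if_not_installed("MASS")
  set.seed(53)
  X <- rbind(matrix(rnorm(120, 0), 60, 2), matrix(rnorm(120, 3), 60, 2))
  y <- rep(c("a", "b"), each = 60)
  m <- lda_fit(X, y)
  pred <- lda_predict(m, X)
  ref <- as.character(stats::predict(MASS::lda(X, grouping = factor(y)))$class)
  expect_gte(mean(pred == ref), 0.99)
  expect_gte(mean(pred == y), 0.95)
  # decision invariant under common affine rescaling of the features
  m2 <- lda_fit(X * 3 + 7, y)
  expect_identical(lda_predict(m2, X * 3 + 7), pred)
  # identical class means: no crash, roughly chance behavior
  set.seed(54)
  Xn <- matrix(rnorm(200), 100, 2)
  yn <- rep(c("a", "b"), 50)
  mn <- lda_fit(Xn, yn)
  expect_true(mean(lda_predict(mn, Xn) == yn) < 0.75)
})

test_that("CSP-LDA decodes linearly generated two-source data", {
  set.seed(55)
  accs <- vapply(1:20, function(rep) {
    A <- matrix(rnorm(16), 4)          # mixing of 4 sources to 4 channels
    gen <- function(cls, k) lapply(1:k, function(i) {
      sdv <- if (cls == "a") c(2, 0.5, 1, 1) else c(0.5, 2, 1, 1)
      X <- A %*% (matrix(rnorm(4 * 200), 4) * sdv)
      tcrossprod(X - rowMeans(X)) / 199
    })
    tr_a <- gen("a", 20); tr_b <- gen("b", 20)
    te_a <- gen("a", 20); te_b <- gen("b", 20)
    f <- csp_fit(list(a = Reduce(`+`, tr_a) / 20, b = Reduce(`+`, tr_b) / 20))
    feat <- function(cs) t(vapply(cs, csp_features, numeric(3), filters = f))
    m <- lda_fit(rbind(feat(tr_a), feat(tr_b)), rep(c("a", "b"), each = 20))
    mean(lda_predict(m, rbind(feat(te_a), feat(te_b))) ==
           rep(c("a", "b"), each = 20))
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})

test_that("CSP filters differ between raw and rebiased class means", {
  set.seed(56)
  mats_a <- spd_around(diag(c(2, 1, 1)), 10, sd = 0.1)
  mats_b <- spd_around(diag(c(1, 2, 1)), 10, sd = 0.1)
  R <- karcher_mean(c(mats_a, mats_b))
  mean_of <- function(ms) Reduce(`+`, ms) / length(ms)
  f_raw <- csp_fit(list(a = mean_of(mats_a), b = mean_of(mats_b)), n_filters = 2)
  f_reb <- csp_fit(list(a = mean_of(lapply(mats_a, rebias, R = R)),
                        b = mean_of(lapply(mats_b, rebias, R = R))), n_filters = 2)
  expect_gt(max(abs(abs(f_raw$filters) - abs(f_reb$filters))), 1e-4)
})
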