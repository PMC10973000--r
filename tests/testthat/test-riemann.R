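# Riemannian geometry: geodesic identities, AIRM invariances, Karcher-mean
# properties, shrinkage covariance, trace normalization, recentering.

test_that("geodesic endpoint and commuting-matrix identities hold", {
  set.seed(31)
  P1 <- rand_spd(4); P2 <- rand_spd(4)
  expect_equal(geodesic(P1, P2, 0), P1, tolerance = 1e-8)
  expect_equal(geodesic(P1, P2, 1), P2, tolerance = 1e-8)
  expect_equal(geodesic(P1, P1, 0.37), P1, tolerance = 1e-8)
  expect_equal(geodesic(diag(c(1, 1)), diag(c(4, 4)), 0.5), diag(c(2, 2)),
               tolerance = 1e-10)
  expect_error(geodesic(P1, P2, 1.2), "\\[0, 1\\]")
})

test_that("AIRM distance closed forms, congruence invariance, and path property", {
  set.seed(32)
  P1 <- rand_spd(4); P2 <- rand_spd(4)
  expect_lt(airm_distance(P1, P1), 1e-7)
  expect_equal(airm_distance(diag(2), diag(exp(c(2, 2)))), 2 * sqrt(2),
               tolerance = 1e-10)
  d12 <- airm_distance(P1, P2)
  for (i in 1:50) {
    A <- rand_spd(4); B <- rand_spd(4); W <- matrix(rnorm(16), 4)
    expect_equal(airm_distance(W %*% A %*% t(W), W %*% B %*% t(W)),
                 airm_distance(A, B), tolerance = 1e-8)
  }
  for (t in c(0.25, 0.5, 0.8))
    expect_equal(airm_distance(P1, geodesic(P1, P2, t)), t * d12,
                 tolerance = 1e-8)
  expect_error(airm_distance(diag(2) * -1, diag(2)), "positive definite")
})

test_that("Karcher mean: fixed points, midpoint, geometric mean, minimality", {
  set.seed(33)
  P <- rand_spd(3)
  expect_equal(unclass(karcher_mean(list(P))), P, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unclass(karcher_mean(list(P, P))), P, tolerance = 1e-7,
               ignore_attr = TRUE)
  P2 <- rand_spd(3)
  expect_lt(airm_distance(karcher_mean(list(P, P2)), geodesic(P, P2, 0.5)), 1e-6)
  dm <- karcher_mean(list(diag(c(1, 2)), diag(c(4, 8)), diag(c(16, 4))))
  expect_equal(unclass(dm), diag(c(4, 4)), tolerance = 1e-6, ignore_attr = TRUE)
  # minimality against random perturbations of the returned mean
  mats <- lapply(1:3, function(i) rand_spd(3))
  km <- karcher_mean(mats)
  obj <- function(Q) sum(vapply(mats, function(C) airm_distance(Q, C)^2, numeric(1)))
  f0 <- obj(km)
  h <- dccabci:::spd_sqrt(km)
  worse <- vapply(1:200, function(i) {
    E <- matrix(rnorm(9, sd = 0.05), 3); E <- (E + t(E)) / 2
    obj(h %*% dccabci:::sym_expm(E) %*% h) >= f0 - 1e-10
  }, logical(1))
  expect_true(all(worse))
  expect_true(attr(km, "converged"))
  # non-convergence carries the last iterate
  cnd <- tryCatch(karcher_mean(mats, tol = 0, max_iter = 2L),
                  dccabci_convergence_failure = function(e) e)
  expect_s3_class(cnd, "dccabci_convergence_failure")
  expect_true(is.matrix(cnd$iterate))
})

test_that("Ledoit-Wolf shrinkage yields SPD output with sensible intensity", {
  set.seed(34)
  # anisotropic large-sample: intensity vanishes, output approaches the SCM
  A <- matrix(rnorm(25), 5)
  X <- A %*% matrix(rnorm(5 * 4000), 5)
  S <- shrinkage_scm(X)
  expect_lt(attr(S, "lambda"), 0.02)
  Xc <- X - rowMeans(X)
  expect_lt(norm(unclass(S) - tcrossprod(Xc) / ncol(X), "F") /
              norm(tcrossprod(Xc) / ncol(X), "F"), 0.05)
  # more channels than samples: still SPD
  S2 <- shrinkage_scm(matrix(rnorm(6 * 4), 6))
  expect_true(is_spd(unclass(S2)))
  expect_gte(attr(S2, "lambda"), 0); expect_lte(attr(S2, "lambda"), 1)
  expect_error(shrinkage_scm(matrix(1:5, 5, 1)), "2 samples")
})

test_that("trace normalization is exact and idempotent", {
  expect_equal(unclass(trace_normalize(diag(c(2, 2)))), diag(c(0.5, 0.5)))
  set.seed(35)
  C <- rand_spd(5)
  T1 <- trace_normalize(C)
  expect_equal(sum(diag(T1)), 1, tolerance = 1e-12)
  expect_equal(trace_normalize(T1), T1, tolerance = 1e-12)
})

test_that("rebias recenters and preserves pairwise AIRM distances", {
  set.seed(36)
  C <- rand_spd(3); R <- rand_spd(3)
  expect_equal(rebias(C, C), diag(3), tolerance = 1e-8)
  expect_equal(rebias(C, diag(3)), C, tolerance = 1e-12)
  mats <- lapply(1:6, function(i) rand_spd(3))
  Rk <- karcher_mean(mats)
  reb <- lapply(mats, rebias, R = Rk)
  expect_lt(airm_distance(karcher_mean(reb), diag(3)), 1e-6)
  expect_equal(airm_distance(reb[[1]], reb[[2]]),
               airm_distance(mats[[1]], mats[[2]]), tolerance = 1e-8)
})

test_that("adaptive reference is causal, respects both variants, and converges", {
  set.seed(37)
  Rt <- rand_spd(3); C1 <- rand_spd(3); C2 <- rand_spd(3)
  for (v in c("as_printed", "running_mean")) {
    st <- adaptive_reference(Rt, v)
    r1 <- adaptive_reference_step(st, C1)
    expect_equal(r1$rebiased, rebias(C1, Rt), tolerance = 1e-10)
    if (v == "as_printed") {
      # second matrix is rebiased with the first test matrix
      r2 <- adaptive_reference_step(r1$state, C2)
      expect_equal(r2$rebiased, rebias(C2, C1), tolerance = 1e-10)
    }
    # identical incoming stream: reference -> C, rebiased -> identity
    st <- adaptive_reference(Rt, v)
    for (i in 1:40) { r <- adaptive_reference_step(st, C1); st <- r$state }
    expect_lt(airm_distance(st$R, C1), 1e-4)
    expect_lt(max(abs(r$rebiased - diag(3))), 1e-4)
  }
  st <- adaptive_reference(Rt)
  expect_error(adaptive_reference_step(st, rand_spd(4)), "dimension")
})
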