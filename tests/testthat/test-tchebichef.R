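# Orthonormal discrete Tchebichef basis, moments, reconstruction

test_that("closed forms hold at small support", {
  b <- tchebichef_basis(2, 1)
  expect_equal(b$values[1, ], c(1, 1) / sqrt(2))
  expect_equal(b$values[2, ], c(-1, 1) / sqrt(2))
  b4 <- tchebichef_basis(4, 1)
  expect_equal(sum(b4$values[1, ]^2), 1, tolerance = 1e-12)
  expect_equal(sum(b4$values[1, ] * b4$values[2, ]), 0, tolerance = 1e-12)
  # t_1 strictly increasing in x
  for (N in c(3, 8, 20)) {
    bb <- tchebichef_basis(N, 1)
    expect_true(all(diff(bb$values[2, ]) > 0))
  }
  expect_error(tchebichef_basis(5, 5), "max_order")
})

test_that("basis is orthonormal to 1e-8 for N <= 64, orders <= 12", {
  for (N in c(2, 3, 5, 8, 16, 33, 64)) {
    ord <- min(N - 1, 12)
    b <- tchebichef_basis(N, ord)
    gram <- b$values %*% t(b$values)
    expect_lt(max(abs(gram - diag(ord + 1))), 1e-8)
  }
})

test_that("monomial coefficients reproduce the recurrence values", {
  for (N in c(4, 12, 32)) {
    ord <- min(N - 1, 10)
    b <- tchebichef_basis(N, ord)
    x <- 0:(N - 1)
    V <- outer(x, 0:ord, `^`)
    expect_lt(max(abs(b$coeffs[1:(ord + 1), ] %*% t(V) - b$values)), 1e-8)
  }
})

test_that("Tchebichef moments of distributions match direct summation", {
  b <- tchebichef_basis(10, 9)
  # uniform distribution: only T_0 survives
  Tm <- tcheb_moments(rep(0.1, 10), b)
  expect_equal(Tm[1], 1 / sqrt(10), tolerance = 1e-12)
  expect_equal(Tm[-1], rep(0, 9), tolerance = 1e-10)
  # point mass at x0: T_n = t_n(x0)
  p <- rep(0, 10); p[4] <- 1
  expect_equal(tcheb_moments(p, b), b$values[, 4], tolerance = 1e-12)
  # random p: direct summation oracle
  set.seed(3)
  p <- runif(10); p <- p / sum(p)
  oracle <- vapply(0:9, function(n) sum(p * b$values[n + 1, ]), 0)
  expect_equal(tcheb_moments(p, b), oracle, tolerance = 1e-12)
  expect_error(tcheb_moments(rep(0.25, 4), b), "support")
})

test_that("raw-moment and distribution paths to Tchebichef moments agree", {
  set.seed(9)
  for (N in c(6, 12, 24)) {
    b <- tchebichef_basis(N, min(N - 1, 8))
    p <- runif(N); p <- p / sum(p)
    x <- 0:(N - 1)
    raw <- vapply(0:b$max_order, function(k) sum(p * x^k), 0)
    expect_equal(tcheb_moments_from_raw(raw, b),
                 tcheb_moments(p, b)[1:(b$max_order + 1)],
                 tolerance = 1e-9)
    # point-mass consistency: M_k = x0^k gives T_n = t_n(x0)
    x0 <- sample(x, 1)
    expect_equal(tcheb_moments_from_raw(x0^(0:b$max_order), b),
                 b$values[, x0 + 1], tolerance = 1e-8)
  }
  b2 <- tchebichef_basis(5, 3)
  expect_equal(tcheb_moments_from_raw(1, b2), 1 / sqrt(5))
  expect_error(tcheb_moments_from_raw(c(2, 1), b2), "M_0")
  expect_error(tcheb_moments_from_raw(rep(1, 6), b2), "support size")
  expect_error(tcheb_moments_from_raw(rep(1, 5), b2), "max_order")
})

test_that("full-order reconstruction is exact and truncation is a projection", {
  set.seed(21)
  N <- 16
  b <- tchebichef_basis(N, N - 1)
  p <- runif(N); p <- p / sum(p)
  Tm <- tcheb_moments(p, b)
  expect_equal(tcheb_reconstruct(Tm, b, clip = FALSE), p,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(as.vector(tcheb_reconstruct(Tm[1], b)), rep(1 / N, N),
               tolerance = 1e-12)
  # SSE decreases monotonically with reconstruction order (before clipping)
  sse <- vapply(1:(N - 1), function(k)
    sum((tcheb_reconstruct(Tm[1:(k + 1)], b, clip = FALSE) - p)^2), 0)
  expect_true(all(diff(sse) <= 1e-12))
  # truncated reconstruction equals projection onto low-degree polynomials
  for (k in c(2, 5, 9)) {
    expect_equal(as.vector(tcheb_reconstruct(Tm[1:(k + 1)], b, clip = FALSE)),
                 poly_project(p, k), tolerance = 1e-9)
  }
})

test_that("reconstruction reproduces its own moments (projection idempotence)", {
  set.seed(33)
  N <- 12
  b <- tchebichef_basis(N, N - 1)
  p <- runif(N); p <- p / sum(p)
  Tm <- tcheb_moments(p, b)
  for (k in c(3, 6)) {
    ph <- tcheb_reconstruct(Tm[1:(k + 1)], b, clip = FALSE)
    Tm2 <- drop(b$values %*% ph)
    expect_equal(Tm2[1:(k + 1)], Tm[1:(k + 1)], tolerance = 1e-10)
    expect_equal(Tm2[(k + 2):N], rep(0, N - k - 1), tolerance = 1e-10)
  }
})

test_that("clipping removes negative mass and renormalises", {
  N <- 8
  b <- tchebichef_basis(N, N - 1)
  p <- c(0.9, rep(0.1 / 7, 7))
  Tm <- tcheb_moments(p, b)
  ph <- tcheb_reconstruct(Tm[1:3], b)
  expect_true(all(ph >= 0))
  expect_equal(sum(ph), 1, tolerance = 1e-12)
  expect_gte(attr(ph, "clipped_mass"), 0)
})

test_that("order selection finds the generating order and breaks ties low", {
  N <- 12
  b <- tchebichef_basis(N, N - 1)
  set.seed(14)
  p0 <- runif(N); p0 <- p0 / sum(p0)
  Tm <- tcheb_moments(p0, b)
  for (k0 in c(2, 4)) {
    # a strictly positive histogram that is exactly a degree-k0 polynomial:
    # truncate, then mix with the uniform (degree-0) distribution
    ph <- as.vector(tcheb_reconstruct(Tm[1:(k0 + 1)], b, clip = FALSE))
    shift <- 2 * max(0, -min(ph))
    ph <- (ph + shift) / (1 + N * shift)
    S <- 200
    counts <- S * ph
    x <- 0:(N - 1)
    raw <- vapply(0:(N - 1), function(k) sum(ph * x^k), 0)
    ks <- select_order(counts, raw, b, k_max = 8)
    expect_equal(as.integer(ks), k0)
  }
  expect_equal(as.integer(select_order(rep(1, N), rep(1, N), b, 1)), 1L)
  expect_error(select_order(rep(0, N), rep(1, N), b, 3), "degenerate")
})
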