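test_that("operator construction validates its inputs", {
  expect_error(nufft_operator(matrix(numeric(0), 0, 2), matrix_size = 16),
               "nonempty")
  expect_error(nufft_operator(cbind(0.7, 0), matrix_size = 16), "cycles/pixel")
  tr <- radial_trajectory(golden_angles(5), 32, scheme = "golden")
  op <- nufft_operator(tr)
  expect_s3_class(op, "nufft_operator")
  expect_equal(op$grid_size, 64L)
  expect_equal(op$normalization, 1 / 32)
})

test_that("forward matches the direct nonuniform DFT oracle", {
  set.seed(42)
  N <- 32
  tr <- radial_trajectory(golden_angles(10), N, scheme = "golden")
  op <- nufft_operator(tr)
  x <- matrix(rnorm(N * N) + 1i * rnorm(N * N), N, N)
  s <- nufft_forward(op, x, as_kspace = FALSE)
  expect_lt(rel_l2_err(s, dft_oracle(x, tr$coords)), 1e-3)
})

test_that("forward matches the analytic Fourier transform of a Gaussian", {
  N <- 32
  sig <- 3
  pc <- seq_len(N) - 1 - N / 2
  g <- exp(-outer(pc^2, pc^2, "+") / (2 * sig^2))
  tr <- radial_trajectory(uniform_angles(12), N, scheme = "uniform")
  op <- nufft_operator(tr)
  s <- nufft_forward(op, g + 0i, as_kspace = FALSE)
  analytic <- 2 * pi * sig^2 * exp(-2 * pi^2 * sig^2 * rowSums(tr$coords^2)) / N
  expect_lt(rel_l2_err(s, analytic), 1e-3)
})

test_that("forward and adjoint satisfy the inner-product identity", {
  set.seed(1)
  N <- 32
  tr <- radial_trajectory(golden_angles(10), N, scheme = "golden")
  op <- nufft_operator(tr)
  for (rep in 1:5) {
    x <- matrix(rnorm(N * N) + 1i * rnorm(N * N), N, N)
    y <- rnorm(nrow(tr$coords)) + 1i * rnorm(nrow(tr$coords))
    lhs <- sum(Conj(nufft_forward(op, x, as_kspace = FALSE)) * y)
    rhs <- sum(Conj(x) * nufft_adjoint(op, y))
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
  }
})

test_that("forward and adjoint are linear and deterministic", {
  set.seed(2)
  N <- 16
  tr <- radial_trajectory(uniform_angles(6), N, scheme = "uniform")
  op <- nufft_operator(tr)
  x1 <- matrix(rnorm(N * N) + 1i * rnorm(N * N), N, N)
  x2 <- matrix(rnorm(N * N) + 1i * rnorm(N * N), N, N)
  f <- function(z) nufft_forward(op, z, as_kspace = FALSE)
  expect_equal(f(2 * x1 - 3i * x2), 2 * f(x1) - 3i * f(x2), tolerance = 1e-12)
  expect_identical(f(x1), f(x1)) # bit-identical repeat
  expect_equal(f(matrix(0 + 0i, N, N)), rep(0 + 0i, nrow(tr$coords)))
  y <- f(x1)
  a <- function(z) nufft_adjoint(op, z)
  expect_equal(a(2 * y), 2 * a(y), tolerance = 1e-12)
  expect_equal(a(rep(0 + 0i, length(y))), matrix(0 + 0i, N, N))
})

test_that("a centered delta produces constant-modulus samples", {
  N <- 32
  tr <- radial_trajectory(golden_angles(8), N, scheme = "golden")
  op <- nufft_operator(tr)
  delta <- matrix(0 + 0i, N, N)
  delta[N / 2 + 1, N / 2 + 1] <- 1
  s <- nufft_forward(op, delta, as_kspace = FALSE)
  expect_equal(Mod(s), rep(1 / N, length(s)), tolerance = 2e-3)
})

test_that("density-compensated gridding of a Nyquist-sampled delta peaks at center", {
  N <- 64
  tr <- radial_trajectory(uniform_angles(402), N, scheme = "uniform")
  op <- nufft_operator(tr)
  delta <- matrix(0 + 0i, N, N)
  delta[N / 2 + 1, N / 2 + 1] <- 1
  rec <- Mod(nufft_adjoint(op, nufft_forward(op, delta, as_kspace = FALSE),
                           apply_dcf = TRUE))
  peak <- rec[N / 2 + 1, N / 2 + 1]
  rec[N / 2 + 1, N / 2 + 1] <- 0
  # a disc-covering trajectory has an Airy-pattern PSF whose first sidelobe
  # is ~13% of the peak; anything clearly above that bound indicates a
  # gridding or DCF defect
  expect_gt(peak, 5 * max(rec))
  # and the sidelobe is the physical one, not larger
  expect_lt(max(rec) / peak, 0.2)
})

test_that("adjoint rejects mismatched sample vectors and k-space objects", {
  tr <- radial_trajectory(uniform_angles(4), 16, scheme = "uniform")
  op <- nufft_operator(tr)
  expect_error(nufft_adjoint(op, rep(0 + 0i, 5)), "does not match")
  other <- sampled_kspace(c(0.1, 0.2), c(0, 0), c(1 + 0i, 2), matrix_size = 16)
  expect_error(nufft_adjoint(op, other), "missing")
  expect_error(nufft_forward(op, matrix(0, 8, 8)), "16x16")
})
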