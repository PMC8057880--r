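test_that("total variation matches hand-evaluated forward differences", {
  expect_equal(total_variation(matrix(5, 8, 8)), 0)
  # rows (0,1) / (0,1): one unit column step per row
  expect_equal(total_variation(matrix(c(0, 0, 1, 1), 2, 2)), 2)
  set.seed(3)
  x <- matrix(rnorm(64), 8, 8)
  expect_equal(total_variation(-2.5 * x), 2.5 * total_variation(x),
               tolerance = 1e-12)
  expect_error(total_variation(matrix(1, 1, 1)), ">= 2")
})

test_that("objective breakdown matches an independent recomputation", {
  set.seed(5)
  N <- 16
  tr <- radial_trajectory(golden_angles(6), N, scheme = "golden")
  op <- nufft_operator(tr)
  x <- matrix(rnorm(N * N) + 1i * rnorm(N * N), N, N)
  y <- dft_oracle(matrix(rnorm(N * N) + 0i, N, N), tr$coords)
  p <- recon_params(lambda1 = 0.3, lambda2 = 0.7)
  ob <- objective(x, y, op, p)
  # independent path: oracle forward, explicit sums
  res <- dft_oracle(x, tr$coords) - y
  # oracle forward differs from gridding by the NUFFT approximation error
  expect_equal(ob$data_term, sum(Mod(res)^2), tolerance = 1e-4)
  w <- dwt2(x, 4)
  expect_equal(ob$l1_term, sum(sqrt(Re(w)^2 + Im(w)^2)), tolerance = 1e-12)
  d1 <- x[c(2:N, N), ] - x; d1[N, ] <- 0
  d2 <- x[, c(2:N, N)] - x; d2[, N] <- 0
  expect_equal(ob$tv_term, sum(sqrt(Mod(d1)^2 + Mod(d2)^2)), tolerance = 1e-12)
  expect_equal(ob$total, ob$data_term + 0.3 * ob$l1_term + 0.7 * ob$tv_term)
  # switching the penalties off leaves pure least squares
  ob0 <- objective(x, y, op, recon_params(lambda1 = 0, lambda2 = 0))
  expect_equal(ob0$total, ob0$data_term)
  zero <- objective(matrix(0 + 0i, N, N), rep(0 + 0i, length(y)), op, p)
  expect_equal(c(zero$data_term, zero$l1_term, zero$tv_term, zero$total),
               rep(0, 4))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(7)
  N <- 16
  tr <- radial_trajectory(golden_angles(8), N, scheme = "golden")
  op <- nufft_operator(tr)
  yv <- nufft_forward(op, matrix(rnorm(N * N) + 0i, N, N), as_kspace = FALSE)
  p <- recon_params(lambda1 = 0.05, lambda2 = 0.05)
  f_of <- function(x) {
    r <- nufft_forward(op, x, as_kspace = FALSE) - yv
    w <- dwt2(x, 4)
    d1 <- x[c(2:N, N), ] - x; d1[N, ] <- 0
    d2 <- x[, c(2:N, N)] - x; d2[, N] <- 0
    sum(Mod(r)^2) + p$lambda1 * sum(sqrt(Mod(w)^2 + p$l1_smooth)) +
      p$lambda2 * sum(sqrt(Mod(d1)^2 + Mod(d2)^2 + p$l1_smooth))
  }
  for (rep in 1:3) {
    x <- matrix(rnorm(N * N) + 1i * rnorm(N * N), N, N)
    d <- matrix(rnorm(N * N) + 1i * rnorm(N * N), N, N)
    g <- eicsmri:::smoothed_gradient(x, yv, op, p)
    eps <- 1e-5
    fd <- (f_of(x + eps * d) - f_of(x - eps * d)) / (2 * eps)
    an <- Re(sum(Conj(g) * d))
    expect_lt(abs(fd - an) / abs(an), 1e-4)
  }
})

test_that("least squares at the Nyquist budget recovers a bandlimited slice", {
  N <- 32
  x_true <- disc_bandlimit(test_slice(N))
  tr <- radial_trajectory(uniform_angles(nyquist_spokes(N)), N,
                          scheme = "uniform")
  op <- nufft_operator(tr)
  y <- nufft_forward(op, x_true + 0i, as_kspace = FALSE)
  res <- ncg_reconstruct(y, op, recon_params(lambda1 = 0, lambda2 = 0,
                                             max_iter = 60))
  expect_lt(rel_l2_err(Mod(res$image), abs(x_true)), 0.05)
  expect_true(all(diff(res$trace$total) <= 1e-9))
  expect_lte(res$trace$total[nrow(res$trace)], res$trace$total[1])
})

test_that("regularized reconstruction beats gridding at aggressive undersampling", {
  N <- 64
  x_true <- test_slice(N, seed = 5)
  tr <- radial_trajectory(golden_angles(20), N, scheme = "golden")
  op <- nufft_operator(tr)
  y <- nufft_forward(op, x_true + 0i, as_kspace = FALSE)
  gridded <- Mod(nufft_adjoint(op, y, apply_dcf = TRUE))
  res <- ncg_reconstruct(y, op, recon_params(max_iter = 40))
  recon <- Mod(res$image)
  expect_lt(rel_l2_err(recon, x_true), rel_l2_err(gridded, x_true))
  expect_lt(total_variation(recon), total_variation(gridded))
  expect_true(all(diff(res$trace$total) <= 1e-9))
})

test_that("stack reconstruction preserves order and matches per-slice calls", {
  stack <- generate_phantom(phantom_spec(n_slices = 3, matrix_size = 32,
                                         drift = 0.004, noise_sigma = 0.005,
                                         seed = 6))
  triple <- make_mask_triple(3, "golden", 32)
  u <- interpolate_stack(undersample_stack(stack, triple), "eics")
  p <- recon_params(max_iter = 10)
  recs <- reconstruct_stack(u, p)
  expect_s3_class(recs, "slice_stack")
  expect_length(recs$data, 3)
  for (i in 1:3) {
    op_i <- eicsmri:::operator_for_kspace(u$slices[[i]])
    solo <- Mod(ncg_reconstruct(u$slices[[i]], op_i, p)$image)
    expect_equal(recs$data[[i]], solo, tolerance = 1e-12)
  }
  # zero input reconstructs to zero
  zero <- slice_stack(replicate(3, matrix(0, 32, 32), simplify = FALSE))
  uz <- interpolate_stack(undersample_stack(zero, triple), "none")
  rz <- reconstruct_stack(uz, recon_params(lambda1 = 0, lambda2 = 0,
                                           max_iter = 5))
  expect_true(all(vapply(rz$data, max, numeric(1)) == 0))
})
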