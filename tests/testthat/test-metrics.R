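test_that("mse and psnr follow their closed forms", {
  expect_equal(mse(matrix(1, 4, 4), matrix(1, 4, 4)), 0)
  expect_equal(mse(matrix(0, 2, 2), matrix(1, 2, 2)), 1)
  expect_equal(mse(matrix(c(0, 1, 1, 0), 2, 2), matrix(c(1, 0, 1, 0), 2, 2)), 0.5)
  expect_error(mse(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  x <- matrix(runif(16), 4, 4)
  expect_equal(psnr(x, x + 0.1), 20, tolerance = 1e-10)
  expect_equal(psnr(x, x + 1), 0, tolerance = 1e-10)
  expect_equal(psnr(x, x + 0.02), 10 * log10(1 / 4e-4), tolerance = 1e-10)
  expect_identical(psnr(x, x), Inf)
})

test_that("correlation matches the explicit formula and its identities", {
  set.seed(2)
  x <- matrix(rnorm(9), 3, 3)
  y <- matrix(rnorm(9), 3, 3)
  expect_equal(corr(x, x), 1)
  expect_equal(corr(x, 2 - x), -1)
  mx <- mean(x); my <- mean(y)
  hand <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(corr(x, y), hand, tolerance = 1e-12)
  expect_error(corr(matrix(1, 3, 3), y), "constant")
})

test_that("ssim identities, symmetry, and the single-window statistic", {
  x <- test_slice(32, seed = 12)
  set.seed(1)
  y <- pmin(pmax(x + matrix(rnorm(32 * 32, 0, 0.05), 32, 32), 0), 1)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_lt(ssim(x, y), 1)
  # global variant against a hand evaluation on a 4x4 pair
  a <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5, 1, 1, 2, 2, 0, 1, 0, 1) / 5, 4, 4)
  b <- matrix(c(1, 1, 3, 3, 2, 2, 4, 4, 1, 2, 2, 3, 1, 1, 0, 0) / 5, 4, 4)
  c1 <- 0.01^2; c2 <- 0.03^2
  ma <- mean(a); mb <- mean(b)
  va <- var(as.vector(a)); vb <- var(as.vector(b))
  cab <- cov(as.vector(a), as.vector(b))
  hand <- ((2 * ma * mb + c1) * (2 * cab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
  expect_equal(ssim(a, b, global = TRUE), hand, tolerance = 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("fsim is bounded, maximal on identity, and penalizes blur", {
  x <- test_slice(64, seed = 13)
  expect_equal(fsim(x, x), 1, tolerance = 1e-12)
  xb <- circular_blur(x, sigma = 2)
  v <- fsim(x, xb)
  expect_true(v >= 0 && v <= 1)
  expect_lt(v, fsim(x, x))
  set.seed(3)
  y <- matrix(runif(64 * 64), 64, 64)
  vy <- fsim(x, y)
  expect_true(vy >= 0 && vy <= 1)
  expect_error(fsim(matrix(0, 16, 16), matrix(0, 16, 16)), "32")
})

test_that("sharpness index: self-consistency, monotonicity, determinism", {
  x <- test_slice(64, seed = 14)
  # a random-phase resample of x is unremarkable among resamples: its tail
  # probability is ~Uniform(0,1), so the median score over draws is
  # -log10(0.5) ~ 0.30 (single draws scatter widely by construction)
  set.seed(21)
  si_draws <- vapply(1:30, function(i) {
    sharpness_index(eicsmri:::random_phase_resample(x),
                    n_resamples = 40, seed = 500 + i)
  }, numeric(1))
  expect_lt(abs(median(si_draws) - (-log10(0.5))), 0.15)
  # blur destroys sharpness
  expect_gt(sharpness_index(x, n_resamples = 40, seed = 6),
            sharpness_index(circular_blur(x, 2), n_resamples = 40, seed = 6))
  # seeded determinism
  expect_identical(sharpness_index(x, n_resamples = 20, seed = 7),
                   sharpness_index(x, n_resamples = 20, seed = 7))
  # the literal printed form drops the tail: both modes encode the same
  # standardized TV deficit z, so they are deterministically linked
  xb <- circular_blur(x, 3)
  si_tail <- sharpness_index(xb, 40, seed = 8)
  si_lit <- sharpness_index(xb, 40, seed = 8, literal = TRUE)
  z <- qnorm(10^(-si_tail), lower.tail = FALSE)
  expect_equal(si_lit, -log10(z), tolerance = 1e-8)
  expect_error(sharpness_index(matrix(1, 8, 8)), "constant")
})

test_that("piqe: flat-image empty-sum case, range, and noise monotonicity", {
  expect_equal(piqe(matrix(0.5, 64, 64)), 1)
  x <- test_slice(128, seed = 15)
  v <- piqe(x)
  expect_true(v > 0 && v <= 100)
  set.seed(4)
  xn <- pmin(pmax(x + matrix(rnorm(128^2, 0, 0.15), 128, 128), 0), 1)
  expect_gt(piqe(xn), v)
  expect_error(piqe(matrix(0, 32, 32)), "64")
})

test_that("additive noise degrades the full-reference metrics in expectation", {
  x <- test_slice(64, seed = 16)
  set.seed(10)
  worse <- function(sigma) {
    vals <- replicate(20, {
      y <- pmin(pmax(x + matrix(rnorm(64 * 64, 0, sigma), 64, 64), 0), 1)
      c(mse = mse(x, y), psnr = psnr(x, y), ssim = ssim(x, y), corr = corr(x, y))
    })
    rowMeans(vals)
  }
  lo <- worse(0.02); hi <- worse(0.1)
  expect_gt(hi[["mse"]], lo[["mse"]])
  expect_lt(hi[["psnr"]], lo[["psnr"]])
  expect_lt(hi[["ssim"]], lo[["ssim"]])
  expect_lt(hi[["corr"]], lo[["corr"]])
})

test_that("stack evaluation reports identities, averages, and metric subsets", {
  stack <- generate_phantom(phantom_spec(n_slices = 3, matrix_size = 64,
                                         noise_sigma = 0, seed = 17))
  rep_id <- evaluate_stack(stack, stack,
                           metrics = c("ssim", "fsim", "mse", "corr"))
  expect_true(all(rep_id$per_slice$ssim == 1))
  expect_true(all(rep_id$per_slice$fsim == 1))
  expect_true(all(rep_id$per_slice$mse == 0))
  expect_equal(rep_id$per_slice$corr, rep(1, 3), tolerance = 1e-12)
  # averages are the column means (three-slice averaging protocol)
  noisy <- slice_stack(lapply(stack$data, function(s) {
    pmin(pmax(s + matrix(rnorm(64 * 64, 0, 0.03), 64, 64), 0), 1)
  }))
  rep2 <- evaluate_stack(noisy, stack, metrics = c("ssim", "mse", "psnr"),
                         metadata = list(method = "test"))
  expect_equal(rep2$averages[["ssim"]], mean(rep2$per_slice$ssim))
  expect_equal(rep2$averages[["mse"]], mean(rep2$per_slice$mse))
  expect_equal(nrow(rep2$per_slice), 3)
  # no-reference metrics work without truth; full-reference ones refuse
  rep_nr <- evaluate_stack(noisy, metrics = c("si", "piqe"),
                           si_resamples = 10)
  expect_true(all(c("si", "piqe") %in% names(rep_nr$averages)))
  expect_error(evaluate_stack(noisy, metrics = "ssim"), "ground truth")
})
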