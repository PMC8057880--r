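test_that("Nyquist spoke count follows the pi/2 rule", {
  expect_identical(nyquist_spokes(256), 402L)
  expect_identical(nyquist_spokes(128), 201L)
  expect_identical(nyquist_spokes(2), 3L)
  expect_error(nyquist_spokes(1), "must be")
  expect_error(nyquist_spokes(12.5), "positive integer")
})

test_that("spoke budgets match the clinical sampling fractions", {
  expect_identical(spokes_for_ratio(0.03, 256), 12L)
  expect_identical(spokes_for_ratio(0.05, 256), 20L)
  expect_identical(spokes_for_ratio(0.07, 256), 28L)
  expect_identical(spokes_for_ratio(0.09, 256), 36L)
  expect_identical(spokes_for_ratio(1.0, 256), 402L)
  expect_error(spokes_for_ratio(0, 256), "fraction")
  expect_error(spokes_for_ratio(1.2, 256), "fraction")
  # monotone nondecreasing in ratio
  budgets <- vapply(seq(0.01, 1, by = 0.01), spokes_for_ratio, integer(1),
                    matrix_size = 256)
  expect_true(all(diff(budgets) >= 0))
})

test_that("golden-angle sequence has the right increment and never repeats", {
  phi <- (1 + sqrt(5)) / 2
  expect_equal(golden_angles(1, 0), 0)
  a3 <- golden_angles(3, 0)
  expect_equal(a3, (0:2 * 180 / phi) %% 180)
  expect_equal(a3[2], 111.2461, tolerance = 1e-4)
  gaps <- diff(golden_angles(50, 0)) %% 180
  expect_true(all(abs(gaps - 180 / phi) < 1e-9 | abs(gaps - (180 / phi - 180)) < 1e-9))
  many <- golden_angles(10000, 0)
  expect_false(anyDuplicated(many) > 0)
})

test_that("uniform angles are evenly spaced with the given offset", {
  expect_equal(uniform_angles(2, 0), c(0, 90))
  expect_equal(uniform_angles(4, 0), c(0, 45, 90, 135))
  expect_equal(uniform_angles(3, 10), c(10, 70, 130))
  a <- uniform_angles(17, 5)
  expect_equal(diff(a), rep(180 / 17, 16))
})

test_that("trajectory coordinates are collinear diameters spanning [-0.5, 0.5)", {
  tr <- radial_trajectory(c(0, 30, 111.25), 32, scheme = "golden")
  expect_s3_class(tr, "radial_trajectory")
  for (j in 1:3) {
    idx <- tr$spoke_ids == j
    k <- tr$coords[idx, ]
    theta <- tr$angles_deg[j] * pi / 180
    # perpendicular component vanishes: samples lie on the spoke's line
    expect_lt(max(abs(-k[, 1] * sin(theta) + k[, 2] * cos(theta))), 1e-12)
    r <- k[, 1] * cos(theta) + k[, 2] * sin(theta)
    expect_equal(r, ((1:32) - 17) / 32)
  }
  expect_error(radial_trajectory(c(10, 190), 32), "distinct")
})

test_that("mask triples are pairwise disjoint round-robin deals", {
  tri <- make_mask_triple(2, "uniform", 8)
  expect_equal(tri[[1]]$angles_deg, c(0, 90))
  expect_equal(tri[[2]]$angles_deg, c(30, 120))
  expect_equal(tri[[3]]$angles_deg, c(60, 150))

  trig <- make_mask_triple(1, "golden", 8)
  expect_equal(unlist(lapply(trig, `[[`, "angles_deg")), golden_angles(3, 0),
               tolerance = 1e-12)

  for (scheme in c("uniform", "golden")) {
    tri <- make_mask_triple(7, scheme, 64)
    all_angles <- unlist(lapply(tri, `[[`, "angles_deg"))
    expect_length(unique(all_angles), 3 * 7)
    expect_length(intersect(tri[[1]]$angles_deg, tri[[2]]$angles_deg), 0)
    expect_length(intersect(tri[[2]]$angles_deg, tri[[3]]$angles_deg), 0)
    expect_length(intersect(tri[[1]]$angles_deg, tri[[3]]$angles_deg), 0)
  }
})

test_that("ramp DCF is a |k| ramp with a quarter-weight DC sample", {
  tr <- radial_trajectory(0, 64, scheme = "uniform")
  w <- ramp_dcf(tr)
  expect_true(all(w >= 0))
  kr <- sqrt(rowSums(tr$coords^2))
  i25 <- which.min(abs(kr - 0.25))
  i50 <- which.min(abs(kr - 0.5))
  expect_equal(w[i25] / w[i50], kr[i25] / kr[i50], tolerance = 1e-12)
  expect_equal(w[kr == 0], min(w[kr > 0]) / 4)
  # nondecreasing in |k| along the spoke except the DC exception
  ord <- order(kr)
  expect_true(all(diff(w[ord][-1]) >= -1e-15))
})

test_that("DCF-weighted gridding flattens a delta's spectrum inside the disc", {
  N <- 64
  tr <- radial_trajectory(uniform_angles(101), N, scheme = "uniform")
  op <- nufft_operator(tr)
  delta <- matrix(0 + 0i, N, N)
  delta[N / 2 + 1, N / 2 + 1] <- 1
  rec <- nufft_adjoint(op, nufft_forward(op, delta, as_kspace = FALSE),
                       apply_dcf = TRUE)
  # oracle: spectrum of the round-trip via the plain (centered) FFT
  idx <- c((N / 2 + 1):N, 1:(N / 2))
  P <- Mod(stats::fft(rec[idx, idx])[idx, idx]) # unit spectrum if identity
  f <- (seq_len(N) - 1 - N / 2) / N
  KR <- sqrt(outer(f^2, f^2, "+"))
  dev <- P[KR <= 0.4] - 1
  expect_lt(sqrt(mean(dev^2)), 0.05)
})

test_that("trajectory export writes one row per sample", {
  tr <- radial_trajectory(uniform_angles(3), 16, scheme = "uniform")
  path <- withr::local_tempfile(fileext = ".tsv")
  export_trajectory(tr, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 3 * 16)
  expect_named(tab, c("spoke_id", "kx", "ky", "dcf_weight"))
  expect_equal(tab$kx, tr$coords[, 1], tolerance = 1e-12)
})
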