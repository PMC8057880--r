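# Independent oracles and small fixtures, built in code at test time.

# Direct (brute-force) nonuniform DFT at arbitrary k-space locations, with
# the package's centered unitary convention. Independent of the gridding
# implementation.
dft_oracle <- function(img, coords) {
  N <- nrow(img)
  pc <- seq_len(N) - 1 - N / 2
  Ax <- exp(-2i * pi * outer(coords[, 1], pc))
  Ay <- exp(-2i * pi * outer(coords[, 2], pc))
  B <- img %*% t(Ay)
  rowSums(Ax * t(B)) / N
}

rel_l2_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
}

# deterministic sharp test slice (no noise, no drift)
test_slice <- function(N, seed = 3) {
  generate_phantom(phantom_spec(n_slices = 3, matrix_size = N, drift = 0,
                                noise_sigma = 0, seed = seed))$data[[1]]
}

# restrict an image to the inscribed k-space disc a radial trajectory covers
disc_bandlimit <- function(img, radius = 0.48) {
  N <- nrow(img)
  f <- (seq_len(N) - 1 - N / 2) / N
  KR <- sqrt(outer(f^2, f^2, "+"))
  sh <- function(z) {
    idx <- c((N / 2 + 1):N, 1:(N / 2))
    z[idx, idx]
  }
  X <- sh(stats::fft(sh(img + 0i)))
  X[KR > radius] <- 0
  Re(sh(stats::fft(sh(X), inverse = TRUE))) / length(img)
}

# circular Gaussian blur (independent of package internals)
circular_blur <- function(img, sigma = 2, half = 7) {
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(img)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in -half:half) K[i, ((i + j - 1) %% n) + 1] <- k[j + half + 1]
  }
  K %*% img %*% t(K)
}

# three undersampled neighbors of one image under a nonoverlapping triple
undersampled_triple_fixture <- function(N = 64, n_spokes = 4, seed = 9) {
  img <- test_slice(N, seed = seed) + 0i
  triple <- make_mask_triple(n_spokes, "golden", N)
  ops <- lapply(triple, nufft_operator)
  lapply(1:3, function(i) nufft_forward(ops[[i]], img, source_mask = i))
}
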