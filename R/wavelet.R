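# Periodized orthogonal Daubechies-4 (4-tap) wavelet transform, used as the
# sparsifying transform Psi of the reconstruction objective. One analysis
# level is an orthonormal circulant matrix (low-pass rows over high-pass
# rows), applied separably to rows and columns of the current approximation
# band; periodization keeps the transform exactly orthonormal at every even
# size, so the inverse is the transpose.

db4_lowpass <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))

# n x n one-level analysis matrix: rows 1..n/2 approximation, n/2+1..n detail
dwt_level_matrix <- function(n) {
  h <- db4_lowpass
  g <- rev(h) * c(1, -1, 1, -1) # quadrature mirror high-pass
  W <- matrix(0, n, n)
  half <- n %/% 2L
  for (i in seq_len(half)) {
    for (k in seq_along(h)) {
      j <- ((2L * (i - 1L) + (k - 1L)) %% n) + 1L
      W[i, j] <- W[i, j] + h[k]
      W[half + i, j] <- W[half + i, j] + g[k]
    }
  }
  W
}

.dwt_cache <- new.env(parent = emptyenv())

dwt_matrix_cached <- function(n) {
  key <- as.character(n)
  if (is.null(.dwt_cache[[key]])) .dwt_cache[[key]] <- dwt_level_matrix(n)
  .dwt_cache[[key]]
}

check_dwt_size <- function(n, levels) {
  if (n %% 2L^levels != 0L) {
    stop_input("image side %d is not a multiple of 2^%d", n, levels)
  }
}

#' Forward 2D Daubechies-4 wavelet transform
#'
#' Multi-level separable periodized transform; orthonormal, so energy is
#' preserved and [idwt2()] is the exact inverse. Coefficients are returned in
#' the standard in-place layout (approximation band in the top-left corner).
#'
#' @param x N x N numeric or complex matrix, N a multiple of `2^levels`.
#' @param levels Number of decomposition levels.
#' @return N x N coefficient matrix.
#' @export
dwt2 <- function(x, levels = 4L) {
  n <- nrow(check_matrix_image(x, name = "x"))
  check_dwt_size(n, levels)
  for (l in seq_len(levels)) {
    m <- n %/% 2L^(l - 1L)
    W <- dwt_matrix_cached(m)
    idx <- seq_len(m)
    x[idx, idx] <- W %*% x[idx, idx] %*% t(W)
  }
  x
}

#' Inverse 2D Daubechies-4 wavelet transform
#'
#' @param w Coefficient matrix from [dwt2()].
#' @param levels Number of decomposition levels (must match the forward).
#' @return N x N matrix.
#' @export
idwt2 <- function(w, levels = 4L) {
  n <- nrow(check_matrix_image(w, name = "w"))
  check_dwt_size(n, levels)
  for (l in rev(seq_len(levels))) {
    m <- n %/% 2L^(l - 1L)
    W <- dwt_matrix_cached(m)
    idx <- seq_len(m)
    w[idx, idx] <- t(W) %*% w[idx, idx] %*% W
  }
  w
}
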