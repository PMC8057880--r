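# Internal helpers shared across modules.

#' @importFrom stats rnorm runif sd var cor fft pnorm
#' @importFrom utils head tail
NULL

# round-half-away-from-zero; base round() is banker's rounding
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x < 1 || x != as.integer(x)) {
    stop_input("`%s` must be a single positive integer, got %s",
               name, deparse(substitute(x)))
  }
  as.integer(x)
}

check_matrix_image <- function(x, n = NULL, name = "image") {
  if (!is.matrix(x)) stop_input("`%s` must be a matrix", name)
  if (nrow(x) != ncol(x)) stop_input("`%s` must be square", name)
  if (!is.null(n) && nrow(x) != n) {
    stop_input("`%s` must be %dx%d, got %dx%d", name, n, n, nrow(x), ncol(x))
  }
  x
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Quadrant swaps for even- or odd-sized matrices (vector or matrix input).
fftshift_idx <- function(n) c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))
ifftshift_idx <- function(n) c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))

fftshift2 <- function(x) x[fftshift_idx(nrow(x)), fftshift_idx(ncol(x)), drop = FALSE]
ifftshift2 <- function(x) x[ifftshift_idx(nrow(x)), ifftshift_idx(ncol(x)), drop = FALSE]

# Centered unitary 2D FFT pair: frequency index m/N, m = -N/2 .. N/2-1,
# image index p - N/2 (0-based). Used by diagnostics and the sharpness index.
fft2c <- function(x) fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
ifft2c <- function(x) fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))

# centered 0-based pixel offsets for an N-point axis
centered_offsets <- function(n) seq_len(n) - 1L - floor(n / 2)

rel_l2 <- function(a, b) {
  d <- sqrt(sum(Mod(a - b)^2))
  r <- sqrt(sum(Mod(b)^2))
  if (r == 0) d else d / r
}
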