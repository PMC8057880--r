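# Image-quality metrics: five full-reference (MSE, PSNR, Pearson
# correlation, SSIM, FSIM) and two no-reference (sharpness index, PIQE).
# All metrics consume real magnitude images; the stack evaluator normalizes
# to [0, 1] by the ground-truth maximum (full-reference) or the image's own
# maximum (no-reference). FSIM and PIQE rescale internally to 0-255 where
# their constants require it.

#' Mean squared error
#' @param x,y Same-shape numeric matrices.
#' @return Nonnegative scalar.
#' @export
mse <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop_input("images must have identical shape")
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(max_val^2 / MSE)` with `max_val` the reference dynamic range
#' (1 after normalization). Identical images give `Inf`.
#'
#' @param x Reference image.
#' @param y Test image.
#' @param max_val Maximum possible value of the reference's range.
#' @return Scalar in dB (possibly `Inf`).
#' @export
psnr <- function(x, y, max_val = 1) {
  e <- mse(x, y)
  if (e == 0) return(Inf)
  10 * log10(max_val^2 / e)
}

#' Pearson correlation between two images
#' @param x,y Same-shape, nonconstant numeric matrices.
#' @return Scalar in `[-1, 1]`.
#' @export
corr <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop_input("images must have identical shape")
  if (sd(x) == 0 || sd(y) == 0) stop_input("correlation undefined for a constant image")
  cor(as.vector(x), as.vector(y))
}

gaussian_kernel_1d <- function(size, sigma) {
  u <- seq_len(size) - (size + 1) / 2
  k <- exp(-u^2 / (2 * sigma^2))
  k / sum(k)
}

# banded matrix applying a 1D kernel along one axis with "valid" support
valid_filter_matrix <- function(n, kernel) {
  w <- length(kernel)
  m <- n - w + 1L
  K <- matrix(0, m, n)
  for (i in seq_len(m)) K[i, i:(i + w - 1L)] <- kernel
  K
}

#' Structural similarity index
#'
#' Local-window SSIM: means, variances and covariance are computed under a
#' sliding Gaussian window (size 11, sigma 1.5 by default, valid support) and
#' the per-window indices `(2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#' ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))` are averaged. With
#' `global = TRUE` the statistic is evaluated once over the whole image
#' (single-window form, handy for hand verification).
#'
#' @param x,y Same-shape images.
#' @param window_size,window_sigma Gaussian window parameters.
#' @param k1,k2 Stabilization constants (defaults 0.01, 0.03).
#' @param L Dynamic range (1 for normalized magnitudes).
#' @param global Evaluate the single-window statistic instead.
#' @return Scalar (1 for identical images).
#' @export
ssim <- function(x, y, window_size = 11L, window_sigma = 1.5,
                 k1 = 0.01, k2 = 0.03, L = 1, global = FALSE) {
  if (!identical(dim(x), dim(y))) stop_input("images must have identical shape")
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  if (global) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / (n - 1)
    vy <- sum((y - my)^2) / (n - 1)
    cxy <- sum((x - mx) * (y - my)) / (n - 1)
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  if (nrow(x) < window_size || ncol(x) < window_size) {
    stop_input("image smaller than the %d-pixel SSIM window", window_size)
  }
  g <- gaussian_kernel_1d(window_size, window_sigma)
  Kr <- valid_filter_matrix(nrow(x), g)
  Kc <- valid_filter_matrix(ncol(x), g)
  smooth <- function(z) Kr %*% z %*% t(Kc)
  mx <- smooth(x); my <- smooth(y)
  vx <- smooth(x * x) - mx^2
  vy <- smooth(y * y) - my^2
  cxy <- smooth(x * y) - mx * my
  num <- (2 * mx * my + c1) * (2 * cxy + c2)
  den <- (mx^2 + my^2 + c1) * (vx + vy + c2)
  mean(num / den)
}

# ---- FSIM -----------------------------------------------------------------

# log-Gabor x angular-spread filter bank in the frequency domain; cached per
# image size (4 scales, 4 orientations)
.fsim_cache <- new.env(parent = emptyenv())

fsim_filter_bank <- function(n, n_scales = 4L, n_orient = 4L,
                             min_wavelength = 6, mult = 2, sigma_onf = 0.55,
                             d_theta_on_sigma = 1.2) {
  key <- paste(n, n_scales, n_orient, sep = "_")
  if (!is.null(.fsim_cache[[key]])) return(.fsim_cache[[key]])
  f <- centered_offsets(n) / n
  fx <- matrix(rep(f, n), n, n)
  fy <- t(fx)
  radius <- ifftshift2(sqrt(fx^2 + fy^2))
  radius[1, 1] <- 1 # avoid log(0) at DC; filter value overwritten below
  theta <- ifftshift2(atan2(-fy, fx))
  sin_t <- sin(theta); cos_t <- cos(theta)
  theta_sigma <- pi / n_orient / d_theta_on_sigma
  bank <- vector("list", n_orient)
  for (o in seq_len(n_orient)) {
    angl <- (o - 1) * pi / n_orient
    ds <- sin_t * cos(angl) - cos_t * sin(angl)
    dc <- cos_t * cos(angl) + sin_t * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    scales <- vector("list", n_scales)
    for (s in seq_len(n_scales)) {
      wavelength <- min_wavelength * mult^(s - 1)
      fo <- 1 / wavelength
      log_gabor <- exp(-(log(radius / fo))^2 / (2 * log(sigma_onf)^2))
      log_gabor[1, 1] <- 0
      scales[[s]] <- log_gabor * spread
    }
    bank[[o]] <- scales
  }
  .fsim_cache[[key]] <- bank
  bank
}

# phase congruency: orientation-wise local energy over summed amplitude
phase_congruency <- function(img, eps = 1e-4) {
  n <- nrow(img)
  bank <- fsim_filter_bank(n)
  F_img <- stats::fft(img)
  energy <- matrix(0, n, n)
  amp_sum <- matrix(0, n, n)
  for (o in seq_along(bank)) {
    sum_resp <- matrix(0 + 0i, n, n)
    amp_o <- matrix(0, n, n)
    for (s in seq_along(bank[[o]])) {
      resp <- stats::fft(F_img * bank[[o]][[s]], inverse = TRUE) / length(img)
      sum_resp <- sum_resp + resp
      amp_o <- amp_o + Mod(resp)
    }
    energy <- energy + Mod(sum_resp)
    amp_sum <- amp_sum + amp_o
  }
  energy / (amp_sum + eps)
}

scharr_gradient <- function(img) {
  n <- nrow(img); m <- ncol(img)
  pad <- img[c(1, seq_len(n), n), c(1, seq_len(m), m)] # replicate border
  sh <- function(di, dj) pad[seq_len(n) + 1 + di, seq_len(m) + 1 + dj]
  gx <- (3 * sh(-1, -1) + 10 * sh(0, -1) + 3 * sh(1, -1) -
           3 * sh(-1, 1) - 10 * sh(0, 1) - 3 * sh(1, 1)) / 16
  gy <- (3 * sh(-1, -1) + 10 * sh(-1, 0) + 3 * sh(-1, 1) -
           3 * sh(1, -1) - 10 * sh(1, 0) - 3 * sh(1, 1)) / 16
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index
#'
#' Combines a phase-congruency similarity (log-Gabor bank, 4 scales x 4
#' orientations) with a gradient-magnitude similarity (Scharr operators),
#' weighting each pixel by the larger of the two phase-congruency maps:
#' `sum(S_PC * S_G * PCm) / sum(PCm)`. Images are rescaled to 0-255
#' internally so the stabilization constants `T1 = 0.85`, `T2 = 160` apply.
#'
#' @param x,y Same-shape images, at least 32 x 32.
#' @param T1,T2 Stabilization constants for the PC and gradient similarities.
#' @return Scalar in `[0, 1]` (1 for identical images).
#' @export
fsim <- function(x, y, T1 = 0.85, T2 = 160) {
  if (!identical(dim(x), dim(y))) stop_input("images must have identical shape")
  if (nrow(x) < 32 || ncol(x) < 32) stop_input("fsim needs images of at least 32 x 32")
  scale <- max(abs(x), abs(y))
  if (scale == 0) scale <- 1
  x <- x / scale * 255
  y <- y / scale * 255
  pc1 <- phase_congruency(x)
  pc2 <- phase_congruency(y)
  g1 <- scharr_gradient(x)
  g2 <- scharr_gradient(y)
  s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  s_g <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / sum(pcm)
}

# ---- sharpness index ------------------------------------------------------

random_phase_resample <- function(img) {
  X <- stats::fft(img)
  W <- stats::fft(matrix(rnorm(length(img)), nrow(img), ncol(img)))
  U <- W / ifelse(Mod(W) == 0, 1, Mod(W)) # Hermitian all-pass
  Re(stats::fft(X * U, inverse = TRUE)) / length(img)
}

#' Sharpness index
#'
#' No-reference sharpness score: how exceptional the image's total variation
#' is among random-phase resamples of itself (same Fourier modulus, phases
#' randomized). With `mu_TV`, `sigma_TV` the Monte-Carlo mean and standard
#' deviation of TV over resamples, the index is
#' `-log10 P(Z > (mu_TV - TV(x)) / sigma_TV)` under a standard normal tail:
#' sharp structure gives a TV far below the resample mean, hence a large
#' index. A random-phase image itself scores about `-log10(0.5) ~ 0.3`.
#'
#' With `literal = TRUE` the tail function is dropped and the index is
#' `-log10((mu_TV - TV(x)) / sigma_TV)` (the compact printed form of the
#' statistic; `NaN` when the argument is nonpositive).
#'
#' @param x Nonconstant numeric matrix.
#' @param n_resamples Number of random-phase resamples.
#' @param seed RNG seed for the resampling.
#' @param literal Use the tail-free variant.
#' @return Scalar; higher means sharper.
#' @export
sharpness_index <- function(x, n_resamples = 100L, seed = 1L, literal = FALSE) {
  if (!is.matrix(x) || sd(x) == 0) {
    stop_input("sharpness index undefined for constant or non-matrix input")
  }
  tvs <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      total_variation(random_phase_resample(x))
    }, numeric(1))
  })
  mu <- mean(tvs)
  sigma <- sd(tvs)
  z <- (mu - total_variation(x)) / sigma
  if (literal) {
    return(-log10(z))
  }
  -pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# ---- PIQE -----------------------------------------------------------------

# mean-subtracted contrast-normalized coefficients (7x7 Gaussian, 0-255 scale)
mscn_coefficients <- function(img) {
  k <- gaussian_kernel_1d(7L, 7 / 6)
  # separable filtering with replicate padding
  filt_axis <- function(z, along_rows) {
    sz <- if (along_rows) nrow(z) else ncol(z)
    idx <- vapply(1:7, function(a) pmin(pmax(seq_len(sz) + a - 4L, 1L), sz),
                  integer(sz))
    acc <- 0
    for (a in 1:7) {
      acc <- acc + k[a] * (if (along_rows) z[idx[, a], , drop = FALSE]
                           else z[, idx[, a], drop = FALSE])
    }
    acc
  }
  mu <- filt_axis(filt_axis(img, TRUE), FALSE)
  sigma <- sqrt(abs(filt_axis(filt_axis(img * img, TRUE), FALSE) - mu^2))
  list(mscn = (img - mu) / (sigma + 1), sigma = sigma)
}

#' Perceptual image quality evaluator (PIQE)
#'
#' Block-based no-reference score. The image is rescaled to 0-255, its
#' mean-subtracted contrast-normalized (MSCN) coefficients computed, and
#' divided into 16 x 16 blocks. Blocks whose MSCN variance exceeds 0.1 are
#' spatially active; an active block is scored as distorted (`D = 100`) when
#' it shows a noticeable blocking artifact (a low-variance 6-pixel segment on
#' its boundary) or noticeable noise (MSCN variance above 0.35), else 0. The
#' score is `(sum(D) + C1) / (N_SA + C1)` with `C1 = 1`: a flat image (no
#' active blocks) scores exactly 1, a fully distorted one approaches 100.
#' Lower is better.
#'
#' @param x Grayscale image, at least 64 x 64.
#' @param activity_threshold MSCN block-variance threshold for spatial
#'   activity.
#' @param noise_threshold MSCN block-variance threshold for the noise
#'   criterion.
#' @param segment_threshold Standard-deviation threshold for the boundary
#'   segment artifact criterion.
#' @return Scalar in `(0, 100]`.
#' @export
piqe <- function(x, activity_threshold = 0.1, noise_threshold = 0.35,
                 segment_threshold = 0.1) {
  if (!is.matrix(x) || nrow(x) < 64 || ncol(x) < 64) {
    stop_input("piqe needs an image of at least 64 x 64")
  }
  scale <- max(abs(x))
  if (scale == 0) scale <- 1
  img <- x / scale * 255
  bs <- 16L
  n <- (nrow(img) %/% bs) * bs
  m <- (ncol(img) %/% bs) * bs
  mscn <- mscn_coefficients(img[seq_len(n), seq_len(m)])$mscn
  n_active <- 0L
  d_sum <- 0
  seg_len <- 6L
  for (bi in seq_len(n %/% bs)) {
    for (bj in seq_len(m %/% bs)) {
      blk <- mscn[((bi - 1L) * bs + 1L):(bi * bs), ((bj - 1L) * bs + 1L):(bj * bs)]
      if (var(as.vector(blk)) <= activity_threshold) next
      n_active <- n_active + 1L
      # boundary segments: runs of 6 pixels along each block edge
      edges <- rbind(blk[1, ], blk[bs, ], blk[, 1], blk[, bs])
      starts <- seq(1L, bs - seg_len + 1L, by = seg_len - 1L)
      seg_sd <- apply(edges, 1, function(e) {
        min(vapply(starts, function(s) sd(e[s:(s + seg_len - 1L)]), numeric(1)))
      })
      impaired <- any(seg_sd < segment_threshold)
      noisy <- var(as.vector(blk)) > noise_threshold
      if (impaired || noisy) d_sum <- d_sum + 100
    }
  }
  (d_sum + 1) / (n_active + 1)
}

# ---- stack evaluation -----------------------------------------------------

METRIC_NAMES <- c("ssim", "fsim", "mse", "psnr", "corr", "si", "piqe")
HIGHER_BETTER <- c(ssim = TRUE, fsim = TRUE, mse = FALSE, psnr = TRUE,
                   corr = TRUE, si = TRUE, piqe = FALSE)

#' Evaluate a reconstructed stack against (optional) ground truth
#'
#' Computes the requested metrics per slice and their column means.
#' Full-reference metrics (ssim, fsim, mse, psnr, corr) need `truth` and
#' consume magnitudes normalized by the ground-truth maximum over the stack;
#' no-reference metrics (si, piqe) are computed on each image normalized by
#' its own maximum and do not need `truth`.
#'
#' @param recon A [slice_stack()] of reconstructions.
#' @param truth Matching [slice_stack()] of references, or `NULL`.
#' @param metrics Subset of `c("ssim","fsim","mse","psnr","corr","si","piqe")`.
#' @param si_resamples,si_seed Sharpness-index Monte-Carlo settings.
#' @param metadata Named list recorded on the report (method, ratio, ...).
#' @return Object of class `metrics_report`: list with `per_slice`
#'   (data.frame), `averages` (named numeric), `metadata`.
#' @export
evaluate_stack <- function(recon, truth = NULL, metrics = METRIC_NAMES,
                           si_resamples = 100L, si_seed = 1L,
                           metadata = list()) {
  stopifnot(inherits(recon, "slice_stack"))
  metrics <- match.arg(metrics, METRIC_NAMES, several.ok = TRUE)
  fr <- intersect(metrics, c("ssim", "fsim", "mse", "psnr", "corr"))
  if (length(fr) && is.null(truth)) {
    stop_input("full-reference metrics (%s) need ground truth",
               paste(fr, collapse = ", "))
  }
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "slice_stack"))
    if (n_slices(truth) != n_slices(recon) ||
        stack_matrix_size(truth) != stack_matrix_size(recon)) {
      stop_input("reconstruction and truth stacks must have matching shape")
    }
    tmax <- max(vapply(truth$data, max, numeric(1)))
    if (tmax == 0) tmax <- 1
  }
  rows <- lapply(seq_len(n_slices(recon)), function(i) {
    r <- recon$data[[i]]
    vals <- list(slice = i)
    if (!is.null(truth)) {
      tn <- truth$data[[i]] / tmax
      rn <- r / tmax
      if ("ssim" %in% metrics) vals$ssim <- ssim(tn, rn)
      if ("fsim" %in% metrics) vals$fsim <- fsim(tn, rn)
      if ("mse" %in% metrics) vals$mse <- mse(tn, rn)
      if ("psnr" %in% metrics) vals$psnr <- psnr(tn, rn)
      if ("corr" %in% metrics) vals$corr <- corr(tn, rn)
    }
    rmax <- max(abs(r))
    rown <- if (rmax > 0) r / rmax else r
    if ("si" %in% metrics) {
      vals$si <- sharpness_index(rown, n_resamples = si_resamples,
                                 seed = si_seed + i)
    }
    if ("piqe" %in% metrics) vals$piqe <- piqe(rown)
    as.data.frame(vals)
  })
  per_slice <- do.call(rbind, rows)
  cols <- setdiff(names(per_slice), "slice")
  averages <- vapply(per_slice[cols], mean, numeric(1))
  structure(
    list(per_slice = per_slice, averages = averages, metadata = metadata),
    class = "metrics_report"
  )
}

#' @export
#' @method print metrics_report
print.metrics_report <- function(x, ...) {
  meta <- if (length(x$metadata)) {
    paste0(" [", paste(names(x$metadata), unlist(x$metadata),
                       sep = "=", collapse = ", "), "]")
  } else ""
  cat(sprintf("<metrics_report> %d slices%s\n", nrow(x$per_slice), meta))
  print(round(x$averages, 4))
  invisible(x)
}
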