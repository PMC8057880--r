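# Synthetic multislice phantom. What interslice interpolation exploits is
# strong but imperfect correlation between neighboring slices; the phantom
# emulates that with an ellipse superposition whose geometry performs a
# slow random walk across slices (so correlation decays with slice lag, as
# anatomy drifts through a real 3D volume), plus additive Gaussian noise.

#' Ordered stack of 2D magnitude slices
#'
#' @param data List of equally sized numeric matrices with values in `[0, 1]`,
#'   or a 3D array with slices along the third dimension.
#' @param slice_thickness Slice thickness, arbitrary units (metadata).
#' @param interslice_gap Gap count used when the stack was decimated
#'   (metadata).
#' @param seed RNG seed the stack was generated from, if any (metadata).
#' @param description Provenance string.
#' @return Object of class `slice_stack`.
#' @export
slice_stack <- function(data, slice_thickness = 1, interslice_gap = 0L,
                        seed = NA_integer_, description = "") {
  if (is.array(data) && length(dim(data)) == 3) {
    data <- lapply(seq_len(dim(data)[3]), function(i) data[, , i])
  }
  if (!is.list(data) || !length(data) || !all(vapply(data, is.matrix, TRUE))) {
    stop_input("`data` must be a nonempty list of matrices or a 3D array")
  }
  dims <- vapply(data, dim, integer(2))
  if (any(dims != dims[1, 1])) stop_input("all slices must be square and equally sized")
  structure(
    list(data = data, slice_thickness = slice_thickness,
         interslice_gap = as.integer(interslice_gap), seed = seed,
         description = description),
    class = "slice_stack"
  )
}

#' @export
#' @method print slice_stack
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %d slices of %dx%d%s\n",
              n_slices(x), stack_matrix_size(x), stack_matrix_size(x),
              if (nzchar(x$description)) paste0(" -- ", x$description) else ""))
  invisible(x)
}

#' @export
#' @method as.array slice_stack
as.array.slice_stack <- function(x, ...) {
  array(unlist(x$data), dim = c(dim(x$data[[1]]), length(x$data)))
}

#' Number of slices in a stack
#' @param stack A [slice_stack()].
#' @return Integer slice count.
#' @export
n_slices <- function(stack) length(stack$data)

#' Matrix size (image side) of a stack's slices
#' @param stack A [slice_stack()].
#' @return Integer side length in pixels.
#' @export
stack_matrix_size <- function(stack) nrow(stack$data[[1]])

#' Phantom generation parameters
#'
#' Defaults are a desk-scale stand-in for a clinical multislice knee volume:
#' 24 slices of 128 x 128, geometric drift of 0.4% of the matrix size per
#' slice step, 1% additive noise, 8 ellipses over a background ellipse.
#'
#' @param n_slices Number of slices.
#' @param matrix_size Image side N (a multiple of 16, so the default 4-level
#'   wavelet applies).
#' @param drift Per-slice standard deviation of the geometric random walk, as
#'   a fraction of N.
#' @param noise_sigma Additive Gaussian noise standard deviation (intensity
#'   units, images live in `[0, 1]`).
#' @param n_ellipses Number of interior ellipses.
#' @param seed RNG seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 24L, matrix_size = 128L, drift = 0.004,
                         noise_sigma = 0.01, n_ellipses = 8L, seed = 1L) {
  n_slices <- check_positive_int(n_slices, "n_slices")
  matrix_size <- check_positive_int(matrix_size, "matrix_size")
  if (matrix_size %% 16L != 0L) stop_input("`matrix_size` must be a multiple of 16")
  if (drift < 0) stop_input("`drift` must be >= 0")
  if (noise_sigma < 0) stop_input("`noise_sigma` must be >= 0")
  n_ellipses <- check_positive_int(n_ellipses, "n_ellipses")
  structure(
    list(n_slices = n_slices, matrix_size = matrix_size, drift = drift,
         noise_sigma = noise_sigma, n_ellipses = n_ellipses,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

render_ellipses <- function(ell, N) {
  x <- matrix(rep(centered_offsets(N), N), N, N)       # row coordinate
  y <- t(x)                                            # column coordinate
  img <- matrix(0, N, N)
  for (e in ell) {
    ct <- cos(e$angle); st <- sin(e$angle)
    u <- (x - e$cx) * ct + (y - e$cy) * st
    v <- -(x - e$cx) * st + (y - e$cy) * ct
    img <- img + e$intensity * ((u / e$a)^2 + (v / e$b)^2 <= 1)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a drifting multislice ellipse phantom
#'
#' The first slice superposes a large background ellipse with
#' `spec$n_ellipses` randomized interior ellipses (centers, axes,
#' orientations and signed intensities drawn under the seed). Each following
#' slice perturbs every ellipse's center, axes and orientation by independent
#' Gaussian steps of standard deviation `drift * N` (a random walk across the
#' stack), then adds pixel noise and clips to `[0, 1]`. Deterministic for a
#' fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return A [slice_stack()].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  N <- spec$matrix_size
  with_seed(spec$seed, {
    ell <- list(list(cx = 0, cy = 0, a = 0.42 * N, b = 0.36 * N,
                     angle = runif(1, 0, pi), intensity = 0.7))
    for (i in seq_len(spec$n_ellipses)) {
      ell[[i + 1L]] <- list(
        cx = runif(1, -0.22, 0.22) * N,
        cy = runif(1, -0.22, 0.22) * N,
        a = runif(1, 0.04, 0.16) * N,
        b = runif(1, 0.04, 0.16) * N,
        angle = runif(1, 0, pi),
        intensity = runif(1, -0.35, 0.45)
      )
    }
    step_sd <- spec$drift * N
    slices <- vector("list", spec$n_slices)
    for (s in seq_len(spec$n_slices)) {
      if (s > 1L && step_sd > 0) {
        ell <- lapply(ell, function(e) {
          e$cx <- e$cx + rnorm(1, 0, step_sd)
          e$cy <- e$cy + rnorm(1, 0, step_sd)
          e$a <- max(2, e$a + rnorm(1, 0, step_sd))
          e$b <- max(2, e$b + rnorm(1, 0, step_sd))
          e$angle <- e$angle + rnorm(1, 0, spec$drift * pi)
          e
        })
      }
      img <- render_ellipses(ell, N)
      if (spec$noise_sigma > 0) {
        img <- pmin(pmax(img + matrix(rnorm(N * N, 0, spec$noise_sigma), N, N), 0), 1)
      }
      slices[[s]] <- img
    }
    slice_stack(slices, seed = spec$seed,
                description = sprintf(
                  "ellipse phantom (%d slices, N=%d, drift=%g, noise=%g, seed=%d)",
                  spec$n_slices, N, spec$drift, spec$noise_sigma, spec$seed))
  })
}

#' Mean interslice correlation by slice lag
#'
#' Diagnostic tying the phantom's drift to the interslice-gap experiment: the
#' pixelwise Pearson correlation between slices `i` and `i + lag`, averaged
#' over `i`. A drifting phantom shows a profile that decays with lag, so
#' decimating the stack by a gap `g` is equivalent to working at lag `g + 1`.
#'
#' @param stack A [slice_stack()].
#' @param max_lag Largest lag to evaluate (`< n_slices`).
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
correlation_profile <- function(stack, max_lag) {
  stopifnot(inherits(stack, "slice_stack"))
  n <- n_slices(stack)
  if (max_lag >= n) stop_input("`max_lag` must be smaller than the slice count")
  if (any(vapply(stack$data, function(s) sd(s) == 0, TRUE))) {
    stop_input("correlation undefined: stack contains a constant slice")
  }
  vapply(0:max_lag, function(lag) {
    mean(vapply(seq_len(n - lag), function(i) {
      cor(as.vector(stack$data[[i]]), as.vector(stack$data[[i + lag]]))
    }, numeric(1)))
  }, numeric(1))
}

#' Write a slice stack to disk
#'
#' Formats by extension: `.nii` / `.nii.gz` (NIfTI, via RNifti) or `.rds`
#' (native array archive). Both round-trip data and metadata losslessly.
#'
#' @param stack A [slice_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  fmt <- stack_format(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(as.array(stack))
    RNifti::writeNifti(img, path, datatype = "double")
  } else {
    saveRDS(stack, path)
  }
  invisible(path)
}

#' Read a slice stack from disk
#'
#' A 3D NIfTI of shape (N, N, S) yields S slices. Magnitudes are normalized
#' to `[0, 1]` by the volume maximum, with the scale recorded in the
#' description.
#'
#' @param path Input path (`.nii`, `.nii.gz`, or `.rds`).
#' @return A [slice_stack()].
#' @export
load_stack <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  fmt <- stack_format(path)
  if (fmt == "rds") {
    stack <- readRDS(path)
    if (!inherits(stack, "slice_stack")) stop_input("%s is not a slice_stack archive", path)
    return(stack)
  }
  arr <- abs(as.array(RNifti::readNifti(path)))
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  if (length(dim(arr)) != 3) stop_input("expected a 2D or 3D NIfTI volume")
  scale <- max(arr)
  if (scale > 0) arr <- arr / scale
  slice_stack(arr, description = sprintf("loaded from %s (scale %g)",
                                         basename(path), scale))
}

stack_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.rds$", path, ignore.case = TRUE)) return("rds")
  stop_input("unsupported stack format: %s (use .nii, .nii.gz or .rds)", path)
}
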