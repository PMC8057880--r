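# Radial k-space trajectory generation: spoke budgets, uniform-angle and
# golden-angle schemes, nonoverlapping mask triples, and ramp density
# compensation. All k-space coordinates are in cycles/pixel in [-0.5, 0.5);
# angles are in degrees reduced modulo 180 (diametric spokes are equivalent).

GOLDEN_RATIO <- (1 + sqrt(5)) / 2

#' Number of radial spokes satisfying azimuthal Nyquist
#'
#' For an `matrix_size` x `matrix_size` image sampled with full-diameter radial
#' spokes, azimuthal Nyquist at the k-space rim requires about pi/2 times the
#' matrix size uniformly spaced spokes (402 spokes for a 256 x 256 image).
#'
#' @param matrix_size Image side length in pixels (integer >= 2).
#' @return Integer spoke count, `round(pi/2 * matrix_size)` (half away from
#'   zero).
#' @examples
#' nyquist_spokes(256) # 402
#' @export
nyquist_spokes <- function(matrix_size) {
  matrix_size <- check_positive_int(matrix_size, "matrix_size")
  if (matrix_size < 2) stop_input("`matrix_size` must be >= 2")
  as.integer(round_half_up(pi / 2 * matrix_size))
}

#' Spoke budget for a target sampling ratio
#'
#' Converts a sampling fraction (relative to the radial Nyquist budget of
#' [nyquist_spokes()]) into a spoke count. At N = 256 the fractions
#' 3%, 5%, 7%, 9% give 12, 20, 28 and 36 spokes.
#'
#' @param ratio Sampling fraction in (0, 1].
#' @param matrix_size Image side length in pixels.
#' @return Integer spoke count (at least 1).
#' @examples
#' spokes_for_ratio(0.03, 256) # 12
#' @export
spokes_for_ratio <- function(ratio, matrix_size) {
  if (length(ratio) != 1L || !is.numeric(ratio) || !is.finite(ratio) ||
      ratio <= 0 || ratio > 1) {
    stop_input("`ratio` must be a single fraction in (0, 1]")
  }
  max(1L, as.integer(round_half_up(ratio * nyquist_spokes(matrix_size))))
}

#' Golden-angle spoke angles
#'
#' Successive spokes are separated by 180 / phi ~ 111.246 degrees (phi the
#' golden ratio), reduced modulo 180. The sequence is self-interleaving: no
#' angle repeats and any prefix covers the half-circle near-uniformly.
#'
#' @param n_spokes Number of spokes.
#' @param start_deg First spoke angle in degrees (default 0).
#' @return Numeric vector of angles in `[0, 180)`, in acquisition order.
#' @export
golden_angles <- function(n_spokes, start_deg = 0) {
  n_spokes <- check_positive_int(n_spokes, "n_spokes")
  (start_deg + (seq_len(n_spokes) - 1) * 180 / GOLDEN_RATIO) %% 180
}

#' Uniformly spaced spoke angles
#'
#' @param n_spokes Number of spokes.
#' @param offset_deg Angular offset of the first spoke in degrees.
#' @return Numeric vector of angles in `[0, 180)` with constant gap
#'   `180 / n_spokes`.
#' @export
uniform_angles <- function(n_spokes, offset_deg = 0) {
  n_spokes <- check_positive_int(n_spokes, "n_spokes")
  (offset_deg + (seq_len(n_spokes) - 1) * 180 / n_spokes) %% 180
}

#' Construct a radial trajectory from spoke angles
#'
#' Each spoke is a full diameter through the k-space origin: `n_readout`
#' samples at radii `(-N/2 .. N/2 - 1)/N` cycles/pixel (so the exact DC point
#' is on every spoke when `n_readout` is even).
#'
#' @param angles_deg Spoke angles in degrees; reduced modulo 180 and required
#'   pairwise distinct.
#' @param matrix_size Target image side N in pixels.
#' @param n_readout Samples per spoke (default `matrix_size`).
#' @param scheme Label, `"uniform"` or `"golden"`.
#' @return An object of class `radial_trajectory` with fields `angles_deg`,
#'   `n_readout`, `matrix_size`, `coords` (one row per sample: kx, ky in
#'   cycles/pixel), `scheme`, `spoke_ids`.
#' @export
radial_trajectory <- function(angles_deg, matrix_size,
                              n_readout = matrix_size,
                              scheme = c("uniform", "golden")) {
  scheme <- match.arg(scheme)
  matrix_size <- check_positive_int(matrix_size, "matrix_size")
  n_readout <- check_positive_int(n_readout, "n_readout")
  angles_deg <- as.numeric(angles_deg) %% 180
  if (length(angles_deg) < 1) stop_input("need at least one spoke angle")
  if (anyDuplicated(angles_deg)) stop_input("spoke angles must be pairwise distinct")
  radii <- centered_offsets(n_readout) / n_readout
  theta <- angles_deg * pi / 180
  coords <- cbind(
    kx = as.vector(outer(radii, cos(theta))),
    ky = as.vector(outer(radii, sin(theta)))
  )
  structure(
    list(
      angles_deg = angles_deg,
      n_readout = n_readout,
      matrix_size = matrix_size,
      coords = coords,
      scheme = scheme,
      spoke_ids = rep(seq_along(angles_deg), each = n_readout)
    ),
    class = "radial_trajectory"
  )
}

#' @export
#' @method print radial_trajectory
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("<radial_trajectory> %s scheme, %d spokes x %d samples, N = %d\n",
              x$scheme, length(x$angles_deg), x$n_readout, x$matrix_size))
  invisible(x)
}

n_spokes <- function(traj) length(traj$angles_deg)

#' Three nonoverlapping radial masks
#'
#' Generates `3 * n_spokes` angles by the chosen scheme and deals them
#' round-robin to three masks, so the masks share the scheme, spoke count and
#' readout length but have pairwise disjoint angle sets. In a multislice
#' acquisition the triple cycles along the stack (slice i gets mask
#' `i mod 3`), which is what makes neighbor slices carry complementary
#' k-space locations.
#'
#' @param n_spokes Spokes per mask.
#' @param scheme `"uniform"` or `"golden"`.
#' @param matrix_size Image side N in pixels.
#' @param offset_or_start Angular offset (uniform) or starting angle (golden),
#'   degrees; default 0.
#' @return An object of class `mask_triple`: a list of three
#'   [radial_trajectory()] objects.
#' @export
make_mask_triple <- function(n_spokes, scheme = c("uniform", "golden"),
                             matrix_size, offset_or_start = 0) {
  scheme <- match.arg(scheme)
  n_spokes <- check_positive_int(n_spokes, "n_spokes")
  all_angles <- switch(scheme,
    uniform = uniform_angles(3L * n_spokes, offset_or_start),
    golden = golden_angles(3L * n_spokes, offset_or_start)
  )
  masks <- lapply(1:3, function(j) {
    radial_trajectory(all_angles[seq(j, length(all_angles), by = 3L)],
                      matrix_size = matrix_size, scheme = scheme)
  })
  structure(masks, class = "mask_triple")
}

#' @export
#' @method print mask_triple
print.mask_triple <- function(x, ...) {
  cat(sprintf("<mask_triple> %s scheme, 3 masks x %d spokes, N = %d\n",
              x[[1]]$scheme, length(x[[1]]$angles_deg), x[[1]]$matrix_size))
  invisible(x)
}

# DCF weights from raw sample radii: N^2 x polar cell area (|k| dk dtheta),
# so the density-compensated adjoint approximates the continuous inverse
# Fourier integral under the package's unitary 1/N operator scaling.
ramp_dcf_radii <- function(kr, matrix_size, n_spokes) {
  w <- matrix_size * pi * kr / n_spokes
  nz <- w[w > 0]
  if (length(nz)) w[w == 0] <- min(nz) / 4
  w
}

#' Ramp (Ram-Lak) density compensation weights
#'
#' Radial sampling overrepresents the k-space center; gridding reconstruction
#' weights each sample by the area of its polar cell, which grows linearly
#' with `|k|` along a spoke. The exact DC sample receives a quarter of the
#' first nonzero-radius weight (its cell is a disc segment, not an annulus).
#' Weights are scaled so that at the Nyquist spoke count the
#' density-compensated adjoint approximately inverts the forward operator.
#'
#' @param traj A [radial_trajectory()].
#' @return An object of class `density_weights`: a nonnegative numeric vector,
#'   one weight per trajectory sample.
#' @export
ramp_dcf <- function(traj) {
  if (!inherits(traj, "radial_trajectory")) {
    stop_input("`traj` must be a radial_trajectory")
  }
  if (nrow(traj$coords) == 0) stop_input("empty trajectory")
  kr <- sqrt(rowSums(traj$coords^2))
  structure(ramp_dcf_radii(kr, traj$matrix_size, n_spokes(traj)),
            class = "density_weights")
}

#' Export a trajectory as a plain-text sample table
#'
#' One row per sample: `spoke_id`, `kx`, `ky`, `dcf_weight`.
#'
#' @param traj A [radial_trajectory()].
#' @param path Output file (TSV). If `NULL`, the data frame is returned
#'   without writing.
#' @return The sample table, invisibly when written.
#' @export
export_trajectory <- function(traj, path = NULL) {
  dcf <- ramp_dcf(traj)
  tab <- data.frame(
    spoke_id = traj$spoke_ids,
    kx = traj$coords[, 1],
    ky = traj$coords[, 2],
    dcf_weight = as.numeric(dcf)
  )
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
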