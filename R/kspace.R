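# SampledKSpace: complex k-space samples keyed by quantized sample location.
# This is the carrier for the set algebra of interslice interpolation: two
# samples are "the same location" iff their coordinates agree after
# quantization to 1e-6 cycles/pixel. With full-diameter radial spokes the
# only location shared between distinct spokes is the exact DC point.

KSPACE_QUANTUM <- 1e-6

kspace_keys <- function(kx, ky) {
  paste(round(kx / KSPACE_QUANTUM), round(ky / KSPACE_QUANTUM))
}

#' Complex k-space samples keyed by location
#'
#' Builds the canonical sample container used by the interpolation set
#' algebra. Coordinates are quantized (step 1e-6 cycles/pixel) into unique
#' location keys; duplicate locations within the input (the DC point shared
#' by every spoke of one mask) are collapsed to their first occurrence, which
#' is lossless because co-located samples of one slice carry equal values.
#'
#' @param kx,ky Sample coordinates in cycles/pixel.
#' @param value Complex sample values, same length.
#' @param matrix_size Image side N the samples refer to.
#' @param n_readout Samples per spoke of the generating mask (default
#'   `matrix_size`), kept for density estimates.
#' @param provenance Optional per-sample tag in `{"T","L","R"}` (assigned by
#'   the interpolation step).
#' @param source_mask Optional identifier of the generating mask.
#' @return Object of class `sampled_kspace` with fields `kx`, `ky`, `value`,
#'   `key`, `provenance`, `source_mask`, `matrix_size`, `n_readout`.
#' @export
sampled_kspace <- function(kx, ky, value, matrix_size,
                           n_readout = matrix_size,
                           provenance = NULL, source_mask = NULL) {
  if (length(kx) != length(ky) || length(kx) != length(value)) {
    stop_input("kx, ky and value must have equal length")
  }
  key <- kspace_keys(kx, ky)
  keep <- !duplicated(key)
  if (!is.null(provenance)) provenance <- provenance[keep]
  structure(
    list(
      kx = as.numeric(kx)[keep],
      ky = as.numeric(ky)[keep],
      value = as.complex(value)[keep],
      key = key[keep],
      provenance = provenance,
      source_mask = source_mask,
      matrix_size = as.integer(matrix_size),
      n_readout = as.integer(n_readout)
    ),
    class = "sampled_kspace"
  )
}

#' @export
#' @method print sampled_kspace
print.sampled_kspace <- function(x, ...) {
  cat(sprintf("<sampled_kspace> %d samples, N = %d%s\n",
              length(x$value), x$matrix_size,
              if (is.null(x$provenance)) "" else " (tagged)"))
  invisible(x)
}

#' @export
#' @method length sampled_kspace
length.sampled_kspace <- function(x) length(x$value)

# values at an arbitrary coordinate list, via location keys
kspace_values_for <- function(ks, coords) {
  idx <- match(kspace_keys(coords[, 1], coords[, 2]), ks$key)
  if (anyNA(idx)) {
    stop_input("k-space object is missing %d of the requested sample locations",
               sum(is.na(idx)))
  }
  ks$value[idx]
}

kspace_subset <- function(ks, keep) {
  structure(
    list(
      kx = ks$kx[keep], ky = ks$ky[keep], value = ks$value[keep],
      key = ks$key[keep],
      provenance = if (is.null(ks$provenance)) NULL else ks$provenance[keep],
      source_mask = ks$source_mask,
      matrix_size = ks$matrix_size, n_readout = ks$n_readout
    ),
    class = "sampled_kspace"
  )
}

kspace_retag <- function(ks, tag) {
  ks$provenance <- rep(tag, length(ks$value))
  ks
}

#' Set difference of two sampled k-spaces
#'
#' Returns the entries of `a` whose locations are absent from `b` (values
#' copied from `a`, provenance inherited). This is the "new information of L
#' with respect to T" step of the interpolation scheme.
#'
#' @param a,b [sampled_kspace()] objects sharing the quantization convention.
#' @return A [sampled_kspace()].
#' @export
set_difference <- function(a, b) {
  stopifnot(inherits(a, "sampled_kspace"), inherits(b, "sampled_kspace"))
  kspace_subset(a, !(a$key %in% b$key))
}

#' Union of disjoint sampled k-spaces
#'
#' Concatenates the parts into one sample set. The parts are expected to be
#' pairwise disjoint in location (guaranteed when built from set differences
#' against a common target); on an unexpected collision the entry from the
#' later-listed part wins and a warning is emitted.
#'
#' @param parts List of [sampled_kspace()] objects.
#' @return A [sampled_kspace()] containing all entries.
#' @export
set_union <- function(parts) {
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, TRUE, "sampled_kspace")))
  kx <- unlist(lapply(parts, `[[`, "kx"))
  ky <- unlist(lapply(parts, `[[`, "ky"))
  value <- unlist(lapply(parts, `[[`, "value"))
  key <- unlist(lapply(parts, `[[`, "key"))
  prov <- lapply(parts, function(p) {
    if (is.null(p$provenance)) rep(NA_character_, length(p$value)) else p$provenance
  })
  prov <- unlist(prov)
  dup <- duplicated(key, fromLast = TRUE) # later-listed part wins
  if (any(dup)) {
    warning(sprintf("set_union: %d colliding sample location(s); later part wins",
                    sum(dup)), call. = FALSE)
  }
  keep <- !dup
  out <- structure(
    list(
      kx = kx[keep], ky = ky[keep], value = value[keep], key = key[keep],
      provenance = if (all(is.na(prov))) NULL else prov[keep],
      source_mask = NULL,
      matrix_size = parts[[1]]$matrix_size,
      n_readout = parts[[1]]$n_readout
    ),
    class = "sampled_kspace"
  )
  out
}

#' Three-slice k-space interpolation (EiCS rule)
#'
#' Fills the target slice's missing k-space locations from both neighbors:
#' `(l - t) + t + (r - t)` in set notation. Every target sample survives
#' unchanged; only locations the target did not acquire are imported, so with
#' pairwise nonoverlapping masks the output has `|t| + |l - t| + |r - t|`
#' samples -- almost three times the acquired budget. Provenance tags `L`,
#' `T`, `R` record where each sample came from.
#'
#' @param l,t,r [sampled_kspace()] of the left neighbor, target, and right
#'   neighbor slice.
#' @return A [sampled_kspace()] with provenance tags.
#' @export
eics_interpolate <- function(l, t, r) {
  l_new <- kspace_retag(set_difference(l, t), "L")
  r_new <- kspace_retag(set_difference(r, t), "R")
  # later-listed part wins in set_union: order gives T top priority, then L
  set_union(list(r_new, l_new, kspace_retag(t, "T")))
}

#' Two-slice k-space interpolation (FiCS baseline)
#'
#' The two-step predecessor of [eics_interpolate()]: the target keeps its own
#' samples and imports the left neighbor's new locations, `t + (l - t)`.
#'
#' @param l,t [sampled_kspace()] of the left neighbor and target slice.
#' @return A [sampled_kspace()] with provenance tags (`T`, `L`).
#' @export
fics_interpolate <- function(l, t) {
  l_new <- kspace_retag(set_difference(l, t), "L")
  set_union(list(l_new, kspace_retag(t, "T")))
}
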