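# Stack-level undersampling and interslice interpolation. A mask triple
# cycles along the stack with period 3, so any three consecutive slices were
# acquired with pairwise nonoverlapping radial masks; each slice's missing
# k-space locations can then be imported verbatim from its two neighbors.

#' Undersample a slice stack with a cycling mask triple
#'
#' Optionally decimates the stack first (keeping every `(gap+1)`-th slice, the
#' interslice-gap experiment), then forward-NUFFT-samples slice `i` with mask
#' `(i - 1) mod 3 + 1` of the triple.
#'
#' @param stack A [slice_stack()].
#' @param triple A [make_mask_triple()] whose `matrix_size` matches the stack.
#' @param gap Nonnegative integer: slices skipped between retained slices.
#' @return Object of class `undersampled_stack`: list with `slices` (list of
#'   [sampled_kspace()]), `triple`, `triple_assignment`, `ratio`, `gap`,
#'   `matrix_size`, `n_readout`, `kept_indices`, `method`.
#' @export
undersample_stack <- function(stack, triple, gap = 0L) {
  stopifnot(inherits(stack, "slice_stack"), inherits(triple, "mask_triple"))
  gap <- as.integer(gap)
  if (gap < 0) stop_input("`gap` must be a nonnegative integer")
  N <- triple[[1]]$matrix_size
  if (stack_matrix_size(stack) != N) {
    stop_input("stack matrix size %d does not match mask matrix size %d",
               stack_matrix_size(stack), N)
  }
  kept <- seq(1L, n_slices(stack), by = gap + 1L)
  if (length(kept) < 3) stop_input("fewer than 3 slices after gap decimation")
  ops <- lapply(triple, nufft_operator)
  assignment <- ((seq_along(kept) - 1L) %% 3L) + 1L
  slices <- lapply(seq_along(kept), function(i) {
    m <- assignment[i]
    nufft_forward(ops[[m]], stack$data[[kept[i]]] + 0i, source_mask = m)
  })
  structure(
    list(
      slices = slices,
      triple = triple,
      triple_assignment = assignment,
      ratio = length(triple[[1]]$angles_deg) / nyquist_spokes(N),
      gap = gap,
      matrix_size = N,
      n_readout = triple[[1]]$n_readout,
      kept_indices = kept,
      method = "none"
    ),
    class = "undersampled_stack"
  )
}

#' @export
#' @method print undersampled_stack
print.undersampled_stack <- function(x, ...) {
  cat(sprintf(
    "<undersampled_stack> %d slices, N = %d, nominal ratio %.3f, gap %d, method %s\n",
    length(x$slices), x$matrix_size, x$ratio, x$gap, x$method))
  invisible(x)
}

#' Interpolate every slice of an undersampled stack
#'
#' Treats each slice as a target with its two neighbors as left and right
#' donors. Interior slices use the three-slice rule ([eics_interpolate()]) or
#' the two-slice rule ([fics_interpolate()], left neighbor only); `"none"`
#' passes the stack through untouched (the plain-CS baseline, every sample
#' tagged `T`). Stack boundaries have only one neighbor, so the first slice
#' under `"eics"` degrades to the two-slice rule with its right neighbor and
#' the last slice (both methods) with its left neighbor; the single donor is
#' tagged `L`.
#'
#' @param u An [undersample_stack()] result.
#' @param method `"eics"`, `"fics"`, or `"none"`.
#' @return An `undersampled_stack` with interpolated, provenance-tagged
#'   slices; attribute `boundary_slices` lists the degraded slice indices.
#' @export
interpolate_stack <- function(u, method = c("eics", "fics", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(u, "undersampled_stack"))
  n <- length(u$slices)
  if (method == "none") {
    u$slices <- lapply(u$slices, kspace_retag, tag = "T")
    u$method <- "none"
    u$mask_combo <- paste0("n", u$triple_assignment)
    return(u)
  }
  if (method == "eics" && n < 3) stop_input("eics needs at least 3 slices")
  if (method == "fics" && n < 2) stop_input("fics needs at least 2 slices")
  s <- u$slices
  combo <- character(n)
  boundary <- integer(0)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (method == "eics") {
      if (i == 1L) {
        out[[i]] <- fics_interpolate(s[[2L]], s[[1L]])
        combo[i] <- paste0("f", u$triple_assignment[2L], "|", u$triple_assignment[1L])
        boundary <- c(boundary, i)
      } else if (i == n) {
        out[[i]] <- fics_interpolate(s[[n - 1L]], s[[n]])
        combo[i] <- paste0("f", u$triple_assignment[n - 1L], "|", u$triple_assignment[n])
        boundary <- c(boundary, i)
      } else {
        out[[i]] <- eics_interpolate(s[[i - 1L]], s[[i]], s[[i + 1L]])
        combo[i] <- paste(u$triple_assignment[c(i - 1L, i, i + 1L)], collapse = "|")
      }
    } else { # fics: left neighbor; first slice falls back to right neighbor
      if (i == 1L) {
        out[[i]] <- fics_interpolate(s[[2L]], s[[1L]])
        combo[i] <- paste0("f", u$triple_assignment[2L], "|", u$triple_assignment[1L])
        boundary <- c(boundary, i)
      } else {
        out[[i]] <- fics_interpolate(s[[i - 1L]], s[[i]])
        combo[i] <- paste0("f", u$triple_assignment[i - 1L], "|", u$triple_assignment[i])
      }
    }
  }
  u$slices <- out
  u$method <- method
  u$mask_combo <- combo # identical combos share one reconstruction operator
  attr(u, "boundary_slices") <- boundary
  u
}

#' Sample-provenance accounting
#'
#' For an interpolated stack, reports per slice the percentage of samples
#' that came from the target slice itself (`T`) versus its left/right donors
#' (`L`, `R`), plus each slice's total sample count as a percentage of the
#' full N x N Cartesian budget. The final row averages over slices. With the
#' three-slice rule on nonoverlapping masks the split is ~34/33/33.
#'
#' @param u An interpolated [undersample_stack()] (provenance tags present).
#' @return `data.frame` with columns `slice`, `pct_T`, `pct_L`, `pct_R`,
#'   `n_samples`, `pct_of_grid`; last row `slice = "average"`.
#' @export
provenance_table <- function(u) {
  stopifnot(inherits(u, "undersampled_stack"))
  if (any(vapply(u$slices, function(s) is.null(s$provenance), TRUE))) {
    stop_input("stack has no provenance tags; run interpolate_stack() first")
  }
  N2 <- as.numeric(u$matrix_size)^2
  rows <- lapply(seq_along(u$slices), function(i) {
    p <- u$slices[[i]]$provenance
    m <- length(p)
    data.frame(
      slice = as.character(i),
      pct_T = 100 * sum(p == "T") / m,
      pct_L = 100 * sum(p == "L") / m,
      pct_R = 100 * sum(p == "R") / m,
      n_samples = m,
      pct_of_grid = 100 * m / N2,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(
    slice = "average",
    pct_T = mean(tab$pct_T), pct_L = mean(tab$pct_L), pct_R = mean(tab$pct_R),
    n_samples = mean(tab$n_samples), pct_of_grid = mean(tab$pct_of_grid),
    stringsAsFactors = FALSE
  )
  rbind(tab, avg)
}
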