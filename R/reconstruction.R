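# Compressed-sensing reconstruction: nonlinear conjugate gradient on
#   f(x) = ||F_u x - y||^2 + lambda1 ||Psi x||_1 + lambda2 TV(x)
# with F_u the undersampling NUFFT, Psi the orthogonal wavelet transform and
# TV the isotropic total variation. Both nonsmooth terms are smoothed as
# sqrt(|.|^2 + mu) inside gradients; reported objective values use the
# unsmoothed l1/TV. Fletcher-Reeves directions with backtracking line search;
# the line search reuses cached transforms of the iterate and direction, so
# each step costs a constant number of NUFFT/DWT applications.

#' Solver configuration for CS reconstruction
#'
#' @param lambda1 l1-wavelet weight. `NULL` (default) scales at solve time to
#'   `lambda_scale * max |gridding recon of y|`, keeping the penalty
#'   commensurate with the data magnitude.
#' @param lambda2 TV weight; same default scaling as `lambda1`.
#' @param lambda_scale Scale for the data-driven lambda defaults.
#' @param l1_smooth Smoothing constant mu in `sqrt(|.|^2 + mu)`.
#' @param max_iter Maximum NCG iterations.
#' @param grad_tol Stop when the gradient norm falls below this.
#' @param ls_alpha Armijo sufficient-decrease constant, in (0, 0.5).
#' @param ls_beta Backtracking shrink factor, in (0, 1).
#' @param ls_max_steps Maximum backtracking halvings per iteration.
#' @param restart_every Fletcher-Reeves restart period.
#' @param wavelet Wavelet family label (only `"db4"` is built in).
#' @param wavelet_levels Decomposition levels.
#' @return Object of class `recon_params`.
#' @export
recon_params <- function(lambda1 = NULL, lambda2 = NULL, lambda_scale = 0.002,
                         l1_smooth = 1e-15, max_iter = 60L, grad_tol = 1e-9,
                         ls_alpha = 0.01, ls_beta = 0.6, ls_max_steps = 20L,
                         restart_every = 50L,
                         wavelet = "db4", wavelet_levels = 4L) {
  if (!is.null(lambda1) && lambda1 < 0) stop_input("lambda1 must be >= 0")
  if (!is.null(lambda2) && lambda2 < 0) stop_input("lambda2 must be >= 0")
  if (l1_smooth <= 0) stop_input("l1_smooth must be > 0")
  if (ls_alpha <= 0 || ls_alpha >= 0.5) stop_input("ls_alpha must be in (0, 0.5)")
  if (ls_beta <= 0 || ls_beta >= 1) stop_input("ls_beta must be in (0, 1)")
  if (!identical(wavelet, "db4")) stop_input("only the db4 wavelet is available")
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, lambda_scale = lambda_scale,
         l1_smooth = l1_smooth, max_iter = as.integer(max_iter),
         grad_tol = grad_tol, ls_alpha = ls_alpha, ls_beta = ls_beta,
         ls_max_steps = as.integer(ls_max_steps),
         restart_every = as.integer(restart_every),
         wavelet = wavelet, wavelet_levels = as.integer(wavelet_levels)),
    class = "recon_params"
  )
}

# forward differences with replicate boundary: last row/column difference 0
fdiff <- function(x) {
  m <- nrow(x); n <- ncol(x)
  d1 <- rbind(x[-1, , drop = FALSE] - x[-m, , drop = FALSE],
              matrix(0, 1, n))
  d2 <- cbind(x[, -1, drop = FALSE] - x[, -n, drop = FALSE],
              matrix(0, m, 1))
  list(d1 = d1, d2 = d2)
}

# adjoint of fdiff (negative divergence with matching boundary handling)
fdiff_adjoint <- function(d1, d2) {
  m <- nrow(d1); n <- ncol(d1)
  z1 <- rbind(matrix(0, 1, n), d1[-m, , drop = FALSE]) - d1
  z1[m, ] <- d1[m - 1, ]
  z2 <- cbind(matrix(0, m, 1), d2[, -n, drop = FALSE]) - d2
  z2[, n] <- d2[, n - 1]
  z1 + z2
}

#' Isotropic total variation of an image
#'
#' Sum over pixels of `sqrt(|d1 x|^2 + |d2 x|^2)` with forward finite
#' differences and replicate boundary (the last row/column difference is
#' zero). Used both as the reconstruction penalty and inside the sharpness
#' index.
#'
#' @param image Numeric or complex matrix, at least 2 x 2.
#' @return Nonnegative scalar.
#' @export
total_variation <- function(image) {
  if (!is.matrix(image) || nrow(image) < 2 || ncol(image) < 2) {
    stop_input("`image` must be a matrix with both sides >= 2")
  }
  d <- fdiff(image)
  sum(sqrt(Mod(d$d1)^2 + Mod(d$d2)^2))
}

#' l1 norm of the wavelet coefficients
#'
#' @param image N x N matrix, N a multiple of `2^levels`.
#' @param wavelet Wavelet family (`"db4"`).
#' @param levels Decomposition levels.
#' @return Sum of coefficient moduli.
#' @export
l1_wavelet <- function(image, wavelet = "db4", levels = 4L) {
  if (!identical(wavelet, "db4")) stop_input("only the db4 wavelet is available")
  sum(Mod(dwt2(image, levels = levels)))
}

resolve_lambdas <- function(p, y, op) {
  if (!is.null(p$lambda1) && !is.null(p$lambda2)) return(p)
  x0 <- nufft_adjoint(op, y, apply_dcf = !is.null(op$dcf))
  s <- p$lambda_scale * max(Mod(x0))
  if (is.null(p$lambda1)) p$lambda1 <- s
  if (is.null(p$lambda2)) p$lambda2 <- s
  p
}

#' Objective value and term-by-term breakdown
#'
#' Evaluates the reconstruction cost at `x`: data term `||F_u x - y||^2`,
#' unsmoothed `||Psi x||_1`, unsmoothed TV, and the weighted total.
#'
#' @param x N x N complex image.
#' @param y [sampled_kspace()] (or complex sample vector) of measurements.
#' @param op The [nufft_operator()] of the sampling pattern.
#' @param p A [recon_params()]; `NULL` lambdas are resolved from the data.
#' @return List of class `objective_breakdown` with `data_term`, `l1_term`,
#'   `tv_term`, `total`, `lambda1`, `lambda2`.
#' @export
objective <- function(x, y, op, p = recon_params()) {
  check_matrix_image(x, op$matrix_size)
  yv <- if (inherits(y, "sampled_kspace")) kspace_values_for(y, op$coords) else as.complex(y)
  p <- resolve_lambdas(p, yv, op)
  r <- nufft_forward_vec(op, x) - yv
  data_term <- sum(Mod(r)^2)
  l1_term <- l1_wavelet(x, levels = p$wavelet_levels)
  tv_term <- total_variation(x)
  structure(
    list(data_term = data_term, l1_term = l1_term, tv_term = tv_term,
         total = data_term + p$lambda1 * l1_term + p$lambda2 * tv_term,
         lambda1 = p$lambda1, lambda2 = p$lambda2),
    class = "objective_breakdown"
  )
}

# smoothed objective from cached transforms at x + t * dx
smoothed_cost <- function(t, cache, p) {
  r <- cache$Fx + t * cache$Fdx - cache$y
  w <- cache$Wx + t * cache$Wdx
  d1 <- cache$D1x + t * cache$D1dx
  d2 <- cache$D2x + t * cache$D2dx
  sum(Mod(r)^2) +
    p$lambda1 * sum(sqrt(Mod(w)^2 + p$l1_smooth)) +
    p$lambda2 * sum(sqrt(Mod(d1)^2 + Mod(d2)^2 + p$l1_smooth))
}

# gradient of the smoothed objective from cached transforms of x
# (complex-gradient convention: directional derivative along d is Re <g, d>)
smoothed_gradient_cached <- function(Fx, Wx, D1x, D2x, yv, op, p) {
  g <- 2 * nufft_adjoint_vec(op, Fx - yv)
  g <- g + p$lambda1 * idwt2(Wx / sqrt(Mod(Wx)^2 + p$l1_smooth),
                             levels = p$wavelet_levels)
  den <- sqrt(Mod(D1x)^2 + Mod(D2x)^2 + p$l1_smooth)
  g + p$lambda2 * fdiff_adjoint(D1x / den, D2x / den)
}

smoothed_gradient <- function(x, yv, op, p) {
  d <- fdiff(x)
  smoothed_gradient_cached(nufft_forward_vec(op, x),
                           dwt2(x, levels = p$wavelet_levels),
                           d$d1, d$d2, yv, op, p)
}

#' Nonlinear conjugate-gradient CS reconstruction of one slice
#'
#' Minimizes the l1-wavelet + TV regularized least-squares objective by
#' Fletcher-Reeves NCG with backtracking (Armijo) line search, starting from
#' the density-compensated gridding reconstruction unless `x0` is given. The
#' recorded objective trace (unsmoothed terms) is nonincreasing over accepted
#' steps; iteration stops at `max_iter`, at gradient norm below `grad_tol`,
#' or when the line search cannot find descent.
#'
#' @param y Measurements: a [sampled_kspace()] keyed to `op`'s trajectory, or
#'   a complex vector in trajectory order.
#' @param op [nufft_operator()] of the sampling pattern (with DCF for the
#'   default starting point).
#' @param p A [recon_params()].
#' @param x0 Optional starting image.
#' @return List of class `ncg_result`: `image` (complex N x N), `trace`
#'   (data.frame of per-iteration objective breakdowns), `iterations`,
#'   `lambda1`, `lambda2`.
#' @export
ncg_reconstruct <- function(y, op, p = recon_params(), x0 = NULL) {
  stopifnot(inherits(op, "nufft_operator"))
  yv <- if (inherits(y, "sampled_kspace")) kspace_values_for(y, op$coords) else as.complex(y)
  if (length(yv) != nrow(op$coords)) stop_input("measurement length mismatch")
  p <- resolve_lambdas(p, yv, op)
  N <- op$matrix_size
  check_dwt_size(N, p$wavelet_levels)
  x <- if (is.null(x0)) {
    nufft_adjoint(op, yv, apply_dcf = !is.null(op$dcf))
  } else {
    check_matrix_image(x0, N) + 0i
  }

  trace_rows <- list()
  record <- function(Fx, Wx, D1x, D2x, it) {
    data_term <- sum(Mod(Fx - yv)^2)
    l1_term <- sum(Mod(Wx))
    tv_term <- sum(sqrt(Mod(D1x)^2 + Mod(D2x)^2))
    total <- data_term + p$lambda1 * l1_term + p$lambda2 * tv_term
    trace_rows[[length(trace_rows) + 1L]] <<- data.frame(
      iter = it, data_term = data_term, l1_term = l1_term,
      tv_term = tv_term, total = total)
    total
  }

  # transforms of the running iterate, updated incrementally along the line
  Fx <- nufft_forward_vec(op, x)
  Wx <- dwt2(x, levels = p$wavelet_levels)
  fdx0 <- fdiff(x)
  D1x <- fdx0$d1; D2x <- fdx0$d2
  record(Fx, Wx, D1x, D2x, 0L)
  g <- smoothed_gradient_cached(Fx, Wx, D1x, D2x, yv, op, p)
  dx <- -g
  g_norm2 <- sum(Mod(g)^2)
  it <- 0L
  while (it < p$max_iter && sqrt(g_norm2) > p$grad_tol) {
    it <- it + 1L
    slope <- Re(sum(Conj(g) * dx))
    if (slope >= 0) { # not a descent direction: steepest-descent restart
      dx <- -g
      slope <- -g_norm2
    }
    fdd <- fdiff(dx)
    cache <- list(
      y = yv,
      Fx = Fx, Fdx = nufft_forward_vec(op, dx),
      Wx = Wx, Wdx = dwt2(dx, levels = p$wavelet_levels),
      D1x = D1x, D2x = D2x, D1dx = fdd$d1, D2dx = fdd$d2
    )
    f0 <- smoothed_cost(0, cache, p)
    # initial step from the data-term quadratic fit, then Armijo backtracking
    curv <- 2 * sum(Mod(cache$Fdx)^2)
    t <- if (curv > 0) -slope / curv else 1
    if (!is.finite(t) || t <= 0) t <- 1
    ls <- 0L
    while (ls < p$ls_max_steps &&
           smoothed_cost(t, cache, p) > f0 + p$ls_alpha * t * slope) {
      t <- t * p$ls_beta
      ls <- ls + 1L
    }
    if (smoothed_cost(t, cache, p) > f0) break # no descent found
    x <- x + t * dx
    Fx <- Fx + t * cache$Fdx
    Wx <- Wx + t * cache$Wdx
    D1x <- D1x + t * cache$D1dx
    D2x <- D2x + t * cache$D2dx
    total <- record(Fx, Wx, D1x, D2x, it)
    if (!is.finite(total)) {
      stop(structure(
        class = c("eics_solver_error", "error", "condition"),
        list(message = "NCG objective became non-finite",
             call = sys.call(-1),
             trace = do.call(rbind, trace_rows))))
    }
    g_new <- smoothed_gradient_cached(Fx, Wx, D1x, D2x, yv, op, p)
    g_new_norm2 <- sum(Mod(g_new)^2)
    beta_fr <- if (it %% p$restart_every == 0L) 0 else g_new_norm2 / g_norm2
    dx <- -g_new + beta_fr * dx
    g <- g_new
    g_norm2 <- g_new_norm2
  }
  list(
    image = x,
    trace = do.call(rbind, trace_rows),
    iterations = it,
    lambda1 = p$lambda1,
    lambda2 = p$lambda2
  )
}

# ramp DCF for an arbitrary sample set (e.g. a union of masks), with the
# effective spoke count estimated from the sample budget
dcf_for_kspace <- function(ks) {
  kr <- sqrt(ks$kx^2 + ks$ky^2)
  n_eff <- max(1L, round(length(ks$value) / ks$n_readout))
  ramp_dcf_radii(kr, ks$matrix_size, n_eff)
}

operator_for_kspace <- function(ks) {
  nufft_operator(cbind(ks$kx, ks$ky), matrix_size = ks$matrix_size,
                 dcf = dcf_for_kspace(ks))
}

#' Reconstruct every slice of an (interpolated) undersampled stack
#'
#' Runs [ncg_reconstruct()] per slice and assembles the magnitude images into
#' a [slice_stack()]. Slices sharing a sampling pattern (the mask triple
#' cycles with period 3) share one precomputed NUFFT operator.
#'
#' @param u An [undersample_stack()] result, interpolated or not.
#' @param p A [recon_params()].
#' @return A [slice_stack()] of magnitude images, in slice order, with the
#'   concatenated per-slice objective traces in attribute `"traces"`.
#' @export
reconstruct_stack <- function(u, p = recon_params()) {
  stopifnot(inherits(u, "undersampled_stack"))
  combos <- if (!is.null(u$mask_combo)) u$mask_combo else {
    paste0("m", u$triple_assignment)
  }
  op_cache <- new.env(parent = emptyenv())
  imgs <- vector("list", length(u$slices))
  traces <- vector("list", length(u$slices))
  for (i in seq_along(u$slices)) {
    ks <- u$slices[[i]]
    key <- combos[i]
    if (is.null(op_cache[[key]])) op_cache[[key]] <- operator_for_kspace(ks)
    res <- tryCatch(
      ncg_reconstruct(ks, op_cache[[key]], p),
      error = function(e) {
        stop_input("reconstruction failed at slice %d: %s", i, conditionMessage(e))
      })
    imgs[[i]] <- Mod(res$image)
    traces[[i]] <- cbind(slice = i, res$trace)
  }
  out <- slice_stack(imgs,
                     description = sprintf("NCG reconstruction (%s, ratio %.3f, gap %d)",
                                           u$method, u$ratio, u$gap))
  attr(out, "traces") <- do.call(rbind, traces)
  out
}
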