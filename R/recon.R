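# Image reconstruction: regularized Kaczmarz on the frequency-space system
# matrix, multi-contrast stacking, system-matrix over-gridding and iron
# quantification.

# system-matrix rows as a plain complex matrix M x N
.sm_matrix <- function(sm) {
  if (sm$mode == "single_patch") sm$S
  else matrix(sm$S, nrow = dim(sm$S)[1] * dim(sm$S)[2])  # (row, patch) x N
}

#' Extract the measurement vector matching a system matrix
#'
#' Transforms a measured frame in the system matrix' processing mode,
#' extracts the selected frequency rows and subtracts the calibration
#' background mean (and, if the measurement carries its own background
#' frames, their mean spectrum as well).
#'
#' @param sm a `system_matrix`.
#' @param frames a `measurement_frames` object.
#' @param frame which measurement frame.
#' @param subtract subtract background spectra.
#' @return Complex vector of length `M` (rows, multi-patch rows are
#'   patch-major flattened).
#' @export
measurement_rows <- function(sm, frames, frame = 1, subtract = TRUE) {
  sp <- spectrum(frames, mode = sm$mode)
  ridx <- 2L * sm$freq$bin + sm$freq$channel    # interleaved full-row index
  if (sm$mode == "single_patch") {
    u <- sp$u[ridx, frame]
    bg <- sm$bg_mean
  } else {
    u <- c(sp$u[ridx, , frame])
    bg <- rep(sm$bg_mean, times = dim(sp$u)[2])
  }
  if (subtract) {
    u <- u - bg
    if (length(frames$background) && dim(frames$background)[1] >= 1) {
      bsp <- spectrum(frames, mode = sm$mode, background = TRUE)
      bu <- if (sm$mode == "single_patch")
        rowMeans(bsp$u[ridx, , drop = FALSE])
      else c(apply(bsp$u[ridx, , , drop = FALSE], c(1, 2), mean))
      u <- u - bu
    }
  }
  u
}

#' Regularized Kaczmarz reconstruction
#'
#' Solves the regularized least-squares problem
#' `argmin_{c >= 0} ||S c - u||_2^2 + lambda_l2 ||c||_2^2 + lambda_l1 ||c||_1`
#' by row-iterative Kaczmarz sweeps with the augmented-variable Tikhonov
#' formulation; L1 shrinkage and the nonnegativity projection are applied
#' between sweeps. Regularization weights are relative to the mean row
#' energy: the absolute Tikhonov weight is `lambda_l2 * mean(||S_i||^2)`, and
#' the soft-threshold per sweep is `lambda_l1 * mean(|u|) / M`.
#'
#' @param sm a `system_matrix`, or a plain complex matrix `M x N`.
#' @param u complex measurement vector of length `M` (see
#'   [measurement_rows()]).
#' @param lambda_l2 relative L2 regularization weight (>= 0).
#' @param lambda_l1 relative L1 weight (>= 0, 0 disables shrinkage).
#' @param iterations number of sweeps over all rows.
#' @param nonneg project onto nonnegative (real) concentrations each sweep.
#' @param shuffle process rows in a seeded random order instead of
#'   sequentially.
#' @param seed seed for the row shuffle.
#' @return An object of class `recon_result` with `c` (concentration per
#'   voxel, nonnegative when `nonneg`), `c_complex` (the unprojected final
#'   iterate), `residual` (`||S c - u||_2`), `grid` and `params`.
#' @export
kaczmarz_solve <- function(sm, u, lambda_l2 = 0.01, lambda_l1 = 0,
                           iterations = 10, nonneg = TRUE,
                           shuffle = FALSE, seed = 1L) {
  S <- if (inherits(sm, "system_matrix")) .sm_matrix(sm) else sm
  grid <- if (inherits(sm, "system_matrix")) sm$grid else NULL
  if (lambda_l2 < 0 || lambda_l1 < 0) stop("negative regularization weight")
  if (iterations < 1) stop("'iterations' must be >= 1", call. = FALSE)
  if (length(u) != nrow(S))
    stop("measurement vector does not match the selected rows", call. = FALSE)
  if (nrow(S) == 0) stop("empty frequency selection", call. = FALSE)
  if (anyNA(S) || anyNA(u)) stop("NaN/NA in solver inputs", call. = FALSE)
  M <- nrow(S)
  energy <- rowSums(Mod(S)^2)
  lambda <- lambda_l2 * mean(energy)
  l1 <- if (lambda_l1 > 0) lambda_l1 * mean(Mod(u)) / M else 0
  ord <- seq_len(M) - 1L
  if (shuffle) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    ord <- sample(ord)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }
  res <- kaczmarz_core(t(S), as.complex(u), lambda, as.integer(iterations),
                       as.integer(ord), l1, nonneg)
  x <- as.vector(res$x)
  c_out <- if (nonneg || lambda_l1 > 0) pmax(Re(x), 0) else x
  structure(list(c = c_out, c_complex = x,
                 residual = sqrt(sum(Mod(S %*% x - u)^2)),
                 grid = grid,
                 params = list(lambda_l2 = lambda_l2, lambda_l1 = lambda_l1,
                               iterations = iterations, nonneg = nonneg,
                               shuffle = shuffle, seed = seed)),
            class = "recon_result")
}

#' Multi-contrast reconstruction with stacked system matrices
#'
#' Column-stacks one system matrix per tracer (identical grids and frequency
#' selections required), solves the joint system and splits the solution into
#' per-tracer concentration channels. Optionally normalizes each channel to
#' its own maximum.
#'
#' @param sm_list list of `system_matrix` objects, one per tracer.
#' @param u complex measurement vector.
#' @param ... solver arguments passed to [kaczmarz_solve()].
#' @param normalize divide each channel by its maximum.
#' @return A `recon_result` whose `c` is an `N x n_tracer` matrix; channel
#'   leakage can be quantified by comparing channel masses.
#' @export
multicontrast_solve <- function(sm_list, u, ..., normalize = FALSE) {
  stopifnot(length(sm_list) >= 2)
  g1 <- sm_list[[1]]$grid
  f1 <- sm_list[[1]]$freq
  for (sm in sm_list[-1]) {
    if (!identical(sm$grid$dims, g1$dims) ||
        max(abs(unlist(sm$grid[c("x", "y", "z")]) -
                unlist(g1[c("x", "y", "z")]))) > 1e-9)
      stop("system-matrix grids differ", call. = FALSE)
    if (!identical(sm$freq$bin, f1$bin) || !identical(sm$freq$channel, f1$channel))
      stop("frequency selections differ", call. = FALSE)
  }
  mats <- lapply(sm_list, .sm_matrix)
  # near-collinear stacking check (identical tracers make the joint system
  # hopelessly ill-posed)
  v1 <- c(mats[[1]]); v2 <- c(mats[[2]])
  cosang <- Mod(sum(Conj(v1) * v2)) / (sqrt(sum(Mod(v1)^2)) * sqrt(sum(Mod(v2)^2)))
  if (is.finite(cosang) && cosang > 0.999)
    warning("stacked system matrices are nearly collinear; ",
            "tracers may not be separable")
  S <- do.call(cbind, mats)
  res <- kaczmarz_solve(S, u, ...)
  N <- g1$n_voxels
  res$c <- matrix(res$c, N, length(sm_list))
  res$grid <- g1
  res
}

# trilinear interpolation of values on grid `g` (x fastest) at positions P
.trilinear <- function(vals, g, P) {
  ix <- function(ax, p) {
    if (length(ax) == 1) return(list(i0 = rep(1, length(p)), w = rep(0, length(p))))
    i0 <- findInterval(p, ax, rightmost.closed = TRUE)
    i0 <- pmin(pmax(i0, 1L), length(ax) - 1L)
    w <- (p - ax[i0]) / (ax[i0 + 1] - ax[i0])
    list(i0 = i0, w = pmin(pmax(w, 0), 1))
  }
  a <- ix(g$x, P[, 1]); b <- ix(g$y, P[, 2]); d <- ix(g$z, P[, 3])
  nx <- length(g$x); ny <- length(g$y); nz <- length(g$z)
  lin <- function(i, j, k) (pmin(k, nz) - 1L) * nx * ny + (pmin(j, ny) - 1L) * nx + pmin(i, nx)
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) a$w else 1 - a$w) * (if (dy) b$w else 1 - b$w) *
         (if (dz) d$w else 1 - d$w)
    out <- out + w * vals[lin(a$i0 + dx, b$i0 + dy, d$i0 + dz)]
  }
  out
}

#' Over-grid (interpolate) a system matrix
#'
#' Per-row trilinear interpolation of the calibration grid onto a finer
#' reconstruction grid spanning the same volume (real and imaginary parts
#' independently), e.g. from 15 x 15 x 11 to 25 x 25 x 19.
#'
#' @param sm a `system_matrix` (single-patch mode).
#' @param new_dims integer `c(nx, ny, nz)` of the target grid.
#' @return A `system_matrix` on the refined grid.
#' @export
interpolate_system_matrix <- function(sm, new_dims) {
  stopifnot(inherits(sm, "system_matrix"))
  if (sm$mode != "single_patch")
    stop("over-gridding is implemented for single-patch matrices", call. = FALSE)
  g <- sm$grid
  span <- function(ax) if (length(ax) > 1) range(ax) else c(ax, ax)
  ng <- list(x = seq(span(g$x)[1], span(g$x)[2], length.out = new_dims[1]),
             y = seq(span(g$y)[1], span(g$y)[2], length.out = new_dims[2]),
             z = seq(span(g$z)[1], span(g$z)[2], length.out = new_dims[3]),
             dims = as.integer(new_dims), n_voxels = as.integer(prod(new_dims)))
  P <- grid_positions(ng)
  S2 <- matrix(0i, nrow(sm$S), nrow(P))
  for (r in seq_len(nrow(sm$S))) {
    S2[r, ] <- .trilinear(Re(sm$S[r, ]), g, P) +
      1i * .trilinear(Im(sm$S[r, ]), g, P)
  }
  out <- sm
  out$S <- S2
  out$grid <- ng
  out
}

#' Quantify iron mass in a reconstruction
#'
#' Sums the reconstructed concentration over a voxel mask and multiplies by
#' the iron mass of the calibration delta sample (concentrations are in
#' delta-sample units, so the sum is directly a mass fraction).
#'
#' @param result a `recon_result` (or numeric concentration vector).
#' @param mask logical or integer voxel mask.
#' @param delta_mass_mg reference mass in mg.
#' @return Iron mass in mg.
#' @export
quantify_iron <- function(result, mask, delta_mass_mg = 1.7) {
  c_vec <- if (inherits(result, "recon_result")) result$c else result
  sum(c_vec[mask]) * delta_mass_mg
}

#' Box mask around a position
#'
#' @param grid a [recon_grid()].
#' @param position center (mm).
#' @param half_width half-width in voxels (default 2, a 5 x 5 x 5 box).
#' @return Logical mask of length `n_voxels`.
#' @export
box_mask <- function(grid, position, half_width = 2L) {
  near <- function(ax, p) {
    i <- which.min(abs(ax - p))
    abs(seq_along(ax) - i) <= half_width
  }
  m <- outer(outer(near(grid$x, position[1]), near(grid$y, position[2]), "&"),
             near(grid$z, position[3]), "&")
  as.vector(m)
}
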