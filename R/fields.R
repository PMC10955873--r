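# Magnetic field models: ideal linear selection-field gradient plus
# homogeneous drive fields, real solid-harmonic expansions fitted from sphere
# samples, current-to-gradient calibration and drive-field distortion (THD).
#
# Units: fields in mT, gradients in T/m, positions in mm. With these units
# H[mT] / G[T/m] is directly a length in mm, so no conversion factors appear.

#' Ideal scanner field model
#'
#' Linear selection-field gradient `H(r) = G (r - center)` superposed with
#' homogeneous drive fields. The default gradient `diag(-0.12, 0.24, -0.12)`
#' T/m is divergence-free (Maxwell coil pair: the y-gradient is twice as
#' strong and of opposite sign as the transverse ones).
#'
#' @param gradient 3x3 gradient matrix in T/m (diagonal for the ideal scanner).
#' @param center field-free-point position at zero drive field, mm.
#' @return An object of class `ideal_field_model`.
#' @export
ideal_field_model <- function(gradient = diag(c(-0.12, 0.24, -0.12)),
                              center = c(0, 0, 0)) {
  gradient <- as.matrix(gradient)
  stopifnot(all(dim(gradient) == c(3, 3)), length(center) == 3)
  if (abs(sum(diag(gradient))) > 1e-8 * max(abs(gradient)))
    warning("gradient is not trace-free (not divergence-free)")
  structure(list(gradient = gradient, center = as.numeric(center)),
            class = "ideal_field_model")
}

#' Selection field of an ideal model at given positions
#'
#' @param field an [ideal_field_model()].
#' @param r positions, a length-3 vector or n x 3 matrix (mm).
#' @return Field vectors in mT (same shape as `r`).
#' @export
selection_field <- function(field, r) {
  r <- rbind(r)
  t(field$gradient %*% (t(r) - field$center))
}

#' Field-free-point position under a homogeneous drive field
#'
#' Solves `G (r - center) + H_df = 0`, i.e. `r = center - G^{-1} H_df`.
#'
#' @param field an [ideal_field_model()].
#' @param H_df drive-field vector(s) in mT (length-3 vector or n x 3 matrix).
#' @return FFP position(s) in mm.
#' @export
ffp_position <- function(field, H_df) {
  G <- field$gradient
  if (abs(det(G)) < 1e-300) stop("singular gradient matrix", call. = FALSE)
  H <- rbind(H_df)
  out <- t(field$center - solve(G, t(H)))
  dimnames(out) <- NULL
  out
}

# ---- real solid harmonics -------------------------------------------------

# Regular real solid harmonics R_l^m(r) evaluated at cartesian points,
# ordered (l, m) with m = -l..l; (L+1)^2 columns. Degree-1 terms are exactly
# the coordinates (m = -1, 0, 1 <-> y, z, x), so linear gradients can be read
# off the degree-1 coefficients directly. Built from the associated Legendre
# recurrence on r^l P_l^m(cos theta) {cos, sin}(m phi) with Schmidt
# semi-normalization scaled such that R_1^m are the bare coordinates.
.solid_harmonics <- function(pos, L) {
  pos <- rbind(pos)
  n <- nrow(pos)
  x <- pos[, 1]; y <- pos[, 2]; z <- pos[, 3]
  r2 <- x^2 + y^2 + z^2
  ncol <- (L + 1L)^2
  B <- matrix(0, n, ncol)
  colnames(B) <- paste0("l", rep(0:L, times = 2 * (0:L) + 1),
                        "m", unlist(lapply(0:L, function(l) -l:l)))
  # complex-free recurrence on the "sectoral ladder":
  # C_m = Re[(x+iy)^m], S_m = Im[(x+iy)^m]
  Cm <- matrix(0, n, L + 1); Sm <- matrix(0, n, L + 1)
  Cm[, 1] <- 1
  if (L >= 1) for (m in 1:L) {
    Cm[, m + 1] <- x * Cm[, m] - y * Sm[, m]
    Sm[, m + 1] <- x * Sm[, m] + y * Cm[, m]
  }
  # P_lm holds the solid associated-Legendre part Q_l^m with
  # Q_m^m = (2m-1)!! , Q_{m+1}^m = (2m+1) z Q_m^m,
  # Q_l^m = ((2l-1) z Q_{l-1}^m - (l-1+m) r2 Q_{l-2}^m) / (l-m)
  idx <- function(l, m) l^2 + l + m + 1L
  for (m in 0:L) {
    qmm <- rep(1, n)
    if (m > 0) qmm <- prod(seq(1, 2 * m - 1, by = 2)) * rep(1, n)
    # normalization making R_1^{\pm1} = x, y and R_1^0 = z:
    # N_l^m = sqrt(2 (l-m)! / (l+m)!) for m>0, 1 for m=0 ... we instead use
    # the "racah" scaling N = (l-m)! ... keep it simple: scale each (l,m)
    # column by s_lm = sqrt((l-m)!/(l+m)!) * (2 - (m==0))^0 ... see below.
    ql <- list()
    ql[[1]] <- qmm                       # l = m
    if (m < L) ql[[2]] <- (2 * m + 1) * z * qmm  # l = m+1
    if (m + 2 <= L) for (l in (m + 2):L) {
      ql[[l - m + 1]] <- ((2 * l - 1) * z * ql[[l - m]] -
                            (l - 1 + m) * r2 * ql[[l - m - 1]]) / (l - m)
    }
    for (l in m:L) {
      s <- sqrt(factorial(l - m) / factorial(l + m)) * (if (m > 0) sqrt(2) else 1)
      # with this scaling: l=1, m=1: s = 1/sqrt(2)*sqrt(2) = 1, Q_1^1 = 1 -> x
      Q <- ql[[l - m + 1]]
      if (m == 0) {
        B[, idx(l, 0)] <- s * Q
      } else {
        B[, idx(l, m)] <- s * Q * Cm[, m + 1]
        B[, idx(l, -m)] <- s * Q * Sm[, m + 1]
      }
    }
  }
  B
}

#' Deterministic well-spread sphere sample positions
#'
#' Spherical Fibonacci point set: a deterministic, nearly uniform arrangement
#' of `n` points on a sphere of radius `radius`, suitable as a sampling design
#' for band-limited field fitting (any `n >= (L+1)^2` gives a well-conditioned
#' degree-`L` solid-harmonic design matrix).
#'
#' @param n number of points.
#' @param radius sphere radius in mm.
#' @param center sphere center, mm.
#' @return An `n` x 3 matrix of positions (mm).
#' @export
sphere_fibonacci <- function(n, radius = 45, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  cz <- 1 - 2 * i / n
  sz <- sqrt(pmax(0, 1 - cz^2))
  p <- radius * cbind(sz * cos(phi), sz * sin(phi), cz)
  sweep(p, 2, center, "+")
}

#' Fit a solid-harmonic field expansion from sphere samples
#'
#' Least-squares fit, per field component, of real regular solid harmonics up
#' to degree `L` against field vectors measured on (or near) a sphere. This
#' represents a source-free field from a small number of samples instead of a
#' Cartesian grid interpolation. Positions are scaled by the sphere radius
#' before building the design matrix so the fit stays well-conditioned at any
#' physical radius.
#'
#' @param positions n x 3 matrix of sample positions (mm).
#' @param values n x 3 matrix of field vectors (mT).
#' @param L maximum expansion degree (default 6).
#' @param center expansion center (mm).
#' @param max_cond maximum tolerated design-matrix condition number.
#' @return An object of class `shf_field`: coefficient matrix
#'   `(L+1)^2 x 3`, `L`, `radius`, `center` and per-component RMS `residual`.
#' @export
fit_spherical_harmonics <- function(positions, values, L = 6,
                                    center = c(0, 0, 0), max_cond = 1e8) {
  positions <- rbind(positions); values <- rbind(values)
  stopifnot(nrow(positions) == nrow(values), ncol(positions) == 3)
  ncoef <- (L + 1L)^2
  if (nrow(positions) < ncoef)
    stop("need at least (L+1)^2 = ", ncoef, " samples for degree ", L,
         call. = FALSE)
  rel <- sweep(positions, 2, center)
  radius <- sqrt(max(rowSums(rel^2)))
  B <- .solid_harmonics(rel / radius, L)
  cond <- kappa(B, exact = FALSE)
  if (!is.finite(cond) || cond > max_cond)
    stop(sprintf("rank-deficient sampling design (condition number %.3g)",
                 cond), call. = FALSE)
  qrB <- qr(B)
  coef <- qr.coef(qrB, values)
  resid <- sqrt(colMeans((B %*% coef - values)^2))
  structure(list(coefficients = coef, L = L, radius = radius,
                 center = as.numeric(center), residual = resid,
                 condition = cond),
            class = "shf_field")
}

#' Evaluate a fitted solid-harmonic field
#'
#' @param shf an `shf_field` from [fit_spherical_harmonics()].
#' @param r positions (length-3 vector or n x 3 matrix, mm).
#' @param warn_outside warn when evaluating beyond the fitted sphere radius.
#' @return Field vectors in mT.
#' @export
evaluate_field <- function(shf, r, warn_outside = TRUE) {
  r <- rbind(r)
  rel <- sweep(r, 2, shf$center)
  if (warn_outside && any(rowSums(rel^2) > (1 + 1e-9) * shf$radius^2))
    warning("evaluating the expansion outside the fitted sphere radius")
  B <- .solid_harmonics(rel / shf$radius, shf$L)
  unname(B %*% shf$coefficients)
}

#' Gradient matrix and field offset of a solid-harmonic field
#'
#' Reads the homogeneous part (degree 0) and the linear part (degree 1) off
#' the expansion coefficients; the degree-1 basis functions are the bare
#' coordinates, so the columns of the gradient are the (y, z, x) coefficients
#' rescaled by the fit radius.
#'
#' @param shf an `shf_field`.
#' @return A list with `offset` (mT at the center) and `gradient` (T/m).
#' @export
shf_linear_part <- function(shf) {
  co <- shf$coefficients
  offset <- unname(co[1, ])
  # rows 2:4 are the degree-1 terms (m = -1, 0, 1) = (y, z, x) / radius;
  # G[c, i] = d H_c / d r_i in mT/mm == T/m
  G <- t(co[c(4, 2, 3), , drop = FALSE]) / shf$radius
  dimnames(G) <- list(c("x", "y", "z"), c("x", "y", "z"))
  list(offset = offset, gradient = G)
}

#' Selection-field current calibration
#'
#' Fits, for each coil-current level, a solid-harmonic expansion of the
#' measured field, extracts the y-gradient strength and the FFP y-offset, and
#' interpolates both piecewise-linearly between current levels (monotone
#' interpolation emulating the saturation behaviour of a soft-iron yoke).
#'
#' @param currents numeric vector of DC current levels (A), at least 3.
#' @param samples a list (one element per current) of lists with `positions`
#'   (n x 3 mm) and `values` (n x 3 mT).
#' @param L expansion degree used per level.
#' @return An object of class `current_calibration`: per-level `gradient_y`
#'   (T/m) and `ffp_y` (mm) plus interpolating functions `gradient_fun(I)` and
#'   `ffp_fun(I)`.
#' @export
current_calibration <- function(currents, samples, L = 4) {
  if (length(currents) < 3) stop("need at least 3 current levels", call. = FALSE)
  stopifnot(length(samples) == length(currents))
  g <- numeric(length(currents)); fy <- numeric(length(currents))
  for (i in seq_along(currents)) {
    fit <- fit_spherical_harmonics(samples[[i]]$positions, samples[[i]]$values, L = L)
    lin <- shf_linear_part(fit)
    G <- lin$gradient
    g[i] <- G[2, 2]
    fy[i] <- if (abs(G[2, 2]) > 0) -lin$offset[2] / G[2, 2] else NA_real_
  }
  o <- order(currents)
  if (any(diff(abs(g[o])) < 0))
    warning("gradient strength is not monotone in current (saturation artifacts?)")
  structure(list(currents = currents[o], gradient_y = g[o], ffp_y = fy[o],
                 gradient_fun = stats::approxfun(currents[o], g[o], rule = 2),
                 ffp_fun = stats::approxfun(currents[o], fy[o], rule = 2)),
            class = "current_calibration")
}

#' Total harmonic distortion of a sampled tone
#'
#' `THD = sqrt(sum_{h >= 2} A_h^2) / A_1` from spectral amplitudes at integer
#' multiples of the fundamental. Amplitudes are estimated by complex
#' projection onto each harmonic over an integer number of fundamental
#' periods (truncating the record to the largest whole number of periods), so
#' a pure sampled sine yields a THD at numerical noise level.
#'
#' @param signal real time samples.
#' @param fs sampling rate (Hz).
#' @param f0 fundamental frequency (Hz).
#' @param n_harmonics number of harmonics (>= 2) included.
#' @return THD as a dimensionless fraction.
#' @export
thd <- function(signal, fs, f0, n_harmonics = 10) {
  n_per <- floor(length(signal) * f0 / fs)
  if (n_per < 3)
    stop("record too short: needs at least 3 periods of f0", call. = FALSE)
  n <- floor(n_per * fs / f0)
  s <- signal[seq_len(n)]
  t <- (seq_len(n) - 1) / fs
  amp <- vapply(seq_len(n_harmonics), function(h) {
    if (h * f0 >= fs / 2) return(0)
    Mod(2 * mean(s * exp(-2i * pi * h * f0 * t)))
  }, numeric(1))
  if (amp[1] <= 0) stop("no energy at the fundamental", call. = FALSE)
  sqrt(sum(amp[-1]^2)) / amp[1]
}
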