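# Frequency-space processing and regularized Kaczmarz reconstruction.

test_that("single- and multi-patch spectra agree on cycle-periodic signals", {
  s <- scanner_sequence(decimation = 1280, n_patches = 4)
  fi <- frame_info(s)
  ci <- cycle_info(s)
  set.seed(2)
  onecycle <- matrix(stats::rnorm(2 * ci$samples_per_cycle), 2)
  fr <- structure(list(
    data = array(0, c(1, 2, fi$K)),
    background = array(0, c(0, 2, fi$K)), seq = s, noise_sd = 0, seed = 1L),
    class = "measurement_frames")
  fr$data[1, , ] <- do.call(cbind, replicate(s$n_patches, onecycle,
                                             simplify = FALSE))
  sp <- spectrum(fr, "single_patch")
  mp <- spectrum(fr, "multi_patch")
  # multi-patch bins sit at single-patch indices k * M_y, identically per patch
  nbc <- floor(ci$samples_per_cycle / 2) + 1
  for (ch in 1:2) {
    k <- 0:(nbc - 1)
    sp_rows <- sp$u[2 * (k * s$n_patches) + ch, 1]
    mp_rows <- mp$u[2 * k + ch, , 1]
    expect_equal(mp_rows, matrix(rep(sp_rows, s$n_patches), ncol = s$n_patches),
                 tolerance = 1e-9)
  }
  # Parseval on the one-sided spectrum (K odd: every bin above DC pairs with
  # its conjugate)
  u1 <- sp$u[seq(1, by = 2, length.out = (fi$K - 1) / 2 + 1), 1]
  spec_energy <- (Mod(u1[1])^2 + 2 * sum(Mod(u1[-1])^2)) * fi$K
  expect_equal(spec_energy, sum(fr$data[1, 1, ]^2), tolerance = 1e-9)
  # non-divisible frame length is rejected
  fr_bad <- fr
  fr_bad$seq$n_patches <- 4L
  fr_bad$data <- fr$data[, , 1:(fi$K - 1), drop = FALSE]
  expect_error(spectrum(fr_bad, "multi_patch"), "match|divisible")
})

test_that("row SNR reflects planted amplitudes and background noise", {
  set.seed(4)
  n_rows <- 40; n_pos <- 12; n_bg <- 200
  sd_bg <- 0.2
  bg <- matrix(complex(real = stats::rnorm(n_rows * n_bg, sd = sd_bg / sqrt(2)),
                       imaginary = stats::rnorm(n_rows * n_bg, sd = sd_bg / sqrt(2))),
               n_rows, n_bg)
  amp <- seq(0.5, 20, length.out = n_rows)
  S <- matrix(0i, n_rows, n_pos)
  S[, 5] <- amp
  snr <- snr_rows(S, bg)
  expect_equal(snr, amp / sd_bg, tolerance = 0.2)
  expect_equal(snr_rows(10 * S, bg), 10 * snr, tolerance = 0.05)
  expect_warning(snr0 <- snr_rows(S, matrix(0i, n_rows, 2)), "zero background")
  expect_true(all(is.infinite(snr0)))
  expect_error(snr_rows(S, bg[, 1, drop = FALSE]), ">= 2")
})

test_that("frequency selection honors threshold and stopband", {
  snr <- c(1, 5, 50, 200, 3)
  expect_identical(select_frequencies(snr, 0), 1:5)
  expect_identical(select_frequencies(snr, Inf), integer(0))
  expect_identical(select_frequencies(snr, 5), c(2L, 3L, 4L))
  f <- c(1e3, 25e3, 50e3, 30e3, 100e3)
  expect_identical(select_frequencies(snr, 5, f = f, enforce_stopband = TRUE),
                   3L)
  expect_error(select_frequencies(snr, 5, enforce_stopband = TRUE), "'f'")
})

test_that("background subtraction removes offsets, nearest block beats global mean", {
  set.seed(6)
  n_rows <- 30
  drift <- function(idx) complex(real = 0.01 * idx, imaginary = -0.005 * idx)
  bg_idx <- c(1:3, 51:53, 101:103)
  bg <- vapply(bg_idx, function(i) rep(drift(i), n_rows), complex(n_rows))
  # background-only measurement is cancelled
  u_bg <- vapply(c(2, 52), function(i) rep(drift(i), n_rows), complex(n_rows))
  resid <- subtract_background(u_bg, bg, u_index = c(4, 54), bg_index = bg_idx)
  expect_lt(max(Mod(resid)), 1e-12)
  # signal plus constant offset is recovered
  sig <- complex(real = stats::rnorm(n_rows), imaginary = stats::rnorm(n_rows))
  u <- cbind(sig + rep(drift(102), n_rows))
  out <- subtract_background(u, bg, u_index = 105, bg_index = bg_idx)
  expect_equal(out[, 1], sig, tolerance = 1e-12)
  # nearest-block correction beats the global mean under drift
  out_nb <- subtract_background(u, bg, u_index = 105, bg_index = bg_idx)
  out_gl <- subtract_background(u, bg)
  expect_lt(sum(Mod(out_nb - sig)^2), sum(Mod(out_gl - sig)^2))
})

test_that("Kaczmarz solves trivial and regularized systems", {
  S <- diag(3) + 0i
  u <- c(1 + 0i, 0i, 0i)
  rec <- kaczmarz_solve(S, u, lambda_l2 = 1e-12, iterations = 50)
  expect_equal(rec$c, c(1, 0, 0), tolerance = 1e-8)
  expect_lt(rec$residual, 1e-8)

  # oracle equivalence: unconstrained solution matches the regularized
  # normal equations
  set.seed(8)
  M <- 60; N <- 40
  S <- matrix(complex(real = stats::rnorm(M * N),
                      imaginary = stats::rnorm(M * N)), M, N)
  u <- complex(real = stats::rnorm(M), imaginary = stats::rnorm(M))
  lam_rel <- 0.05
  rec <- kaczmarz_solve(S, u, lambda_l2 = lam_rel, iterations = 1000,
                        nonneg = FALSE)
  lam <- lam_rel * mean(rowSums(Mod(S)^2))
  oracle <- solve(Conj(t(S)) %*% S + lam * diag(N), Conj(t(S)) %*% u)
  expect_lt(sqrt(sum(Mod(rec$c_complex - oracle[, 1])^2) /
                   sum(Mod(oracle)^2)), 1e-6)

  # the regularized objective is non-increasing over sweeps (lambda_l1 = 0)
  obj <- vapply(c(1, 2, 5, 10, 20, 50), function(it) {
    r <- kaczmarz_solve(S, u, lambda_l2 = lam_rel, iterations = it,
                        nonneg = FALSE)
    sum(Mod(S %*% r$c_complex - u)^2) + lam * sum(Mod(r$c_complex)^2)
  }, numeric(1))
  expect_true(all(diff(obj) <= 1e-8 * obj[1]))

  # nonnegativity projection
  rec_nn <- kaczmarz_solve(S, u, lambda_l2 = lam_rel, iterations = 50,
                           nonneg = TRUE)
  expect_true(all(rec_nn$c >= 0))
  # determinism, including the seeded row shuffle
  r1 <- kaczmarz_solve(S, u, iterations = 20, shuffle = TRUE, seed = 9)
  r2 <- kaczmarz_solve(S, u, iterations = 20, shuffle = TRUE, seed = 9)
  expect_identical(r1$c, r2$c)
  # error paths
  expect_error(kaczmarz_solve(S[0, , drop = FALSE], u[0]), "empty")
  u_bad <- u; u_bad[1] <- NA
  expect_error(kaczmarz_solve(S, u_bad), "NaN|NA")
  expect_error(kaczmarz_solve(S, u[-1]), "does not match")
})

test_that("L1 shrinkage sparsifies small coefficients", {
  set.seed(12)
  M <- 80; N <- 50
  S <- matrix(complex(real = stats::rnorm(M * N),
                      imaginary = stats::rnorm(M * N)), M, N)
  c_true <- numeric(N); c_true[c(7, 23)] <- c(2, 1)
  u <- (S %*% c_true)[, 1] + 0.05 * complex(real = stats::rnorm(M),
                                            imaginary = stats::rnorm(M))
  rec0 <- kaczmarz_solve(S, u, lambda_l2 = 1e-3, lambda_l1 = 0, iterations = 50)
  rec1 <- kaczmarz_solve(S, u, lambda_l2 = 1e-3, lambda_l1 = 5, iterations = 50)
  expect_lt(sum(rec1$c > 1e-6), sum(rec0$c > 1e-6))
  expect_gt(rec1$c[7], 0.5 * rec0$c[7])
})

test_that("two tracers separate into their own channels", {
  s <- scanner_sequence(decimation = 1280, n_patches = 5)
  g <- recon_grid(c(7, 1, 1), fov = c(120, 0, 0))
  p_a <- particle_model("resotran-like")
  p_b <- particle_model("synomag-like", core_diameter = 25)
  sm_a <- simulate_system_matrix(s, grid = g, particles = p_a, max_rows = 120)
  sm_b <- simulate_system_matrix(s, grid = g, particles = p_b, max_rows = 120)
  # restrict to the common selected rows
  common <- intersect(paste(sm_a$freq$channel, sm_a$freq$bin),
                      paste(sm_b$freq$channel, sm_b$freq$bin))
  ka <- match(common, paste(sm_a$freq$channel, sm_a$freq$bin))
  kb <- match(common, paste(sm_b$freq$channel, sm_b$freq$bin))
  for (nm in c("S", "bg_mean", "bg_sd", "snr", "amp")) {
    sm_a[[nm]] <- if (nm == "S") sm_a$S[ka, , drop = FALSE] else sm_a[[nm]][ka]
    sm_b[[nm]] <- if (nm == "S") sm_b$S[kb, , drop = FALSE] else sm_b[[nm]][kb]
  }
  sm_a$freq <- sm_a$freq[ka, ]; row.names(sm_a$freq) <- NULL
  sm_b$freq <- sm_b$freq[kb, ]; row.names(sm_b$freq) <- NULL

  # tracer A at -40 mm, tracer B at +40 mm (grid positions 2 and 6)
  ph <- phantom(rbind(c(-40, 0, 0), c(40, 0, 0)),
                tracer = c("resotran-like", "synomag-like"))
  mf <- simulate_frame(ph, s, particles = list("resotran-like" = p_a,
                                               "synomag-like" = p_b),
                       warn_fov = FALSE)
  u <- measurement_rows(sm_a, mf)
  rec <- multicontrast_solve(list(sm_a, sm_b), u, lambda_l2 = 1e-6,
                             iterations = 200)
  cc <- rec$c
  # each dot lands in its own channel at the right place
  expect_equal(which.max(cc[, 1]), 2L)
  expect_equal(which.max(cc[, 2]), 6L)
  # channel leakage well below the qualitative bound
  leak_a <- sum(cc[5:7, 1]) / sum(cc[1:3, 1])
  leak_b <- sum(cc[1:3, 2]) / sum(cc[5:7, 2])
  expect_lt(leak_a, 0.2)
  expect_lt(leak_b, 0.2)

  # single-tracer input leaves the other channel nearly empty
  ph_a <- phantom(c(-40, 0, 0), tracer = "resotran-like")
  mf_a <- simulate_frame(ph_a, s, particles = p_a, warn_fov = FALSE)
  rec_a <- multicontrast_solve(list(sm_a, sm_b), measurement_rows(sm_a, mf_a),
                               lambda_l2 = 1e-6, iterations = 200)
  expect_lt(sum(rec_a$c[, 2]) / sum(rec_a$c[, 1]), 0.2)

  # identical tracers are flagged as near-collinear
  expect_warning(multicontrast_solve(list(sm_a, sm_a), u, iterations = 2),
                 "collinear")
  # mismatched grids are rejected
  sm_c <- sm_b
  sm_c$grid <- recon_grid(c(7, 1, 1), fov = c(100, 0, 0))
  expect_error(multicontrast_solve(list(sm_a, sm_c), u), "grids")
})

test_that("system-matrix over-gridding is exact for affine rows", {
  sm <- desk_sm()
  g <- sm$grid
  # identity refinement changes nothing
  sm_id <- interpolate_system_matrix(sm, g$dims)
  expect_equal(sm_id$S, sm$S, tolerance = 1e-12)
  # rows affine in position are reproduced exactly on a finer grid
  P <- grid_positions(g)
  sm_lin <- sm
  sm_lin$S <- rbind((1 + 2 * P[, 1] - P[, 2] + 0.5 * P[, 3]) + 0i,
                    (3 - P[, 1]) + 1i * (P[, 2] + P[, 3]))
  sm_lin$freq <- sm$freq[1:2, ]
  for (nm in c("bg_mean", "bg_sd", "snr", "amp"))
    sm_lin[[nm]] <- sm[[nm]][1:2]
  fine <- interpolate_system_matrix(sm_lin, c(17, 17, 9))
  Pf <- grid_positions(fine$grid)
  expect_equal(fine$S[1, ], (1 + 2 * Pf[, 1] - Pf[, 2] + 0.5 * Pf[, 3]) + 0i,
               tolerance = 1e-10)
  expect_equal(fine$S[2, ], (3 - Pf[, 1]) + 1i * (Pf[, 2] + Pf[, 3]),
               tolerance = 1e-10)
  # smooth rows: refining the target grid reduces the interpolation error
  f_band <- function(P) cos(P[, 1] / 25) * sin(P[, 2] / 30) + cos(P[, 3] / 40)
  sm_s <- sm_lin
  sm_s$S <- rbind(f_band(P) + 0i)
  sm_s$freq <- sm$freq[1, , drop = FALSE]
  err_at <- function(dims) {
    fi <- interpolate_system_matrix(sm_s, dims)
    max(Mod(fi$S[1, ] - f_band(grid_positions(fi$grid))))
  }
  expect_lt(err_at(c(33, 33, 17)), err_at(c(17, 17, 9)) + 1e-12)
})

test_that("iron quantification sums masked concentration times delta mass", {
  g <- recon_grid(c(3, 3, 3), fov = c(20, 20, 20))
  cc <- numeric(27); cc[14] <- 1
  expect_equal(quantify_iron(cc, cc > 0, 1.7), 1.7)
  expect_equal(quantify_iron(cc, rep(FALSE, 27), 1.7), 0)
  m <- box_mask(g, c(0, 0, 0), 1)
  expect_equal(sum(m), 27)
  m0 <- box_mask(g, c(-10, -10, -10), 0)
  expect_equal(which(m0), 1L)
})
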