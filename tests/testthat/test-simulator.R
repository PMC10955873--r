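# Langevin particle model, phantom generators and the signal-level
# simulator, including the independent dense-quadrature oracle for the
# mixing-frequency structure.

test_that("the Langevin function has the right limits and values", {
  expect_identical(langevin(0), 0)
  # high-precision value of coth(1) - 1
  expect_equal(langevin(1), 0.3130352854993312, tolerance = 1e-12)
  expect_gt(langevin(1e6), 1 - 1e-5)
  expect_equal(langevin(-2), -langevin(2))
  # series and direct branches agree at the switchover (slope 1/3 there)
  expect_equal(langevin(0.99999e-4), langevin(1.00001e-4), tolerance = 1e-4)
})

test_that("magnetization is linear in concentration and saturates", {
  p <- particle_model()
  expect_equal(magnetization(c(0, 0, 0), p), matrix(0, 1, 3))
  H <- c(3, -2, 1)
  expect_equal(magnetization(-H, p), -magnetization(H, p))
  expect_equal(magnetization(H, p, 4), 4 * magnetization(H, p, 1))
  # |M| -> concentration (saturation response 1 per unit mass) as |H| grows
  Mbig <- magnetization(c(1e5, 0, 0), p, 2.5)
  expect_equal(sqrt(sum(Mbig^2)), 2.5, tolerance = 1e-3)
  expect_error(magnetization(H, p, -1), "negative")
  # distinct cores give distinct field scalings
  p2 <- particle_model("synomag-like", core_diameter = 25)
  expect_gt(p2$beta, p$beta)
})

test_that("an empty phantom gives silent frames and noise is reproducible", {
  s <- desk_seq()
  empty <- phantom(matrix(numeric(0), 0, 3))
  mf <- simulate_frame(empty, s)
  expect_true(all(mf$data == 0))

  n <- add_noise(mf, sd = 0.5, seed = 99)
  n2 <- add_noise(mf, sd = 0.5, seed = 99)
  expect_identical(n$data, n2$data)
  expect_equal(stats::sd(n$data), 0.5, tolerance = 0.02)
  expect_identical(add_noise(mf, sd = 0), mf)
})

test_that("the forward model is linear in tracer mass", {
  s <- desk_seq()
  ph1 <- make_delta_sample(c(10, 5, -10))
  ph2 <- make_delta_sample(c(10, 5, -10), conc_mg_ml = 17)
  m1 <- simulate_frame(ph1, s)$data
  m2 <- simulate_frame(ph2, s)$data
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  # superposition of two phantoms
  pha <- make_delta_sample(c(-20, 0, 0))
  phb <- make_delta_sample(c(25, 10, 10))
  phab <- phantom(rbind(c(-20, 0, 0), c(25, 10, 10)))
  expect_equal(simulate_frame(phab, s)$data,
               simulate_frame(pha, s)$data + simulate_frame(phb, s)$data,
               tolerance = 1e-9)
})

test_that("a centered delta sample emits only at mixing frequencies", {
  # one static Lissajous cycle (no sweep): every signal tone sits at a
  # mixing combination k = m_x * 75 + m_z * 76 of the per-cycle bins,
  # folded at the sampling Nyquist
  s <- scanner_sequence(decimation = 256, n_patches = 1, sweep_amplitude = 0)
  fi <- frame_info(s)
  K <- fi$K
  ph <- make_delta_sample(c(0, 0, 0))
  mf <- simulate_frame(ph, s, oversample = 4)
  u <- spectrum(mf)$u[, 1]
  amp2 <- Mod(u)^2
  bins <- (seq_along(u) - 1) %/% 2
  ci <- cycle_info(s)
  m <- expand.grid(m_x = 0:40, m_z = 0:40)
  kmix <- m$m_x * ci$periods_x + m$m_z * ci$periods_z
  fold <- function(k, n) {                      # alias a bin index into [0, n/2]
    k <- k %% n
    pmin(k, n - k)
  }
  mixbins <- unique(fold(kmix, K))
  on_mix <- bins %in% mixbins
  expect_gt(sum(amp2[on_mix]) / sum(amp2), 1 - 1e-9)
  # without the sweep the y channel sees no field component and stays silent
  expect_equal(max(Mod(u[seq(2, length(u), by = 2)])), 0)

  # independent oracle: re-derive the x channel by direct quadrature at 16x
  os <- 16L
  p <- particle_model()
  fm <- ideal_field_model()
  fr <- drive_frequencies(s)
  n_os <- K * os
  dt <- 1 / (fi$f_sample * os)
  t <- (0:(n_os - 1)) * dt
  H <- cbind(5 * sin(2 * pi * fr[["f_x"]] * t), 0,
             4 * sin(2 * pi * fr[["f_z"]] * t))
  Hn <- sqrt(rowSums(H^2))
  mx <- 1700 * langevin(p$beta_mT * Hn) / Hn * H[, 1]
  ux <- -(mx[c(2:n_os, 1)] - mx[c(n_os, 1:(n_os - 1))]) / (2 * dt)
  ux <- ux[seq(1, n_os, by = os)]
  ora <- stats::fft(ux)[seq_len(floor(K / 2) + 1)] / K
  sim_x <- u[seq(1, length(u), by = 2)]
  top <- order(Mod(ora), decreasing = TRUE)[1:25]
  expect_lt(max(Mod(sim_x[top] - ora[top])) / max(Mod(ora)), 0.01)
})

test_that("system-matrix calibration is deterministic and shift-invariant", {
  s <- scanner_sequence(decimation = 1280, n_patches = 3)
  g <- recon_grid(c(3, 3, 1), fov = c(60, 40, 0))
  sm1 <- simulate_system_matrix(s, grid = g, max_rows = 50, noise_sd = 0.1,
                                seed = 5, n_bg_per_plane = 4)
  sm2 <- simulate_system_matrix(s, grid = g, max_rows = 50, noise_sd = 0.1,
                                seed = 5, n_bg_per_plane = 4)
  expect_identical(sm1$S, sm2$S)
  expect_identical(sm1$bg_sd, sm2$bg_sd)
  expect_equal(sm1$delta_mass_mg, 1.7)
  expect_equal(sm1$n_background, 4)
  # background frames carry no particle signal: with zero noise the
  # background statistics vanish while signal rows do not
  sm0 <- simulate_system_matrix(s, grid = g, max_rows = 50, seed = 5,
                                n_bg_per_plane = 4)
  expect_true(all(sm0$bg_sd == 0))
  expect_gt(min(sm0$amp), 0)
})

test_that("the dilution series doubles masses at constant volume", {
  dil <- make_dilution_series()
  expect_length(dil, 8)
  masses <- vapply(dil, function(pp) pp[[1]]$mass_ug[1], numeric(1))
  expect_equal(masses, 4 * 2^(0:7))
  expect_equal(masses[-1] / masses[-8], rep(2, 7))
  expect_true(all(vapply(dil, function(pp)
    all(vapply(pp, function(x) x$volume_uL[1], numeric(1)) == 50), logical(1))))
  expect_length(dil[[1]], 3)
})

test_that("two-dot phantoms step along the requested axis", {
  edge <- (200 * 1e3)^(1 / 3)
  ph0 <- make_two_dot("x", 0)
  expect_equal(ph0$x[2] - ph0$x[1], edge)   # touching cubes
  for (ax in c("x", "y", "z")) {
    ph <- make_two_dot(ax, 7.5)
    delta <- c(ph$x[2] - ph$x[1], ph$y[2] - ph$y[1], ph$z[2] - ph$z[1])
    expect_equal(delta[[c(x = 1, y = 2, z = 3)[[ax]]]], 7.5 + edge)
    expect_equal(sum(delta != 0), 1)
  }
  expect_error(make_two_dot("x", -1), ">= 0")
})

test_that("the perfusion phantom obeys flow physics", {
  ph0 <- make_perfusion_phantom(stenosis_left = 0, delay_spread_s = 0)
  L <- ph0$hemisphere == "left"
  # symmetric flows give identical hemisphere curves
  expect_equal(ph0$curves[, L], ph0$curves[, !L], tolerance = 1e-12)
  # complete occlusion silences the left hemisphere (no error)
  ph1 <- make_perfusion_phantom(stenosis_left = 1)
  expect_true(all(ph1$curves[, ph1$hemisphere == "left"] == 0))
  expect_gt(max(ph1$curves[, ph1$hemisphere == "right"]), 0)
  expect_error(make_perfusion_phantom(stenosis_left = 1.2), "0, 1")
  # central volume theorem: the time integral of concentration is flow
  # independent (fast kernel so truncation is negligible)
  ph_a <- make_perfusion_phantom(stenosis_left = 0.5, v_eff_ml = 1,
                                 n_frames = 400, delay_spread_s = 0)
  iL <- sum(ph_a$curves[, ph_a$hemisphere == "left"][, 1])
  iR <- sum(ph_a$curves[, ph_a$hemisphere == "right"][, 1])
  expect_equal(iL / iR, 1, tolerance = 0.01)
  # identical seeds give bit-identical phantoms
  expect_identical(make_perfusion_phantom(0.25, seed = 3)$curves,
                   make_perfusion_phantom(0.25, seed = 3)$curves)
})
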