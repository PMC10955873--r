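# Signal-level simulator: induced-voltage frames for point-sample phantoms
# under the ideal field model, and emulation of the robot-based system-matrix
# calibration with interleaved background frames.
#
# The receive model is a homogeneous scalar sensitivity per channel picking
# the x- and y-components of dM/dt; signals are in arbitrary units (the
# physical receive-chain gain is not modelled). The magnetization is sampled
# on an internally oversampled time grid, differentiated by central
# differences and decimated to the sequence sampling rate.

#' Reconstruction / calibration grid
#'
#' Regular voxel grid centered on `center`, with positions spanning the given
#' field of view edge-to-edge (`n` positions span `fov`, spacing
#' `fov / (n - 1)`).
#'
#' @param n integer vector `c(nx, ny, nz)`.
#' @param fov extents in mm (defaults to the 140 x 110 x 100 calibration
#'   volume).
#' @param center grid center (mm).
#' @return A list with axes `x`, `y`, `z` (mm), `dims` and `n_voxels`.
#' @export
recon_grid <- function(n = c(15, 15, 11), fov = c(140, 110, 100),
                       center = c(0, 0, 0)) {
  ax <- lapply(1:3, function(i) {
    if (n[i] == 1) center[i]
    else seq(-fov[i] / 2, fov[i] / 2, length.out = n[i]) + center[i]
  })
  list(x = ax[[1]], y = ax[[2]], z = ax[[3]],
       dims = as.integer(n), n_voxels = as.integer(prod(n)))
}

#' Voxel center positions of a grid
#'
#' Positions ordered x-fastest, z-slowest (column-major 3D array order).
#'
#' @param grid a [recon_grid()].
#' @return An `n_voxels` x 3 matrix (mm).
#' @export
grid_positions <- function(grid) {
  g <- expand.grid(x = grid$x, y = grid$y, z = grid$z, KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

.resolve_particles <- function(phantom, particles) {
  if (inherits(particles, "particle_model"))
    particles <- stats::setNames(list(particles), unique(phantom$tracer)[1])
  labels <- unique(phantom$tracer)
  missing <- setdiff(labels, names(particles))
  if (length(missing))
    stop("no particle model for tracer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  particles
}

#' Simulate measurement frames for a phantom
#'
#' Forward-simulates the induced voltages of the x- and y-receive channels
#' for one or more identical frames: for every sample the total field (static
#' gradient offset + drive waveforms + sweep field) is evaluated on a
#' `oversample`-times finer time grid, the Langevin magnetization is
#' differentiated by central differences, decimated, summed over samples and
#' scaled by the channel sensitivities. Optional white Gaussian noise is
#' added reproducibly; matching background (empty-bore) frames carry the same
#' noise model.
#'
#' @param phantom a [phantom()].
#' @param seq a [scanner_sequence()].
#' @param field an [ideal_field_model()].
#' @param particles a [particle_model()] or named list of models keyed by
#'   tracer label.
#' @param receive channel sensitivities `c(x, y)` (arbitrary units).
#' @param noise_sd noise standard deviation (same arbitrary units).
#' @param seed integer seed for the noise stream.
#' @param oversample internal oversampling factor for the derivative.
#' @param n_frames number of measurement frames.
#' @param n_background number of background frames.
#' @param mass_scale optional `n_frames` x `n_samples` matrix of per-frame
#'   mass scaling factors (slow dynamics such as a bolus passage).
#' @param warn_fov warn when a sample lies outside the drive-field FOV.
#' @return An object of class `measurement_frames`: `data` and `background`
#'   arrays of dim `(frames, 2, K)`, plus sequence and acquisition metadata.
#' @export
simulate_frame <- function(phantom, seq, field = ideal_field_model(),
                           particles = particle_model(),
                           receive = c(1, 1), noise_sd = 0, seed = 1L,
                           oversample = 4L, n_frames = 1L,
                           n_background = 0L, mass_scale = NULL,
                           warn_fov = TRUE) {
  fi <- frame_info(seq)
  K <- fi$K
  n_os <- K * oversample
  dt <- 1 / (fi$f_sample * oversample)
  t <- (0:(n_os - 1)) * dt
  particles <- .resolve_particles(phantom, particles)

  G <- field$gradient
  df <- drive_waveforms(seq, t)
  hx_d <- df[, 1]; hz_d <- df[, 2]
  hy_sw <- -G[2, 2] * selection_sweep(seq, t)

  if (warn_fov && nrow(phantom) > 0) {
    ax <- seq$amplitude_x / abs(G[1, 1])
    az <- seq$amplitude_z / abs(G[3, 3])
    ay <- seq$sweep_amplitude
    out <- abs(phantom$x - field$center[1]) > ax |
      abs(phantom$y - field$center[2]) > ay + ax |
      abs(phantom$z - field$center[3]) > az
    if (any(out)) warning(sum(out), " phantom sample(s) outside the sampled FOV")
  }

  clean <- matrix(0, 2, K)
  per_sample <- vector("list", nrow(phantom))
  for (s in seq_len(nrow(phantom))) {
    p <- particles[[phantom$tracer[s]]]
    r <- c(phantom$x[s], phantom$y[s], phantom$z[s])
    h0 <- as.numeric(G %*% (r - field$center))  # mT (mm * T/m)
    Hx <- h0[1] + hx_d
    Hy <- h0[2] + hy_sw
    Hz <- h0[3] + hz_d
    Hn <- sqrt(Hx^2 + Hy^2 + Hz^2)
    Ln <- ifelse(Hn > 0, langevin(p$beta_mT * Hn) / Hn, 0)
    mass <- phantom$mass_ug[s]
    mx <- mass * Ln * Hx
    my <- mass * Ln * Hy
    # periodic central difference, then decimate to the sequence rate
    ddt <- function(m) (m[c(2:n_os, 1)] - m[c(n_os, 1:(n_os - 1))]) / (2 * dt)
    ux <- -receive[1] * ddt(mx)[seq(1, n_os, by = oversample)]
    uy <- -receive[2] * ddt(my)[seq(1, n_os, by = oversample)]
    per_sample[[s]] <- rbind(ux, uy)
    clean <- clean + per_sample[[s]]
  }

  data <- array(0, c(n_frames, 2, K))
  for (j in seq_len(n_frames)) {
    fr <- clean
    if (!is.null(mass_scale)) {
      fr <- matrix(0, 2, K)
      for (s in seq_len(nrow(phantom)))
        fr <- fr + mass_scale[j, s] * per_sample[[s]]
    }
    data[j, , ] <- fr
  }
  background <- array(0, c(max(n_background, 0L), 2, K))
  out <- structure(list(data = data, background = background, seq = seq,
                        noise_sd = noise_sd, seed = as.integer(seed),
                        oversample = as.integer(oversample)),
                   class = "measurement_frames")
  if (noise_sd > 0) out <- add_noise(out, noise_sd, seed) else out
}

#' Add reproducible white Gaussian noise to measurement frames
#'
#' @param frames a `measurement_frames` object.
#' @param sd noise standard deviation; 0 returns the input unchanged.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return The frames with noise added to data and background alike.
#' @export
add_noise <- function(frames, sd, seed = frames$seed) {
  stopifnot(inherits(frames, "measurement_frames"))
  if (sd == 0) return(frames)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  frames$data <- frames$data + stats::rnorm(length(frames$data), sd = sd)
  if (length(frames$background))
    frames$background <- frames$background +
      stats::rnorm(length(frames$background), sd = sd)
  frames$noise_sd <- sd
  frames
}

# one-sided spectrum of a single frame: 2 x n_bins complex
.frame_spectrum_sp <- function(fr) {
  K <- ncol(fr)
  nb <- floor(K / 2) + 1L
  rbind(stats::fft(fr[1, ])[1:nb], stats::fft(fr[2, ])[1:nb]) / K
}

#' Emulate a robot-based system-matrix calibration
#'
#' Moves a delta sample over every voxel of `grid`, simulates one frame per
#' position, Fourier-transforms it and assembles the frequency-space system
#' matrix. After each xy-plane, `n_bg_per_plane` empty (background) frames
#' are recorded; their per-bin mean and standard deviation provide the
#' background statistics for SNR analysis and subtraction.
#'
#' Rows are selected by SNR threshold when noise is present, or by relative
#' row energy (`energy_floor` times the strongest row) for noise-free
#' simulations, and capped at `max_rows` rows ordered by SNR/energy.
#'
#' @param seq,field,particles,receive,noise_sd,seed,oversample as in
#'   [simulate_frame()].
#' @param grid a [recon_grid()]; the default desk-scale grid is 9 x 9 x 5
#'   over 140 x 110 x 100 mm^3.
#' @param delta_volume_uL,delta_conc delta-sample volume (uL) and
#'   concentration (mg Fe/mL); the product (1.7 mg by default) becomes the
#'   quantification reference mass.
#' @param tracer tracer label of the calibration sample.
#' @param n_bg_per_plane background frames after each xy-plane.
#' @param mode `"single_patch"` (whole-frame transform, fine frequency grid)
#'   or `"multi_patch"` (per-cycle transform, patch-resolved rows).
#' @param snr_threshold minimum row SNR kept.
#' @param max_rows cap on retained rows (bin/channel pairs in multi-patch
#'   mode, each carrying all patches).
#' @param energy_floor relative row-amplitude floor used when no noise is
#'   present.
#' @param enforce_stopband drop rows inside the receive-filter stopband
#'   (which contains the overwhelming drive-field feedthrough) and the DC bin.
#' @param stopband stopband limits in Hz.
#' @return An object of class `system_matrix`; see [kaczmarz_solve()].
#' @export
simulate_system_matrix <- function(seq, field = ideal_field_model(),
                                   particles = particle_model(),
                                   grid = recon_grid(c(9, 9, 5)),
                                   delta_volume_uL = 200, delta_conc = 8.5,
                                   tracer = NULL,
                                   receive = c(1, 1), noise_sd = 0,
                                   seed = 1L, oversample = 4L,
                                   n_bg_per_plane = 12L,
                                   mode = c("single_patch", "multi_patch"),
                                   snr_threshold = 5, max_rows = 2000L,
                                   energy_floor = 1e-6,
                                   enforce_stopband = TRUE,
                                   stopband = c(20e3, 33e3)) {
  mode <- match.arg(mode)
  if (is.null(tracer))
    tracer <- if (inherits(particles, "particle_model")) particles$name
              else names(particles)[1]
  fi <- frame_info(seq)
  ci <- cycle_info(seq)
  pos <- grid_positions(grid)
  N <- nrow(pos)
  K <- fi$K
  nb <- floor(K / 2) + 1L

  # frequency-space accumulation, positions in columns
  if (mode == "single_patch") {
    spec <- matrix(0i, 2L * nb, N)
  } else {
    spc <- ci$samples_per_cycle
    nbc <- floor(spc / 2) + 1L
    My <- seq$n_patches
    spec <- array(0i, c(2L * nbc, My, N))
  }

  n_planes <- grid$dims[3]
  per_plane <- grid$dims[1] * grid$dims[2]
  bg_list <- list()
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  to_rows <- function(fr) {
    if (mode == "single_patch") {
      c(.frame_spectrum_sp(fr))                 # interleaved: row = 2*bin + ch
    } else {
      spc <- ci$samples_per_cycle
      My <- seq$n_patches
      out <- array(0i, c(2L * nbc, My))
      for (ch in 1:2) {
        cyc <- matrix(fr[ch, ], spc, My)        # one cycle per column
        S <- stats::mvfft(cyc)[1:nbc, , drop = FALSE] / spc
        out[seq(ch, by = 2, length.out = nbc), ] <- S
      }
      out
    }
  }

  for (v in seq_len(N)) {
    ph <- phantom(pos[v, ], delta_volume_uL, delta_conc, tracer)
    mf <- simulate_frame(ph, seq, field, particles, receive,
                         noise_sd = noise_sd,
                         seed = sample.int(.Machine$integer.max, 1),
                         oversample = oversample, warn_fov = FALSE)
    fr <- matrix(mf$data[1, , ], 2, K)
    if (mode == "single_patch") spec[, v] <- to_rows(fr)
    else spec[, , v] <- to_rows(fr)
    if (v %% per_plane == 0 && n_bg_per_plane > 0) {
      for (b in seq_len(n_bg_per_plane)) {
        bg <- matrix(stats::rnorm(2L * K, sd = noise_sd), 2, K)
        bg_list[[length(bg_list) + 1L]] <-
          if (mode == "single_patch") to_rows(bg) else to_rows(bg)
      }
    }
  }

  # background statistics per row (multi-patch: patches pooled as samples)
  n_rows_full <- if (mode == "single_patch") 2L * nb else 2L * nbc
  if (length(bg_list)) {
    allbg <- do.call(cbind, lapply(bg_list, function(b) matrix(b, n_rows_full)))
    bg_mean <- rowMeans(allbg)
    bg_sd <- sqrt(rowMeans(Mod(allbg - bg_mean)^2))
  } else {
    bg_mean <- complex(n_rows_full)
    bg_sd <- numeric(n_rows_full)
  }

  # row amplitude: max over positions (and patches in multi-patch mode)
  amp <- apply(Mod(spec), 1, max)
  snr <- ifelse(bg_sd > 0, amp / bg_sd, Inf)
  row_f <- ((seq_len(n_rows_full) - 1L) %/% 2L) *
    (if (mode == "single_patch") fi$delta_f_SP else ci$delta_f_MP)
  inband <- if (enforce_stopband)
    !(row_f >= stopband[1] & row_f <= stopband[2]) & row_f > 0
  else rep(TRUE, n_rows_full)
  if (length(bg_list) && noise_sd > 0) {
    score <- snr
    keep <- which(snr >= snr_threshold & inband)
  } else {
    score <- amp
    keep <- which(amp >= energy_floor * max(amp[inband]) & inband)
  }
  if (length(keep) > max_rows)
    keep <- keep[order(score[keep], decreasing = TRUE)[seq_len(max_rows)]]
  keep <- sort(keep)

  f <- drive_frequencies(seq)
  bins <- (keep - 1L) %/% 2L
  chans <- (keep - 1L) %% 2L + 1L
  if (mode == "single_patch") {
    freq <- data.frame(channel = chans, bin = bins, f = bins * fi$delta_f_SP)
    S <- spec[keep, , drop = FALSE]
  } else {
    freq <- data.frame(channel = chans, bin = bins, f = bins * ci$delta_f_MP)
    S <- spec[keep, , , drop = FALSE]           # rows x patches x positions
  }

  structure(list(S = S, freq = freq, grid = grid, mode = mode,
                 bg_mean = bg_mean[keep], bg_sd = bg_sd[keep],
                 snr = snr[keep], amp = amp[keep],
                 delta_mass_mg = delta_volume_uL * delta_conc / 1e3,
                 seq = seq, n_background = length(bg_list),
                 seed = as.integer(seed)),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> %s: %d rows x %d voxels (grid %s), delta mass %.3g mg\n",
              x$mode, nrow(x$freq),
              x$grid$n_voxels, paste(x$grid$dims, collapse = "x"),
              x$delta_mass_mg))
  invisible(x)
}
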