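# Bolus perfusion post-processing on reconstructed time series:
# (i) time framing around the first bolus passage, (ii) voxel-wise Hann
# low-pass with DC exclusion, (iii) 10% threshold masking, and (iv) TTP /
# MTT / rCBF / rCBV parameter maps.

#' Time-series volume
#'
#' A reconstructed concentration time series: one row per frame, one column
#' per voxel.
#'
#' @param data frames x voxels numeric matrix.
#' @param frame_period frame duration in s (0.248064 for the 4 Hz sequence).
#' @param t0 bolus injection reference time (s).
#' @param grid optional [recon_grid()].
#' @return An object of class `time_series_volume`.
#' @export
time_series_volume <- function(data, frame_period = 0.248064, t0 = 0,
                               grid = NULL) {
  data <- as.matrix(data)
  if (frame_period <= 0) stop("'frame_period' must be positive", call. = FALSE)
  if (any(!is.finite(data))) stop("non-finite values in series", call. = FALSE)
  structure(list(data = data, frame_period = frame_period, t0 = t0,
                 grid = grid),
            class = "time_series_volume")
}

.series_times <- function(series) {
  (seq_len(nrow(series$data)) - 1) * series$frame_period
}

#' Crop a series to the first bolus passage
#'
#' Detects the bolus arrival on the global mean signal (first frame above
#' `arrival_frac` of its eventual peak), starts the window `pre_s` seconds
#' before arrival (the injection lead-in) and ends it once the global signal
#' has returned to the zero band (`zero_frac` of peak) for good.
#'
#' @param series a [time_series_volume()].
#' @param arrival_frac arrival detection threshold, fraction of the global
#'   peak.
#' @param zero_frac zero-return band, fraction of the global peak.
#' @param pre_s seconds included before the detected arrival.
#' @return The cropped `time_series_volume`, with attributes
#'   `arrival_frame` and `window` (frame indices into the input).
#' @export
frame_window <- function(series, arrival_frac = 0.10, zero_frac = 0.02,
                         pre_s = 5) {
  g <- rowMeans(series$data)
  peak <- max(g)
  if (peak <= 0) stop("no bolus found: series has no positive signal",
                      call. = FALSE)
  arrival <- which(g >= arrival_frac * peak)[1]
  if (is.na(arrival)) stop("no bolus found", call. = FALSE)
  start <- max(1L, arrival - round(pre_s / series$frame_period))
  above <- which(g > zero_frac * peak)
  end <- min(nrow(series$data), max(above) + 1L)
  out <- series
  out$data <- series$data[start:end, , drop = FALSE]
  out$t0 <- series$t0 - (start - 1L) * series$frame_period
  attr(out, "arrival_frame") <- arrival
  attr(out, "window") <- c(start, end)
  out
}

#' Voxel-wise Hann low-pass with DC exclusion
#'
#' Filters each voxel's time course in the frequency domain: the temporal
#' Fourier coefficients at bins `1..window_size` are tapered by a Hann-shaped
#' half window, the DC bin is zeroed (removing the concentration offset) and
#' all higher bins are discarded.
#'
#' @param series a [time_series_volume()].
#' @param window_size number of retained temporal frequency bins.
#' @return The filtered `time_series_volume` (real-valued).
#' @export
hann_lowpass <- function(series, window_size = 10) {
  n <- nrow(series$data)
  if (n < 2 * window_size)
    stop("series shorter than twice the filter window", call. = FALSE)
  w <- numeric(n)
  b <- seq_len(min(window_size, n - 1))
  taper <- 0.5 * (1 + cos(pi * b / window_size))
  w[1 + b] <- taper                # positive-frequency bins
  w[n + 1 - b] <- taper            # conjugate bins
  F <- stats::mvfft(series$data)
  out <- series
  out$data <- Re(stats::mvfft(F * w, inverse = TRUE)) / n
  out
}

#' Threshold mask
#'
#' Keeps voxels whose temporal maximum reaches at least `fraction` of the
#' global maximum over all voxels and frames.
#'
#' @param series a [time_series_volume()].
#' @param fraction threshold fraction (default 0.10).
#' @return Logical vector, one element per voxel.
#' @export
threshold_mask <- function(series, fraction = 0.10) {
  vox_max <- apply(series$data, 2, max)
  vox_max >= fraction * max(vox_max)
}

#' Time-to-peak map
#'
#' Per voxel, the time of the signal maximum relative to the reference time
#' `t0` (bolus injection); ties resolve to the earliest frame. TTP stays on
#' the frame grid.
#'
#' @param series a [time_series_volume()].
#' @param mask logical voxel mask; unmasked voxels return `NA`.
#' @return Numeric vector of TTP in seconds.
#' @export
ttp <- function(series, mask = rep(TRUE, ncol(series$data))) {
  tt <- .series_times(series)
  out <- rep(NA_real_, ncol(series$data))
  idx <- apply(series$data[, mask, drop = FALSE], 2, which.max)
  out[mask] <- tt[idx] - series$t0
  out
}

# half-maximum crossing times around the peak, linear sub-frame interpolation
.fwhm_one <- function(y, tt) {
  pk <- which.max(y)
  half <- y[pk] / 2
  if (y[pk] <= 0) return(NA_real_)
  left <- NA_real_; right <- NA_real_
  for (i in rev(seq_len(pk - 1))) {
    if (y[i] <= half) {
      left <- tt[i] + (tt[i + 1] - tt[i]) * (half - y[i]) / (y[i + 1] - y[i])
      break
    }
  }
  n <- length(y)
  if (pk < n) for (i in (pk + 1):n) {
    if (y[i] <= half) {
      left_y <- y[i - 1]
      right <- tt[i - 1] + (tt[i] - tt[i - 1]) * (left_y - half) / (left_y - y[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Mean-transit-time map (FWHM surrogate)
#'
#' Per voxel, the full width at half maximum of the bolus passage, with
#' sub-frame resolution by linear interpolation between frames. Voxels whose
#' curve never crosses the half maximum on one side are marked invalid
#' (`NA`), not extrapolated.
#'
#' @param series a [time_series_volume()].
#' @param mask logical voxel mask.
#' @return Numeric vector of MTT in seconds.
#' @export
mtt_fwhm <- function(series, mask = rep(TRUE, ncol(series$data))) {
  tt <- .series_times(series)
  out <- rep(NA_real_, ncol(series$data))
  out[mask] <- apply(series$data[, mask, drop = FALSE], 2, .fwhm_one, tt = tt)
  out
}

#' Relative cerebral-blood-flow map
#'
#' Per voxel, the highest positive temporal gradient of the concentration
#' (the value of the steepest uptake slope, a flow surrogate), normalized to
#' the maximum over the masked volume.
#'
#' @param series a [time_series_volume()].
#' @param mask logical voxel mask.
#' @param normalize divide by the volume-wide maximum.
#' @return Numeric vector; in `[0, 1]` when normalized.
#' @export
rcbf <- function(series, mask = rep(TRUE, ncol(series$data)),
                 normalize = TRUE) {
  d <- diff(series$data) / series$frame_period
  out <- rep(NA_real_, ncol(series$data))
  out[mask] <- apply(d[, mask, drop = FALSE], 2, max)
  if (normalize) {
    mx <- max(out, na.rm = TRUE)
    if (mx > 0) out <- out / mx
  }
  out
}

#' Relative cerebral-blood-volume map
#'
#' Per voxel, the trapezoidal integral of the concentration over its positive
#' support within the frame window (area under the bolus curve), normalized
#' to the maximum over the masked volume.
#'
#' @param series a [time_series_volume()].
#' @param mask logical voxel mask.
#' @param normalize divide by the volume-wide maximum.
#' @return Numeric vector; in `[0, 1]` when normalized.
#' @export
rcbv <- function(series, mask = rep(TRUE, ncol(series$data)),
                 normalize = TRUE) {
  dt <- series$frame_period
  y <- pmax(series$data, 0)
  n <- nrow(y)
  auc <- dt * (colSums(y) - 0.5 * (y[1, ] + y[n, ]))
  out <- rep(NA_real_, ncol(series$data))
  out[mask] <- auc[mask]
  if (normalize) {
    mx <- max(out, na.rm = TRUE)
    if (mx > 0) out <- out / mx
  }
  out
}

#' Perfusion post-processing pipeline
#'
#' Runs the four steps in their fixed order: time framing, Hann low-pass with
#' DC exclusion, threshold masking, and parameter map computation.
#'
#' @param series a [time_series_volume()].
#' @param window_size Hann filter size in frequency bins.
#' @param mask_fraction threshold-mask fraction.
#' @param arrival_frac,zero_frac,pre_s framing parameters, see
#'   [frame_window()].
#' @param align_t0 shift the TTP reference to the detected bolus arrival.
#' @return An object of class `perfusion_maps` with `ttp`, `mtt`, `rcbf`,
#'   `rcbv`, `mask`, the filtered `series` and the normalization constants.
#' @export
perfusion_pipeline <- function(series, window_size = 10, mask_fraction = 0.10,
                               arrival_frac = 0.10, zero_frac = 0.02,
                               pre_s = 5, align_t0 = TRUE) {
  cropped <- frame_window(series, arrival_frac, zero_frac, pre_s)
  filt <- hann_lowpass(cropped, window_size)
  mask <- threshold_mask(filt, mask_fraction)
  if (!any(mask)) {
    warning("threshold mask is empty")
    empty <- rep(NA_real_, ncol(series$data))
    return(structure(list(ttp = empty, mtt = empty, rcbf = empty,
                          rcbv = empty, mask = mask, series = filt,
                          norm = c(rcbf = NA_real_, rcbv = NA_real_)),
                     class = "perfusion_maps"))
  }
  if (align_t0) {
    arr <- attr(cropped, "arrival_frame") - attr(cropped, "window")[1]
    filt$t0 <- arr * filt$frame_period
  }
  cbf_raw <- rcbf(filt, mask, normalize = FALSE)
  cbv_raw <- rcbv(filt, mask, normalize = FALSE)
  norm <- c(rcbf = max(cbf_raw, na.rm = TRUE), rcbv = max(cbv_raw, na.rm = TRUE))
  structure(list(ttp = ttp(filt, mask),
                 mtt = mtt_fwhm(filt, mask),
                 rcbf = cbf_raw / ifelse(norm[["rcbf"]] > 0, norm[["rcbf"]], 1),
                 rcbv = cbv_raw / ifelse(norm[["rcbv"]] > 0, norm[["rcbv"]], 1),
                 mask = mask, series = filt, norm = norm),
            class = "perfusion_maps")
}
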