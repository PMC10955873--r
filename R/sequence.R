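# Imaging sequence: 2D Lissajous drive-field excitation in the xz-plane
# combined with a slow triangular selection-field sweep along y. All timing
# quantities are derived from integer clock dividers so that cycle and frame
# lengths are exact; floating point enters only when waveforms are evaluated.

.gcd <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' Scanner sequence description
#'
#' Parametric description of the 3D imaging sequence: two sinusoidal drive
#' fields whose frequencies are integer divisions of a common base clock
#' (closing into a 2D Lissajous trajectory in the xz-plane), plus a slow
#' selection-field sweep that shifts the field-free point (FFP) along y over
#' `n_patches` Lissajous cycles per frame.
#'
#' Defaults describe the full-scale 4 Hz head-scanner sequence: drive
#' frequencies 125/4864 MHz (x, about 25.699 kHz) and 125/4800 MHz
#' (z, about 26.042 kHz), decimated sampling at 125/64 MHz, 85 patches and a
#' +/-43 mm triangular FFP sweep. [desk_sequence()] provides a reduced variant
#' for fast simulation studies.
#'
#' @param base_clock DAC/ADC base clock in Hz.
#' @param divider_x,divider_z integer frequency dividers for the x and z drive
#'   channels; drive frequency is `base_clock / divider`.
#' @param decimation integer decimation of the base clock giving the sampling
#'   rate `base_clock / decimation`. The samples per Lissajous cycle must be an
#'   integer.
#' @param amplitude_x,amplitude_z drive-field amplitudes in mT.
#' @param n_patches number of Lissajous cycles (patches) per 3D frame, `M_y`.
#' @param sweep_amplitude maximum FFP offset along y in mm (to each side).
#' @param sweep_waveform `"triangular"` (default) or `"sinusoidal"` selection
#'   sweep.
#' @param frame_rate nominal frame rate in Hz (informational label; the exact
#'   frame duration follows from the timing algebra, see [frame_info()]).
#' @return An object of class `scanner_sequence`.
#' @examples
#' seq <- scanner_sequence()
#' drive_frequencies(seq)
#' frame_info(seq)$K
#' @export
scanner_sequence <- function(base_clock = 125e6,
                             divider_x = 4864L,
                             divider_z = 4800L,
                             decimation = 64L,
                             amplitude_x = 5,
                             amplitude_z = 4,
                             n_patches = 85L,
                             sweep_amplitude = 43,
                             sweep_waveform = c("triangular", "sinusoidal"),
                             frame_rate = 4) {
  sweep_waveform <- match.arg(sweep_waveform)
  for (nm in c("divider_x", "divider_z", "decimation", "n_patches")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v != round(v))
      stop("'", nm, "' must be a positive integer", call. = FALSE)
  }
  if (base_clock <= 0) stop("'base_clock' must be positive", call. = FALSE)
  structure(
    list(base_clock = base_clock,
         divider_x = as.integer(divider_x),
         divider_z = as.integer(divider_z),
         decimation = as.integer(decimation),
         amplitude_x = amplitude_x,
         amplitude_z = amplitude_z,
         n_patches = as.integer(n_patches),
         sweep_amplitude = sweep_amplitude,
         sweep_waveform = sweep_waveform,
         frame_rate = frame_rate),
    class = "scanner_sequence")
}

#' Reduced desk-scale sequence
#'
#' Same drive dividers and field amplitudes as the full-scale sequence, but a
#' coarser sampling rate (decimation 256) and fewer patches (17), keeping every
#' timing invariant exact while making frame-level simulation cheap.
#'
#' @param n_patches number of patches per frame.
#' @param decimation sampling decimation of the base clock.
#' @param ... further arguments passed to [scanner_sequence()].
#' @return A `scanner_sequence`.
#' @export
desk_sequence <- function(n_patches = 17L, decimation = 256L, ...) {
  scanner_sequence(n_patches = n_patches, decimation = decimation, ...)
}

#' @export
print.scanner_sequence <- function(x, ...) {
  f <- drive_frequencies(x)
  ci <- cycle_info(x)
  fi <- frame_info(x)
  cat("<scanner_sequence>\n")
  cat(sprintf("  drive: f_x = %.3f kHz (%g mT), f_z = %.3f kHz (%g mT)\n",
              f[["f_x"]] / 1e3, x$amplitude_x, f[["f_z"]] / 1e3, x$amplitude_z))
  cat(sprintf("  cycle: T = %.4f ms, %d samples, periods %d (x) : %d (z)\n",
              ci$T_cycle * 1e3, ci$samples_per_cycle, ci$periods_x, ci$periods_z))
  cat(sprintf("  frame: %d patches, T = %.4f ms, K = %d, df = %.3f Hz\n",
              x$n_patches, fi$T_frame * 1e3, fi$K, fi$delta_f_SP))
  cat(sprintf("  sweep: %s, +/-%g mm\n", x$sweep_waveform, x$sweep_amplitude))
  invisible(x)
}

#' Drive-field frequencies
#'
#' @param seq a [scanner_sequence()].
#' @return Named numeric vector `c(f_x =, f_z =)` in Hz.
#' @export
drive_frequencies <- function(seq) {
  stopifnot(inherits(seq, "scanner_sequence"))
  if (seq$divider_x == 0 || seq$divider_z == 0)
    stop("zero divider: invalid configuration", call. = FALSE)
  c(f_x = seq$base_clock / seq$divider_x, f_z = seq$base_clock / seq$divider_z)
}

#' Closed Lissajous cycle timing
#'
#' The closed 2D Lissajous cycle is the least common period of both drive
#' channels: `lcm(divider_x, divider_z)` base-clock ticks. For the default
#' dividers 4864 and 4800 the ratio reduces to 76/75, the cycle lasts 364800
#' ticks (about 2.918 ms) and contains 75 x-periods and 76 z-periods.
#'
#' @param seq a [scanner_sequence()].
#' @param max_ticks guard against pathological divider pairs whose common
#'   period would be astronomically long.
#' @return A list with `T_cycle` (s), `samples_per_cycle` (at the decimated
#'   rate), `periods_x`, `periods_z`, `delta_f_MP` (Hz, `1/T_cycle`) and
#'   `ticks` (base-clock ticks per cycle).
#' @export
cycle_info <- function(seq, max_ticks = 1e9) {
  stopifnot(inherits(seq, "scanner_sequence"))
  g <- .gcd(seq$divider_x, seq$divider_z)
  ticks <- (seq$divider_x / g) * seq$divider_z  # lcm, exact in doubles
  if (ticks > max_ticks)
    stop("drive dividers do not close within ", format(max_ticks),
         " base-clock ticks", call. = FALSE)
  if (ticks %% seq$decimation != 0)
    stop("samples per cycle is not an integer at decimation ",
         seq$decimation, call. = FALSE)
  list(T_cycle = ticks / seq$base_clock,
       samples_per_cycle = as.integer(ticks / seq$decimation),
       periods_x = as.integer(ticks / seq$divider_x),
       periods_z = as.integer(ticks / seq$divider_z),
       delta_f_MP = seq$base_clock / ticks,
       ticks = ticks)
}

#' Frame timing
#'
#' One 3D frame consists of `n_patches` Lissajous cycles swept along y.
#'
#' @param seq a [scanner_sequence()].
#' @return A list with `T_frame` (s), `K` (samples per frame per channel),
#'   `delta_f_SP` (single-patch frequency spacing, Hz) and `f_sample` (Hz).
#' @export
frame_info <- function(seq) {
  ci <- cycle_info(seq)
  list(T_frame = seq$n_patches * ci$T_cycle,
       K = as.integer(seq$n_patches) * ci$samples_per_cycle,
       delta_f_SP = ci$delta_f_MP / seq$n_patches,
       f_sample = seq$base_clock / seq$decimation)
}

#' Mixing frequency of a harmonic component
#'
#' Frequency of the intermodulation component `m_x * f_x + m_z * f_z`.
#'
#' @param seq a [scanner_sequence()].
#' @param m_x,m_z nonnegative integer mixing factors.
#' @return Frequency in Hz.
#' @export
mixing_frequency <- function(seq, m_x, m_z) {
  if (any(m_x < 0) || any(m_z < 0))
    stop("mixing factors must be nonnegative", call. = FALSE)
  f <- drive_frequencies(seq)
  m_x * f[["f_x"]] + m_z * f[["f_z"]]
}

#' Single-patch frequency index from mixing factors
#'
#' In single-patch processing the spectrum is sampled on the fine grid
#' `delta_f_SP = delta_f_MP / M_y`, and each component is indexed by
#' `k = m_y + M_y * (m_x * M_x + m_z * M_z)`, where `M_x`, `M_z` are the
#' drive-field periods per Lissajous cycle and `m_y` encodes the sideband
#' produced by the slow sweep.
#'
#' @param seq a [scanner_sequence()].
#' @param m_x,m_y,m_z integer mixing factors; `m_y` must lie in `[0, M_y)`.
#' @return Integer frequency index (vectorized over the mixing factors).
#' @seealso [decompose_index()]
#' @export
single_patch_index <- function(seq, m_x, m_y, m_z) {
  ci <- cycle_info(seq)
  M_y <- seq$n_patches
  if (any(m_y < 0 | m_y >= M_y))
    stop("'m_y' must lie in [0, n_patches)", call. = FALSE)
  if (any(m_x < 0) || any(m_z < 0))
    stop("mixing factors must be nonnegative", call. = FALSE)
  as.integer(m_y + M_y * (m_x * ci$periods_x + m_z * ci$periods_z))
}

#' Decompose a single-patch frequency index into mixing factors
#'
#' Inverts [single_patch_index()]: `m_y = k mod M_y`, and the remaining
#' per-cycle index `r = m_x * M_x + m_z * M_z` is resolved by the unique
#' nonnegative solution with minimal `m_z` (unique whenever `r < M_x * M_z`,
#' because `M_x` and `M_z` are coprime).
#'
#' @param seq a [scanner_sequence()].
#' @param k nonnegative integer frequency index (vectorized).
#' @return A data.frame with columns `k`, `m_x`, `m_y`, `m_z`; rows where no
#'   nonnegative decomposition exists carry `NA` mixing factors.
#' @export
decompose_index <- function(seq, k) {
  ci <- cycle_info(seq)
  M_y <- seq$n_patches
  if (any(k < 0)) stop("'k' must be nonnegative", call. = FALSE)
  m_y <- k %% M_y
  r <- (k - m_y) / M_y
  Mx <- ci$periods_x
  Mz <- ci$periods_z
  # m_z = r * inv(Mz) mod Mx, minimal nonnegative; then m_x from the remainder
  inv <- which((Mz * (seq_len(Mx) - 1L)) %% Mx == 1L) - 1L
  if (length(inv) == 0L) inv <- 0L  # Mx == 1
  m_z <- (r * inv) %% Mx
  m_x <- (r - Mz * m_z) / Mx
  bad <- m_x < 0 | m_x != round(m_x)
  m_x[bad] <- NA_integer_
  m_z[bad] <- NA_integer_
  data.frame(k = as.integer(k), m_x = as.integer(m_x),
             m_y = as.integer(m_y), m_z = as.integer(m_z))
}

#' Drive-field waveforms
#'
#' Both channels are sinusoidal with zero phase at `t = 0`:
#' `H_x = A_x sin(2 pi f_x t)`, `H_z = A_z sin(2 pi f_z t)`.
#'
#' @param seq a [scanner_sequence()].
#' @param t time points in seconds.
#' @return A two-column matrix (mT) with columns `H_x`, `H_z`.
#' @export
drive_waveforms <- function(seq, t) {
  if (any(!is.finite(t))) stop("'t' must be finite", call. = FALSE)
  f <- drive_frequencies(seq)
  cbind(H_x = seq$amplitude_x * sin(2 * pi * f[["f_x"]] * t),
        H_z = seq$amplitude_z * sin(2 * pi * f[["f_z"]] * t))
}

#' Selection-field FFP sweep along y
#'
#' One frame contains one positive-going and one negative-going sweep: the
#' triangular waveform starts at `-sweep_amplitude` at `t = 0`, reaches
#' `+sweep_amplitude` at `T_frame / 2` and returns. The sinusoidal variant is
#' `-A cos(2 pi t / T_frame)`.
#'
#' @param seq a [scanner_sequence()].
#' @param t time points in seconds (wrapped periodically into the frame).
#' @return FFP y-offset in mm.
#' @export
selection_sweep <- function(seq, t) {
  Tf <- frame_info(seq)$T_frame
  A <- seq$sweep_amplitude
  u <- (t / Tf) %% 1
  if (seq$sweep_waveform == "triangular") {
    A * (1 - 2 * abs(2 * u - 1))  # -A at u = 0, +A at u = 1/2
  } else {
    -A * cos(2 * pi * u)
  }
}

#' Mean FFP sweep speed along y
#'
#' For the triangular sweep the FFP moves at constant speed
#' `4 * sweep_amplitude / T_frame`.
#'
#' @param seq a [scanner_sequence()].
#' @return Speed in mm/s.
#' @export
ffp_sweep_speed <- function(seq) {
  4 * seq$sweep_amplitude / frame_info(seq)$T_frame
}

#' Slice spacing of the 3D trajectory
#'
#' Distance the FFP advances along y during one closed 2D Lissajous cycle,
#' `ffp_speed * T_cycle`. With the default sweep this is
#' `4 * sweep_amplitude / M_y` (about 2.02 mm for the full-scale sequence at
#' the nominal 68.8 cm/s sweep speed, and 2.008 mm at exactly 688 mm/s).
#'
#' @param seq a [scanner_sequence()].
#' @param ffp_speed FFP speed along y in mm/s; defaults to [ffp_sweep_speed()].
#' @return Slice spacing in mm.
#' @export
slice_spacing <- function(seq, ffp_speed = ffp_sweep_speed(seq)) {
  if (any(ffp_speed < 0)) stop("'ffp_speed' must be nonnegative", call. = FALSE)
  ffp_speed * cycle_info(seq)$T_cycle
}

#' Read / write a sequence configuration
#'
#' The sequence is serialized as a YAML mapping whose keys are exactly the
#' [scanner_sequence()] fields (SI units: Hz, mT, mm).
#'
#' @param seq a [scanner_sequence()].
#' @param path file path.
#' @return `write_sequence` returns `path` invisibly; `read_sequence` returns
#'   a `scanner_sequence`.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "scanner_sequence"))
  yaml::write_yaml(unclass(seq), path)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(scanner_sequence, x)
}
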