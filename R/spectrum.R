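# Frequency-space processing of measured frames: Fourier transforms in the
# multi-patch (per-cycle) and single-patch (whole-frame) interpretations,
# SNR-based frequency selection and background subtraction.

#' Fourier spectra of measurement frames
#'
#' Single-patch processing transforms the entire frame (bin spacing
#' `delta_f_SP`); multi-patch processing transforms each Lissajous cycle
#' separately (bin spacing `delta_f_MP`), retaining the patch index. Rows are
#' interleaved as `row = 2 * bin + channel` to match system-matrix layout.
#'
#' @param frames a `measurement_frames` object from [simulate_frame()].
#' @param mode `"single_patch"` or `"multi_patch"`.
#' @param background transform the background frames instead of the data.
#' @return An object of class `mpi_spectrum`: complex array `u` of dim
#'   `(rows, frames)` (single-patch) or `(rows, patches, frames)`
#'   (multi-patch), with `delta_f`, `mode` and the originating sequence.
#' @export
spectrum <- function(frames, mode = c("single_patch", "multi_patch"),
                     background = FALSE) {
  stopifnot(inherits(frames, "measurement_frames"))
  mode <- match.arg(mode)
  seq <- frames$seq
  fi <- frame_info(seq)
  ci <- cycle_info(seq)
  dat <- if (background) frames$background else frames$data
  nf <- dim(dat)[1]
  K <- dim(dat)[3]
  if (K != fi$K) stop("frame length does not match the sequence", call. = FALSE)
  if (mode == "single_patch") {
    nb <- floor(K / 2) + 1L
    u <- array(0i, c(2L * nb, nf))
    for (j in seq_len(nf))
      u[, j] <- c(.frame_spectrum_sp(matrix(dat[j, , ], 2, K)))
    delta_f <- fi$delta_f_SP
  } else {
    spc <- ci$samples_per_cycle
    if (K %% spc != 0)
      stop("frame length not divisible by samples per cycle", call. = FALSE)
    My <- K %/% spc
    nb <- floor(spc / 2) + 1L
    u <- array(0i, c(2L * nb, My, nf))
    for (j in seq_len(nf)) {
      for (ch in 1:2) {
        cyc <- matrix(dat[j, ch, ], spc, My)
        u[seq(ch, by = 2, length.out = nb), , j] <-
          stats::mvfft(cyc)[1:nb, , drop = FALSE] / spc
      }
    }
    delta_f <- ci$delta_f_MP
  }
  structure(list(u = u, delta_f = delta_f, mode = mode, seq = seq),
            class = "mpi_spectrum")
}

#' Row-wise SNR of calibration spectra
#'
#' For each frequency row, the maximal signal amplitude over all calibration
#' positions divided by the background standard deviation of that bin
#' (`use = "max"`; `use = "mean"` averages over positions instead).
#'
#' @param S complex matrix, rows x calibration positions.
#' @param background complex matrix, rows x background frames (>= 2).
#' @param use `"max"` (default) or `"mean"` amplitude over positions.
#' @return Numeric SNR per row; rows with zero background deviation get
#'   `Inf` (flagged with a warning).
#' @export
snr_rows <- function(S, background, use = c("max", "mean")) {
  use <- match.arg(use)
  if (ncol(background) < 2) stop("need >= 2 background frames", call. = FALSE)
  bg_mean <- rowMeans(background)
  bg_sd <- sqrt(rowMeans(Mod(background - bg_mean)^2))
  amp <- Mod(S - bg_mean)
  a <- if (use == "max") apply(amp, 1, max) else rowMeans(amp)
  if (any(bg_sd == 0)) warning("zero background deviation: infinite SNR rows")
  ifelse(bg_sd > 0, a / bg_sd, Inf)
}

#' Select frequency rows by SNR and receive stopband
#'
#' Keeps rows with `snr >= threshold`; with `enforce_stopband`, additionally
#' drops rows whose frequency lies in the receive-filter band-stop region
#' (20-33 kHz by default, where the fundamental feedthrough is suppressed).
#'
#' @param snr numeric SNR per row.
#' @param threshold SNR threshold (typically 3 to 100).
#' @param f row frequencies in Hz (required when `enforce_stopband`).
#' @param enforce_stopband drop rows inside `stopband`.
#' @param stopband numeric `c(lo, hi)` in Hz.
#' @return Integer vector of retained row indices.
#' @export
select_frequencies <- function(snr, threshold = 5, f = NULL,
                               enforce_stopband = FALSE,
                               stopband = c(20e3, 33e3)) {
  keep <- snr >= threshold
  if (enforce_stopband) {
    if (is.null(f)) stop("'f' required to enforce the stopband", call. = FALSE)
    keep <- keep & !(f >= stopband[1] & f <= stopband[2])
  }
  which(keep)
}

#' Subtract background spectra from measurement spectra
#'
#' Subtracts, from every measurement column, the mean spectrum of the
#' temporally nearest preceding background block (background frames recorded
#' in contiguous blocks between measurement frames). Without acquisition
#' indices the global background mean is used.
#'
#' @param u complex matrix, rows x measurement frames.
#' @param background complex matrix, rows x background frames.
#' @param u_index,bg_index optional acquisition indices (any monotone time
#'   stamp) of measurement and background frames; background frames whose
#'   indices are consecutive form one block.
#' @return The corrected matrix `u`.
#' @export
subtract_background <- function(u, background, u_index = NULL,
                                bg_index = NULL) {
  u <- as.matrix(u); background <- as.matrix(background)
  if (is.null(u_index) || is.null(bg_index))
    return(u - rowMeans(background))
  stopifnot(length(u_index) == ncol(u), length(bg_index) == ncol(background))
  blk <- cumsum(c(1, diff(bg_index) > 1))
  blk_mean <- vapply(split(seq_along(bg_index), blk), function(ix)
    rowMeans(background[, ix, drop = FALSE]), complex(nrow(background)))
  blk_pos <- vapply(split(bg_index, blk), stats::median, numeric(1))
  for (j in seq_len(ncol(u))) {
    prior <- which(blk_pos <= u_index[j])
    b <- if (length(prior)) prior[which.max(blk_pos[prior])]
         else which.min(abs(blk_pos - u_index[j]))
    u[, j] <- u[, j] - blk_mean[, b]
  }
  u
}
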