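# Phantom generators: point-sample phantoms (delta samples, dilution series,
# two-dot resolution phantoms) and the dynamic two-hemisphere perfusion
# phantom with a gamma-variate bolus input and exponential residue kernel.

#' Point-sample phantom
#'
#' A phantom is a set of small tracer samples, each with a position (mm), a
#' volume (uL), an iron concentration (mg Fe/mL) and a tracer label. Total
#' iron mass (ug) is `volume * concentration`.
#'
#' @param positions n x 3 matrix of sample centers (mm).
#' @param volume_uL sample volumes (uL), recycled.
#' @param conc_mg_ml iron concentrations (mg Fe/mL), recycled.
#' @param tracer tracer labels, recycled.
#' @return An object of class `phantom` (a data.frame of samples).
#' @export
phantom <- function(positions, volume_uL = 200, conc_mg_ml = 8.5,
                    tracer = "resotran-like") {
  positions <- rbind(positions)
  stopifnot(ncol(positions) == 3)
  if (any(conc_mg_ml < 0)) stop("negative concentration", call. = FALSE)
  n <- nrow(positions)
  s <- data.frame(x = positions[, 1], y = positions[, 2], z = positions[, 3],
                  volume_uL = rep_len(volume_uL, n),
                  conc_mg_ml = rep_len(conc_mg_ml, n),
                  tracer = rep_len(tracer, n))
  s$mass_ug <- s$volume_uL * s$conc_mg_ml
  structure(s, class = c("phantom", "data.frame"))
}

#' Calibration delta sample
#'
#' The cubic 200 uL reference sample at 8.5 mg Fe/mL (1.7 mg iron) used for
#' system-matrix calibration.
#'
#' @param position sample center (mm).
#' @param volume_uL,conc_mg_ml sample volume and concentration.
#' @param tracer tracer label.
#' @return A `phantom` with one sample.
#' @export
make_delta_sample <- function(position = c(0, 0, 0), volume_uL = 200,
                              conc_mg_ml = 8.5, tracer = "resotran-like") {
  phantom(position, volume_uL, conc_mg_ml, tracer)
}

#' Dilution series phantoms
#'
#' Eight 50 uL samples with iron masses doubling from 4 to 512 ug, each
#' placed consecutively at three positions along the y-axis, mirroring a
#' sensitivity protocol in which a moving artifact distinguishes real signal
#' from system background.
#'
#' @param masses_ug iron masses (ug).
#' @param positions_y the three sample y-positions (mm).
#' @param volume_uL sample volume (uL).
#' @param tracer tracer label.
#' @return A list (one element per mass) of lists of `phantom`s (one per
#'   position).
#' @export
make_dilution_series <- function(masses_ug = 4 * 2^(0:7),
                                 positions_y = c(-20, 0, 20),
                                 volume_uL = 50,
                                 tracer = "resotran-like") {
  lapply(masses_ug, function(m) {
    lapply(positions_y, function(y0) {
      phantom(c(0, y0, 0), volume_uL = volume_uL,
              conc_mg_ml = m / volume_uL, tracer = tracer)
    })
  })
}

#' Two-dot resolution phantom
#'
#' One delta sample fixed at the center plus an identical sample offset along
#' one main axis; the offset is specified edge-to-edge, with the cube edge
#' length derived from the sample volume.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param edge_to_edge edge-to-edge distance in mm (>= 0; stepped in 0.5 mm
#'   increments in the resolution protocol).
#' @param volume_uL,conc_mg_ml per-sample volume and concentration.
#' @param tracer tracer labels (length 1 or 2; two labels give a two-tracer
#'   phantom for multi-contrast experiments).
#' @return A `phantom` with two samples.
#' @export
make_two_dot <- function(axis = c("x", "y", "z"), edge_to_edge = 10,
                         volume_uL = 200, conc_mg_ml = 8.5,
                         tracer = "resotran-like") {
  axis <- match.arg(axis)
  if (edge_to_edge < 0) stop("'edge_to_edge' must be >= 0", call. = FALSE)
  edge <- (volume_uL * 1e3)^(1 / 3)  # uL -> mm^3, cube edge in mm
  ctc <- edge_to_edge + edge
  off <- c(x = 1, y = 2, z = 3)[[axis]]
  pos <- matrix(0, 2, 3)
  pos[2, off] <- ctc
  phantom(pos, volume_uL, conc_mg_ml, tracer = rep_len(tracer, 2))
}

#' Gamma-variate bolus input curve
#'
#' `c(t) = A ((t - t0)/tp)^alpha exp(alpha (1 - (t - t0)/tp))` for `t > t0`,
#' zero before arrival; peaks with value `A` at `t = t0 + tp`.
#'
#' @param t time (s).
#' @param t0 arrival time (s).
#' @param alpha shape parameter.
#' @param tp time-to-peak after arrival (s).
#' @param A peak amplitude.
#' @return Concentration values.
#' @export
gamma_variate <- function(t, t0 = 6, alpha = 3, tp = 2, A = 1) {
  u <- (t - t0) / tp
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- A * u[pos]^alpha * exp(alpha * (1 - u[pos]))
  out
}

#' Two-hemisphere perfusion phantom with stenosis
#'
#' Two tissue-mimicking compartments ("hemispheres", 50 mL cylinders filled
#' with glass spheres) perfused independently. The right hemisphere runs at
#' the reference flow; the left at `(1 - stenosis) *` reference. Each voxel's
#' concentration curve is the indicator-dilution response
#' `m_h(t) = F_h (c_a * R_h)(t)` with a shared gamma-variate arterial input
#' `c_a` and exponential residue `R_h(t) = exp(-t / MTT_h)`,
#' `MTT_h = V_eff / F_h`. `V_eff` is the tracer-accessible pore volume of a
#' hemisphere (a few mL of the 50 mL cylinder; the glass-sphere packing
#' occupies the rest), chosen so the full bolus passage fits the acquisition
#' window. The injected iron (bolus volume x concentration) splits between
#' hemispheres in proportion to flow and is conserved by construction.
#'
#' @param stenosis_left stenosis fraction in `[0, 1]` of the left hemisphere
#'   (1 = complete occlusion, zero left-side signal).
#' @param flow_right reference flow in mL/min.
#' @param bolus_volume_uL,bolus_conc bolus volume (uL) and concentration
#'   (mg Fe/mL); defaults carry 2.8 mg iron.
#' @param v_eff_ml effective tracer-accessible volume per hemisphere (mL).
#' @param t0,alpha,tp arterial input timing, see [gamma_variate()].
#' @param n_frames,frame_period acquisition raster (150 frames of 0.248064 s
#'   by default, 37.2 s).
#' @param voxels_per_hemisphere voxels per compartment.
#' @param delay_spread_s largest intra-hemisphere arrival delay (s); voxels
#'   further along the distribution rod fill later, which gives each
#'   hemisphere a mild internal heterogeneity.
#' @param seed seed for the deterministic per-voxel delay assignment.
#' @return An object of class `perfusion_phantom`: `curves`
#'   (frames x voxels concentration matrix, arbitrary units proportional to
#'   mg Fe/mL), `hemisphere` (factor `"left"`/`"right"` per voxel), `times`
#'   (s), plus the generating parameters.
#' @export
make_perfusion_phantom <- function(stenosis_left = 0, flow_right = 100,
                                   bolus_volume_uL = 100, bolus_conc = 28,
                                   v_eff_ml = 5,
                                   t0 = 6, alpha = 3, tp = 2,
                                   n_frames = 150, frame_period = 0.248064,
                                   voxels_per_hemisphere = 32,
                                   delay_spread_s = 0.6,
                                   seed = 1L) {
  if (stenosis_left < 0 || stenosis_left > 1)
    stop("'stenosis_left' must be in [0, 1]", call. = FALSE)
  F_R <- flow_right / 60              # mL/s
  F_L <- (1 - stenosis_left) * F_R
  iron_mg <- bolus_volume_uL / 1e3 * bolus_conc
  times <- (seq_len(n_frames) - 1) * frame_period
  # arterial input: normalized gamma variate scaled so that
  # integral(c_a) * (F_L + F_R) == injected iron; the indicator-dilution
  # convolution runs on an 8x finer internal grid for quadrature accuracy
  sub <- 8L
  nf <- n_frames * sub
  dtf <- frame_period / sub
  times_f <- (seq_len(nf) - 1) * dtf
  auc1 <- tp * exp(alpha) * gamma(alpha + 1) / alpha^(alpha + 1)  # closed form
  c_a <- gamma_variate(times_f, t0, alpha, tp, A = 1) *
    iron_mg / ((F_L + F_R) * auc1)
  hemi_curve <- function(F_h) {
    if (F_h <= 0) return(numeric(n_frames))
    mtt <- v_eff_ml / F_h
    R <- exp(-(times_f + dtf / 2) / mtt)  # midpoint rule for the decay kernel
    # discrete causal convolution F_h * (c_a (*) R) dt on the fine grid
    full <- stats::convolve(c_a, rev(R), type = "open")[seq_len(nf)]
    (F_h * full * dtf / v_eff_ml)[seq(1, nf, by = sub)]
  }
  base <- list(left = hemi_curve(F_L), right = hemi_curve(F_R))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  nv <- voxels_per_hemisphere
  delays <- stats::runif(2 * nv, 0, delay_spread_s)
  curves <- matrix(0, n_frames, 2 * nv)
  hemi <- rep(c("left", "right"), each = nv)
  for (v in seq_len(2 * nv)) {
    b <- base[[hemi[v]]]
    if (all(b == 0)) next
    curves[, v] <- stats::approx(times + delays[v], b, xout = times,
                                 rule = 2)$y
  }
  structure(list(curves = curves, hemisphere = factor(hemi), times = times,
                 frame_period = frame_period, stenosis_left = stenosis_left,
                 flow_right = flow_right, v_eff_ml = v_eff_ml,
                 iron_mg = iron_mg, t0 = t0, alpha = alpha, tp = tp,
                 seed = seed),
            class = "perfusion_phantom")
}
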