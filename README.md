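# mpiscan

Simulation, system-matrix reconstruction and perfusion analysis for a
head-scale magnetic particle imaging (MPI) scanner.

MPI localizes superparamagnetic iron-oxide tracers through the nonlinear
harmonics their magnetization injects into receive coils. This package
implements the computational chain of a human-head-scale scanner whose
field-free point (FFP) follows a closed 2D Lissajous trajectory in the
xz-plane (drive frequencies $f_x = 125/4864$ MHz and $f_z = 125/4800$ MHz,
ratio 76:75) while a slow triangular selection-field sweep shifts the
trajectory along y over $M_y = 85$ patches, sampling a 3D volume at 4 Hz.
It is written for people building or studying system-matrix MPI pipelines
who need a fully synthetic, reproducible stand-in for the scanner: every
stage from sequence timing to perfusion maps runs on simulated data with
explicit seeds.

**What's inside**

* *Sequence algebra* — exact integer-clock timing: cycle length
  $T^{MP}_{cycle} \approx 2.918$ ms, frame length $K = 484{,}500$ samples
  (248.064 ms), single-patch bin spacing $\Delta f^{SP} = 4.031$ Hz, and
  the frequency-index decomposition
  $k = m_y + M_y (m_x M_x + m_z M_z)$ with its inverse.
* *Trajectory geometry* — closed-form Lissajous self-intersection (node)
  points and the largest sampling gap.
* *Field models* — ideal gradient (diag(−0.12, 0.24, −0.12) T/m), real
  solid-harmonic expansions fitted from sphere samples, current-to-gradient
  calibration, THD estimation.
* *Simulator* — equilibrium Langevin magnetization
  $L(\xi) = \coth\xi - 1/\xi$, induced-voltage frames, robot-style
  system-matrix calibration (15×15×11 grid over 140×110×100 mm³ at full
  scale) with interleaved background frames, dilution/two-dot/perfusion
  phantom generators.
* *Reconstruction* — SNR-based frequency selection, background
  subtraction, regularized Kaczmarz solving
  $\min_{c \ge 0} \|Sc-u\|_2^2 + \lambda_{L^2}\|c\|_2^2 +
  \lambda_{L^1}\|c\|_1$ (C++ core), multi-patch and single-patch modes,
  multi-contrast stacking, trilinear over-gridding, iron quantification.
* *Perfusion* — time framing, voxel-wise Hann low-pass with DC exclusion,
  10% threshold masking, and TTP / MTT (FWHM) / rCBF (max uptake slope) /
  rCBV (AUC) maps.
* *Characterization* — profile-line half/quarter-maximum resolution
  criterion, stepped two-dot resolution studies, dilution-series
  detection-limit logic.

## Worked example

```r
library(mpiscan)

seq <- scanner_sequence()        # full-scale 4 Hz sequence
seq
#> <scanner_sequence>
#>   drive: f_x = 25.699 kHz (5 mT), f_z = 26.042 kHz (4 mT)
#>   cycle: T = 2.9184 ms, 5700 samples, periods 75 (x) : 76 (z)
#>   frame: 85 patches, T = 248.0640 ms, K = 484500, df = 4.031 Hz
#>   sweep: triangular, +/-43 mm

trajectory_gap(seq, half_axes = c(42, 33.5))
#> largest trajectory gap: 1.759 mm (11249 node points)

# desk-scale calibration: delta sample stepped over a 9x9x5 grid
desk <- desk_sequence()
sm <- simulate_system_matrix(desk, grid = recon_grid(c(9, 9, 5)), seed = 1)
sm
#> <system_matrix> single_patch: 2000 rows x 405 voxels (grid 9x9x5), delta mass 1.7 mg

# simulate a 64 ug iron sample, reconstruct, quantify
ph  <- phantom(c(0, 0, 0), volume_uL = 50, conc_mg_ml = 64 / 50)
mf  <- simulate_frame(ph, desk)
rec <- kaczmarz_solve(sm, measurement_rows(sm, mf),
                      lambda_l2 = 1e-6, iterations = 100)
quantify_iron(rec, box_mask(sm$grid, c(0, 0, 0)), sm$delta_mass_mg) * 1e3
#> [1] 64.87779

# perfusion battery member: 50% stenosis of the left hemisphere
phant <- make_perfusion_phantom(stenosis_left = 0.5, seed = 7)
maps  <- perfusion_pipeline(time_series_volume(phant$curves, phant$frame_period))
left  <- phant$hemisphere == "left"  & maps$mask
right <- phant$hemisphere == "right" & maps$mask
round(c(mtt_left  = median(maps$mtt[left]),  mtt_right = median(maps$mtt[right]),
        rcbf_left = median(maps$rcbf[left]), rcbf_right = median(maps$rcbf[right])), 2)
#>   mtt_left  mtt_right  rcbf_left rcbf_right
#>       5.75       4.76       0.62       1.00
```

The recovered mass (64.9 µg for 64 µg programmed) shows the linearity of
the forward model and the calibration-referenced quantification; the
perfusion medians show the flow reduction lengthening the transit time and
suppressing the uptake slope in the stenosed hemisphere while the healthy
side is unchanged.

A thin command-line wrapper lives in `inst/cli/mpiscan`
(`simulate`, `calibrate`, `reconstruct`, `perfusion`, `characterize`,
`targets`).

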