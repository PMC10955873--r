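---
title: "Methods: sequence algebra, simulation and reconstruction for a head-scale MPI scanner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence algebra, simulation and reconstruction for a head-scale MPI scanner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpiscan)
```

# Scope and model

Magnetic particle imaging (MPI) localizes superparamagnetic iron-oxide
tracers through the nonlinear harmonics their magnetization injects into
receive coils. `mpiscan` implements the computational chain of a head-scale
scanner whose field-free point (FFP) is driven on a closed 2D Lissajous
trajectory in the xz-plane by two sinusoidal drive fields while a slow
triangular selection-field sweep shifts the trajectory along y, sampling a
3D volume at a 4 Hz frame rate. All stages run on synthetic data: the
package contains no measured datasets and the simulator is a first-class,
tested component.

The chain is: exact sequence timing (`scanner_sequence()`, `cycle_info()`,
`frame_info()`), trajectory geometry (`trajectory_gap()`), field models
(`ideal_field_model()`, `fit_spherical_harmonics()`), the Langevin signal
simulator (`simulate_frame()`, `simulate_system_matrix()`), frequency-space
reconstruction (`spectrum()`, `snr_rows()`, `kaczmarz_solve()`,
`multicontrast_solve()`), perfusion post-processing
(`perfusion_pipeline()`) and characterization protocols
(`resolution_study()`, `detection_limit()`).

# Sequence timing is integer arithmetic

Both drive frequencies divide a 125 MHz base clock: $f_x = 125/4864$ MHz
$\approx 25.699$ kHz and $f_z = 125/4800$ MHz $\approx 26.042$ kHz. The
closed Lissajous cycle is the least common period,
$\mathrm{lcm}(4864, 4800) = 364800$ ticks $\approx 2.918$ ms, during which
the x channel completes $364800/4864 = 75$ periods and the z channel 76.
At the decimated sampling rate 125/64 MHz one cycle holds exactly 5700
samples; a frame of $M_y = 85$ patches holds $K = 484500$ samples in
$248.064$ ms, giving the single-patch bin spacing
$\Delta f^{SP} = 1/T_{frame} \approx 4.031$ Hz and the multi-patch spacing
$\Delta f^{MP} \approx 342.654$ Hz. All of these are computed as exact
integer/rational quantities; floating point enters only when waveforms are
evaluated.

**Axis-period assignment.** The scanner's sequence description assigns 76
periods to x and 75 to z, while the divider arithmetic makes x (the slower
channel) complete 75. `cycle_info()` reports the ratio-derived assignment,
and every frequency-index computation (`mixing_frequency()`,
`single_patch_index()`) is written directly in terms of $m_x f_x + m_z f_z$,
which is invariant under the naming swap. Geometry functions accept a
`periods` argument so either convention can be requested explicitly.

**Phase conventions** are not dictated by the hardware description, so we
fix them for reproducibility: both drive channels start at phase 0
(`sin`), the triangular sweep starts at $-43$ mm, and sample $n$ sits at
$t = n/f_s$ (0-based).

# Trajectory gap

The sampling density of a Lissajous trajectory is inhomogeneous; the
coarsest stretch bounds the achievable resolution from below.
`lissajous_nodes()` enumerates all self-intersections of
$(a\sin 2\pi p t,\; b\sin 2\pi q t)$ in closed form (a node pairs a
full-period shift in one channel with a sine-reflection in the other), and
`trajectory_gap()` reports the maximal Euclidean distance between node
passages that are consecutive along the trajectory. A dense-sampling
segment-intersection oracle in the test suite confirms the analytic node
set to better than 1%.

Alternative conventions give materially different numbers at the nominal
half-axes (42 mm, 33.5 mm): the maximal nearest-neighbour node distance is
1.12 mm, the largest-hole diameter of the curve 1.05 mm, and the maximal
adjacent-node distance 1.74–1.76 mm depending on the axis-period
assignment. We use the adjacent-node convention with the sequence
description's assignment (x: 76), which yields 1.76 mm; published values
near 1.8 mm for this sequence family sit within a few percent of it, and
the remaining difference traces to the (unstated) convention rather than to
the node enumeration.

# Field models

The ideal selection field is a trace-free linear gradient
$\mathrm{diag}(-0.12, 0.24, -0.12)$ T/m; with fields expressed as flux
density in mT and positions in mm, `ffp_position()` is literally
$r = c - G^{-1}H$ with no unit factors. Real field imperfections are
represented, as in field-calibration practice, by per-component real solid
harmonics fitted from vector samples on a sphere
(`fit_spherical_harmonics()`). The degree-1 basis functions are the bare
coordinates, so gradients and FFP offsets read directly off the
coefficients (`shf_linear_part()`), which also powers the
current-to-gradient calibration (`current_calibration()`, piecewise-linear
in current to follow soft-iron saturation). Published sphere-sampling
tables (spherical t-designs) are external data; the package instead ships
a deterministic spherical-Fibonacci generator — least-squares fitting does
not require exact designs, only a well-conditioned point set, and the fit
refuses rank-deficient designs naming the condition number. The expansion
degree is configurable with default $L = 6$, consistent with the 36–86
point designs used for such measurements. Drive-field distortion is
quantified by `thd()`, the RMS of harmonics $\ge 2$ over the fundamental,
estimated by complex projection over an integer number of periods.

# The synthetic scanner

`simulate_frame()` evaluates, for every point sample, the total field
(static gradient offset + drive waveforms + sweep field) on an internally
4x-oversampled time grid, applies the equilibrium Langevin magnetization
$M \propto L(\beta |B|)\hat B$ with $L(\xi) = \coth\xi - 1/\xi$ (series
branch below $10^{-4}$), differentiates by periodic central differences,
decimates to the sequence rate, and picks the x- and y-components as the
two receive channels with scalar sensitivities. Tracer parameters are
synthetic stand-ins with realistic scales: "resotran-like" (20 nm core,
$M_s = 474$ kA/m, 293 K, $\beta \approx 492\,\mathrm{T}^{-1}$, i.e.
$\xi \approx 2.5$ at the 5 mT drive amplitude) and "synomag-like" (25 nm),
whose distinct $\beta$ makes their harmonic spectra separable — the
precondition for multi-contrast unmixing. Signals carry arbitrary units
(no receive-chain gain or transfer function is modelled), magnetic moments
are expressed per mass of iron, and the forward model is strictly linear
in tracer mass — the basis for quantification.

`simulate_system_matrix()` emulates the robot calibration: a 200 uL,
8.5 mg/mL delta sample (1.7 mg iron) visits every voxel of the calibration
grid, one frame per position, with 12 empty background frames after each
xy-plane (the count is configurable; the protocol description leaves it
ambiguous). Rows are stored in frequency space in either interpretation:
single-patch (whole-frame FFT, fine bins) or multi-patch (per-cycle FFT,
patch-resolved). Row selection uses the SNR definition *maximal amplitude
over calibration positions divided by the per-bin background standard
deviation* (a mean-over-positions variant is available) — the definition
is a design choice, as is the threshold; for noise-free simulations a
relative row-energy floor substitutes. The receive-filter stopband
(20–33 kHz) is excluded by default: it contains the overwhelming
drive-frequency feedthrough, which would otherwise dominate the mean row
energy that scales the regularization.

# Reconstruction

Images solve
$\arg\min_{c \ge 0} \|Sc-u\|_2^2 + \lambda_{L2}\|c\|_2^2 +
\lambda_{L1}\|c\|_1$ by row-iterative Kaczmarz sweeps with the
augmented-variable Tikhonov formulation (the exact solver used throughout
MPI); the C++ core iterates rows stored contiguously. Two details are
deliberate design choices documented here because the method family leaves
them open:

* **Regularization scaling:** $\lambda_{L2}$ is relative to the mean row
  energy $\overline{\|S_i\|^2}$ (the common MPI convention), and the L1
  soft-threshold per sweep is $\lambda_{L1}\,\overline{|u|}/M$.
* **L1 and nonnegativity** are applied between sweeps (iterative
  shrinkage hybrid), after which the iterate is real; with both disabled
  the solver converges to the complex Tikhonov solution and is verified
  against the regularized normal equations to $10^{-6}$ relative error on
  systems up to $200 \times 100$.

Row order is sequential by default with an optional seeded shuffle; all
paths are deterministic given the seed. `multicontrast_solve()`
column-stacks one system matrix per tracer on identical grids and
frequency selections, warns on near-collinear stacks (indistinguishable
tracers), and splits the joint solution into per-tracer channels.
Over-gridding (`interpolate_system_matrix()`) refines the calibration grid
per row by trilinear interpolation, real and imaginary parts
independently — exact for rows affine in position. `quantify_iron()` sums
the reconstructed concentration over a mask (default: a 5x5x5-voxel box
around the known position; the protocol's mask geometry is unstated) and
multiplies by the delta-sample mass.

# Perfusion maps

`perfusion_pipeline()` composes four fixed steps: (i) time framing — the
bolus arrival is the first frame where the global mean signal exceeds 10%
of its eventual peak (the detector threshold is a design choice), the
window opens 5 s earlier and closes when the global signal stays below a
2% zero band; (ii) a voxel-wise frequency-domain Hann low-pass: temporal
bins 1..10 tapered by $\tfrac12(1+\cos \pi b/10)$, DC zeroed (removing
the concentration offset), higher bins discarded; (iii) a 10% threshold
mask; (iv) the maps. TTP is the frame-grid peak time relative to the
reference; MTT is the full width at half maximum with sub-frame linear
interpolation (voxels whose curve never crosses half maximum are marked
invalid, not extrapolated); rCBF is the *value* of the steepest positive
temporal gradient — the method description's formula (`argmax`) literally
returns a time, but its prose equates rCBF with the gradient itself, and
only the value behaves like a flow surrogate; rCBV is the trapezoidal area
under the positive curve. rCBF and rCBV are normalized to the volume
maximum. The default TTP reference is the detected arrival (matching the
usual display convention); for cross-experiment batteries a common
injection-time reference (`align_t0 = FALSE`) avoids frame-grid
quantization of per-experiment arrival detection.

# The perfusion phantom generator

`make_perfusion_phantom()` emulates two 50 mL glass-sphere-filled
cylinders perfused independently at 100 mL/min reference flow, with
stenosis expressed as a flow reduction of the left side and a 100 uL,
28 mg/mL bolus (2.8 mg iron). Per-voxel curves follow indicator-dilution
theory: a shared gamma-variate arterial input
($t_0 = 6$ s, $\alpha = 3$, $t_p = 2$ s) convolved with an exponential
residue $\exp(-t/\mathrm{MTT})$, $\mathrm{MTT} = V_{eff}/F$, evaluated on
an 8x-fine internal grid with a midpoint-rule kernel so the central volume
theorem holds to better than 1%. $V_{eff}$, the tracer-accessible pore
volume, defaults to 5 mL: dense sphere packings leave roughly a third of
the cylinder as pore space and only part of it is actively perfused; the
value is fixed once so that the full bolus passage — including the 75%
stenosis level, whose MTT reaches ~12 s — completes within the 150-frame
(37.2 s) acquisition. Injected iron splits between hemispheres in
proportion to flow and is conserved. Mild per-voxel arrival jitter
(uniform, 0.6 s, seeded) stands in for intra-phantom heterogeneity.

What the generator does *not* emulate: field imperfections (the ideal
gradient is used, so shift-invariance is exact rather than approximate),
particle relaxation (Néel/Brown dynamics), receive transfer functions,
coil-geometry sensitivities, scanner drift and structured background.
Consequently, passing tests demonstrate the correctness and internal
consistency of the processing chain under its stated model — not the
hardware-dependent performance figures of a physical scanner, whose
resolution and detection limits depend on exactly the effects excluded
here. The characterization protocols therefore assert orderings and
monotonicity, never absolute millimetre or microgram values.

# Desk scale and numerical choices

Simulation-level tests run a reduced sequence — decimation 256 (488 kHz
sampling), 17 patches, calibration grid 9x9x5 over the full
140x110x100 mm³ volume — which preserves every timing invariant exactly
while keeping a full calibration at a few seconds; the full-scale
sequence is exercised wherever only timing algebra is involved.
Noise-free round trips use $\lambda_{L2} = 10^{-6}$ and 100 sweeps;
noisy reconstructions typically want $10^{-3}$–$10^{-2}$ and 10–20
sweeps. Other numerical choices: periodic central differences for the
induced voltage (4x oversampling keeps the derivative error of the
highest retained harmonic below 1%); FWHM crossings by linear
interpolation; TTP ties resolve to the earliest frame; background
subtraction uses the nearest preceding background block; the container
stores complex data natively via R serialization with a versioned schema,
and volumes/maps export to NIfTI.

# Known limitations

* The trajectory-gap value depends on a convention the field has not
  standardized; the package documents and tests one convention and exposes
  the node set for any other.
* Multi-patch reconstruction treats each patch's FFT bins as rows of one
  joint system; it does not exploit the shift-invariant block structure
  computationally.
* The simulator's particle model is equilibrium-only; spectra of real
  tracers differ in phase and high-harmonic decay.
* Absolute CBF/CBV are out of scope (no arterial input function), as in
  the underlying protocol; maps are relative by construction.
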