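# Shared desk-scale fixtures, built once per test session. The desk-scale
# study conditions are: decimation 256 (sampling 488 kHz), 17 patches per
# frame, calibration grid 9 x 9 x 5 over 140 x 110 x 100 mm^3.

.fixtures <- new.env(parent = emptyenv())

desk_seq <- function() {
  if (is.null(.fixtures$seq)) .fixtures$seq <- desk_sequence()
  .fixtures$seq
}

# noise-free single-patch desk system matrix (shared; expensive to build)
desk_sm <- function() {
  if (is.null(.fixtures$sm)) {
    .fixtures$sm <- simulate_system_matrix(desk_seq(),
                                           grid = recon_grid(c(9, 9, 5)),
                                           max_rows = 1500, seed = 1L)
  }
  .fixtures$sm
}

# reconstruct a phantom frame against the shared desk system matrix
desk_recon <- function(ph, lambda_l2 = 1e-6, iterations = 100, ...) {
  sm <- desk_sm()
  mf <- simulate_frame(ph, desk_seq(), warn_fov = FALSE)
  u <- measurement_rows(sm, mf)
  kaczmarz_solve(sm, u, lambda_l2 = lambda_l2, iterations = iterations, ...)
}

# synthetic band-limited solid-harmonic field with known coefficients
random_shf <- function(L = 6, radius = 45, seed = 3) {
  set.seed(seed)
  co <- matrix(stats::rnorm(3 * (L + 1)^2), (L + 1)^2, 3)
  structure(list(coefficients = co, L = L, radius = radius,
                 center = c(0, 0, 0)),
            class = "shf_field")
}
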