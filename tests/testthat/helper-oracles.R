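# Independent numeric oracles used by the tests. They never call the code
# paths they validate: widths come from dense evaluation / root finding on
# the analytic curves, areas from an independent trapezoid implementation.

# brute-force FWHM of an arbitrary sampled curve (dense grid assumed)
oracle_fwhm_samples <- function(t, y) {
  y <- pmax(y, 0)
  M <- max(y)
  if (M <= 0) return(NA_real_)
  above <- which(y >= M / 2)
  t[max(above)] - t[min(above)]
}

# brute-force FWHM of a gamma-variate on a 1e-4 s grid
oracle_gamma_fwhm <- function(tp, alpha, t0 = 0, span = 40) {
  t <- seq(t0, t0 + span * tp, by = 1e-4)
  x <- pmax(t - t0, 0) / tp
  oracle_fwhm_samples(t, x^alpha * exp(alpha * (1 - x)))
}

# tic construction shortcut
make_tic <- function(times, values) {
  structure(list(times = times, values = values, source = "test"),
            class = "tic")
}

# small stack builder: values is a 3D array already in concentration
# convention
make_stack <- function(values, dt = 0.5, bit_depth = 8L) {
  frame_stack(values, dt, bit_depth = bit_depth)
}
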