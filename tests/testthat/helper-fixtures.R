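# shared fixtures: the resting-state P450 heme-domain CW parameters and the
# X-band acquisition window used throughout the suite

resting_sys <- function() {
  spin_system(c(2.44, 2.25, 1.92), gstrain = c(0.040, 0.0080, 0.010), lw_mT = 2)
}

xband_exp <- function(n_points = 1024L,
                      harmonic = c("first_derivative", "absorption")) {
  experiment_cw(9.68, 200, 420, n_points = n_points,
                harmonic = match.arg(harmonic))
}

# trapezoid integral of a spectrum1d
trapz_spec <- function(sp) {
  dB <- sp$field_mT[2] - sp$field_mT[1]
  y <- sp$intensity
  sum((y[-1] + y[-length(y)]) / 2) * dB
}

# random physically ordered coefficient triples (a >= b >= c >= 0)
random_coefficients <- function(n, seed) {
  set.seed(seed)
  a <- stats::runif(n, 0.85, 1.15)
  u <- stats::runif(n, 0, 0.3)
  v <- stats::runif(n, 0, 0.3)
  data.frame(a = a, b = pmax(u, v), c = pmin(u, v))
}
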