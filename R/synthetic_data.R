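#' Generate a noisy CW powder spectrum
#'
#' Wraps [simulate_cw()] with an optional linear baseline ramp and
#' additive white Gaussian noise whose RMS is expressed relative to the
#' maximum absolute intensity of the clean spectrum. Fully reproducible:
#' the seed is mandatory.
#'
#' @param sys A [spin_system].
#' @param exp An [experiment_cw].
#' @param noise_rms Noise RMS relative to max|clean| (>= 0).
#' @param ramp Length-2 numeric `c(intercept, slope)` of a linear baseline
#'   added across the sweep (in clean-spectrum intensity units; the slope
#'   applies to a 0..1 normalized field coordinate).
#' @param seed Integer RNG seed (required).
#' @param n_orientations Passed to [simulate_cw()].
#' @return A [spectrum1d]; its `meta$clean` holds the noise-free trace.
#' @export
#' @examples
#' sys <- spin_system(c(2.44, 2.25, 1.92), c(0.040, 0.0080, 0.010), 2)
#' ex <- experiment_cw(9.68, 200, 420, 1024)
#' sp <- make_cw(sys, ex, noise_rms = 0.01, seed = 42)
make_cw <- function(sys, exp, noise_rms = 0.01, ramp = c(0, 0), seed,
                    n_orientations = 2000L) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (noise_rms < 0) stop("noise_rms must be >= 0", call. = FALSE)
  clean <- simulate_cw(sys, exp, n_orientations = n_orientations)
  scale <- max(abs(clean$intensity))
  x01 <- seq(0, 1, length.out = length(clean$field_mT))
  y <- clean$intensity + ramp[1] + ramp[2] * x01
  if (noise_rms > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), sd = noise_rms * scale)
  }
  spectrum1d(clean$field_mT, y,
             meta = c(clean$meta,
                      list(clean = clean$intensity, seed = seed,
                           noise_rms = noise_rms, ramp = ramp)))
}

#' Generate a 2D HYSCORE time trace
#'
#' Sum over correlated frequency pairs of exponentially decaying cosine
#' products A cos(2 pi nu1 t1 + phase) cos(2 pi nu2 t2 + phase)
#' exp(-(t1 + t2)/decay), plus a DC offset and white Gaussian noise. This
#' mimics the statistical structure of a 4-pulse HYSCORE trace well enough
#' to exercise the full processing chain; it is not a density-matrix
#' amplitude simulation.
#'
#' @param pairs Two-column matrix of correlated frequencies (MHz), one row
#'   per pair.
#' @param amps Amplitude per pair (recycled).
#' @param decay_ns Exponential decay constant, ns.
#' @param dwell_ns Dwell time of both axes, ns (16 or 24 in the
#'   experiments emulated here).
#' @param n_points Points per axis.
#' @param tau_ns tau of the pulse sequence, ns (stored in metadata; when
#'   `blind_spots = TRUE` the amplitudes are scaled by
#'   sin^2(pi nu1 tau) sin^2(pi nu2 tau)).
#' @param dc Constant offset.
#' @param phase Phase of the cosines, rad.
#' @param noise_rms Noise RMS relative to the maximum clean amplitude.
#' @param blind_spots Apply the tau suppression factor?
#' @param seed Integer RNG seed (required).
#' @param field_mT,mw_freq_GHz Observer metadata, stored only.
#' @return A time-domain [hyscore_map].
#' @export
#' @examples
#' tr <- make_hyscore_trace(pairs = cbind(7.43, 16.73), seed = 7)
make_hyscore_trace <- function(pairs, amps = 1, decay_ns = 800,
                               dwell_ns = 16, n_points = 128L, tau_ns = 208,
                               dc = 0, phase = 0, noise_rms = 0.01,
                               blind_spots = FALSE, seed,
                               field_mT = 283.8, mw_freq_GHz = 9.68) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  pairs <- matrix(pairs, ncol = 2L)   # zero rows = DC-only trace
  nyq <- 1e3 / (2 * dwell_ns)
  if (nrow(pairs) && any(pairs > nyq)) {
    stop(sprintf("frequency above the Nyquist limit %.2f MHz for dwell %g ns",
                 nyq, dwell_ns), call. = FALSE)
  }
  amps <- rep_len(amps, nrow(pairs))
  t1 <- (seq_len(n_points) - 1) * dwell_ns
  t2 <- t1
  m <- matrix(dc, n_points, n_points)
  decay <- outer(exp(-t1 / decay_ns), exp(-t2 / decay_ns))
  for (i in seq_len(nrow(pairs))) {
    a <- amps[i]
    if (blind_spots) {
      a <- a * sin(pi * pairs[i, 1] * tau_ns * 1e-3)^2 *
        sin(pi * pairs[i, 2] * tau_ns * 1e-3)^2
    }
    m <- m + a * outer(cos(2 * pi * pairs[i, 1] * t1 * 1e-3 + phase),
                       cos(2 * pi * pairs[i, 2] * t2 * 1e-3 + phase)) * decay
  }
  if (noise_rms > 0) {
    set.seed(as.integer(seed))
    m <- m + stats::rnorm(length(m), sd = noise_rms * max(abs(amps), 1e-12))
  }
  hyscore_map(t1, t2, m, domain = "time",
              meta = list(field_mT = field_mT, mw_freq_GHz = mw_freq_GHz,
                          tau_ns = tau_ns, dwell_ns = dwell_ns,
                          pairs = pairs, seed = seed))
}

#' Write a reproducible suite of fixture files
#'
#' Generates, from one seed, the small file set the I/O and fitting layers
#' are validated against: a 1D CW spectrum in BES3T form in both byte
#' orders, a 2D HYSCORE time trace in BES3T (real and complex variants),
#' ASCII twins of both, the packaged g-tensor table, and a manifest with
#' MD5 checksums.
#'
#' @param outdir Writable output directory (created if absent).
#' @param seed Integer RNG seed.
#' @return Data frame manifest (file, md5), invisibly written to
#'   `MANIFEST.txt` as well.
#' @export
make_fixture_suite <- function(outdir, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sys <- spin_system(c(2.44, 2.25, 1.92), c(0.040, 0.0080, 0.010), lw_mT = 2)
  ex <- experiment_cw(9.68, 200, 420, n_points = 1024L)
  cw <- make_cw(sys, ex, noise_rms = 0.01, seed = seed, n_orientations = 800L)
  ds_cw <- epr_dataset(list(list(values = cw$field_mT, unit = "mT", name = "B0")),
                       cw$intensity)
  write_bes3t(ds_cw, file.path(outdir, "cw_big"), endian = "big")
  write_bes3t(ds_cw, file.path(outdir, "cw_little"), endian = "little")
  write_ascii(ds_cw, file.path(outdir, "cw.txt"))

  tr <- make_hyscore_trace(pairs = cbind(7.43, 16.73), n_points = 128L,
                           dwell_ns = 16, tau_ns = 250, noise_rms = 0.01,
                           seed = seed + 1L)
  ds_hy <- epr_dataset(list(list(values = tr$axis1, unit = "ns", name = "t1"),
                            list(values = tr$axis2, unit = "ns", name = "t2")),
                       tr$values)
  write_bes3t(ds_hy, file.path(outdir, "hyscore_2d"), endian = "big")
  write_ascii(ds_hy, file.path(outdir, "hyscore_2d.txt"))
  ds_cplx <- epr_dataset(ds_hy$axes, tr$values + 0.25i * tr$values)
  write_bes3t(ds_cplx, file.path(outdir, "hyscore_2d_cplx"), endian = "big")

  gtab_src <- system.file("extdata", "cw_gtensor_table.csv", package = "hemeEPR")
  file.copy(gtab_src, file.path(outdir, "gtensor_table.csv"), overwrite = TRUE)

  files <- sort(setdiff(list.files(outdir), "MANIFEST.txt"))
  md5 <- unname(tools::md5sum(file.path(outdir, files)))
  manifest <- data.frame(file = files, md5 = md5, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "MANIFEST.txt"),
                     row.names = FALSE, quote = FALSE, sep = "\t")
  manifest
}
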