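test_that("proton Larmor frequency follows the nuclear Zeeman closed form", {
  expect_equal(larmor_frequency(350, "1H"), 14.902, tolerance = 2e-4)
  expect_equal(larmor_frequency(283.8, "1H"), 12.08, tolerance = 5e-4)
  expect_identical(larmor_frequency(0, "1H"), 0)
  expect_error(larmor_frequency(350, "57Fe"), "1H")
})

test_that("nuclear frequencies reproduce the secular/pseudo-secular formulas", {
  nu_I <- larmor_frequency(283.8, "1H")
  # the fitted proton coupling, evaluated along the unique axis
  nf <- nuclear_frequencies(hyperfine_coupling(-1.095, 5.20), nu_I, 0)
  expect_equal(nf$nu_alpha_MHz, 7.43, tolerance = 1e-3)
  expect_equal(nf$nu_beta_MHz, 16.73, tolerance = 1e-3)

  # isotropic limit: B = 0, exact split by aiso
  a <- 3.7
  nfi <- nuclear_frequencies(hyperfine_coupling(a, 0), nu_I, runif(1, 0, pi / 2))
  expect_equal(nfi$nu_alpha_MHz, abs(nu_I - a / 2), tolerance = 1e-12)
  expect_equal(nfi$nu_beta_MHz, nu_I + a / 2, tolerance = 1e-12)
  # ... and negating aiso swaps the two manifolds exactly
  nfn <- nuclear_frequencies(hyperfine_coupling(-a, 0), nu_I, 0.3)
  expect_equal(nfn$nu_alpha_MHz, nfi$nu_beta_MHz, tolerance = 1e-12)
  expect_equal(nfn$nu_beta_MHz, nfi$nu_alpha_MHz, tolerance = 1e-12)

  # magic angle with aiso = 0: secular part cancels, both roots coincide
  T <- 5.20
  thm <- acos(1 / sqrt(3))
  nfm <- nuclear_frequencies(hyperfine_coupling(0, T), nu_I, thm)
  bm <- 3 * T * sin(thm) * cos(thm)
  expect_equal(nfm$nu_alpha_MHz, sqrt(nu_I^2 + (bm / 2)^2), tolerance = 1e-12)
  expect_equal(nfm$nu_alpha_MHz, nfm$nu_beta_MHz, tolerance = 1e-12)
})

test_that("correlation ridge is continuous, mirrored and anchored", {
  nu_I <- 12.08
  hfc <- hyperfine_coupling(-1.095, 5.20, beta_deg = 22)
  rc <- ridge_curve(hfc, nu_I, n_theta = 181)
  expect_identical(nrow(rc), 362L)
  ab <- rc[rc$branch == "alpha_beta", ]
  ba <- rc[rc$branch == "beta_alpha", ]
  expect_identical(ab$nu1_MHz, ba$nu2_MHz)

  # endpoints equal the closed-form frequencies at theta = 0 and pi/2
  e0 <- nuclear_frequencies(hfc, nu_I, 0)
  e9 <- nuclear_frequencies(hfc, nu_I, pi / 2)
  expect_equal(ab$nu1_MHz[1], e0$nu_alpha_MHz, tolerance = 1e-12)
  expect_equal(ab$nu2_MHz[nrow(ab)], e9$nu_beta_MHz, tolerance = 1e-12)

  # smoothness: adjacent jumps bounded relative to the swept span
  for (col in c("nu1_MHz", "nu2_MHz")) {
    span <- diff(range(ab[[col]]))
    expect_lt(max(abs(diff(ab[[col]]))), 5 / nrow(ab) * max(span, 1))
  }

  # zero dipolar coupling collapses each branch to a single point
  rc0 <- ridge_curve(hyperfine_coupling(-1.095, 0), nu_I, n_theta = 50)
  for (br in split(rc0, rc0$branch)) {
    expect_equal(diff(range(br$nu1_MHz)), 0, tolerance = 1e-12)
    expect_equal(diff(range(br$nu2_MHz)), 0, tolerance = 1e-12)
  }
})

test_that("ridge apex shift matches second-order theory at weak coupling", {
  nu_I <- 12.08
  # 9 T^2 / (32 nu_I) is a second-order result; verify where it is valid
  for (T in c(0.3, 0.5, 1.0)) {
    shift <- ridge_apex_shift(hyperfine_coupling(-1.095, T), nu_I)
    expect_equal(shift, 9 * T^2 / (32 * nu_I), tolerance = 0.01)
  }
})

test_that("blind-spot and orientation-selection weights behave", {
  nu_I <- 12.08
  hfc <- hyperfine_coupling(-1.095, 5.20, beta_deg = 22)
  rc <- ridge_curve(hfc, nu_I, n_theta = 91, tau_ns = 250)
  expect_true(all(rc$weight >= 0 & rc$weight <= 1))
  # suppression exactly at nu = k/tau: a frequency of 4 MHz with tau 250 ns
  w <- sin(pi * 4 * 0.250)^2
  expect_equal(w, 0, tolerance = 1e-12)
  rs <- ridge_curve(hfc, nu_I, n_theta = 91, orientation_select = TRUE)
  expect_equal(which.max(rs$weight[1:91]),
               which.min(abs(seq(0, pi / 2, length.out = 91) - 22 * pi / 180)))
})

test_that("point-dipole distance inverts the dipolar coupling", {
  # prefactor built from constants: (mu0/4 pi h) ge be gn bn = 79.06 MHz A^3
  expect_equal(dipolar_from_distance(1), 79.06, tolerance = 1e-3)
  expect_equal(round(point_dipole_distance(5.20), 2), 2.48)
  T248 <- dipolar_from_distance(2.48)
  expect_gt(T248, 5.18); expect_lt(T248, 5.22)
  r <- c(0.8, 1.7, 2.48, 5.3)
  expect_equal(point_dipole_distance(dipolar_from_distance(r)), r,
               tolerance = 1e-12)
  expect_true(all(diff(dipolar_from_distance(seq(1, 10, by = 0.5))) < 0))
  expect_error(point_dipole_distance(0), "T_MHz")
  expect_error(dipolar_from_distance(-1), "r_A")
})

test_that("hyscore processing localizes a known correlation peak", {
  t <- (0:127) * 16
  m <- outer(cos(2 * pi * 7.4e-3 * t), cos(2 * pi * 16.7e-3 * t)) *
    outer(exp(-t / 900), exp(-t / 900))
  raw <- hyscore_map(t, t, m, domain = "time")
  sp <- process_hyscore(raw)
  expect_s3_class(sp, "hyscore_map")
  expect_identical(sp$domain, "frequency")
  pk <- which(sp$values == max(sp$values), arr.ind = TRUE)
  df <- sp$axis1[2] - sp$axis1[1]
  expect_lt(abs(sp$axis1[pk[1]] - 7.4), df + 1e-9)
  expect_lt(abs(sp$axis2[pk[2]] - 16.7), df + 1e-9)

  # all-zero input stays zero; DC is absorbed by the cubic baseline
  z <- process_hyscore(hyscore_map(t, t, matrix(0, 128, 128), domain = "time"))
  expect_identical(max(z$values), 0)
  dc <- process_hyscore(hyscore_map(t, t, matrix(3.2, 128, 128), domain = "time"))
  expect_lt(max(dc$values), 1e-8)
})

test_that("processing chain is linear and energy-conserving pre-magnitude", {
  t <- (0:63) * 16
  set.seed(9)
  m1 <- matrix(rnorm(64^2), 64, 64)
  m2 <- outer(cos(2 * pi * 5e-3 * t), cos(2 * pi * 9e-3 * t))
  p <- function(m, ...) process_hyscore(hyscore_map(t, t, m, domain = "time"),
                                        output = "complex", ...)$values
  expect_equal(p(m1 + m2), p(m1) + p(m2), tolerance = 1e-10)

  # Parseval on the windowed, baseline-corrected, zero-filled transform
  mb <- hemeEPR:::.poly_baseline_rows(m2, 3)
  mb <- t(hemeEPR:::.poly_baseline_rows(t(mb), 3))
  mw <- mb * outer(hemeEPR:::.hamming(64), hemeEPR:::.hamming(64))
  ft <- p(m2)
  expect_equal(sum(abs(ft)^2) / prod(dim(ft)), sum(mw^2), tolerance = 1e-10)
})

test_that("processing rejects malformed input", {
  t <- (0:31) * 16
  m <- matrix(0, 32, 32)
  expect_error(process_hyscore(hyscore_map(c(t[-32], 600), t, m, domain = "time")),
               "dwell")
  expect_error(process_hyscore(hyscore_map(t, t, m, domain = "time"),
                               baseline_order = 32), "baseline_order")
  fr <- hyscore_map(1:4, 1:4, matrix(1, 4, 4), domain = "frequency")
  expect_error(process_hyscore(fr), "time-domain")
  expect_error(hyscore_map(1:4, 1:4, matrix(-1, 4, 4), domain = "frequency"),
               "non-negative")
})
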