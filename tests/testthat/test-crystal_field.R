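test_that("g-tensor construction enforces positivity, ordering and sigmas", {
  g <- gtensor(2.44, 2.25, 1.92, sigma = c(0.005, 0.002, 0.002), label = "x")
  expect_s3_class(g, "gtensor")
  expect_identical(c(g$gz, g$gy, g$gx), c(2.44, 2.25, 1.92))
  expect_warning(g2 <- gtensor(1.92, 2.44, 2.25), "reordered")
  expect_identical(c(g2$gz, g2$gy, g2$gx), c(2.44, 2.25, 1.92))
  expect_error(gtensor(-2, 2, 2), "positive")
  expect_error(gtensor(2.4, 2.2, 1.9, sigma = c(-0.1, 0, 0)), "non-negative")
})

test_that("orbital coefficients reproduce the one-hole inversion", {
  # resting-state heme domain: published a/b reproduced at 3 decimals;
  # c and m^2 follow the inversion formula, not the (internally
  # inconsistent) printed cells
  co <- coefficients_from_g(c(2.440, 2.25, 1.92))
  expect_equal(round(co$a, 3), 0.996)
  expect_equal(round(co$b, 3), 0.110)
  expect_equal(co$c, 0.33 / sqrt(8 * 2.77), tolerance = 1e-12)
  expect_equal(co$m_squared, co$a^2 + co$b^2 + co$c^2, tolerance = 1e-15)

  # independent hand evaluation for the reference protein
  co2 <- coefficients_from_g(c(2.418, 2.26, 1.92))
  expect_equal(co2$a, 0.99591, tolerance = 1e-4)
  expect_equal(co2$b, 0.10602, tolerance = 1e-4)
  expect_equal(co2$c, 0.07238, tolerance = 1e-4)
  expect_equal(co2$m_squared, 1.00831, tolerance = 1e-4)

  # isotropic closed form: a = sqrt(g0/2), b = c = 0
  for (g0 in c(2, 2.0023, 2.2)) {
    coi <- coefficients_from_g(c(g0, g0, g0))
    expect_equal(coi$a, sqrt(g0 / 2), tolerance = 1e-14)
    expect_identical(coi$b, 0)
    expect_identical(coi$c, 0)
  }

  # unsorted input is canonicalized (with a warning) before inversion
  expect_warning(co3 <- coefficients_from_g(c(1.92, 2.25, 2.440)), "reordered")
  expect_identical(co3, co)
})

test_that("forward map matches hand evaluation and inverts exactly", {
  g <- g_from_coefficients(1, 0, 0)
  expect_equal(c(g$gz, g$gy, g$gx), c(2, 2, 2), tolerance = 1e-15)

  g2 <- g_from_coefficients(0.9964, 0.1105, 0.0701)
  expect_equal(c(g2$gz, g2$gy, g2$gx), c(2.440, 2.250, 1.920), tolerance = 1e-3)

  g3 <- g_from_coefficients(0.99, 0.10, 0.10)   # b = c forces gz = gy
  expect_equal(c(g3$gz, g3$gy, g3$gx), c(2.3562, 2.3562, 1.8802),
               tolerance = 1e-12)

  expect_error(g_from_coefficients(0, 0, 0), "invalid coefficients")
})

test_that("coefficient -> g -> coefficient round trip is algebraically exact", {
  tr <- random_coefficients(1000, seed = 101)
  for (i in seq_len(nrow(tr))) {
    co <- coefficients_from_g(g_from_coefficients(tr$a[i], tr$b[i], tr$c[i]))
    expect_equal(co$a, tr$a[i], tolerance = 1e-12)
    expect_equal(co$b, tr$b[i], tolerance = 1e-12)
    expect_equal(co$c, tr$c[i], tolerance = 1e-12)
  }
  # normalized triples recover m^2 = 1 exactly
  n <- sqrt(tr$a^2 + tr$b^2 + tr$c^2)
  for (i in seq_len(50)) {
    co <- coefficients_from_g(
      g_from_coefficients(tr$a[i] / n[i], tr$b[i] / n[i], tr$c[i] / n[i]))
    expect_equal(co$m_squared, 1, tolerance = 1e-12)
  }
})

test_that("crystal-field ratios reproduce the published analysis", {
  cf <- crystal_field_ratios(c(2.440, 2.25, 1.92))
  expect_equal(round(cf$v_over_xi, 2), 4.74)
  expect_equal(round(cf$delta_over_xi, 2), 5.44)
  expect_equal(round(cf$rhombicity, 2), 0.87)

  # histidine adduct, g-values from the CW simulation table
  expect_equal(round(crystal_field_ratios(c(2.42, 2.24, 1.92))$v_over_xi, 2),
               4.89)

  # absolute energies with the free-iron spin-orbit constant
  cfa <- crystal_field_ratios(c(2.440, 2.25, 1.92), xi = 400)
  expect_equal(cfa$v_abs, 1894.5, tolerance = 1e-3)
  expect_equal(cfa$delta_abs, 2174.1, tolerance = 1e-3)

  expect_error(crystal_field_ratios(c(2.4, 2.0, 2.0)), "gy - gx")
  expect_error(crystal_field_ratios(c(2.0, 2.0, 2.0)), "degenerate")
})

test_that("ratio invariants hold across the physical g range", {
  set.seed(77)
  for (i in 1:200) {
    gx <- runif(1, 1.7, 2.0)
    gy <- gx + runif(1, 0.05, 0.5)
    gz <- gy + runif(1, 0.001, 0.5)
    cf <- crystal_field_ratios(c(gz, gy, gx))
    expect_equal(cf$rhombicity * cf$delta_over_xi, cf$v_over_xi,
                 tolerance = 1e-12)
  }
  # V/xi decreases with gz at fixed gy, gx (seen across the measured range)
  gz_grid <- seq(2.40, 2.50, by = 0.005)
  v <- vapply(gz_grid,
              function(gz) crystal_field_ratios(c(gz, 2.25, 1.92))$v_over_xi,
              numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("uncertainty propagation follows the chosen rule", {
  g <- gtensor(2.440, 2.25, 1.92, sigma = c(0.005, 0.002, 0.002))
  lin <- propagate_uncertainties(g, method = "linear_sum")
  # analytic partials at this point: |dV/dgz| = 8.408, |dV/dgy| = 1.836,
  # |dV/dgx| = 8.534, dotted with the sigmas
  expect_equal(lin$sigma_v, 0.06278, tolerance = 1e-3)

  quad <- propagate_uncertainties(g, method = "quadrature")
  expect_lt(quad$sigma_v, lin$sigma_v)

  g0 <- gtensor(2.440, 2.25, 1.92, sigma = c(0, 0, 0))
  for (m in c("linear_sum", "quadrature")) {
    p <- propagate_uncertainties(g0, method = m)
    expect_identical(c(p$sigma_v, p$sigma_delta, p$sigma_rhombicity), c(0, 0, 0))
  }
  p0 <- propagate_uncertainties(g0, method = "monte_carlo", seed = 1)
  expect_identical(c(p0$sigma_v, p0$sigma_delta, p0$sigma_rhombicity), c(0, 0, 0))

  m1 <- propagate_uncertainties(g, method = "monte_carlo", seed = 42)
  m2 <- propagate_uncertainties(g, method = "monte_carlo", seed = 42)
  expect_identical(m1$sigma_v, m2$sigma_v)
  expect_error(propagate_uncertainties(g, method = "monte_carlo"), "seed")
  expect_error(propagate_uncertainties(g, method = "monte_carlo",
                                       seed = 1, n_draws = 10), "1000")
})

test_that("quadrature never exceeds the linear worst case", {
  set.seed(55)
  for (i in 1:100) {
    gx <- runif(1, 1.7, 2.0)
    gy <- gx + runif(1, 0.05, 0.5)
    gz <- gy + runif(1, 0.01, 0.5)
    g <- gtensor(gz, gy, gx, sigma = runif(3, 0, 0.01))
    lin <- propagate_uncertainties(g, method = "linear_sum")
    quad <- propagate_uncertainties(g, method = "quadrature")
    expect_lte(quad$sigma_v, lin$sigma_v + 1e-15)
    expect_lte(quad$sigma_delta, lin$sigma_delta + 1e-15)
    expect_lte(quad$sigma_rhombicity, lin$sigma_rhombicity + 1e-15)
  }
})

test_that("batch analysis reports per-row results and isolates failures", {
  path <- system.file("extdata", "cw_gtensor_table.csv", package = "hemeEPR")
  df <- read_gtensor_table(path)
  expect_identical(nrow(df), 5L)

  rep <- analyze_table(df)
  expect_identical(nrow(rep), 5L)
  expect_identical(rep$label[1], "CYP116B5hd")
  expect_true(all(rep$status == "ok"))
  r1 <- format_analysis_table(rep)[1, ]
  expect_equal(r1$V_xi, 4.74)
  expect_equal(r1$Delta_xi, 5.44)
  expect_equal(r1$V_Delta, 0.87)
  expect_equal(r1$a, 0.996)
  expect_equal(r1$b, 0.110)
  expect_equal(r1$dV_xi, 0.06)

  # degenerate row flagged, valid rows unaffected
  rows <- list(gtensor(2.44, 2.25, 1.92, sigma = c(0.005, 0.002, 0.002)),
               gtensor(2.2, 2.0, 2.0, label = "degenerate"),
               gtensor(2.42, 2.24, 1.92, sigma = c(0.005, 0.002, 0.002)))
  rep2 <- analyze_table(rows)
  expect_identical(rep2$status[c(1, 3)], c("ok", "ok"))
  expect_match(rep2$status[2], "degenerate")
  expect_true(is.na(rep2$V_xi[2]))

  expect_error(analyze_table(list()), "at least one")
})

test_that("analysis reports round-trip through CSV and JSON", {
  rep <- analyze_table(read_gtensor_table(
    system.file("extdata", "cw_gtensor_table.csv", package = "hemeEPR")))
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_analysis_report(rep, csv, format = "csv")
  write_analysis_report(rep, json, format = "json")
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_identical(names(back)[1:14],
                   c("label", "gz", "gy", "gx", "a", "b", "c", "m2",
                     "V_xi", "dV_xi", "Delta_xi", "dDelta_xi",
                     "V_Delta", "dV_Delta"))
  expect_equal(back$V_xi[1], 4.74)
  jb <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(jb$V_xi[1], 4.74)
})
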