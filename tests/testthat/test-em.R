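test_that("a matched straight coax reflects almost nothing and a shorted one totally", {
  sol <- em_solve(coax_mesh("exterior"), coax_materials(), 2.45e9, input_power = 10)
  expect_lt(Mod(sol$gamma_complex), 0.05)
  # all incident power leaves through the matched end (lossless line)
  expect_equal(sol$radiated_power, 10, tolerance = 0.02)
  expect_equal(sol$absorbed_power, 0)

  short <- em_solve(coax_mesh("pec"), coax_materials(), 2.45e9, input_power = 10)
  expect_equal(Mod(short$gamma_complex), 1, tolerance = 1e-3)
})

test_that("reflection_db and swr_from_gamma implement their definitions", {
  expect_equal(reflection_db(10, 10), 0)
  expect_equal(reflection_db(10, 2.5), -6.0206, tolerance = 1e-4)
  expect_equal(reflection_db(10, 0), -Inf)
  expect_error(reflection_db(10, 11), "passive")
  expect_error(reflection_db(0, 0), "p_in")

  expect_equal(swr_from_gamma(0), 1)
  expect_equal(swr_from_gamma(0.3031), 1.87, tolerance = 1e-3)
  expect_equal(swr_from_gamma(0.5), 3)
  expect_error(swr_from_gamma(1), "gamma_mag")
  expect_error(swr_from_gamma(-0.1), "gamma_mag")
})

test_that("SAR is sigma/(2 rho)|E|^2, zero in lossless regions, and mass-integrates to the absorbed power", {
  m <- rect_mesh(0.01, 0.02, 0, 0.01, 2, 2, region = "tissue")
  fake <- structure(
    list(
      E_r = rep(complex(real = 100), nrow(m$tri)),
      E_z = rep(complex(real = 0), nrow(m$tri)),
      mesh = m
    ),
    class = "abl_em"
  )
  mat <- list(tissue = material_properties("t",
    eps_r = 5, sigma = 1,
    k_thermal = 0.5, density = 1000, heat_capacity = 3500
  ))
  sar <- compute_sar(fake, mat)
  expect_equal(unique(sar$sar), 5) # 1/(2*1000) * 100^2

  lossless <- list(tissue = material_properties("l",
    eps_r = 5, sigma = 0,
    k_thermal = 0.5, density = 1000, heat_capacity = 3500
  ))
  expect_true(all(compute_sar(fake, lossless)$sar == 0))

  # on a real solve, volume-integrated rho*SAR reproduces the dissipation
  run <- full_run("breast_only")
  expect_equal(
    mwablate:::sar_total_power(run$sar),
    run$em$absorbed_power,
    tolerance = 0.02
  )
})

test_that("power balance closes within 2 percent and |gamma| <= 1 on scenario solves", {
  for (kind in c("breast_only", "tumor_in_breast")) {
    em <- full_run(kind)$em
    g <- Mod(em$gamma_complex)
    expect_lte(g, 1 + 1e-6)
    total <- em$reflected_power + em$absorbed_power + em$radiated_power
    expect_equal(total, em$input_power, tolerance = 0.02)
  }
})

test_that("the solve is linear in input power: SAR doubles, gamma is unchanged", {
  scn <- build_scenario("breast_only")
  mesh <- full_run("breast_only")$mesh
  em1 <- full_run("breast_only")$em
  scn2 <- build_scenario("breast_only", list(input_power = 20))
  em2 <- solve_harmonic(mesh, scn2)
  expect_equal(em2$gamma_complex, em1$gamma_complex, tolerance = 1e-10)
  expect_equal(em2$absorbed_power, 2 * em1$absorbed_power, tolerance = 1e-8)
  s1 <- compute_sar(em1, scn$region_materials)$sar
  s2 <- compute_sar(em2, scn2$region_materials)$sar
  nz <- s1 > 0
  expect_equal(unname(s2[nz] / s1[nz]), rep(2, sum(nz)), tolerance = 1e-8)
})

test_that("manufactured Bessel-mode solution converges at the P1 rate", {
  # u = J1(k r), k = k0 sqrt(eps): an exact interior solution; imposed on
  # the outer boundaries, compared (r-weighted L2) under refinement.
  err <- bessel_errors(c(16, 32))
  rate <- log2(err[1] / err[2])
  expect_gt(rate, 1.6) # expected ~2 for linear elements
})

test_that("frequency sweeps are consistent with single solves and keep SWR >= 1", {
  run <- full_run("breast_only")
  sw <- frequency_sweep(run$mesh, run$scenario, 2.4e9, 2.5e9, n_points = 3)
  expect_equal(sw$frequency[2], 2.45e9)
  expect_equal(sw$swr[2], swr_from_gamma(Mod(run$em$gamma_complex)),
    tolerance = 1e-12
  )
  expect_true(all(sw$swr >= 1))
  expect_true(all(sw$gamma_mag >= 0 & sw$gamma_mag <= 1))

  # matched line sweep: flat and nearly reflectionless across the band
  msw <- purrr::map_dbl(c(2e9, 2.75e9, 3.5e9), function(f) {
    Mod(em_solve(coax_mesh("exterior"), coax_materials(), f)$gamma_complex)
  })
  expect_true(all((1 + msw) / (1 - msw) < 1.11))

  expect_error(frequency_sweep(run$mesh, run$scenario, 2e9, 3e9, n_points = 1), "n_points")
  expect_error(frequency_sweep(run$mesh, run$scenario, 3e9, 2e9), "f_start")
})

test_that("solves without any excitation or port configuration fail loudly", {
  m <- rect_mesh(0.01, 0.02, 0, 0.01, 2, 2, region = "tissue")
  m$btag[] <- "pec"
  mat <- list(tissue = material_library()$breast)
  expect_error(em_solve(m, mat, 2.45e9), "port")
  m2 <- coax_mesh()
  expect_error(em_solve(m2, list(), 2.45e9), "no material")
})
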