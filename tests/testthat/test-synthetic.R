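test_that("dispersion curves anchor exactly at 2.45 GHz and have the measured shape", {
  tum <- dispersion_model("tumor")
  bre <- dispersion_model("breast")
  at <- dispersion_at(tum, 2.45e9)
  expect_equal(at$eps_r, 59.385)
  expect_equal(at$sigma, 3.156)
  atb <- dispersion_at(bre, 2.45e9)
  expect_equal(atb$eps_r, 5.1467)
  expect_equal(atb$sigma, 0.137)
  # permittivity decreasing, conductivity increasing across 2-3.5 GHz
  f <- seq(2e9, 3.5e9, length.out = 31)
  for (m in list(tum, bre)) {
    d <- dispersion_at(m, f)
    expect_true(all(diff(d$eps_r) < 0))
    expect_true(all(diff(d$sigma) > 0))
    expect_true(all(d$eps_r >= 1 & d$sigma >= 0))
  }
  # tumour properties are roughly tenfold the breast values at anchor
  expect_gt(at$eps_r / atb$eps_r, 10)
})

test_that("property draws are exact at cv = 0, reproducible, and calibrated in spread", {
  m <- dispersion_model("tumor")
  d0 <- sample_properties(m, cv = 0)
  expect_equal(d0$eps_r, 59.385)
  expect_equal(d0$sigma, 3.156)

  d1 <- sample_properties(m, cv = 0.1, seed = 42)
  d2 <- sample_properties(m, cv = 0.1, seed = 42)
  expect_identical(d1$sigma, d2$sigma)
  expect_identical(d1$eps_r, d2$eps_r)
  expect_error(sample_properties(m, cv = -0.1), "cv")

  # Monte-Carlo check of the mean-preserving lognormal parameterisation
  sig <- vapply(
    seq_len(1e4),
    function(s) sample_properties(m, cv = 0.1, seed = s)$sigma,
    numeric(1)
  )
  expect_equal(sd(sig) / mean(sig), 0.1, tolerance = 0.01)
  expect_equal(mean(sig), 3.156, tolerance = 0.01)
})

test_that("probe simulation applies lag, noise, clipping and quantisation", {
  tt <- seq(0, 10, by = 0.05)
  # zero noise, zero lag: identity (up to quantisation grid, which 1.25 hits)
  p0 <- probe_model(noise_sd = 0, tau = 0)
  out <- simulate_probe(tt, rep(1.25, length(tt)), p0)
  expect_equal(out$reading, rep(1.25, length(tt)))

  # range clip at the 120 C probe limit
  hot <- simulate_probe(tt, rep(130, length(tt)), p0)
  expect_true(all(hot$reading == 120))

  # first-order step response reaches 63.2 percent of the step at t = tau
  tau <- 0.25
  fine <- seq(0, 2, by = 0.005)
  step <- c(0, rep(100, length(fine) - 1))
  lag <- simulate_probe(fine, step, probe_model(noise_sd = 0, tau = tau))
  at_tau <- lag$reading[which.min(abs(fine - tau))]
  expect_equal(at_tau, 100 * (1 - exp(-1)), tolerance = 0.01)

  # noise is reproducible under seed and quantised to 0.01 C
  pn <- probe_model(noise_sd = 0.3, tau = 0)
  a <- simulate_probe(tt, 40 + sin(tt), pn, seed = 7)
  b <- simulate_probe(tt, 40 + sin(tt), pn, seed = 7)
  expect_identical(a$reading, b$reading)
  expect_true(all(abs(a$reading * 100 - round(a$reading * 100)) < 1e-9))
  expect_error(simulate_probe(c(0, 0, 1), c(1, 2, 3), pn), "increasing")
})

test_that("cv-perturbed tissue properties propagate through the full model", {
  # end-to-end: perturbed dielectrics give finite, scattered SWR; the cv = 0
  # member reproduces the deterministic run bit-for-bit
  base <- full_run("breast_only")
  m <- dispersion_model("breast")
  swrs <- purrr::map_dbl(1:3, function(s) {
    draw <- sample_properties(m, cv = 0.1, seed = s)
    scn <- build_scenario("breast_only", list(
      materials = list(breast = list(eps_r = draw$eps_r, sigma = draw$sigma))
    ))
    em <- solve_harmonic(base$mesh, scn)
    swr_from_gamma(Mod(em$gamma_complex))
  })
  expect_true(all(is.finite(swrs)) && all(swrs >= 1))
  expect_gt(diff(range(swrs)), 0) # perturbations actually move the answer

  d0 <- sample_properties(m, cv = 0)
  scn0 <- build_scenario("breast_only", list(
    materials = list(breast = list(eps_r = d0$eps_r, sigma = d0$sigma))
  ))
  em0 <- solve_harmonic(base$mesh, scn0)
  expect_identical(em0$gamma_complex, base$em$gamma_complex)
})
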