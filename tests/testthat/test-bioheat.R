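slab_material <- function() {
  list(slab = material_properties("slab",
    eps_r = 5, sigma = 0.1,
    k_thermal = 0.5, density = 1000, heat_capacity = 100
  ))
}

test_that("zero source, zero perfusion, equal initial and boundary temperature stays constant", {
  m <- rect_mesh(0.01, 0.03, 0, 0.02, 6, 6, region = "slab")
  prob <- bioheat_problem(m, slab_material(),
    source = 0,
    initial_temperature = 25, boundary_temperature = 25,
    end_time = 20, dt = 1
  )
  series <- solve_transient(prob)
  expect_lt(max(abs(series$T - 25)), 1e-9)
})

test_that("a uniformly heated slab reaches the textbook steady parabola", {
  # heat flows only along z (insulated radial faces), so the axisymmetric
  # solve must reproduce T(z) = Tw + q (L z - z^2) / (2 k)
  k <- 0.5
  q <- 1e5
  L <- 0.02
  m <- rect_mesh(0.5, 0.52, 0, L, 4, 40,
    region = "slab",
    tags = list(
      left = "insulated", right = "insulated",
      bottom = "exterior", top = "exterior"
    )
  )
  prob <- bioheat_problem(m, slab_material(),
    source = q,
    initial_temperature = 25, boundary_temperature = 25,
    end_time = 500, dt = 2
  )
  series <- solve_transient(prob)
  z <- m$nodes[, 2]
  exact <- 25 + q * (L * z - z^2) / (2 * k)
  Tend <- series$T[, ncol(series$T)]
  expect_equal(max(Tend), 25 + q * L^2 / (8 * k), tolerance = 1e-3)
  expect_equal(Tend, exact, tolerance = 1e-3)
})

test_that("assemble_source converts SAR to a volumetric power density", {
  m <- rect_mesh(0.01, 0.02, 0, 0.01, 2, 2, region = "tissue")
  mat <- list(tissue = material_properties("t",
    eps_r = 5, sigma = 1,
    k_thermal = 0.5, density = 1000, heat_capacity = 3500
  ))
  sar <- structure(
    list(sar = rep(5, nrow(m$tri)), mesh = m, materials = mat),
    class = "abl_sar"
  )
  expect_equal(unique(assemble_source(sar)), 5000) # 5 W/kg * 1000 kg/m^3
  sar$sar[] <- 0
  expect_true(all(assemble_source(sar) == 0))

  # on the real pipeline the volume integral of Q_ext equals the absorbed power
  run <- full_run("breast_only")
  q <- assemble_source(run$sar)
  geo <- mwablate:::triangle_geometry(run$mesh)
  expect_equal(
    sum(q * 2 * pi * geo$rbar * geo$area),
    run$em$absorbed_power,
    tolerance = 0.02
  )
})

test_that("the discrete maximum principle holds on the heating scenarios", {
  for (kind in c("breast_only", "tumor_in_breast")) {
    series <- full_run(kind)$series
    expect_gte(min(series$T), 25 - 1e-9)
    expect_true(all(is.finite(series$T)))
    expect_true(all(diff(series$times) > 0))
  }
})

test_that("a dominant perfusion sink drives tissue towards blood temperature", {
  m <- rect_mesh(0.2, 0.3, 0, 0.1, 8, 8,
    region = "tissue",
    tags = list(
      left = "insulated", right = "insulated",
      bottom = "exterior", top = "exterior"
    )
  )
  mat <- list(tissue = material_library()$breast)
  prob <- bioheat_problem(m, mat,
    source = 0,
    blood = blood_parameters(perfusion_rate = 1, blood_temperature = 37),
    perfusion = TRUE,
    initial_temperature = 25, boundary_temperature = 25,
    end_time = 200, dt = 1
  )
  series <- solve_transient(prob)
  centre <- which.min((m$nodes[, 1] - 0.25)^2 + (m$nodes[, 2] - 0.05)^2)
  expect_equal(series$T[centre, ncol(series$T)], 37, tolerance = 0.1)
})

test_that("invalid bioheat inputs are rejected", {
  m <- rect_mesh(0.01, 0.02, 0, 0.01, 2, 2, region = "tissue")
  mat <- list(tissue = material_library()$breast)
  expect_error(bioheat_problem(m, mat, source = -1), "Q_ext")
  expect_error(bioheat_problem(m, mat, end_time = -5), "end_time")
  expect_error(bioheat_problem(m, list(), source = 0), "no material")
  bad <- mat
  bad$tissue$k_thermal <- -1
  expect_error(bioheat_problem(m, bad), "thermal")
})
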