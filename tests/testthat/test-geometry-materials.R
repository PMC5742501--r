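test_that("material library carries the published dielectric and thermal constants", {
  lib <- material_library()
  expect_equal(lib$tumor$sigma, 3.156)
  expect_equal(lib$tumor$eps_r, 59.385)
  expect_equal(lib$breast$sigma, 0.137)
  expect_equal(lib$breast$eps_r, 5.1467)
  expect_equal(lib$breast$k_thermal, 0.42)
  expect_equal(lib$tumor$k_thermal, 0.50)
  expect_equal(lib$catheter$eps_r, 2.60)
  expect_equal(lib$coax_dielectric$eps_r, 2.03)
  for (m in lib) {
    expect_true(m$is_conductor || m$eps_r >= 1)
    expect_gte(m$sigma, 0)
    expect_equal(m$mu_r, 1)
    expect_true(m$k_thermal > 0 && m$density > 0 && m$heat_capacity > 0)
  }
  # overrides reach the named field and nothing else
  lib2 <- material_library(list(breast = list(heat_capacity = 2800)))
  expect_equal(lib2$breast$heat_capacity, 2800)
  expect_equal(lib2$breast$k_thermal, 0.42)
  expect_error(material_library(list(steel = list(sigma = 1))), "unknown material")
})

test_that("effective wavelength follows c/(f sqrt(eps mu))", {
  # tumour tissue at the operating frequency: 15.88 mm to 4 significant figures
  expect_equal(signif(1e3 * effective_wavelength(2.45e9, 59.385, 1), 4), 15.88)
  # vacuum reduces to c/f
  expect_equal(effective_wavelength(1e9, 1, 1), 299792458 / 1e9)
  # sqrt scaling: eps_r = 4 halves the vacuum wavelength exactly
  expect_equal(
    effective_wavelength(2.45e9, 4, 1),
    effective_wavelength(2.45e9, 1, 1) / 2
  )
  expect_error(effective_wavelength(-1, 2), "frequency")
  expect_error(effective_wavelength(1e9, 0.5), "eps_r")
})

test_that("scenario constructors enforce their contracts", {
  scn <- build_scenario("tumor_in_breast")
  expect_equal(scn$tumor_radius, 12.5)
  expect_equal(scn$input_power, 10)
  expect_equal(scn$frequency, 2.45e9)
  expect_equal(scn$ambient_temperature, 25)
  expect_true("tumor" %in% names(scn$region_materials))

  b <- build_scenario("breast_only", list(input_power = 10))
  expect_false("tumor" %in% names(b$region_materials))
  expect_false("tumor" %in% region_at(b, seq(0, 29, by = 0.5), 40))

  expect_error(
    build_scenario("tumor_in_breast", list(tumor_radius = 200)),
    "invariant"
  )
  expect_error(
    build_scenario("tumor_in_breast", list(tumor_radius = 1)),
    "invariant"
  )
  expect_error(build_scenario("breast_only", list(insertion_depth = 90)), "invariant")
  expect_error(build_scenario("breast_only", list(nonsense = 1)), "unknown")

  ph <- build_scenario("phantom")
  expect_equal(ph$region_materials$tissue$name, "phantom_breast")
  expect_equal(ph$region_materials$tumor$eps_r, 59.385)
})

test_that("region map partitions the half-plane and areas match analytic values", {
  for (kind in c("breast_only", "tumor_in_breast")) {
    scn <- build_scenario(kind)
    ar <- region_areas(scn, n = 500)
    expect_equal(sum(ar$area_mm2), scn$domain_radius * scn$domain_height)
    # tumour semicircle minus the antenna column it swallows; coarse check
    if (kind == "tumor_in_breast") {
      a_tum <- ar$area_mm2[ar$region == "tumor"]
      expect_lt(abs(a_tum - pi * 12.5^2 / 2) / (pi * 12.5^2 / 2), 0.12)
    }
  }
})

test_that("scenario round-trips through the YAML config unchanged", {
  scn <- build_scenario("tumor_in_breast", list(input_power = 12.5))
  path <- withr::local_tempfile(fileext = ".yaml")
  scenario_to_yaml(scn, path)
  back <- scenario_from_yaml(path)
  expect_equal(unclass(back$geometry), unclass(scn$geometry))
  expect_equal(unclass(back$blood), unclass(scn$blood))
  for (f in c(
    "kind", "domain_radius", "domain_height", "tumor_radius",
    "input_power", "frequency", "ambient_temperature", "insertion_depth",
    "slot_fill"
  )) {
    expect_equal(back[[f]], scn[[f]], info = f)
  }
  expect_equal(
    purrr::map(back$region_materials, unclass),
    purrr::map(scn$region_materials, unclass)
  )
})
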