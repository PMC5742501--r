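analytic_series <- function(m, Tfun) {
  Tn <- Tfun(m$nodes[, 1] * 1e3, m$nodes[, 2] * 1e3) # mm arguments
  structure(
    list(times = 0, T = matrix(Tn, ncol = 1), mesh = m, problem = NULL),
    class = "abl_temp_series"
  )
}

test_that("isotherm extraction inverts an analytic radial field", {
  m <- rect_mesh(0, 10e-3, 0, 10e-3, 200, 8, region = "tissue")
  # T = 100 - 10 r(mm): the 55 C contour is the line r = 4.5 mm
  s <- analytic_series(m, function(r, z) 100 - 10 * r)
  iso <- extract_isotherm(m, s$T[, 1], 55)
  expect_gt(nrow(iso), 0)
  expect_true(all(abs(c(iso$r1, iso$r2) - 4.5) < 1e-6))
  expect_equal(lesion_radius(s, 55, 0), 4.5, tolerance = 1e-6)
  # every isotherm point interpolates back to the level
  expect_true(all(abs((100 - 10 * iso$r1) - 55) < 0.01))

  # a uniform cold field has no contour and zero radius
  cold <- analytic_series(m, function(r, z) 25 + 0 * r)
  expect_equal(nrow(extract_isotherm(m, cold$T[, 1], 55)), 0)
  expect_equal(lesion_radius(cold, 55, 0), 0)
})

test_that("lesion radius of a Gaussian hot spot matches a dense grid scan", {
  m <- rect_mesh(0, 20e-3, 0, 20e-3, 160, 160, region = "tissue")
  Tfun <- function(r, z) 25 + 60 * exp(-((r - 3)^2 + (z - 10)^2) / 18)
  s <- analytic_series(m, Tfun)
  got <- lesion_radius(s, 55, 0)
  # oracle: brute-force max radius over a dense evaluation grid
  g <- expand.grid(r = seq(0, 20, by = 0.002), z = seq(8, 12, by = 0.01))
  oracle <- max(g$r[Tfun(g$r, g$z) >= 55])
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("probe traces reproduce nodal values and linear fields exactly", {
  m <- rect_mesh(0, 10e-3, 0, 10e-3, 10, 10, region = "tissue")
  s <- analytic_series(m, function(r, z) 20 + 3 * r) # linear in r
  # at a mesh node: exactly the nodal value
  node <- 37
  tr <- probe_trace(s, cbind(m$nodes[node, 1] * 1e3, m$nodes[node, 2] * 1e3))
  expect_identical(tr$temperature, s$T[node, 1])
  # inside an element: barycentric interpolation reproduces linear fields
  tr2 <- probe_trace(s, cbind(2.37, 5.91))
  expect_equal(tr2$temperature, 20 + 3 * 2.37, tolerance = 1e-12)
  expect_error(probe_trace(s, cbind(50, 5)), "outside")
})

test_that("lesion radius grows monotonically during heating and t_max matches the series", {
  run <- full_run("breast_only")
  times <- run$series$times[run$series$times >= 100]
  radii <- purrr::map_dbl(times, function(t) lesion_radius(run$series, 55, t))
  expect_true(all(diff(radii) > -1e-9))
  expect_equal(run$lesion$t_max, max(run$series$T))
  # radius = 0 iff no node reaches the level
  expect_equal(lesion_radius(run$series, 200, max(times)), 0)
  expect_gt(run$lesion$lesion_radius, 0)
})

test_that("default probes sit at the published sensor positions relative to the slots", {
  scn <- build_scenario("breast_only")
  p <- default_probes(scn)
  lv <- mwablate:::scenario_levels(scn)
  expect_equal(unname(p["hottest", ]), c(1.6, lv$z_slot_centre + 2.6))
  expect_equal(unname(p["max_radius", ]), c(4.2, lv$z_slot_centre + 3))
  run <- full_run("breast_only")
  traces <- run$lesion$probe_traces
  expect_s3_class(traces, "tbl_df")
  expect_equal(sort(unique(traces$probe)), 1:3)
  # the "hottest point" probe heats far more than the near-surface probe
  final <- dplyr::filter(traces, .data$time == max(.data$time))
  expect_gt(final$temperature[final$probe == 1], final$temperature[final$probe == 3] + 10)
})

test_that("lesion reports serialise to JSON", {
  run <- full_run("breast_only")
  path <- withr::local_tempfile(fileext = ".json")
  write_lesion_json(run$lesion, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$t_max, run$lesion$t_max, tolerance = 1e-9)
  expect_equal(obj$lesion_radius_mm, run$lesion$lesion_radius, tolerance = 1e-9)
})
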