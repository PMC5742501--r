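# Shared fixtures: built once per test run and memoised, because the full
# scenario pipelines are the expensive part of the suite.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# straight matched/shorted coax oracle meshes (UT-085 cross-section)
coax_mesh <- function(termination = c("exterior", "pec"), nz = 80) {
  termination <- match.arg(termination)
  a <- 0.51e-3 / 2
  b <- 1.68e-3 / 2
  m <- rect_mesh(a, b, 0, 0.04, 6, nz,
    region = "coax_dielectric",
    tags = list(left = "pec", right = "pec", bottom = termination, top = "port")
  )
  m$port_radii <- c(a, b)
  m
}

coax_materials <- function() material_library()["coax_dielectric"]

full_run <- function(kind, power = 10) {
  memo(sprintf("run_%s_%s", kind, power), {
    run_scenario(build_scenario(kind, list(input_power = power)))
  })
}

breast_em <- function() full_run("breast_only")$em

# relative r-weighted L2 error of the manufactured Bessel-mode solution
# u = J1(k r) on [0, R] x [0, Z], Dirichlet-imposed on the outer boundary
bessel_errors <- function(nrs, eps = 4, f = 2.45e9) {
  k <- 2 * pi * f / 299792458 * sqrt(eps)
  mat <- list(med = material_properties("med",
    eps_r = eps, sigma = 0,
    k_thermal = 1, density = 1, heat_capacity = 1
  ))
  exact <- function(r, z) besselJ(k * r, 1)
  vapply(nrs, function(nr) {
    m <- rect_mesh(0, 0.05, 0, 0.02, nr, max(4, nr %/% 4),
      region = "med",
      tags = list(
        left = "axis", right = "dirichlet",
        bottom = "dirichlet", top = "dirichlet"
      )
    )
    sol <- em_solve(m, mat, f, dirichlet_fun = exact)
    geo <- mwablate:::triangle_geometry(m)
    uc <- (sol$u[m$tri[, 1]] + sol$u[m$tri[, 2]] + sol$u[m$tri[, 3]]) / 3
    ex <- exact(geo$rbar, 0)
    sqrt(
      sum(geo$area * geo$rbar * Mod(uc - ex)^2) /
        sum(geo$area * geo$rbar * Mod(ex)^2)
    )
  }, numeric(1))
}
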