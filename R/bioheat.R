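#' @name bioheat
#' @title Transient Pennes bioheat solver
#'
#' @description Solves the axisymmetric Pennes equation
#' \deqn{\rho c\,\partial_t T = \nabla\cdot(k\nabla T)
#'   + \rho_{bl} C_{bl} \omega (T_{bl} - T) + Q_{ext}}
#' on the same mesh as the electromagnetic solve, one-way coupled through
#' the volumetric source `Q_ext = sigma |E|^2 / 2` (peak phasors), i.e.
#' `Q_ext = rho * SAR`. Metabolic heating is neglected and the perfusion
#' rate is a volumetric rate (1/s) applied in tissue regions only;
#' perfusion zero reproduces the ex vivo condition. Discretisation:
#' P1 elements, lumped (row-sum) mass, backward Euler — unconditionally
#' stable and, on the non-obtuse triangles the mesher produces, satisfying
#' a discrete maximum principle.
NULL

#' Volumetric heat source from a SAR field
#'
#' `Q_ext = rho * SAR = sigma |E|^2 / 2` per element (W/m^3); its volume
#' integral equals the absorbed electromagnetic power.
#'
#' @param sar_field An `abl_sar` from [compute_sar()].
#' @param materials Named material list sharing the SAR field's region map.
#' @return Numeric vector of per-element `Q_ext` (W/m^3).
#' @export
assemble_source <- function(sar_field, materials = sar_field$materials) {
  regs <- unique(sar_field$mesh$region)
  missing_m <- setdiff(regs, names(materials))
  if (length(missing_m)) {
    abort(sprintf(
      "region mismatch between SAR field and materials: %s",
      paste(missing_m, collapse = ", ")
    ))
  }
  rho <- purrr::map_dbl(materials, "density")[sar_field$mesh$region]
  rho * sar_field$sar
}

#' Define a transient bioheat problem
#'
#' @param mesh An `abl_mesh` (all regions participate in the thermal solve).
#' @param materials Named material list keyed by mesh region.
#' @param source Per-element volumetric source `Q_ext` (W/m^3, >= 0), e.g.
#'   from [assemble_source()]; recycled scalar allowed.
#' @param blood A [blood_parameters()]; the perfusion sink is active when
#'   `perfusion = TRUE` and applies in the regions listed in
#'   `perfused_regions`.
#' @param perfusion Logical; default `FALSE` (ex-vivo-like reproduction
#'   scenarios).
#' @param perfused_regions Regions carrying blood perfusion.
#' @param initial_temperature Uniform initial temperature (degrees C).
#' @param boundary_temperature Exterior Dirichlet temperature (degrees C).
#' @param end_time Simulated duration (s, > 0).
#' @param dt Backward-Euler time step (s, > 0).
#' @param snapshot_every Interval between stored snapshots (s).
#' @param dirichlet_tags Boundary tags held at `boundary_temperature`
#'   (the symmetry axis is always zero-flux).
#' @return An object of class `abl_bioheat_problem`.
#' @export
bioheat_problem <- function(mesh, materials, source = 0,
                            blood = blood_parameters(),
                            perfusion = FALSE,
                            perfused_regions = c("tissue", "tumor"),
                            initial_temperature = 25,
                            boundary_temperature = 25,
                            end_time = 500, dt = 1, snapshot_every = 10,
                            dirichlet_tags = c("exterior", "port")) {
  if (end_time <= 0 || dt <= 0) abort("end_time and dt must be > 0")
  source <- rep_len(source, nrow(mesh$tri))
  if (any(source < 0)) abort("Q_ext must be >= 0")
  missing_m <- setdiff(unique(mesh$region), names(materials))
  if (length(missing_m)) {
    abort(sprintf("no material for region(s): %s", paste(missing_m, collapse = ", ")))
  }
  for (m in materials) {
    if (m$k_thermal <= 0 || m$density <= 0 || m$heat_capacity <= 0) {
      abort(sprintf("material '%s' has non-positive thermal parameters", m$name))
    }
  }
  structure(
    list(
      mesh = mesh, materials = materials, source = source, blood = blood,
      perfusion = perfusion, perfused_regions = perfused_regions,
      initial_temperature = initial_temperature,
      boundary_temperature = boundary_temperature,
      end_time = end_time, dt = dt, snapshot_every = snapshot_every,
      dirichlet_tags = dirichlet_tags
    ),
    class = "abl_bioheat_problem"
  )
}

#' Run the transient bioheat solve
#'
#' Backward-Euler integration with one sparse Cholesky factorisation reused
#' across all steps. Returns snapshots at `t = 0`, every `snapshot_every`
#' seconds, and `t = end_time`.
#'
#' @param problem An [bioheat_problem()].
#' @return An object of class `abl_temp_series`: `times` (s) and `T`
#'   (nodes x snapshots matrix, degrees C), plus mesh/problem references.
#' @export
solve_transient <- function(problem) {
  mesh <- problem$mesh
  geo <- triangle_geometry(mesh)
  n <- nrow(mesh$nodes)
  tri <- mesh$tri
  A <- geo$area
  rr <- geo$r
  bb <- geo$b
  cc <- geo$c

  kvec <- purrr::map_dbl(problem$materials, "k_thermal")[mesh$region]
  rhoc <- (purrr::map_dbl(problem$materials, "density") *
    purrr::map_dbl(problem$materials, "heat_capacity"))[mesh$region]

  perf_coef <- rep(0, nrow(tri))
  if (problem$perfusion) {
    bl <- problem$blood
    perf_coef[mesh$region %in% problem$perfused_regions] <-
      bl$density_bl * bl$heat_capacity_bl * bl$perfusion_rate
  }

  # conduction stiffness (r-weighted), triplets
  ii <- jj <- integer(0)
  vv <- numeric(0)
  for (i in 1:3) {
    for (j in 1:3) {
      S <- kvec * A * geo$rbar * (bb[, i] * bb[, j] + cc[, i] * cc[, j])
      ii <- c(ii, tri[, i])
      jj <- c(jj, tri[, j])
      vv <- c(vv, S)
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))

  # lumped r-weighted masses: integral of lambda_i r dA = A (2 r_i + r_j + r_k) / 12
  wi <- cbind(
    A * (2 * rr[, 1] + rr[, 2] + rr[, 3]) / 12,
    A * (rr[, 1] + 2 * rr[, 2] + rr[, 3]) / 12,
    A * (rr[, 1] + rr[, 2] + 2 * rr[, 3]) / 12
  )
  Ml <- numeric(n) # rho c lumped mass
  Pl <- numeric(n) # perfusion lumped mass
  Fv <- numeric(n) # source load
  for (i in 1:3) {
    Ml <- Ml + unname(tapply_add(tri[, i], rhoc * wi[, i], n))
    Pl <- Pl + unname(tapply_add(tri[, i], perf_coef * wi[, i], n))
    Fv <- Fv + unname(tapply_add(tri[, i], problem$source * wi[, i], n))
  }
  if (problem$perfusion) Fv <- Fv + Pl * problem$blood$blood_temperature

  bnodes <- unique(as.vector(
    mesh$bedges[mesh$btag %in% problem$dirichlet_tags, , drop = FALSE]
  ))
  free <- setdiff(seq_len(n), bnodes)

  dt <- problem$dt
  nstep <- ceiling(problem$end_time / dt - 1e-9)
  Amat <- K + Matrix::Diagonal(n, Ml / dt + Pl)
  Aff <- Amat[free, free, drop = FALSE]
  Afd <- Amat[free, bnodes, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Aff), LDL = FALSE)

  Tb <- problem$boundary_temperature
  Tn <- rep(problem$initial_temperature, n)
  Tn[bnodes] <- Tb
  rhs_const <- Fv[free] - as.numeric(Afd %*% rep(Tb, length(bnodes)))

  snap_every <- max(1L, round(problem$snapshot_every / dt))
  times <- 0
  snaps <- list(Tn)
  for (s in seq_len(nstep)) {
    rhs <- (Ml[free] / dt) * Tn[free] + rhs_const
    Tn[free] <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    if (s %% snap_every == 0L || s == nstep) {
      times <- c(times, s * dt)
      snaps[[length(snaps) + 1L]] <- Tn
    }
  }
  structure(
    list(
      times = times, T = do.call(cbind, snaps), mesh = mesh,
      problem = problem
    ),
    class = "abl_temp_series"
  )
}

tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.abl_temp_series <- function(x, ...) {
  cat(sprintf(
    "<abl_temp_series> %d snapshots over %g s | final max %.2f C at t = %g s\n",
    length(x$times), max(x$times), max(x$T[, ncol(x$T)]), max(x$times)
  ))
  invisible(x)
}

#' @export
tidy.abl_temp_series <- function(x, ...) {
  tibble(
    time = x$times,
    T_max = apply(x$T, 2, max),
    T_min = apply(x$T, 2, min),
    T_mean = apply(x$T, 2, mean)
  )
}

#' @export
glance.abl_temp_series <- function(x, ...) {
  peak <- which.max(apply(x$T, 2, max))
  tibble(
    end_time = max(x$times),
    t_max = max(x$T),
    time_of_max = x$times[peak],
    dt = x$problem$dt,
    n_nodes = nrow(x$T)
  )
}

# nodal temperatures at (or nearest stored to) a requested time
series_at_time <- function(series, at_time) {
  if (at_time < min(series$times) - 1e-9 || at_time > max(series$times) + 1e-9) {
    abort("at_time outside the stored time range")
  }
  k <- which.min(abs(series$times - at_time))
  series$T[, k]
}
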