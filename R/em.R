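#' @name em_solver
#' @title Time-harmonic axisymmetric electromagnetic solver
#'
#' @description Solves the TM axisymmetric scalar problem for the azimuthal
#' magnetic field `H_phi` (the standard formulation for coaxially fed
#' rotationally symmetric applicators), with complex relative permittivity
#' `eps_c = eps_r - j sigma / (omega eps0)` (time convention
#' `e^{+j omega t}`, peak phasors). Internally the scaled unknown
#' `w = r H_phi` is discretised — its weak form
#' \deqn{\int \frac{1}{\tilde\varepsilon}\,\nabla w\cdot\nabla q\,
#'   \frac{dr\,dz}{r} - k_0^2 \int w\,q\,\frac{dr\,dz}{r}}
#' carries no `u/r` cross terms and represents the coaxial TEM mode
#' (`w` constant) exactly, which keeps the port quantities accurate on
#' linear elements. Metal surfaces are perfect electric conductors (the
#' natural boundary condition); the coaxial port carries an incident TEM
#' mode `H_phi = C/r` normalised so the time-averaged incident power equals
#' the requested input power; exterior boundaries use a first-order
#' absorbing (scattering) condition with the local medium's wavenumber;
#' `w = 0` on the symmetry axis.
NULL

# Build a lookup from boundary edge -> adjacent triangle index.
edge_adjacent_tri <- function(mesh) {
  t <- mesh$tri
  e <- rbind(t[, 1:2], t[, 2:3], t[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tri_of <- rep(seq_len(nrow(t)), 3)
  bkey <- paste(
    pmin(mesh$bedges[, 1], mesh$bedges[, 2]),
    pmax(mesh$bedges[, 1], mesh$bedges[, 2])
  )
  tri_of[match(bkey, key)]
}

# 2-point Gauss data for a set of boundary edges: returns per-edge node ids,
# lengths, and per-Gauss-point shape values / radii.
edge_gauss <- function(mesh, e_idx) {
  n1 <- mesh$bedges[e_idx, 1]
  n2 <- mesh$bedges[e_idx, 2]
  p1 <- mesh$nodes[n1, , drop = FALSE]
  p2 <- mesh$nodes[n2, , drop = FALSE]
  L <- sqrt(rowSums((p2 - p1)^2))
  tg <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  list(
    n1 = n1, n2 = n2, L = L,
    t1 = tg[1], t2 = tg[2],
    r_g1 = p1[, 1] + tg[1] * (p2[, 1] - p1[, 1]),
    r_g2 = p1[, 1] + tg[2] * (p2[, 1] - p1[, 1])
  )
}

#' Low-level harmonic solve on a tagged mesh
#'
#' Most users call [solve_harmonic()]; this entry point takes an explicit
#' region-to-material map and is what the analytic test oracles (straight
#' coax, manufactured Bessel solution) drive directly.
#'
#' @param mesh An `abl_mesh` with `region` tags and boundary tags among
#'   `axis`, `port`, `exterior`, `pec`, `dirichlet`.
#' @param materials Named list of [material_properties()] keyed by region.
#' @param frequency Frequency (Hz).
#' @param input_power Incident port power (W).
#' @param port_radii Inner/outer radii (m) of the coax annulus at the port;
#'   defaults to `mesh$port_radii`.
#' @param dirichlet_fun Optional `function(r, z)` returning complex `H_phi`
#'   values imposed on nodes of edges tagged `dirichlet` (manufactured
#'   solutions).
#' @return An object of class `abl_em` with nodal complex `H_phi` (`u`),
#'   per-element complex `E_r`, `E_z`, the complex port reflection
#'   coefficient `gamma_complex`, and the power bookkeeping
#'   (`input_power`, `reflected_power`, `absorbed_power`,
#'   `radiated_power`).
#' @export
em_solve <- function(mesh, materials, frequency, input_power = 10,
                     port_radii = mesh$port_radii, dirichlet_fun = NULL,
                     exterior_impedance = c("medium", "air")) {
  exterior_impedance <- match.arg(exterior_impedance)
  if (frequency <= 0) abort("frequency must be > 0")
  omega <- 2 * pi * frequency
  k0 <- omega / .c0

  regs <- unique(mesh$region)
  missing_m <- setdiff(regs, names(materials))
  if (length(missing_m)) {
    abort(sprintf("no material for region(s): %s", paste(missing_m, collapse = ", ")))
  }
  is_cond <- purrr::map_lgl(materials, "is_conductor")[mesh$region]
  el <- which(!is_cond)
  if (!length(el)) abort("EM domain is empty (all regions are conductors)")

  geo <- triangle_geometry(mesh)
  eps_c <- purrr::map(materials, complex_permittivity, frequency = frequency)
  epse <- unlist(eps_c[mesh$region[el]], use.names = FALSE)
  D <- 1 / epse
  A <- geo$area[el]
  rb <- geo$rbar[el]
  bb <- geo$b[el, , drop = FALSE]
  cc <- geo$c[el, , drop = FALSE]
  tri <- mesh$tri[el, , drop = FALSE]

  # triplet assembly of K = S - k0^2 M on the w = r*H_phi unknown,
  # centroid quadrature for the 1/r weight
  ii <- jj <- integer(0)
  vv <- complex(0)
  for (i in 1:3) {
    for (j in 1:3) {
      S <- D * A * (bb[, i] * bb[, j] + cc[, i] * cc[, j]) / rb
      M <- A * (1 + (i == j)) / 12 / rb
      ii <- c(ii, tri[, i])
      jj <- c(jj, tri[, j])
      vv <- c(vv, S - k0^2 * M)
    }
  }

  n <- nrow(mesh$nodes)
  rhs <- complex(n)

  # boundary terms (all with the 1/r weight) -------------------------------
  adj <- edge_adjacent_tri(mesh)
  active_edge <- !is_cond[adj]
  btag <- mesh$btag
  C_H <- 0
  port_found <- FALSE

  edge_mass_over_r <- function(e_idx, coef) {
    g <- edge_gauss(mesh, e_idx)
    w1 <- g$L / 2 # Gauss weights
    sh11 <- (1 - g$t1)^2 / g$r_g1 + (1 - g$t2)^2 / g$r_g2
    sh22 <- g$t1^2 / g$r_g1 + g$t2^2 / g$r_g2
    sh12 <- (1 - g$t1) * g$t1 / g$r_g1 + (1 - g$t2) * g$t2 / g$r_g2
    list(
      i = c(g$n1, g$n2, g$n1, g$n2),
      j = c(g$n1, g$n2, g$n2, g$n1),
      v = c(coef * w1 * sh11, coef * w1 * sh22, coef * w1 * sh12, coef * w1 * sh12)
    )
  }

  pe <- which(btag == "port" & active_edge)
  if (length(pe)) {
    port_found <- TRUE
    if (is.null(port_radii)) abort("port edges present but no port_radii on the mesh")
    pm <- unique(mesh$region[adj[pe]])
    if (length(pm) != 1) abort("port boundary spans more than one region")
    eps_d <- Re(eps_c[[pm]])
    beta <- k0 * sqrt(eps_d)
    Dd <- 1 / eps_d
    Zd <- sqrt(.mu0 / (.eps0 * eps_d))
    C_H <- sqrt(input_power / (pi * Zd * log(port_radii[2] / port_radii[1])))
    em <- edge_mass_over_r(pe, complex(imaginary = beta * Dd))
    ii <- c(ii, em$i)
    jj <- c(jj, em$j)
    vv <- c(vv, em$v)
    # load: 2 j beta Dd C_H * integral(phi_i / r ds)
    g <- edge_gauss(mesh, pe)
    lc <- complex(imaginary = 2 * beta * Dd * C_H)
    l1 <- lc * g$L / 2 * ((1 - g$t1) / g$r_g1 + (1 - g$t2) / g$r_g2)
    l2 <- lc * g$L / 2 * (g$t1 / g$r_g1 + g$t2 / g$r_g2)
    for (kk in seq_along(pe)) {
      rhs[g$n1[kk]] <- rhs[g$n1[kk]] + l1[kk]
      rhs[g$n2[kk]] <- rhs[g$n2[kk]] + l2[kk]
    }
  }

  xe <- which(btag == "exterior" & active_edge)
  if (length(xe)) {
    eps_med <- unlist(eps_c[mesh$region[adj[xe]]], use.names = FALSE)
    # impedance-type absorbing condition: coef = j omega eps0 Z_s.
    # "medium": Z_s of the local medium (first-order scattering condition);
    # "air": Z_s of free space on every exterior face (the alternative
    # reading of the published boundary-settings table).
    coef <- if (exterior_impedance == "medium") {
      1i * k0 / sqrt(eps_med)
    } else {
      rep(1i * k0 + 0i, length(xe))
    }
    for (kk in seq_along(xe)) {
      em <- edge_mass_over_r(xe[kk], coef[kk])
      ii <- c(ii, em$i)
      jj <- c(jj, em$j)
      vv <- c(vv, em$v)
    }
  }

  # DOFs: nodes incident to EM elements; Dirichlet on axis (w = 0) and on
  # any prescribed 'dirichlet' edges (w = r * H_phi)
  em_nodes <- sort(unique(as.vector(tri)))
  fixed <- integer(0)
  fixed_val <- complex(0)
  ax_nodes <- intersect(
    unique(as.vector(mesh$bedges[btag == "axis" & active_edge, ])),
    em_nodes
  )
  if (length(ax_nodes)) {
    fixed <- ax_nodes
    fixed_val <- complex(length(ax_nodes))
  }
  de <- which(btag == "dirichlet" & active_edge)
  if (length(de)) {
    if (is.null(dirichlet_fun)) abort("mesh has 'dirichlet' edges but no dirichlet_fun")
    dn <- setdiff(unique(as.vector(mesh$bedges[de, , drop = FALSE])), fixed)
    fixed <- c(fixed, dn)
    fixed_val <- c(fixed_val, mesh$nodes[dn, 1] * as.complex(dirichlet_fun(
      mesh$nodes[dn, 1], mesh$nodes[dn, 2]
    )))
  }
  if (!port_found && !length(de)) {
    abort("configuration error: mesh has neither port nor dirichlet boundary edges")
  }

  free <- setdiff(em_nodes, fixed)

  # complex sparse solve via the equivalent real 2n x 2n block system
  loc <- integer(n)
  loc[free] <- seq_along(free)
  nf <- length(free)
  isfree <- logical(n)
  isfree[free] <- TRUE
  isfixed <- logical(n)
  isfixed[fixed] <- TRUE
  is_ff <- isfree[ii] & isfree[jj]
  is_fd <- isfree[ii] & isfixed[jj]

  bvec <- rhs[free]
  if (length(fixed) && any(is_fd)) {
    xd <- complex(n)
    xd[fixed] <- fixed_val
    contrib <- vv[is_fd] * xd[jj[is_fd]]
    agg <- rowsum(cbind(Re(contrib), Im(contrib)), loc[ii[is_fd]])
    idx <- as.integer(rownames(agg))
    bvec[idx] <- bvec[idx] - complex(real = agg[, 1], imaginary = agg[, 2])
  }

  i_f <- loc[ii[is_ff]]
  j_f <- loc[jj[is_ff]]
  v_f <- vv[is_ff]
  Areal <- Matrix::sparseMatrix(
    i = c(i_f, i_f + nf, i_f, i_f + nf),
    j = c(j_f, j_f + nf, j_f + nf, j_f),
    x = c(Re(v_f), Re(v_f), -Im(v_f), Im(v_f)),
    dims = c(2 * nf, 2 * nf)
  )
  sol <- tryCatch(
    Matrix::solve(Areal, c(Re(bvec), Im(bvec))),
    error = function(e) {
      abort(sprintf(
        "harmonic solve failed (singular or ill-conditioned system): %s",
        conditionMessage(e)
      ))
    }
  )
  sol <- as.numeric(sol)
  w <- complex(n)
  w[free] <- complex(real = sol[seq_len(nf)], imaginary = sol[nf + seq_len(nf)])
  w[fixed] <- fixed_val
  w[setdiff(seq_len(n), em_nodes)] <- NA_complex_

  # nodal H_phi (w / r; zero on the axis by the w = 0 condition)
  u <- w / ifelse(mesh$nodes[, 1] > 0, mesh$nodes[, 1], Inf)

  # element fields: E_r = -(1/(j w eps) ) (1/r) dw/dz, E_z = (1/(j w eps)) (1/r) dw/dr
  w1 <- w[tri[, 1]]
  w2 <- w[tri[, 2]]
  w3 <- w[tri[, 3]]
  dw_dr <- w1 * bb[, 1] + w2 * bb[, 2] + w3 * bb[, 3]
  dw_dz <- w1 * cc[, 1] + w2 * cc[, 2] + w3 * cc[, 3]
  jweps <- complex(imaginary = omega * .eps0) * epse
  E_r_el <- -dw_dz / (jweps * rb)
  E_z_el <- dw_dr / (jweps * rb)

  m <- nrow(mesh$tri)
  E_r <- E_z <- rep(NA_complex_, m)
  E_r[el] <- E_r_el
  E_z[el] <- E_z_el

  sig <- purrr::map_dbl(materials, "sigma")[mesh$region[el]]
  absorbed <- sum(sig / 2 * (Mod(E_r_el)^2 + Mod(E_z_el)^2) * 2 * pi * rb * A)

  # port reflection by modal overlap against the incident 1/r TEM mode:
  # <f, m> = int f m r dr = int (w_f / r) dr
  gamma <- NA_complex_
  reflected <- NA_real_
  if (port_found) {
    g <- edge_gauss(mesh, pe)
    dr1 <- abs(mesh$nodes[g$n2, 1] - mesh$nodes[g$n1, 1])
    wg1 <- w[g$n1] + g$t1 * (w[g$n2] - w[g$n1])
    wg2 <- w[g$n1] + g$t2 * (w[g$n2] - w[g$n1])
    I_u <- sum(dr1 / 2 * (wg1 / g$r_g1 + wg2 / g$r_g2))
    I_inc <- sum(dr1 / 2 * (C_H / g$r_g1 + C_H / g$r_g2))
    gamma <- (I_u - I_inc) / I_inc
    reflected <- Mod(gamma)^2 * input_power
  }

  # outward radiated power through absorbing exterior edges: the imposed
  # first-order condition ties E_t = Z_med H_phi there, so the outward
  # Poynting flux is (1/2) Re(Z_med) |H_phi|^2 = (1/2) Re(Z_med) |w|^2/r^2
  radiated <- 0
  if (length(xe)) {
    eps_med <- unlist(eps_c[mesh$region[adj[xe]]], use.names = FALSE)
    ReZ <- Re(sqrt(.mu0 / (.eps0 * eps_med)))
    g <- edge_gauss(mesh, xe)
    wg1 <- w[g$n1] + g$t1 * (w[g$n2] - w[g$n1])
    wg2 <- w[g$n1] + g$t2 * (w[g$n2] - w[g$n1])
    lineint <- g$L / 2 * (Mod(wg1)^2 / g$r_g1 + Mod(wg2)^2 / g$r_g2)
    radiated <- sum(pi * ReZ * lineint)
  }

  structure(
    list(
      frequency = frequency, u = u, w = w, E_r = E_r, E_z = E_z,
      gamma_complex = gamma, input_power = input_power,
      reflected_power = reflected, absorbed_power = absorbed,
      radiated_power = radiated, mesh = mesh, em_elements = el,
      C_H = C_H
    ),
    class = "abl_em"
  )
}

#' Solve the harmonic EM problem for a scenario
#'
#' @param mesh An `abl_mesh` from [generate_mesh()].
#' @param scenario The `abl_scenario` the mesh was generated from.
#' @param frequency Frequency (Hz); defaults to the scenario's.
#' @return An `abl_em` solution (see [em_solve()]).
#' @export
solve_harmonic <- function(mesh, scenario, frequency = scenario$frequency) {
  if (!any(mesh$btag == "port")) {
    abort("mesh has no port boundary; cannot excite the antenna")
  }
  em_solve(mesh, scenario$region_materials, frequency,
    input_power = scenario$input_power,
    exterior_impedance = scenario$exterior_impedance %||% "medium"
  )
}

#' @export
print.abl_em <- function(x, ...) {
  cat(sprintf(
    "<abl_em> f = %.4g GHz | gamma = %.4f %+.4fi (|gamma| = %.4f, SWR = %.3f)\n",
    x$frequency / 1e9, Re(x$gamma_complex), Im(x$gamma_complex),
    Mod(x$gamma_complex), swr_from_gamma(min(Mod(x$gamma_complex), 1 - 1e-12))
  ))
  cat(sprintf(
    "  P_in %.3g W | reflected %.3g W | absorbed %.3g W | radiated %.3g W\n",
    x$input_power, x$reflected_power, x$absorbed_power, x$radiated_power
  ))
  invisible(x)
}

#' @export
glance.abl_em <- function(x, ...) {
  tibble(
    frequency = x$frequency,
    gamma_mag = Mod(x$gamma_complex),
    gamma_db = reflection_db(x$input_power, x$reflected_power),
    swr = swr_from_gamma(Mod(x$gamma_complex)),
    input_power = x$input_power,
    reflected_power = x$reflected_power,
    absorbed_power = x$absorbed_power,
    radiated_power = x$radiated_power,
    power_balance_error = abs(x$input_power -
      (x$reflected_power + x$absorbed_power + x$radiated_power)) / x$input_power
  )
}

#' Reflection coefficient in decibels
#'
#' `10 log10(P_reflected / P_in)` dB. Total reflection gives 0 dB; a
#' perfectly matched antenna gives `-Inf` (conventionally reported as
#' "below -60 dB").
#'
#' @param p_in Input power (W, > 0).
#' @param p_reflected Reflected power (W, between 0 and `p_in`).
#' @return Reflection in dB.
#' @export
reflection_db <- function(p_in, p_reflected) {
  if (any(p_in <= 0)) abort("p_in must be > 0")
  if (any(p_reflected < 0) || any(p_reflected > p_in)) {
    abort("p_reflected must lie in [0, p_in] (passive reflection)")
  }
  10 * log10(p_reflected / p_in)
}

#' Standing wave ratio from a reflection magnitude
#'
#' `SWR = (1 + |gamma|) / (1 - |gamma|)`; 1.0 is a perfect match.
#'
#' @param gamma_mag `|gamma|` in `[0, 1)`.
#' @return SWR (dimensionless, >= 1).
#' @export
swr_from_gamma <- function(gamma_mag) {
  if (any(gamma_mag < 0) || any(gamma_mag >= 1)) {
    abort("gamma_mag must lie in [0, 1)")
  }
  (1 + gamma_mag) / (1 - gamma_mag)
}

#' Specific absorption rate field
#'
#' `SAR = sigma / (2 rho) |E|^2` per element (peak-phasor convention, W/kg).
#' Zero in lossless regions and in conductors.
#'
#' @param solution An `abl_em`.
#' @param materials Named material list sharing the solution's region map
#'   (a scenario's `region_materials`).
#' @return An object of class `abl_sar`: per-element `sar` (W/kg) plus the
#'   mesh and material references.
#' @export
compute_sar <- function(solution, materials) {
  mesh <- solution$mesh
  missing_m <- setdiff(unique(mesh$region), names(materials))
  if (length(missing_m)) {
    abort(sprintf("no material for region(s): %s", paste(missing_m, collapse = ", ")))
  }
  sig <- purrr::map_dbl(materials, "sigma")[mesh$region]
  rho <- purrr::map_dbl(materials, "density")[mesh$region]
  if (any(sig > 0 & rho <= 0)) abort("lossy region with non-positive density")
  E2 <- Mod(solution$E_r)^2 + Mod(solution$E_z)^2
  sar <- sig / (2 * rho) * E2
  sar[is.na(sar)] <- 0 # conductor elements carry no EM field
  structure(
    list(sar = sar, mesh = mesh, materials = materials, em = solution),
    class = "abl_sar"
  )
}

#' @export
print.abl_sar <- function(x, ...) {
  cat(sprintf(
    "<abl_sar> %d elements | max %.4g W/kg | mass-weighted total %.4g W\n",
    length(x$sar), max(x$sar), sar_total_power(x)
  ))
  invisible(x)
}

# volume integral of rho * SAR (equals the absorbed EM power)
sar_total_power <- function(sar_field) {
  geo <- triangle_geometry(sar_field$mesh)
  rho <- purrr::map_dbl(sar_field$materials, "density")[sar_field$mesh$region]
  sum(rho * sar_field$sar * 2 * pi * geo$rbar * geo$area)
}

#' Frequency sweep of reflection and SWR
#'
#' One harmonic solve per frequency on a fixed mesh.
#'
#' @param mesh An `abl_mesh` with a port.
#' @param scenario The corresponding `abl_scenario`.
#' @param f_start,f_stop Sweep band (Hz), `f_start < f_stop`.
#' @param n_points Number of frequencies (>= 2).
#' @return A tibble of class `abl_sweep`: `frequency`, `gamma_mag`,
#'   `gamma_db`, `swr`.
#' @export
frequency_sweep <- function(mesh, scenario, f_start = 2e9, f_stop = 3.5e9,
                            n_points = 31) {
  if (!(f_start < f_stop)) abort("need f_start < f_stop")
  if (n_points < 2) abort("n_points must be >= 2")
  freqs <- seq(f_start, f_stop, length.out = n_points)
  rows <- purrr::map(freqs, function(f) {
    sol <- tryCatch(
      solve_harmonic(mesh, scenario, frequency = f),
      error = function(e) {
        abort(sprintf("sweep failed at %.4g GHz: %s", f / 1e9, conditionMessage(e)))
      }
    )
    g <- Mod(sol$gamma_complex)
    tibble(
      frequency = f, gamma_mag = g,
      gamma_db = reflection_db(sol$input_power, g^2 * sol$input_power),
      swr = swr_from_gamma(min(g, 1 - 1e-12))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("abl_sweep", class(out))
  out
}
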