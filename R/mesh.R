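#' @name mesh
#' @title Graded triangular meshes of the axisymmetric half-plane
#'
#' @description Meshes are stored as an `abl_mesh` list: `nodes` (n x 2
#' matrix of (r, z) coordinates in metres), `tri` (m x 3 node index
#' triples, counter-clockwise), `region` (character per triangle),
#' `bedges`/`btag` (boundary edges of the rectangle and their tags: `axis`,
#' `port`, `exterior`), and `h` (the size parameters used). The mesher is a
#' graded tensor-product triangulation: every straight material interface
#' (conductor radii, catheter, slot edges, tip, cap) is a grid line, so
#' those interfaces are resolved exactly by element edges; the curved
#' tumour boundary is resolved by a local refinement band with centroid
#' region tagging.
NULL

# Graded 1D point distribution between fixed breakpoints.
# sizefun(x) returns the local target spacing; each sub-interval gets
# ceil(integral of 1/size) equal increments of the cumulative density.
graded_axis <- function(breaks, sizefun) {
  breaks <- sort(unique(breaks))
  pts <- breaks[1]
  for (i in seq_len(length(breaks) - 1)) {
    x0 <- breaks[i]
    x1 <- breaks[i + 1]
    xs <- seq(x0, x1, length.out = 201)
    s <- sizefun(xs)
    dens <- 1 / s
    cum <- c(0, cumsum(diff(xs) * (dens[-1] + dens[-length(dens)]) / 2))
    total <- cum[length(cum)]
    n <- max(1L, ceiling(total - 1e-9))
    xi <- approx(cum, xs, xout = seq(0, total, length.out = n + 1))$y
    pts <- c(pts, xi[-1])
  }
  pts
}

band_size <- function(x, lo, hi, h_at, slope, cap) {
  d <- pmax(0, lo - x, x - hi)
  pmin(cap, h_at + slope * d)
}

#' Generate a graded mesh for a scenario
#'
#' Element sizes grade geometrically from fine values near the slots, the
#' antenna annuli and the tip up to `h_max` far away. `h_min` is a floor on
#' any target size; `h_max` bounds every element edge (cell dimensions are
#' capped at `h_max / sqrt(2)` so diagonals stay below `h_max`). `refine`
#' scales all targets down uniformly and is used by the mesh-convergence
#' checks.
#'
#' @param scenario An `abl_scenario`.
#' @param h_min Minimum element size floor (mm).
#' @param h_max Maximum element size (mm); must exceed `h_min`. Should stay
#'   below a quarter wavelength of the lossiest tissue (about 4 mm for
#'   tumour tissue at 2.45 GHz) for a resolved harmonic solve.
#' @param refine Uniform refinement factor (>= 1); 2 halves all sizes.
#' @return An `abl_mesh`.
#' @export
generate_mesh <- function(scenario, h_min = 0.004, h_max = 2, refine = 1) {
  if (!(h_min > 0 && h_min < h_max)) abort("need 0 < h_min < h_max")
  lam_t <- 1e3 * min(purrr::map_dbl(
    scenario$region_materials,
    function(m) {
      if (m$is_conductor) Inf else effective_wavelength(scenario$frequency, m$eps_r)
    }
  ))
  if (h_max > lam_t / 4) {
    abort(sprintf(
      "h_max = %g mm exceeds a quarter of the shortest in-band wavelength (%.3g mm)",
      h_max, lam_t
    ))
  }
  g <- scenario$geometry
  lv <- scenario_levels(scenario)
  R <- scenario$domain_radius
  H <- scenario$domain_height

  h_cap <- h_max / sqrt(2) / refine
  h_fine <- max(h_min, min(0.22, h_cap)) / refine
  h_tum <- max(h_min, min(0.6, h_cap)) / refine
  slope <- 0.35

  r_breaks <- c(0, g$r_inner, g$r_dielectric, g$r_outer, g$r_catheter, R)
  z_breaks <- c(
    0, lv$z_cap_bot, lv$z_tip, lv$z_short_top,
    lv$s1l, lv$s1u, lv$s2l, lv$s2u, H
  )
  has_tumor <- !is.na(scenario$tumor_radius)
  if (has_tumor) {
    Rt <- scenario$tumor_radius
    zc <- lv$z_slot_centre
    r_breaks <- c(r_breaks, Rt)
    z_breaks <- c(z_breaks, zc - Rt, zc + Rt)
  }

  s_r <- function(r) {
    s <- band_size(r, 0, g$r_catheter, h_fine, slope, h_cap)
    if (has_tumor) {
      s <- pmin(s, band_size(r, Rt - 1.5, Rt + 1.5, h_tum, slope, h_cap))
    }
    pmax(s, h_min)
  }
  s_z <- function(z) {
    s <- pmin(
      band_size(z, lv$s1l - 1, lv$s2u + 1, h_fine, slope, h_cap),
      band_size(z, lv$z_cap_bot - 0.5, lv$z_short_top + 0.5, h_fine, slope, h_cap)
    )
    if (has_tumor) {
      s <- pmin(
        s,
        band_size(z, zc - Rt - 1.5, zc - Rt + 1.5, h_tum, slope, h_cap),
        band_size(z, zc + Rt - 1.5, zc + Rt + 1.5, h_tum, slope, h_cap)
      )
    }
    pmax(s, h_min)
  }

  rs <- graded_axis(r_breaks, s_r)
  zs <- graded_axis(z_breaks, s_z)
  mesh <- tensor_mesh(rs * 1e-3, zs * 1e-3) # mm -> m
  cent <- triangle_centroids(mesh)
  mesh$region <- region_at(scenario, cent[, 1] * 1e3, cent[, 2] * 1e3)
  mesh$btag <- tag_rectangle_boundary(
    mesh, R * 1e-3, H * 1e-3,
    port = c(g$r_inner, g$r_dielectric) * 1e-3
  )
  mesh$h <- list(h_min = h_min, h_max = h_max, refine = refine)
  mesh$port_radii <- c(g$r_inner, g$r_dielectric) * 1e-3
  mesh
}

#' Structured rectangle mesh (mainly for tests and oracles)
#'
#' Uniform tensor-product mesh of `[r0, r1] x [z0, z1]` with `2 * nr * nz`
#' triangles, a single region, and boundary tags assignable per side.
#'
#' @param r0,r1,z0,z1 Rectangle extents in metres.
#' @param nr,nz Cell counts per axis.
#' @param region Region label for every triangle.
#' @param tags Named list with entries `left`, `right`, `bottom`, `top`
#'   giving the boundary tag of each side.
#' @return An `abl_mesh`.
#' @export
rect_mesh <- function(r0, r1, z0, z1, nr, nz, region = "tissue",
                      tags = list(
                        left = "axis", right = "exterior",
                        bottom = "exterior", top = "exterior"
                      )) {
  rs <- seq(r0, r1, length.out = nr + 1)
  zs <- seq(z0, z1, length.out = nz + 1)
  mesh <- tensor_mesh(rs, zs)
  mesh$region <- rep(region, nrow(mesh$tri))
  mid_r <- (mesh$nodes[mesh$bedges[, 1], 1] + mesh$nodes[mesh$bedges[, 2], 1]) / 2
  mid_z <- (mesh$nodes[mesh$bedges[, 1], 2] + mesh$nodes[mesh$bedges[, 2], 2]) / 2
  tol <- 1e-12 + 1e-9 * max(abs(r1), abs(z1))
  tag <- rep(NA_character_, nrow(mesh$bedges))
  tag[abs(mid_r - r0) < tol] <- tags$left
  tag[abs(mid_r - r1) < tol] <- tags$right
  tag[abs(mid_z - z0) < tol] <- tags$bottom
  tag[abs(mid_z - z1) < tol] <- tags$top
  mesh$btag <- tag
  mesh$h <- list(
    h_min = min(diff(rs), diff(zs)) * 1e3,
    h_max = max(diff(rs), diff(zs)) * 1e3, refine = 1
  )
  mesh
}

# Core tensor-product triangulation; coordinates in metres.
tensor_mesh <- function(rs, zs) {
  nodes_r <- rs
  nodes_z <- zs
  nr <- length(nodes_r)
  nz <- length(nodes_z)
  nodes <- cbind(
    r = rep(nodes_r, times = nz),
    z = rep(nodes_z, each = nr)
  )
  idx <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = nr - 1L)
  n00 <- idx(i, j)
  n10 <- idx(i + 1L, j)
  n01 <- idx(i, j + 1L)
  n11 <- idx(i + 1L, j + 1L)
  tri <- rbind(
    cbind(n00, n10, n11),
    cbind(n00, n11, n01)
  )
  mesh <- structure(
    list(nodes = nodes, tri = tri, region = NULL, bedges = NULL, btag = NULL),
    class = "abl_mesh"
  )
  mesh$bedges <- boundary_edges(mesh)
  mesh
}

# Edges owned by exactly one triangle.
boundary_edges <- function(mesh) {
  t <- mesh$tri
  e <- rbind(t[, 1:2], t[, 2:3], t[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

tag_rectangle_boundary <- function(mesh, R, H, port) {
  mid_r <- (mesh$nodes[mesh$bedges[, 1], 1] + mesh$nodes[mesh$bedges[, 2], 1]) / 2
  mid_z <- (mesh$nodes[mesh$bedges[, 1], 2] + mesh$nodes[mesh$bedges[, 2], 2]) / 2
  tol <- 1e-9 * max(R, H)
  tag <- rep("exterior", length(mid_r))
  tag[mid_r < tol] <- "axis"
  on_top <- abs(mid_z - H) < tol
  tag[on_top & mid_r > port[1] - tol & mid_r < port[2] + tol] <- "port"
  tag
}

# --- geometric helpers ------------------------------------------------------

triangle_geometry <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  area <- det / 2
  # shape-function gradients: grad lambda_i = (b_i, c_i)
  b1 <- (p2[, 2] - p3[, 2]) / det
  b2 <- (p3[, 2] - p1[, 2]) / det
  b3 <- (p1[, 2] - p2[, 2]) / det
  c1 <- (p3[, 1] - p2[, 1]) / det
  c2 <- (p1[, 1] - p3[, 1]) / det
  c3 <- (p2[, 1] - p1[, 1]) / det
  list(
    area = area,
    r = cbind(p1[, 1], p2[, 1], p3[, 1]),
    z = cbind(p1[, 2], p2[, 2], p3[, 2]),
    rbar = (p1[, 1] + p2[, 1] + p3[, 1]) / 3,
    b = cbind(b1, b2, b3), c = cbind(c1, c2, c3)
  )
}

triangle_centroids <- function(mesh) {
  (mesh$nodes[mesh$tri[, 1], , drop = FALSE] +
    mesh$nodes[mesh$tri[, 2], , drop = FALSE] +
    mesh$nodes[mesh$tri[, 3], , drop = FALSE]) / 3
}

#' Mesh summary statistics
#'
#' Deterministic summary used in logs: node/element/boundary counts,
#' minimum interior angle, edge-length range, and per-region element
#' counts and areas.
#'
#' @param mesh An `abl_mesh`.
#' @return A list of class `abl_mesh_report`.
#' @export
mesh_quality_report <- function(mesh) {
  geo <- triangle_geometry(mesh)
  if (any(geo$area <= 0)) abort("mesh contains non-positively-oriented triangles")
  e1 <- sqrt((geo$r[, 2] - geo$r[, 1])^2 + (geo$z[, 2] - geo$z[, 1])^2)
  e2 <- sqrt((geo$r[, 3] - geo$r[, 2])^2 + (geo$z[, 3] - geo$z[, 2])^2)
  e3 <- sqrt((geo$r[, 1] - geo$r[, 3])^2 + (geo$z[, 1] - geo$z[, 3])^2)
  # law of cosines per corner
  ang <- function(a, b, c) acos(pmin(1, pmax(-1, (a^2 + b^2 - c^2) / (2 * a * b))))
  angles <- cbind(ang(e1, e3, e2), ang(e1, e2, e3), ang(e2, e3, e1))
  reg <- mesh$region %||% rep("domain", nrow(mesh$tri))
  structure(
    list(
      n_nodes = nrow(mesh$nodes),
      n_elements = nrow(mesh$tri),
      n_boundary_edges = nrow(mesh$bedges),
      min_angle_deg = min(angles) * 180 / pi,
      edge_length_range = range(c(e1, e2, e3)),
      total_area = sum(geo$area),
      region_elements = table(reg),
      region_area = tapply(geo$area, reg, sum)
    ),
    class = "abl_mesh_report"
  )
}

#' @export
print.abl_mesh_report <- function(x, ...) {
  cat(sprintf(
    "<mesh> %d nodes, %d elements, %d boundary edges | min angle %.2f deg | edges %.3g-%.3g m\n",
    x$n_nodes, x$n_elements, x$n_boundary_edges, x$min_angle_deg,
    x$edge_length_range[1], x$edge_length_range[2]
  ))
  print(x$region_elements)
  invisible(x)
}

#' @export
print.abl_mesh <- function(x, ...) {
  cat(sprintf(
    "<abl_mesh> %d nodes, %d triangles, regions: %s\n",
    nrow(x$nodes), nrow(x$tri),
    paste(unique(x$region %||% "untagged"), collapse = ", ")
  ))
  invisible(x)
}

#' Export a mesh (with optional fields) as legacy ASCII VTK
#'
#' Writes an unstructured-grid `.vtk` file readable by ParaView/VisIt.
#' Axisymmetric (r, z) coordinates map to (x, y), zero z.
#'
#' @param mesh An `abl_mesh`.
#' @param path Output file path.
#' @param point_data Named list of per-node numeric vectors.
#' @param cell_data Named list of per-triangle numeric vectors.
#' @return `path` invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tri)
  writeLines(c(
    "# vtk DataFile Version 3.0", "mwablate mesh", "ASCII",
    "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)
  ), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf(
    "3 %d %d %d",
    mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L, mesh$tri[, 3] - 1L
  ), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(
        sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"
      ), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(
        sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"
      ), con)
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}
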