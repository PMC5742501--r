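#' @name lesion_metrics
#' @title Lesion metrics from temperature fields
#'
#' @description The ablation zone is taken as the region enclosed by the
#' 55 degree C isotherm (cell death in under a minute at that temperature).
#' The lesion radius is the axis-distance (r-coordinate) of the farthest
#' point of that isotherm, measured from the centre of the applicator.
NULL

#' Extract an isotherm from a nodal temperature field
#'
#' Linear interpolation along triangle edges; returns the contour as a set
#' of per-triangle segments (closed or boundary-terminated polylines when
#' chained). Every returned point sits on the requested level to linear
#' interpolation accuracy.
#'
#' @param mesh An `abl_mesh`.
#' @param temperature Nodal temperatures (degrees C).
#' @param level Isotherm level (degrees C).
#' @return A tibble of class `abl_isotherm` with columns `triangle`, `r1`,
#'   `z1`, `r2`, `z2` (mm); empty if the level is not crossed.
#' @export
extract_isotherm <- function(mesh, temperature, level = 55) {
  stopifnot(length(temperature) == nrow(mesh$nodes))
  tri <- mesh$tri
  Tv <- cbind(temperature[tri[, 1]], temperature[tri[, 2]], temperature[tri[, 3]])
  pr <- cbind(mesh$nodes[tri[, 1], 1], mesh$nodes[tri[, 2], 1], mesh$nodes[tri[, 3], 1])
  pz <- cbind(mesh$nodes[tri[, 1], 2], mesh$nodes[tri[, 2], 2], mesh$nodes[tri[, 3], 2])

  segs <- list()
  edge_pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  cross_r <- cross_z <- matrix(NA_real_, nrow(tri), 3)
  for (e in 1:3) {
    a <- edge_pairs[[e]][1]
    bidx <- edge_pairs[[e]][2]
    Ta <- Tv[, a]
    Tb <- Tv[, bidx]
    hit <- (Ta - level) * (Tb - level) < 0
    t <- (level - Ta[hit]) / (Tb[hit] - Ta[hit])
    cross_r[hit, e] <- pr[hit, a] + t * (pr[hit, bidx] - pr[hit, a])
    cross_z[hit, e] <- pz[hit, a] + t * (pz[hit, bidx] - pz[hit, a])
  }
  ncross <- rowSums(!is.na(cross_r))
  two <- which(ncross == 2)
  if (!length(two)) {
    out <- tibble(
      triangle = integer(0), r1 = numeric(0), z1 = numeric(0),
      r2 = numeric(0), z2 = numeric(0)
    )
  } else {
    pts <- t(vapply(two, function(k) {
      w <- which(!is.na(cross_r[k, ]))
      c(cross_r[k, w[1]], cross_z[k, w[1]], cross_r[k, w[2]], cross_z[k, w[2]])
    }, numeric(4)))
    out <- tibble(
      triangle = two,
      r1 = pts[, 1] * 1e3, z1 = pts[, 2] * 1e3,
      r2 = pts[, 3] * 1e3, z2 = pts[, 4] * 1e3
    )
  }
  attr(out, "level") <- level
  class(out) <- c("abl_isotherm", class(out))
  out
}

#' Lesion radius from a temperature series
#'
#' Maximum axis-distance (r-coordinate, mm) over all points of the
#' `level`-degree isotherm at the requested time; zero when no node reaches
#' the level. Nodes at or above the level are included so a contour hugging
#' the domain boundary cannot shrink the measure.
#'
#' @param series An `abl_temp_series`.
#' @param level Isotherm level (degrees C), default 55.
#' @param at_time Evaluation time (s); defaults to the final snapshot.
#' @return Radius in mm.
#' @export
lesion_radius <- function(series, level = 55, at_time = max(series$times)) {
  Tn <- series_at_time(series, at_time)
  hot <- Tn >= level
  if (!any(hot)) {
    return(0)
  }
  iso <- extract_isotherm(series$mesh, Tn, level)
  max(series$mesh$nodes[hot, 1] * 1e3, iso$r1, iso$r2)
}

# barycentric coordinates of a point in each candidate triangle
locate_point <- function(mesh, r_m, z_m) {
  geo <- triangle_geometry(mesh)
  # solve for lambda_2, lambda_3 via gradients: lambda_i(p) = lambda_i(centroid) + grad.(p - centroid)
  l <- vapply(1:3, function(i) {
    1 / 3 + geo$b[, i] * (r_m - geo$rbar) + geo$c[, i] * (z_m - (geo$z[, 1] + geo$z[, 2] + geo$z[, 3]) / 3)
  }, numeric(nrow(mesh$tri)))
  tol <- -1e-9
  inside <- which(l[, 1] >= tol & l[, 2] >= tol & l[, 3] >= tol)
  if (!length(inside)) {
    abort(sprintf("position (%.3g, %.3g) mm is outside the domain", r_m * 1e3, z_m * 1e3))
  }
  k <- inside[1]
  list(tri = k, lambda = pmax(l[k, ], 0) / sum(pmax(l[k, ], 0)))
}

#' Temperature-probe time series by barycentric interpolation
#'
#' Interpolates the stored snapshots at fixed (r, z) probe positions; at a
#' mesh node the trace is exactly the nodal history, and any field that is
#' linear over the containing triangle is reproduced to round-off.
#'
#' @param series An `abl_temp_series`.
#' @param positions Two-column matrix / data frame of probe positions
#'   (r, z) in mm.
#' @return A tibble: `probe`, `r_mm`, `z_mm`, `time`, `temperature`.
#' @export
probe_trace <- function(series, positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2) abort("positions must have two columns (r, z) in mm")
  rows <- purrr::map(seq_len(nrow(positions)), function(p) {
    loc <- locate_point(series$mesh, positions[p, 1] * 1e-3, positions[p, 2] * 1e-3)
    nodes <- series$mesh$tri[loc$tri, ]
    Tv <- as.numeric(loc$lambda %*% series$T[nodes, , drop = FALSE])
    tibble(
      probe = p, r_mm = positions[p, 1], z_mm = positions[p, 2],
      time = series$times, temperature = Tv
    )
  })
  dplyr::bind_rows(rows)
}

#' Default probe positions
#'
#' The hottest point next to the slots (1.6, 2.6) mm, the maximum ablation
#' radius (4.2, 3) mm — both given relative to the slot centre — and a
#' near-surface point beside the applicator shaft.
#'
#' @param scenario An `abl_scenario` (to convert slot-relative coordinates
#'   into domain coordinates).
#' @return Matrix of (r, z) positions in mm.
#' @export
default_probes <- function(scenario) {
  lv <- scenario_levels(scenario)
  rbind(
    hottest = c(1.6, lv$z_slot_centre + 2.6),
    max_radius = c(4.2, lv$z_slot_centre + 3),
    near_surface = c(scenario$geometry$r_catheter + 0.5, scenario$domain_height - 2)
  )
}

#' Post-process a temperature series into a lesion report
#'
#' @param series An `abl_temp_series`.
#' @param level Ablation isotherm (degrees C).
#' @param at_time Report time (s); defaults to the final snapshot (500 s in
#'   the stock scenarios, the time needed to approach steady state).
#' @param probes Optional probe positions (mm) for traces.
#' @return An object of class `abl_lesion`: `t_max` (max over every stored
#'   snapshot of the nodal maxima), `time_of_max`, `lesion_radius` (mm),
#'   `isotherm` segments, `probe_traces`.
#' @export
lesion_report <- function(series, level = 55, at_time = max(series$times),
                          probes = NULL) {
  per_snap <- apply(series$T, 2, max)
  Tn <- series_at_time(series, at_time)
  iso <- extract_isotherm(series$mesh, Tn, level)
  structure(
    list(
      t_max = max(per_snap),
      time_of_max = series$times[which.max(per_snap)],
      lesion_radius = lesion_radius(series, level, at_time),
      level = level, at_time = at_time,
      isotherm = iso,
      probe_traces = if (!is.null(probes)) probe_trace(series, probes) else NULL
    ),
    class = "abl_lesion"
  )
}

#' @export
print.abl_lesion <- function(x, ...) {
  cat(sprintf(
    "<abl_lesion> T_max = %.1f C (t = %g s) | %g C isotherm radius = %.2f mm at t = %g s\n",
    x$t_max, x$time_of_max, x$level, x$lesion_radius, x$at_time
  ))
  invisible(x)
}

#' @export
glance.abl_lesion <- function(x, ...) {
  tibble(
    t_max = x$t_max, time_of_max = x$time_of_max,
    lesion_radius = x$lesion_radius, level = x$level, at_time = x$at_time
  )
}

#' Write a lesion report as JSON
#'
#' @param report An `abl_lesion`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_lesion_json <- function(report, path) {
  obj <- list(
    t_max = report$t_max, time_of_max = report$time_of_max,
    lesion_radius_mm = report$lesion_radius, level = report$level,
    at_time = report$at_time,
    isotherm = as.data.frame(report$isotherm)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
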