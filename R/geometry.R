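#' Parametric double-slot microcoaxial antenna geometry
#'
#' All lengths in millimetres. The antenna is a semirigid microcoaxial cable
#' (inner conductor / PTFE dielectric / outer conductor) inside a PTFE
#' catheter, with two ring slots cut in the outer conductor near a
#' short-circuited tip. Defaults follow the published applicator: conductor
#' diameters 0.51 / 1.68 / 2.197 mm, catheter 2.64 mm, two 1 mm wide slots,
#' total length 140 mm. The axial layout follows the design rule that both
#' the tip-to-slot gap and the slot-to-slot gap equal a quarter effective
#' wavelength in tumour tissue at 2.45 GHz (0.25 lambda_eff = 3.97 mm),
#' which places the slot centres about 5 mm apart.
#'
#' @param r_inner Radius of the central conductor (mm).
#' @param r_dielectric Outer radius of the coax dielectric (mm).
#' @param r_outer Outer radius of the outer conductor (mm).
#' @param r_catheter Outer radius of the catheter (mm).
#' @param slot_width Axial width of each ring slot (mm).
#' @param slot_separation Axial gap between the two slots, edge to edge (mm).
#' @param tip_to_first_slot Distance from the antenna tip to the tip-side
#'   edge of the first slot (mm). Default `0.25 * lambda_eff` in tumour
#'   tissue at 2.45 GHz.
#' @param total_length Total applicator length (mm); only the inserted
#'   portion is modelled.
#' @param tip_length Axial extent of the shorting metal at the tip (mm).
#' @param cap_length Axial extent of the catheter cap below the tip (mm).
#'
#' @return An object of class `abl_antenna`.
#' @export
antenna_geometry <- function(r_inner = 0.51 / 2,
                             r_dielectric = 1.68 / 2,
                             r_outer = 2.197 / 2,
                             r_catheter = 2.64 / 2,
                             slot_width = 1,
                             slot_separation = 0.25 * 1e3 *
                               effective_wavelength(2.45e9, 59.385),
                             tip_to_first_slot = 0.25 * 1e3 *
                               effective_wavelength(2.45e9, 59.385),
                             total_length = 140,
                             tip_length = 0.5,
                             cap_length = 0.5) {
  if (!(r_inner < r_dielectric && r_dielectric < r_outer && r_outer < r_catheter)) {
    abort("antenna radii must satisfy r_inner < r_dielectric < r_outer < r_catheter")
  }
  if (slot_width <= 0) abort("slot_width must be > 0")
  if (slot_separation <= 0) abort("slot_separation must be > 0")
  if (tip_to_first_slot <= tip_length) {
    abort("tip_to_first_slot must exceed the tip shorting length")
  }
  slot_span <- tip_to_first_slot + 2 * slot_width + slot_separation
  if (slot_span >= total_length) abort("slots must lie within the antenna length")
  structure(
    list(
      r_inner = r_inner, r_dielectric = r_dielectric, r_outer = r_outer,
      r_catheter = r_catheter, slot_width = slot_width,
      slot_separation = slot_separation, tip_to_first_slot = tip_to_first_slot,
      total_length = total_length, tip_length = tip_length,
      cap_length = cap_length
    ),
    class = "abl_antenna"
  )
}

#' Build a simulation scenario
#'
#' A scenario bundles the antenna geometry, the axisymmetric computational
#' domain, the region-to-material map, blood parameters, and the excitation.
#' Three canonical constructors exist:
#' \describe{
#'   \item{`breast_only`}{applicator in homogeneous breast tissue;}
#'   \item{`tumor_in_breast`}{a 12.5 mm-radius spherical tumour centred on
#'     the slots (a semicircle in the (r,z) half-plane), surrounded by
#'     breast tissue;}
#'   \item{`phantom`}{tissue-mimicking phantom properties in the same
#'     tumour-in-breast layout.}
#' }
#'
#' The antenna is inserted along the symmetry axis from the top of the
#' domain; by default the insertion depth places the slot pair at the axial
#' midplane of the domain, where the tumour (if any) is centred.
#'
#' @param kind One of `"breast_only"`, `"tumor_in_breast"`, `"phantom"`.
#' @param overrides Named list overriding scenario fields: `domain_radius`,
#'   `domain_height`, `tumor_radius`, `input_power`, `frequency`,
#'   `ambient_temperature`, `insertion_depth`, `slot_fill` (`"air"` or
#'   `"coax_dielectric"`), `geometry` (an [antenna_geometry()] or named list
#'   of its arguments), `materials` (overrides passed to
#'   [material_library()]), `blood` (a [blood_parameters()]).
#'
#' @return An object of class `abl_scenario`. Lengths in mm, power in W,
#'   frequency in Hz, temperatures in degrees C.
#' @export
#' @examples
#' scn <- build_scenario("tumor_in_breast")
#' scn$tumor_radius # 12.5 mm
build_scenario <- function(kind = c("breast_only", "tumor_in_breast", "phantom"),
                           overrides = list()) {
  kind <- match.arg(kind)
  known <- c(
    "domain_radius", "domain_height", "tumor_radius", "input_power",
    "frequency", "ambient_temperature", "insertion_depth", "slot_fill",
    "geometry", "materials", "blood"
  )
  bad <- setdiff(names(overrides), known)
  if (length(bad)) abort(sprintf("unknown scenario override(s): %s", paste(bad, collapse = ", ")))

  geo <- overrides$geometry %||% antenna_geometry()
  if (!inherits(geo, "abl_antenna")) geo <- do.call(antenna_geometry, geo)
  lib <- material_library(overrides$materials %||% list())

  s <- list(
    kind = kind,
    geometry = geo,
    domain_radius = overrides$domain_radius %||% 30,
    domain_height = overrides$domain_height %||% 80,
    tumor_radius = overrides$tumor_radius %||%
      (if (kind == "breast_only") NA_real_ else 12.5),
    input_power = overrides$input_power %||% 10,
    frequency = overrides$frequency %||% 2.45e9,
    ambient_temperature = overrides$ambient_temperature %||% 25,
    slot_fill = overrides$slot_fill %||% "air",
    blood = overrides$blood %||% blood_parameters()
  )
  if (kind == "breast_only" && !is.null(overrides$tumor_radius) &&
    !is.na(overrides$tumor_radius)) {
    abort("breast_only scenario cannot carry a tumor_radius")
  }

  # place the centre of the slot pair at the domain axial midplane
  slot_centre_rel <- geo$tip_to_first_slot + geo$slot_width + geo$slot_separation / 2
  s$insertion_depth <- overrides$insertion_depth %||%
    (s$domain_height / 2 + slot_centre_rel)

  tissue <- switch(kind,
    breast_only = lib$breast, tumor_in_breast = lib$breast,
    phantom = lib$phantom_breast
  )
  tum <- switch(kind,
    breast_only = NULL, tumor_in_breast = lib$tumor, phantom = lib$phantom_tumor
  )
  s$region_materials <- list(
    conductor = lib$copper,
    coax_dielectric = lib$coax_dielectric,
    slot = if (s$slot_fill == "air") lib$air else lib$coax_dielectric,
    catheter = lib$catheter,
    tissue = tissue
  )
  if (!is.null(tum)) s$region_materials$tumor <- tum

  s <- structure(s, class = "abl_scenario")
  validate_scenario(s)
  s
}

# Derived axial positions (mm, z measured up from the domain bottom).
scenario_levels <- function(s) {
  g <- s$geometry
  z_tip <- s$domain_height - s$insertion_depth
  s1l <- z_tip + g$tip_to_first_slot
  s2l <- s1l + g$slot_width + g$slot_separation
  list(
    z_tip = z_tip,
    z_cap_bot = z_tip - g$cap_length,
    z_short_top = z_tip + g$tip_length,
    s1l = s1l, s1u = s1l + g$slot_width,
    s2l = s2l, s2u = s2l + g$slot_width,
    z_slot_centre = z_tip + g$tip_to_first_slot + g$slot_width +
      g$slot_separation / 2
  )
}

validate_scenario <- function(s) {
  g <- s$geometry
  lv <- scenario_levels(s)
  if (g$r_catheter >= s$domain_radius) {
    abort("invariant violated: catheter radius must be smaller than domain_radius")
  }
  if (lv$z_cap_bot <= 0) {
    abort("invariant violated: antenna tip (and catheter cap) must lie inside the domain")
  }
  if (lv$s2u >= s$domain_height) {
    abort("invariant violated: both slots must lie strictly within the inserted portion")
  }
  if (s$insertion_depth > g$total_length) {
    abort("invariant violated: insertion_depth exceeds the antenna length")
  }
  if (!is.na(s$tumor_radius)) {
    if (s$tumor_radius <= g$r_catheter) {
      abort("invariant violated: tumor_radius must exceed the catheter radius")
    }
    zc <- lv$z_slot_centre
    if (s$tumor_radius >= s$domain_radius ||
      zc - s$tumor_radius <= 0 || zc + s$tumor_radius >= s$domain_height) {
      abort("invariant violated: tumor sphere must fit inside the domain")
    }
  }
  if (s$input_power <= 0) abort("invariant violated: input_power must be > 0")
  if (s$frequency <= 0) abort("invariant violated: frequency must be > 0")
  invisible(s)
}

#' Region label at points of the axisymmetric half-plane
#'
#' Classifies (r, z) points (mm) into the scenario's region partition:
#' `conductor`, `coax_dielectric`, `slot`, `catheter`, `tumor`, `tissue`.
#' The partition covers the whole rectangle `[0, domain_radius] x
#' [0, domain_height]` with no gaps or overlaps.
#'
#' @param s An `abl_scenario`.
#' @param r,z Coordinate vectors (mm), recycled to common length.
#' @return Character vector of region labels.
#' @export
region_at <- function(s, r, z) {
  g <- s$geometry
  lv <- scenario_levels(s)
  n <- max(length(r), length(z))
  r <- rep_len(r, n)
  z <- rep_len(z, n)

  in_slot <- (z > lv$s1l & z < lv$s1u) | (z > lv$s2l & z < lv$s2u)
  cond <- (r < g$r_inner & z > lv$z_tip) |
    (r < g$r_outer & z > lv$z_tip & z < lv$z_short_top) |
    (r > g$r_dielectric & r < g$r_outer & z > lv$z_short_top & !in_slot)
  diel <- !cond & r < g$r_dielectric & z > lv$z_short_top
  slot <- !cond & !diel & r > g$r_dielectric & r < g$r_outer & z > lv$z_short_top
  cath <- !cond & !diel & !slot & r < g$r_catheter & z > lv$z_cap_bot

  out <- rep("tissue", n)
  if (!is.na(s$tumor_radius)) {
    zc <- lv$z_slot_centre
    out[r^2 + (z - zc)^2 < s$tumor_radius^2] <- "tumor"
  }
  out[cath] <- "catheter"
  out[slot] <- "slot"
  out[diel] <- "coax_dielectric"
  out[cond] <- "conductor"
  out
}

#' Numeric region areas of the (r,z) half-plane partition
#'
#' Midpoint quadrature of [region_at()] on an `n x n` grid; the areas sum to
#' `domain_radius * domain_height` exactly because the partition is total.
#'
#' @param s An `abl_scenario`.
#' @param n Grid resolution per axis.
#' @return Tibble with `region` and `area_mm2`.
#' @export
region_areas <- function(s, n = 400) {
  dr <- s$domain_radius / n
  dz <- s$domain_height / n
  rg <- (seq_len(n) - 0.5) * dr
  zg <- (seq_len(n) - 0.5) * dz
  pts <- expand.grid(r = rg, z = zg)
  lab <- region_at(s, pts$r, pts$z)
  tibble(region = names(table(lab)), area_mm2 = as.numeric(table(lab)) * dr * dz) |>
    dplyr::arrange(dplyr::desc(.data$area_mm2))
}

#' @export
print.abl_scenario <- function(x, ...) {
  cat(sprintf(
    "<abl_scenario> %s: domain %g x %g mm, P = %g W @ %g GHz, T_amb = %g C\n",
    x$kind, x$domain_radius, x$domain_height, x$input_power,
    x$frequency / 1e9, x$ambient_temperature
  ))
  if (!is.na(x$tumor_radius)) {
    cat(sprintf("  tumour radius %g mm centred on the slots\n", x$tumor_radius))
  }
  cat(sprintf(
    "  regions: %s\n",
    paste(names(x$region_materials), collapse = ", ")
  ))
  invisible(x)
}

#' Serialize a scenario to a YAML config
#'
#' Keys match the scenario/geometry/material field names; lengths in mm,
#' power in W, frequency in Hz, temperatures in degrees C. A scenario
#' round-trips through [scenario_from_yaml()] unchanged.
#'
#' @param s An `abl_scenario`.
#' @param path File path to write; if `NULL` the YAML string is returned.
#' @return `path` invisibly, or the YAML string.
#' @export
scenario_to_yaml <- function(s, path = NULL) {
  mats <- purrr::map(s$region_materials, function(m) {
    m <- unclass(m)
    m[c(
      "name", "eps_r", "sigma", "mu_r", "k_thermal", "density",
      "heat_capacity", "is_conductor"
    )]
  })
  obj <- list(
    kind = s$kind,
    geometry = unclass(s$geometry),
    domain_radius = s$domain_radius,
    domain_height = s$domain_height,
    tumor_radius = if (is.na(s$tumor_radius)) NULL else s$tumor_radius,
    input_power = s$input_power,
    frequency = s$frequency,
    ambient_temperature = s$ambient_temperature,
    insertion_depth = s$insertion_depth,
    slot_fill = s$slot_fill,
    blood = unclass(s$blood),
    region_materials = mats
  )
  txt <- yaml::as.yaml(obj, precision = 15)
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Load a scenario from a YAML config
#'
#' @param path File path written by [scenario_to_yaml()] (or hand-edited).
#' @return An `abl_scenario`.
#' @export
scenario_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  geo <- do.call(antenna_geometry, obj$geometry)
  s <- structure(
    list(
      kind = obj$kind,
      geometry = geo,
      domain_radius = obj$domain_radius,
      domain_height = obj$domain_height,
      tumor_radius = obj$tumor_radius %||% NA_real_,
      input_power = obj$input_power,
      frequency = obj$frequency,
      ambient_temperature = obj$ambient_temperature,
      slot_fill = obj$slot_fill,
      blood = do.call(blood_parameters, obj$blood),
      insertion_depth = obj$insertion_depth,
      region_materials = purrr::map(obj$region_materials, function(m) {
        do.call(material_properties, m)
      })
    ),
    class = "abl_scenario"
  )
  validate_scenario(s)
  s
}
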