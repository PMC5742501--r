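#' Electromagnetic and thermal properties of one medium
#'
#' Container for the constants that drive both physics: the complex
#' permittivity entering the harmonic Maxwell solve and the thermal constants
#' entering the Pennes bioheat solve.
#'
#' @param name Medium label.
#' @param eps_r Relative permittivity (dimensionless, >= 1 for physical media).
#' @param sigma Electrical conductivity (S/m, >= 0).
#' @param mu_r Relative magnetic permeability (1 for all media modelled here).
#' @param k_thermal Thermal conductivity (W/m/K).
#' @param density Mass density (kg/m^3).
#' @param heat_capacity Specific heat capacity (J/kg/K).
#' @param is_conductor Logical; metals are treated as perfect electric
#'   conductors in the electromagnetic solve (excluded from the EM domain,
#'   natural PEC boundary) but participate in the thermal solve.
#'
#' @return An object of class `abl_material`.
#' @export
material_properties <- function(name, eps_r, sigma, mu_r = 1,
                                k_thermal, density, heat_capacity,
                                is_conductor = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is_conductor && eps_r < 1) {
    abort(sprintf("material '%s': eps_r must be >= 1 for physical media", name))
  }
  if (sigma < 0) abort(sprintf("material '%s': sigma must be >= 0", name))
  if (mu_r != 1) abort(sprintf("material '%s': only mu_r = 1 media are supported", name))
  if (k_thermal <= 0 || density <= 0 || heat_capacity <= 0) {
    abort(sprintf("material '%s': thermal properties must be positive", name))
  }
  structure(
    list(
      name = name, eps_r = eps_r, sigma = sigma, mu_r = mu_r,
      k_thermal = k_thermal, density = density, heat_capacity = heat_capacity,
      is_conductor = is_conductor
    ),
    class = "abl_material"
  )
}

#' @export
print.abl_material <- function(x, ...) {
  cat(sprintf(
    "<abl_material> %s: eps_r=%.4g sigma=%.4g S/m | k=%.3g W/m/K rho=%.4g kg/m3 c=%.4g J/kg/K%s\n",
    x$name, x$eps_r, x$sigma, x$k_thermal, x$density, x$heat_capacity,
    if (x$is_conductor) " [PEC]" else ""
  ))
  invisible(x)
}

#' Blood parameters for the Pennes perfusion term
#'
#' The perfusion sink is `rho_bl * C_bl * omega * (T_bl - T)` with the
#' perfusion rate `omega` given as a volumetric rate (1/s). A rate of zero
#' reproduces the ex vivo condition (no perfusion).
#'
#' @param density_bl Blood density (kg/m^3).
#' @param heat_capacity_bl Blood specific heat (J/kg/K).
#' @param perfusion_rate Volumetric blood perfusion rate (1/s, >= 0);
#'   default 0.0036 1/s, the rate listed among the simulation conditions.
#' @param blood_temperature Arterial blood temperature (degrees C).
#'
#' @return An object of class `abl_blood`.
#' @export
blood_parameters <- function(density_bl = 920, heat_capacity_bl = 3639,
                             perfusion_rate = 0.0036, blood_temperature = 37) {
  if (perfusion_rate < 0) abort("perfusion_rate must be >= 0")
  if (density_bl <= 0 || heat_capacity_bl <= 0) {
    abort("blood density and heat capacity must be positive")
  }
  structure(
    list(
      density_bl = density_bl, heat_capacity_bl = heat_capacity_bl,
      perfusion_rate = perfusion_rate, blood_temperature = blood_temperature
    ),
    class = "abl_blood"
  )
}

#' Registry of all material property sets used by the model
#'
#' Dielectric values: tumour (59.385, 3.156 S/m) and breast (5.1467,
#' 0.137 S/m) at 2.45 GHz; coaxial cable internal dielectric 2.03 and PTFE
#' catheter 2.60. Thermal conductivities: breast 0.42, tumour 0.50 W/m/K.
#' Breast/tumour mass density and heat capacity are not part of the published
#' property set; the defaults below come from standard tissue-property
#' literature and are configurable — they affect only the transient approach
#' to steady state, not the steady temperature field.
#'
#' @param overrides Named list of partial material overrides, e.g.
#'   `list(breast = list(heat_capacity = 2800))`.
#'
#' @return Named list of [material_properties()] objects with entries
#'   `breast`, `tumor`, `coax_dielectric`, `catheter`, `air`, `copper`,
#'   `phantom_breast`, `phantom_tumor`.
#' @export
#' @examples
#' lib <- material_library()
#' lib$tumor$sigma # 3.156
material_library <- function(overrides = list()) {
  lib <- list(
    breast = material_properties("breast",
      eps_r = 5.1467, sigma = 0.137,
      k_thermal = 0.42, density = 1000, heat_capacity = 3000
    ),
    tumor = material_properties("tumor",
      eps_r = 59.385, sigma = 3.156,
      k_thermal = 0.50, density = 1050, heat_capacity = 3600
    ),
    coax_dielectric = material_properties("coax_dielectric",
      eps_r = 2.03, sigma = 0,
      k_thermal = 0.20, density = 2200, heat_capacity = 1050
    ),
    catheter = material_properties("catheter",
      eps_r = 2.60, sigma = 0,
      k_thermal = 0.20, density = 2200, heat_capacity = 1050
    ),
    air = material_properties("air",
      eps_r = 1, sigma = 0,
      k_thermal = 0.026, density = 1.2, heat_capacity = 1005
    ),
    copper = material_properties("copper",
      eps_r = 1, sigma = 0,
      k_thermal = 400, density = 8960, heat_capacity = 385,
      is_conductor = TRUE
    ),
    # Synthetic stand-ins for the benchtop tissue-mimicking materials:
    # dielectrics are the measured 2.45 GHz values; thermal constants are
    # plausible oil-based (breast) and water/ethanol (tumour) mixture values.
    phantom_breast = material_properties("phantom_breast",
      eps_r = 5.1467, sigma = 0.137,
      k_thermal = 0.25, density = 950, heat_capacity = 2500
    ),
    phantom_tumor = material_properties("phantom_tumor",
      eps_r = 59.385, sigma = 3.156,
      k_thermal = 0.55, density = 1000, heat_capacity = 3800
    )
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(lib)) abort(sprintf("unknown material '%s'", nm))
    fields <- overrides[[nm]]
    for (f in names(fields)) lib[[nm]][[f]] <- fields[[f]]
  }
  structure(lib, class = "abl_material_library")
}

#' Tidy view of a material library
#'
#' @param x Material library (named list of `abl_material`).
#' @param ... Unused.
#' @return A tibble with one row per medium.
#' @export
tidy.abl_material_library <- function(x, ...) {
  purrr::map_dfr(unclass(x), function(m) tibble::as_tibble(unclass(m)))
}

#' Effective wavelength in a dielectric medium
#'
#' `lambda_eff = c / (f * sqrt(eps_r * mu_r))`. At 2.45 GHz with the tumour
#' permittivity 59.385 this is 15.88 mm; a quarter of it sets the tip-to-slot
#' spacing of the applicator.
#'
#' @param frequency Operating frequency (Hz, > 0).
#' @param eps_r Relative permittivity (>= 1).
#' @param mu_r Relative permeability (> 0).
#'
#' @return Wavelength in metres.
#' @export
#' @examples
#' effective_wavelength(2.45e9, 59.385) * 1e3 # 15.88 mm
effective_wavelength <- function(frequency, eps_r, mu_r = 1) {
  if (any(frequency <= 0)) abort("frequency must be > 0")
  if (any(eps_r < 1)) abort("eps_r must be >= 1")
  if (any(mu_r <= 0)) abort("mu_r must be > 0")
  .c0 / (frequency * sqrt(eps_r * mu_r))
}

# Complex relative permittivity eps_r - j sigma/(omega eps0), e^{+j omega t}.
complex_permittivity <- function(mat, frequency) {
  omega <- 2 * pi * frequency
  complex(real = mat$eps_r, imaginary = -mat$sigma / (omega * .eps0))
}
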