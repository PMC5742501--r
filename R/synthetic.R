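#' @name synthetic_data
#' @title Synthetic stand-ins for measured inputs
#'
#' @description Emulators for the three measured inputs of a benchtop
#' validation campaign: frequency-dependent tissue dielectric curves,
#' subject-to-subject property variation, and noisy fibre-optic temperature
#' probe readings. They let validation-style comparisons run without
#' hardware; they do not claim to reproduce any particular measured
#' spectrum beyond the 2.45 GHz anchor values.
NULL

#' Tissue dielectric dispersion model
#'
#' Linear-in-log-frequency curves anchored exactly at the 2.45 GHz values
#' (tumour 59.385 / 3.156 S/m, breast 5.1467 / 0.137 S/m), with relative
#' permittivity decreasing and conductivity increasing with frequency over
#' the 2-3.5 GHz band — the qualitative shape of measured tissue spectra
#' in this band. Slopes are per natural-log frequency unit.
#'
#' @param tissue `"breast"` or `"tumor"`.
#' @param eps_slope,sigma_slope Optional slope overrides.
#' @return An object of class `abl_dispersion` with a `predict()`-style
#'   accessor via [dispersion_at()].
#' @export
dispersion_model <- function(tissue = c("breast", "tumor"),
                             eps_slope = NULL, sigma_slope = NULL) {
  tissue <- match.arg(tissue)
  anchor <- switch(tissue,
    breast = list(eps_r = 5.1467, sigma = 0.137, es = -0.4, ss = 0.25),
    tumor = list(eps_r = 59.385, sigma = 3.156, es = -4.0, ss = 3.0)
  )
  structure(
    list(
      tissue = tissue, f0 = 2.45e9,
      eps_anchor = anchor$eps_r, sigma_anchor = anchor$sigma,
      eps_slope = eps_slope %||% anchor$es,
      sigma_slope = sigma_slope %||% anchor$ss
    ),
    class = "abl_dispersion"
  )
}

#' Evaluate a dispersion model
#'
#' @param model An [dispersion_model()].
#' @param frequency Frequencies (Hz).
#' @return Tibble with `frequency`, `eps_r`, `sigma`.
#' @export
dispersion_at <- function(model, frequency) {
  lf <- log(frequency / model$f0)
  tibble(
    frequency = frequency,
    eps_r = pmax(1, model$eps_anchor + model$eps_slope * lf),
    sigma = pmax(0, model$sigma_anchor + model$sigma_slope * lf)
  )
}

#' Draw subject-perturbed material properties
#'
#' Dielectric properties vary from subject to subject; this draws a
#' multiplicative log-normal perturbation of the dispersion model's
#' permittivity and conductivity at the given frequency. The log-normal is
#' mean-preserving with coefficient of variation `cv`; `cv = 0` returns the
#' anchor values exactly, and a fixed seed reproduces the draw.
#'
#' @param model An [dispersion_model()].
#' @param frequency Frequency (Hz).
#' @param cv Relative standard deviation (>= 0).
#' @param seed Integer seed.
#' @param base Template [material_properties()] supplying the thermal
#'   constants; defaults to the matching entry of [material_library()].
#' @return An `abl_material` with perturbed `eps_r` and `sigma`.
#' @export
sample_properties <- function(model, frequency = model$f0, cv = 0, seed = 1,
                              base = NULL) {
  if (cv < 0) abort("cv must be >= 0")
  d <- dispersion_at(model, frequency)
  if (is.null(base)) {
    base <- material_library()[[model$tissue]]
  }
  fac <- c(1, 1)
  if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    fac <- withr::with_seed(seed, exp(rnorm(2, mean = -sdl^2 / 2, sd = sdl)))
  }
  material_properties(
    name = sprintf("%s_draw", model$tissue),
    eps_r = max(1, d$eps_r * fac[1]),
    sigma = d$sigma * fac[2],
    k_thermal = base$k_thermal, density = base$density,
    heat_capacity = base$heat_capacity
  )
}

#' Fibre-optic temperature probe model
#'
#' First-order sensor lag (response time constant 0.25 s), additive
#' Gaussian read noise, clipping to the 0-120 degree C probe range, and
#' quantisation to the 0.01 degree C thermometer resolution.
#'
#' @param sample_interval Sampling interval (s).
#' @param noise_sd Additive noise standard deviation (degrees C).
#' @param tau Response time constant (s).
#' @param range Measurement range (degrees C).
#' @param resolution Quantisation step (degrees C).
#' @return An object of class `abl_probe_model`.
#' @export
probe_model <- function(sample_interval = 1, noise_sd = 0.1, tau = 0.25,
                        range = c(0, 120), resolution = 0.01) {
  if (tau < 0 || noise_sd < 0) abort("tau and noise_sd must be >= 0")
  structure(
    list(
      sample_interval = sample_interval, noise_sd = noise_sd, tau = tau,
      range = range, resolution = resolution
    ),
    class = "abl_probe_model"
  )
}

#' Simulate noisy probe readings from a true temperature trace
#'
#' Applies the first-order lag exactly for piecewise-constant input between
#' samples, adds Gaussian noise, clips to range, quantises. Deterministic
#' under a fixed seed; with `tau = 0` and `noise_sd = 0` the reading equals
#' the (clipped, quantised) input.
#'
#' @param time Monotone time grid (s).
#' @param temperature True temperatures (degrees C) on that grid.
#' @param probe An [probe_model()].
#' @param seed Integer seed.
#' @return Tibble: `time`, `true`, `reading`.
#' @export
simulate_probe <- function(time, temperature, probe = probe_model(), seed = 1) {
  if (length(time) != length(temperature)) abort("time/temperature length mismatch")
  if (any(diff(time) <= 0)) abort("time grid must be strictly increasing")
  n <- length(time)
  y <- numeric(n)
  y[1] <- temperature[1]
  if (probe$tau > 0) {
    for (i in 2:n) {
      a <- exp(-(time[i] - time[i - 1]) / probe$tau)
      y[i] <- a * y[i - 1] + (1 - a) * temperature[i]
    }
  } else {
    y <- temperature
  }
  if (probe$noise_sd > 0) {
    y <- y + withr::with_seed(seed, rnorm(n, sd = probe$noise_sd))
  }
  y <- pmin(probe$range[2], pmax(probe$range[1], y))
  y <- round(y / probe$resolution) * probe$resolution
  tibble(time = time, true = temperature, reading = y)
}
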