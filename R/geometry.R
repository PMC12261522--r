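#' Cuboid scintillator geometry
#'
#' Describes a rectangular scintillator crystal read out through one face.
#' The crystal frame has its origin at the centre of the exit (photodetector)
#' face: `x` and `y` span the face, `z` runs from 0 (detector) to `length_z`
#' (far end), so the emission depth of interaction is simply the `z`
#' coordinate. The exit face at `z = 0` is optically coupled (Fresnel
#' transmission into a medium of index `n_coupling`); the five remaining
#' faces carry a diffuse reflector with scalar reflectivity.
#'
#' Defaults describe a 3 x 3 x 10 mm BGO crystal (index 2.15) coupled with
#' epoxy (index 1.56) and wrapped in Teflon.
#'
#' @param half_width_x,half_width_y Half-widths of the exit face in mm.
#' @param length_z Crystal length along the readout axis in mm.
#' @param n_crystal Refractive index of the scintillator bulk.
#' @param n_coupling Refractive index of the optical coupling medium at the
#'   exit face.
#' @param reflector_reflectivity Survival probability at a reflector face,
#'   in `[0, 1]`.
#' @param attenuation_length Bulk attenuation length in mm; `Inf` disables
#'   bulk absorption.
#' @param max_bounces Photons are killed after this many surface
#'   interactions (counted separately from absorption).
#'
#' @return An object of class `crystal_geometry`.
#' @examples
#' geom <- crystal_geometry()
#' geom$length_z
#' @export
crystal_geometry <- function(half_width_x = 1.5,
                             half_width_y = 1.5,
                             length_z = 10.0,
                             n_crystal = 2.15,
                             n_coupling = 1.56,
                             reflector_reflectivity = 0.95,
                             attenuation_length = 300,
                             max_bounces = 1000L) {
  stopifnot(
    half_width_x > 0, half_width_y > 0, length_z > 0,
    n_crystal >= 1, n_coupling >= 1,
    reflector_reflectivity >= 0, reflector_reflectivity <= 1,
    attenuation_length > 0,
    max_bounces >= 1
  )
  structure(
    list(
      half_width_x = half_width_x,
      half_width_y = half_width_y,
      length_z = length_z,
      n_crystal = n_crystal,
      n_coupling = n_coupling,
      reflector_reflectivity = reflector_reflectivity,
      attenuation_length = attenuation_length,
      max_bounces = as.integer(max_bounces)
    ),
    class = "crystal_geometry"
  )
}

#' @export
print.crystal_geometry <- function(x, ...) {
  cat(sprintf(
    "<crystal_geometry> %g x %g x %g mm, n = %g -> %g, reflectivity %g, attenuation %g mm\n",
    2 * x$half_width_x, 2 * x$half_width_y, x$length_z,
    x$n_crystal, x$n_coupling, x$reflector_reflectivity, x$attenuation_length
  ))
  invisible(x)
}

#' Scintillation emission spectrum
#'
#' Gaussian model of the optical emission spectrum in energy, truncated to
#' strictly positive energies by resampling. The default mean of 2.58 eV
#' corresponds to the ~480 nm emission peak of BGO.
#'
#' @param mean_energy Mean photon energy in eV.
#' @param sd_energy Standard deviation in eV; 0 gives a monochromatic line.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(mean_energy = 2.58, sd_energy = 0.15) {
  stopifnot(mean_energy > 0, sd_energy >= 0)
  structure(
    list(mean_energy = mean_energy, sd_energy = sd_energy),
    class = "emission_spectrum"
  )
}

#' Scintillation light yield model
#'
#' Number of optical photons created per event, Poisson-distributed. The
#' default mean of 2400 corresponds to a 420 keV photoelectron in BGO and
#' gives roughly 2.4 million photons for 1000 events.
#'
#' @param mean_photons_per_event Mean photons per event (Poisson mean).
#' @return An object of class `yield_model`.
#' @export
yield_model <- function(mean_photons_per_event = 2400) {
  stopifnot(mean_photons_per_event >= 0)
  structure(
    list(mean_photons_per_event = mean_photons_per_event, law = "poisson"),
    class = "yield_model"
  )
}

#' Read a simulation configuration file
#'
#' Loads geometry, emission spectrum and yield settings from a YAML file
#' with top-level keys `geometry`, `spectrum` and `yield`; unknown keys are
#' an error, missing ones fall back to the documented defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `geometry`, `spectrum` and `yield`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("geometry", "spectrum", "yield")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  }
  check_args <- function(given, fn, what) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad) > 0) {
      stop("unknown ", what, " settings: ", paste(bad, collapse = ", "))
    }
    given
  }
  list(
    geometry = do.call(crystal_geometry,
                       check_args(raw$geometry %||% list(), crystal_geometry, "geometry")),
    spectrum = do.call(emission_spectrum,
                       check_args(raw$spectrum %||% list(), emission_spectrum, "spectrum")),
    yield = do.call(yield_model,
                    check_args(raw$yield %||% list(), yield_model, "yield"))
  )
}

point_inside <- function(point, geometry, strict = TRUE) {
  cmp <- if (strict) `<` else `<=`
  cmp(abs(point[1]), geometry$half_width_x) &&
    cmp(abs(point[2]), geometry$half_width_y) &&
    point[3] > 0 && point[3] < geometry$length_z
}
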