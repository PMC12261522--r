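#' Sample photon energies from an emission spectrum
#'
#' Draws energies from the Gaussian spectrum model, resampling any
#' non-positive draws so every returned energy is strictly positive.
#'
#' @param n Number of energies to draw.
#' @param spectrum An [emission_spectrum()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of `n` energies in eV.
#' @export
sample_emission_spectrum <- function(n, spectrum = emission_spectrum(), seed = NULL) {
  if (!is_count(n)) stop("`n` must be a single non-negative integer")
  with_seed(seed)
  e <- stats::rnorm(n, spectrum$mean_energy, spectrum$sd_energy)
  while (any(bad <- e <= 0)) {
    e[bad] <- stats::rnorm(sum(bad), spectrum$mean_energy, spectrum$sd_energy)
  }
  e
}

#' Sample isotropic unit direction vectors
#'
#' Uniform directions on the sphere: `cos(theta)` uniform on `[-1, 1]`,
#' azimuth uniform on `[0, 2*pi)`.
#'
#' @param n Number of directions.
#' @param seed Optional integer seed.
#' @return An `n x 3` matrix of unit vectors.
#' @export
isotropic_directions <- function(n, seed = NULL) {
  if (!is_count(n)) stop("`n` must be a single non-negative integer")
  with_seed(seed)
  cz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sz <- sqrt(pmax(0, 1 - cz^2))
  cbind(dX = sz * cos(phi), dY = sz * sin(phi), dZ = cz)
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized Fresnel reflectances at a planar
#' dielectric interface. Beyond the critical angle (when `n_in > n_out`)
#' the reflectance is exactly 1 (total internal reflection).
#'
#' @param cos_incidence Cosine of the incidence angle, in `(0, 1]`.
#'   Vectorized.
#' @param n_in,n_out Refractive indices of the incident and transmitting
#'   media.
#' @return Reflectance in `[0, 1]`, same length as `cos_incidence`.
#' @examples
#' fresnel_reflectance(1, 2.15, 1.56) # normal incidence off BGO/epoxy
#' @export
fresnel_reflectance <- function(cos_incidence, n_in, n_out) {
  if (any(cos_incidence <= 0 | cos_incidence > 1)) {
    stop("`cos_incidence` must lie in (0, 1]")
  }
  stopifnot(n_in >= 1, n_out >= 1)
  sin2_t <- (n_in / n_out)^2 * (1 - cos_incidence^2)
  r <- rep(1, length(cos_incidence)) # total internal reflection default
  ok <- sin2_t < 1
  if (any(ok)) {
    ci <- cos_incidence[ok]
    ct <- sqrt(1 - sin2_t[ok])
    rs <- ((n_in * ci - n_out * ct) / (n_in * ci + n_out * ct))^2
    rp <- ((n_in * ct - n_out * ci) / (n_in * ct + n_out * ci))^2
    r[ok] <- (rs + rp) / 2
  }
  pmin(pmax(r, 0), 1)
}

#' Refract a direction at a planar interface
#'
#' Vector form of Snell's law. The outward surface normal must point out of
#' the incident medium, so `sum(direction * normal) > 0` for a photon
#' travelling into the surface.
#'
#' @param direction Incident unit direction (length-3).
#' @param normal Outward unit surface normal (length-3).
#' @param n_in,n_out Refractive indices.
#' @return The transmitted unit direction, or `NULL` when the angle is
#'   beyond the critical angle (total internal reflection); no error is
#'   raised in that case.
#' @export
refract <- function(direction, normal, n_in, n_out) {
  ci <- sum(direction * normal)
  if (ci <= 0) stop("`direction` must point into the surface (direction . normal > 0)")
  eta <- n_in / n_out
  sin2_t <- eta^2 * (1 - ci^2)
  if (sin2_t >= 1) return(NULL)
  ct <- sqrt(1 - sin2_t)
  t <- eta * direction - (eta * ci - ct) * normal
  t / sqrt(sum(t^2))
}

# Vectorized transport of a photon bundle through the crystal.
#
# All photons advance one surface interaction per loop iteration. Faces:
# z = 0 is the optically coupled exit (Fresnel transmit/reflect), the five
# others are diffuse reflectors (Lambertian re-emission with survival
# probability reflector_reflectivity). Bulk attenuation is exponential in
# path length. Returns exit records plus outcome counts.
trace_bundle <- function(pos, dir, energy, geometry) {
  n <- nrow(pos)
  status <- integer(n) # 0 alive, 1 exit, 2 absorbed, 3 capped
  bounces <- integer(n)
  out <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("X", "Y", "dX", "dY", "dZ")))
  hx <- geometry$half_width_x
  hy <- geometry$half_width_y
  lz <- geometry$length_z
  att <- geometry$attenuation_length

  alive <- which(status == 0L)
  while (length(alive) > 0) {
    p <- pos[alive, , drop = FALSE]
    d <- dir[alive, , drop = FALSE]

    plane_t <- function(x, v, lo, hi) {
      t <- rep(Inf, length(x))
      t[v > 0] <- (hi - x[v > 0]) / v[v > 0]
      t[v < 0] <- (lo - x[v < 0]) / v[v < 0]
      t
    }
    tx <- plane_t(p[, 1], d[, 1], -hx, hx)
    ty <- plane_t(p[, 2], d[, 2], -hy, hy)
    tz <- plane_t(p[, 3], d[, 3], 0, lz)
    tmin <- pmin(tx, ty, tz)
    face <- ifelse(tmin == tz, ifelse(d[, 3] < 0, "exit", "zfar"),
                   ifelse(tmin == tx, "x", "y"))

    # bulk attenuation over the flight path
    if (is.finite(att)) {
      s_abs <- stats::rexp(length(alive)) * att
      killed <- s_abs < tmin
    } else {
      killed <- rep(FALSE, length(alive))
    }
    status[alive[killed]] <- 2L

    p <- p + d * tmin
    # snap onto the hit plane to avoid drift
    p[face == "x", 1] <- sign(d[face == "x", 1]) * hx
    p[face == "y", 2] <- sign(d[face == "y", 2]) * hy
    p[face == "exit", 3] <- 0
    p[face == "zfar", 3] <- lz
    p[, 1] <- pmin(pmax(p[, 1], -hx), hx)
    p[, 2] <- pmin(pmax(p[, 2], -hy), hy)
    p[, 3] <- pmin(pmax(p[, 3], 0), lz)
    pos[alive, ] <- p

    live <- !killed
    u <- stats::runif(length(alive))

    # exit face: Fresnel transmit or specular reflect
    at_exit <- live & face == "exit"
    if (any(at_exit)) {
      ci <- -d[at_exit, 3]
      refl <- fresnel_reflectance(ci, geometry$n_crystal, geometry$n_coupling)
      transmit <- u[at_exit] >= refl
      idx_t <- alive[at_exit][transmit]
      if (length(idx_t) > 0) {
        eta <- geometry$n_crystal / geometry$n_coupling
        ct <- sqrt(1 - eta^2 * (1 - ci[transmit]^2))
        dt <- cbind(eta * d[at_exit, 1, drop = TRUE][transmit],
                    eta * d[at_exit, 2, drop = TRUE][transmit],
                    -ct)
        out[idx_t, ] <- cbind(p[at_exit, 1][transmit],
                              p[at_exit, 2][transmit],
                              dt)
        status[idx_t] <- 1L
      }
      idx_r <- alive[at_exit][!transmit]
      if (length(idx_r) > 0) {
        dir[idx_r, 3] <- -dir[idx_r, 3]
        bounces[idx_r] <- bounces[idx_r] + 1L
      }
    }

    # reflector faces: survive with probability reflector_reflectivity,
    # then re-emit from a cosine lobe about the inward normal
    at_refl <- live & face != "exit"
    if (any(at_refl)) {
      surv <- u[at_refl] < geometry$reflector_reflectivity
      status[alive[at_refl][!surv]] <- 2L
      idx_s <- alive[at_refl][surv]
      if (length(idx_s) > 0) {
        m <- length(idx_s)
        cth <- sqrt(stats::runif(m))
        sth <- sqrt(pmax(0, 1 - cth^2))
        phi <- stats::runif(m, 0, 2 * pi)
        a1 <- sth * cos(phi)
        a2 <- sth * sin(phi)
        f <- face[at_refl][surv]
        newd <- matrix(0, m, 3)
        px <- pos[idx_s, , drop = FALSE]
        is_x <- f == "x"
        is_y <- f == "y"
        is_z <- f == "zfar"
        # inward normal along the hit axis; lobe tangents on the other two
        newd[is_x, 1] <- -sign(px[is_x, 1]) * cth[is_x]
        newd[is_x, 2] <- a1[is_x]
        newd[is_x, 3] <- a2[is_x]
        newd[is_y, 2] <- -sign(px[is_y, 2]) * cth[is_y]
        newd[is_y, 1] <- a1[is_y]
        newd[is_y, 3] <- a2[is_y]
        newd[is_z, 3] <- -cth[is_z]
        newd[is_z, 1] <- a1[is_z]
        newd[is_z, 2] <- a2[is_z]
        dir[idx_s, ] <- newd
        bounces[idx_s] <- bounces[idx_s] + 1L
      }
    }

    capped <- status == 0L & bounces > geometry$max_bounces
    status[capped] <- 3L
    alive <- which(status == 0L)
  }

  list(
    status = status,
    bounces = bounces,
    exits = tibble::tibble(
      X = unname(out[status == 1L, "X"]),
      Y = unname(out[status == 1L, "Y"]),
      dX = unname(out[status == 1L, "dX"]),
      dY = unname(out[status == 1L, "dY"]),
      dZ = unname(out[status == 1L, "dZ"]),
      EKine = unname(energy[status == 1L])
    )
  )
}

#' Trace a single photon through the crystal
#'
#' Propagates one optical photon until it exits through the photodetector
#' face, is absorbed (in the bulk or at a reflector), or exceeds the bounce
#' cap.
#'
#' @param position Length-3 starting position in mm, strictly inside the
#'   crystal.
#' @param direction Length-3 unit direction.
#' @param energy Photon energy in eV.
#' @param geometry A [crystal_geometry()].
#' @param seed Optional integer seed.
#' @return A list with `outcome` (one of `"exit"`, `"absorbed"`,
#'   `"capped"`), `bounces`, and for exits a one-row `record` tibble with
#'   columns `X, Y, dX, dY, dZ, EKine`.
#' @export
trace_photon <- function(position, direction, energy = 2.58,
                         geometry = crystal_geometry(), seed = NULL) {
  if (!point_inside(position, geometry)) {
    stop("photon must start strictly inside the crystal")
  }
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) stop("`direction` must be a unit vector")
  stopifnot(energy > 0)
  with_seed(seed)
  res <- trace_bundle(matrix(position, 1), matrix(direction, 1), energy, geometry)
  list(
    outcome = c("exit", "absorbed", "capped")[res$status],
    bounces = res$bounces,
    record = if (res$status == 1L) res$exits else NULL
  )
}

phase_space_columns <- c("X", "Y", "dX", "dY", "dZ", "EKine", "emX", "emY", "emZ")

#' Simulate detected photons from one emission point
#'
#' Emits `n_photons` isotropically from `point` with energies drawn from
#' `spectrum`, traces them through the crystal, and returns one row per
#' photon transmitted through the photodetector face (the photodetector is
#' ideal: every transmitted photon is detected). Positions and directions
#' are recorded after refraction into the coupling medium.
#'
#' @param point Length-3 emission point in mm, strictly inside the crystal.
#' @param n_photons Number of photons to emit.
#' @param geometry A [crystal_geometry()].
#' @param spectrum An [emission_spectrum()].
#' @param seed Optional integer seed; fixed seed gives an identical table.
#' @return A phase-space tibble with columns
#'   `X, Y, dX, dY, dZ, EKine, emX, emY, emZ` and at most `n_photons` rows.
#' @examples
#' ps <- simulate_point(c(0.5, 0.5, 1), 1000, seed = 1)
#' nrow(ps) # detected subset
#' @export
simulate_point <- function(point, n_photons,
                           geometry = crystal_geometry(),
                           spectrum = emission_spectrum(),
                           seed = NULL) {
  if (!point_inside(point, geometry)) stop("emission point outside the crystal")
  if (!is_count(n_photons)) stop("`n_photons` must be a single non-negative integer")
  with_seed(seed)
  if (n_photons == 0) {
    return(empty_phase_space())
  }
  energy <- sample_emission_spectrum(n_photons, spectrum)
  dirs <- isotropic_directions(n_photons)
  pos <- matrix(rep(point, each = n_photons), n_photons, 3)
  res <- trace_bundle(pos, dirs, energy, geometry)
  dplyr::mutate(res$exits,
                emX = point[1], emY = point[2], emZ = point[3])
}

empty_phase_space <- function() {
  tibble::tibble(
    X = double(), Y = double(), dX = double(), dY = double(), dZ = double(),
    EKine = double(), emX = double(), emY = double(), emZ = double()
  )
}

#' Sample scintillation events for an activity level
#'
#' Draws the number of decays in an acquisition as
#' `Poisson(activity * duration)` and, for each event, the number of
#' optical photons created (`n_op`) from the yield model. All events share
#' the supplied emission point, mirroring a fixed electron source position.
#'
#' @param activity Source activity in Bq.
#' @param duration Acquisition duration in s.
#' @param yield A [yield_model()].
#' @param emission_point Length-3 emission point in mm.
#' @param seed Optional integer seed.
#' @return An event tibble with columns `event_id, emX, emY, emZ, n_op`.
#' @examples
#' ev <- sample_events(1000, 1, emission_point = c(0.5, 0.5, 1), seed = 1)
#' sum(ev$n_op) # ~ 2.4 million photons
#' @export
sample_events <- function(activity, duration, yield = yield_model(),
                          emission_point = c(0.5, 0.5, 1.0), seed = NULL) {
  if (!is.numeric(activity) || activity <= 0) stop("`activity` must be positive")
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be positive")
  with_seed(seed)
  n_events <- stats::rpois(1, activity * duration)
  tibble::tibble(
    event_id = seq_len(n_events),
    emX = emission_point[1],
    emY = emission_point[2],
    emZ = emission_point[3],
    n_op = stats::rpois(n_events, yield$mean_photons_per_event)
  )
}

#' Expand an event table into a per-step particle log
#'
#' Produces the kind of step-level record a tracking simulation emits when
#' photons are killed at creation: for each event, one electron record at
#' step 0 located at the emission point, followed by `n_op` optical-photon
#' creation records. Useful as input to
#' [extract_emission_coordinates()].
#'
#' @param events An event tibble from [sample_events()].
#' @return A tibble with columns `event_id, particle, step_index, x, y, z`.
#' @export
as_event_log <- function(events) {
  electrons <- tibble::tibble(
    event_id = events$event_id,
    particle = "e-",
    step_index = 0L,
    x = events$emX, y = events$emY, z = events$emZ
  )
  photons <- tidyr::uncount(
    tibble::tibble(
      event_id = events$event_id,
      particle = "opticalphoton",
      x = events$emX, y = events$emY, z = events$emZ,
      n = events$n_op
    ),
    weights = .data$n
  )
  photons <- dplyr::mutate(
    dplyr::group_by(photons, .data$event_id),
    step_index = dplyr::row_number()
  )
  photons <- dplyr::ungroup(photons)
  log <- dplyr::bind_rows(electrons,
                          dplyr::select(photons, "event_id", "particle",
                                        "step_index", "x", "y", "z"))
  dplyr::arrange(log, .data$event_id, .data$step_index, .data$particle)
}
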