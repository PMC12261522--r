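#' Extract per-event emission coordinates and photon counts
#'
#' The surrogate needs two inputs per event: the emission coordinates and
#' the number of optical photons to generate (`n_op`). From a step-level
#' particle log — where optical photons are recorded at creation and then
#' killed, rather than tracked — this takes the earliest electron record of
#' each event as the emission point and counts the optical-photon records.
#'
#' @param event_log A data frame with columns
#'   `event_id, particle, step_index, x, y, z`; particle types may
#'   interleave. Electrons are `"e-"`, optical photons `"opticalphoton"`.
#' @return An event tibble with columns `event_id, emX, emY, emZ, n_op`
#'   (events with zero photons are retained).
#' @export
extract_emission_coordinates <- function(event_log) {
  needed <- c("event_id", "particle", "step_index", "x", "y", "z")
  missing <- setdiff(needed, names(event_log))
  if (length(missing) > 0) {
    stop("event log missing column(s): ", paste(missing, collapse = ", "))
  }
  electrons <- dplyr::filter(event_log, .data$particle == "e-")
  no_electron <- setdiff(unique(event_log$event_id), unique(electrons$event_id))
  if (length(no_electron) > 0) {
    stop("event(s) without an electron record: ",
         paste(sort(no_electron), collapse = ", "))
  }
  first_e <- dplyr::slice_min(dplyr::group_by(electrons, .data$event_id),
                              .data$step_index, n = 1, with_ties = FALSE)
  first_e <- dplyr::ungroup(first_e)
  counts <- dplyr::count(
    dplyr::filter(event_log, .data$particle == "opticalphoton"),
    .data$event_id, name = "n_op"
  )
  out <- dplyr::left_join(
    dplyr::select(first_e, "event_id", emX = "x", emY = "y", emZ = "z"),
    counts,
    by = "event_id"
  )
  out <- dplyr::mutate(out, n_op = as.integer(tidyr::replace_na(.data$n_op, 0L)))
  dplyr::arrange(out, .data$event_id)
}

#' Generate detector-face phase space with the trained surrogate
#'
#' For each event, draws `n_op` latent vectors, conditions the generator on
#' the event's emission coordinates (normalized with the statistics stored
#' in the checkpoint), denormalizes the six generated features back to
#' physical units and attaches the emission coordinates. Latents are drawn
#' up front from the seed, so the generation batch size cannot change the
#' result.
#'
#' @param events Event tibble (`event_id, emX, emY, emZ, n_op`), e.g. from
#'   [extract_emission_coordinates()] or [sample_events()].
#' @param checkpoint A `gan_checkpoint` carrying generator parameters and
#'   normalization statistics.
#' @param seed Optional integer seed.
#' @param geometry Crystal geometry used to validate the emission points.
#' @param clip If `TRUE`, clamp `|X|, |Y|` to the face half-widths and
#'   rescale `(dX, dY, dZ)` to unit norm. Off by default: raw generator
#'   output is reported faithfully.
#' @param batch_size Rows per generator call (memory bound only).
#' @return A phase-space tibble with exactly `sum(events$n_op)` rows.
#' @export
run_surrogate <- function(events, checkpoint, seed = NULL,
                          geometry = crystal_geometry(), clip = FALSE,
                          batch_size = 65536) {
  stopifnot(inherits(checkpoint, "gan_checkpoint"))
  if (is.null(checkpoint$stats)) stop("checkpoint carries no normalization stats")
  if (nrow(events) > 0) {
    ok <- purrr::pmap_lgl(events[, c("emX", "emY", "emZ")],
                          ~ point_inside(c(..1, ..2, ..3), geometry, strict = FALSE))
    if (!all(ok)) {
      stop("emission point(s) outside the crystal for event(s): ",
           paste(events$event_id[!ok], collapse = ", "))
    }
  }
  n_total <- sum(events$n_op)
  if (n_total == 0) return(empty_phase_space())

  stats <- checkpoint$stats
  config <- checkpoint$config
  cond_phys <- tibble::tibble(
    emX = rep(events$emX, events$n_op),
    emY = rep(events$emY, events$n_op),
    emZ = rep(events$emZ, events$n_op)
  )
  cond <- as.matrix(normalize_table(cond_phys, stats))
  with_seed(seed)
  z <- matrix(stats::rnorm(n_total * config$latent_dim), n_total)

  feat_norm <- matrix(NA_real_, n_total, 6)
  starts <- seq(1, n_total, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1, n_total)
    feat_norm[s:e, ] <- generator_forward(z[s:e, , drop = FALSE],
                                          cond[s:e, , drop = FALSE],
                                          checkpoint$generator)
  }
  colnames(feat_norm) <- phase_space_columns[1:6]
  feat <- denormalize_table(tibble::as_tibble(feat_norm), stats)
  out <- dplyr::bind_cols(feat, cond_phys)
  if (clip) out <- clip_phase_space(out, geometry)
  out
}

clip_phase_space <- function(table, geometry) {
  nrm <- sqrt(table$dX^2 + table$dY^2 + table$dZ^2)
  nrm[nrm == 0] <- 1
  dplyr::mutate(
    table,
    X = pmin(pmax(.data$X, -geometry$half_width_x), geometry$half_width_x),
    Y = pmin(pmax(.data$Y, -geometry$half_width_y), geometry$half_width_y),
    dX = .data$dX / nrm, dY = .data$dY / nrm, dZ = .data$dZ / nrm
  )
}

#' Subsample a phase-space table without replacement
#'
#' Uniform random subset of exactly `n` rows, used to match sample sizes
#' before a similarity comparison.
#'
#' @param table A phase-space tibble.
#' @param n Rows to keep; must not exceed `nrow(table)`.
#' @param seed Optional integer seed.
#' @return A tibble with exactly `n` rows.
#' @export
subsample_phase_space <- function(table, n, seed = NULL) {
  if (!is_count(n)) stop("`n` must be a single non-negative integer")
  if (n > nrow(table)) {
    stop("cannot subsample ", n, " rows from a table of ", nrow(table))
  }
  with_seed(seed)
  table[sample.int(nrow(table), n), ]
}
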