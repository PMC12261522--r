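#' Phase-space table schema
#'
#' A phase-space table records one detected optical photon per row at the
#' photodetector face: position `X, Y` (mm), direction components
#' `dX, dY, dZ`, kinetic energy `EKine` (eV), and the emission coordinates
#' `emX, emY, emZ` (mm) that condition the surrogate. Column order and
#' names are fixed.
#'
#' @param table A data frame to validate.
#' @return `table`, invisibly, as a tibble in canonical column order.
#' @export
check_phase_space <- function(table) {
  missing <- setdiff(phase_space_columns, names(table))
  extra <- setdiff(names(table), phase_space_columns)
  if (length(missing) > 0 || length(extra) > 0) {
    stop(
      "phase-space schema mismatch",
      if (length(missing) > 0) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra) > 0) paste0("; extra: ", paste(extra, collapse = ", "))
    )
  }
  invisible(tibble::as_tibble(table)[phase_space_columns])
}

#' Emission-point grid
#'
#' Builds the default training grid: a 10-point triangular lattice covering
#' one octant of the crystal cross-section (positions
#' `x, y in {0, 0.5, 1.0, hx - 0.01}` with `y <= x`, so boundary points sit
#' strictly inside the face), replicated at each requested depth of
#' interaction. With the default three depths this gives 30 emission
#' points, including the reference point `(0.5, 0.5, 1.0)`.
#'
#' @param geometry A [crystal_geometry()].
#' @param depths Depths of interaction in mm (distance from the
#'   photodetector face), each strictly inside `(0, length_z)`.
#' @return A tibble with columns `emX, emY, emZ`, one row per point.
#' @examples
#' nrow(emission_grid()) # 30
#' @export
emission_grid <- function(geometry = crystal_geometry(),
                          depths = c(1.0, 5.0, 9.0)) {
  if (any(depths <= 0 | depths >= geometry$length_z)) {
    stop("all depths must lie strictly inside (0, length_z)")
  }
  eps <- 0.01
  xv <- c(0, 0.5, 1.0, geometry$half_width_x - eps)
  xv <- xv[xv < geometry$half_width_x]
  cross <- tidyr::crossing(emX = xv, emY = xv)
  cross <- dplyr::filter(cross, .data$emY <= .data$emX)
  grid <- tidyr::crossing(cross, emZ = sort(depths))
  grid <- dplyr::arrange(grid, .data$emZ, .data$emX, .data$emY)
  if (anyDuplicated(grid) > 0) stop("duplicate emission points")
  grid
}

#' Build a training dataset over an emission grid
#'
#' Runs the transport simulation at every grid point, re-simulating in
#' batches until exactly `n_per_point` detected rows are accumulated for
#' each point (equal-size per-point sets), then concatenates the tables.
#'
#' @param grid A tibble of emission points (`emX, emY, emZ`), e.g. from
#'   [emission_grid()].
#' @param n_per_point Detected rows to accumulate per emission point.
#' @param geometry A [crystal_geometry()].
#' @param spectrum An [emission_spectrum()].
#' @param seed Optional integer seed; fixed seed reproduces the table.
#' @return A phase-space tibble with `nrow(grid) * n_per_point` rows.
#' @export
build_training_dataset <- function(grid, n_per_point,
                                   geometry = crystal_geometry(),
                                   spectrum = emission_spectrum(),
                                   seed = NULL) {
  stopifnot(is_count(n_per_point), n_per_point > 0)
  with_seed(seed)
  parts <- purrr::pmap(grid, function(emX, emY, emZ) {
    point <- c(emX, emY, emZ)
    acc <- list()
    got <- 0L
    emit <- as.integer(ceiling(n_per_point / 0.5)) # rough detection efficiency guess
    while (got < n_per_point) {
      batch <- simulate_point(point, emit, geometry, spectrum)
      acc[[length(acc) + 1]] <- batch
      got <- got + nrow(batch)
      # refine the batch size from the observed efficiency
      eff <- max(got / (emit * length(acc)), 0.05)
      emit <- as.integer(ceiling((n_per_point - got) / eff * 1.2)) + 100L
    }
    dplyr::slice_head(dplyr::bind_rows(acc), n = n_per_point)
  })
  dplyr::bind_rows(parts)
}

#' Per-column normalization statistics
#'
#' Computes the mean and standard deviation of every column of a
#' phase-space table. These statistics are stored at training time and are
#' the only statistics used to denormalize generated data. The population
#' convention (divide by `N`) is used for the standard deviation.
#'
#' @param table A phase-space tibble (all nine columns).
#' @return An object of class `normalization_stats`: a tibble with columns
#'   `column, mean, sd`, plus `n_rows` and a content hash as attributes.
#' @export
compute_stats <- function(table) {
  table <- check_phase_space(table)
  if (nrow(table) == 0) stop("cannot compute statistics of an empty table")
  stats_tbl <- tibble::tibble(
    column = names(table),
    mean = unname(purrr::map_dbl(table, mean)),
    sd = unname(purrr::map_dbl(table, ~ sqrt(mean((.x - mean(.x))^2))))
  )
  const <- stats_tbl$column[stats_tbl$sd == 0]
  if (length(const) > 0) {
    stop("constant column(s) with zero standard deviation: ",
         paste(const, collapse = ", "))
  }
  structure(stats_tbl,
            class = c("normalization_stats", class(stats_tbl)),
            n_rows = nrow(table),
            dataset_hash = dataset_hash(table))
}

# order-sensitive numeric content hash, used to tie checkpoints to the
# statistics of the dataset they were trained on
dataset_hash <- function(table) {
  x <- unlist(lapply(table, function(col) c(length(col), sum(col), sum(col^2))))
  paste(format(sum(x * seq_along(x)), digits = 17), length(x), sep = "-")
}

#' Normalize or denormalize a phase-space table
#'
#' `normalize_table()` z-scores every column covered by `stats`;
#' `denormalize_table()` inverts it. Conditioning columns are normalized
#' together with the features at training time; generated output carries
#' only the six feature columns, so `stats` may cover a subset of the nine
#' columns on denormalization.
#'
#' @param table A data frame whose columns are all present in `stats`.
#' @param stats A [compute_stats()] result.
#' @return A tibble of the same shape.
#' @export
normalize_table <- function(table, stats) {
  scale_table(table, stats, forward = TRUE)
}

#' @rdname normalize_table
#' @export
denormalize_table <- function(table, stats) {
  scale_table(table, stats, forward = FALSE)
}

scale_table <- function(table, stats, forward) {
  missing <- setdiff(names(table), stats$column)
  if (length(missing) > 0) {
    stop("no statistics for column(s): ", paste(missing, collapse = ", "))
  }
  out <- tibble::as_tibble(table)
  for (nm in names(out)) {
    i <- match(nm, stats$column)
    out[[nm]] <- if (forward) {
      (out[[nm]] - stats$mean[i]) / stats$sd[i]
    } else {
      out[[nm]] * stats$sd[i] + stats$mean[i]
    }
  }
  out
}

#' Persist normalization statistics as JSON
#'
#' @param stats A [compute_stats()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path) {
  jsonlite::write_json(
    list(
      columns = stats$column, mean = stats$mean, sd = stats$sd,
      n_rows = attr(stats, "n_rows"),
      dataset_hash = attr(stats, "dataset_hash")
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    tibble::tibble(column = raw$columns, mean = raw$mean, sd = raw$sd),
    class = c("normalization_stats", class(tibble::tibble())),
    n_rows = raw$n_rows,
    dataset_hash = raw$dataset_hash
  )
}

#' Read and write phase-space tables
#'
#' CSV and Parquet I/O with strict schema checking: files must contain
#' exactly the nine phase-space columns in canonical order. Parquet
#' round-trips floats bit-exactly.
#'
#' @param table A phase-space tibble.
#' @param path File path; the format is inferred from the `.csv` or
#'   `.parquet` extension unless `format` is given.
#' @param format `"csv"` or `"parquet"`.
#' @return `read_phase_space()` returns the table; `write_phase_space()`
#'   returns `path` invisibly.
#' @export
write_phase_space <- function(table, path, format = NULL) {
  table <- check_phase_space(table)
  format <- format %||% guess_format(path)
  if (format == "parquet" && !requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required for parquet I/O")
  }
  switch(format,
    csv = utils::write.csv(table, path, row.names = FALSE),
    parquet = arrow::write_parquet(table, path),
    stop("unsupported format: ", format)
  )
  invisible(path)
}

#' @rdname write_phase_space
#' @export
read_phase_space <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  if (format == "parquet" && !requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required for parquet I/O")
  }
  table <- switch(format,
    csv = tibble::as_tibble(utils::read.csv(path)),
    parquet = arrow::read_parquet(path),
    stop("unsupported format: ", format)
  )
  check_phase_space(table)
  tibble::as_tibble(table)[phase_space_columns]
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "parquet")) ext
  else stop("cannot infer format from extension: ", path)
}
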