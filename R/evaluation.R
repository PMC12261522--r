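#' Histogram Jensen-Shannon distance between two samples
#'
#' Bins both samples on a common grid spanning their combined min-max
#' range, normalizes the counts to probability vectors, and returns the
#' Jensen-Shannon distance: the square root of the Jensen-Shannon
#' divergence computed with base-2 logarithms, so the distance is bounded
#' by 1. Empty bins contribute zero (`0 * log 0 = 0`). The distance is
#' symmetric in its arguments; similarity is defined as `1 - distance`.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param n_bins Number of histogram bins (>= 2).
#' @return The JS distance in `[0, 1]`.
#' @examples
#' histogram_jsd(rnorm(1000), rnorm(1000), 100)
#' @export
histogram_jsd <- function(sample_a, sample_b, n_bins = 100) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("samples must be non-empty")
  }
  stopifnot(n_bins >= 2)
  lo <- min(sample_a, sample_b)
  hi <- max(sample_a, sample_b)
  if (lo == hi) hi <- lo + 1 # all mass in one bin: identical distributions
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  p <- bin_probs(sample_a, breaks, n_bins)
  q <- bin_probs(sample_b, breaks, n_bins)
  js_distance(p, q)
}

bin_probs <- function(x, breaks, n_bins) {
  idx <- findInterval(x, breaks, all.inside = TRUE)
  tabulate(idx, nbins = n_bins) / length(x)
}

# JS distance between two probability vectors, base-2 logs
js_distance <- function(p, q) {
  m <- (p + q) / 2
  xlogx <- function(a, b) {
    ok <- a > 0
    sum(a[ok] * (log2(a[ok]) - log2(b[ok])))
  }
  div <- (xlogx(p, m) + xlogx(q, m)) / 2
  sqrt(max(0, min(div, 1)))
}

#' Per-feature similarity report for two phase-space tables
#'
#' Computes the histogram JS distance and the `1 - JSD` similarity for each
#' of the six phase-space features (`X, Y, dX, dY, dZ, EKine`) on their 1-D
#' marginals.
#'
#' @param table_a,table_b Data frames carrying at least the six feature
#'   columns.
#' @param n_bins Histogram bins per feature.
#' @return A tibble of class `similarity_report` with columns
#'   `feature, distance, similarity`; sample sizes and the bin count are
#'   attached as attributes.
#' @export
similarity_report <- function(table_a, table_b, n_bins = 100) {
  feats <- phase_space_columns[1:6]
  for (tb in list(table_a, table_b)) {
    missing <- setdiff(feats, names(tb))
    if (length(missing) > 0) {
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    }
  }
  d <- purrr::map_dbl(feats, ~ histogram_jsd(table_a[[.x]], table_b[[.x]], n_bins))
  structure(
    tibble::tibble(feature = feats, distance = d, similarity = 1 - d),
    class = c("similarity_report", class(tibble::tibble())),
    n_a = nrow(table_a), n_b = nrow(table_b), n_bins = as.integer(n_bins)
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> %d vs %d rows, %d bins, mean similarity %.1f%%\n",
              attr(x, "n_a"), attr(x, "n_b"), attr(x, "n_bins"),
              100 * mean(x$similarity)))
  NextMethod()
}

#' Tidy and summarize similarity reports
#'
#' `tidy()` returns the per-feature table; `glance()` a one-row summary
#' with the mean and minimum similarity.
#'
#' @param x A `similarity_report`.
#' @param ... Unused.
#' @method tidy similarity_report
#' @export
tidy.similarity_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.similarity_report
#' @method glance similarity_report
#' @export
glance.similarity_report <- function(x, ...) {
  tibble::tibble(
    mean_similarity = mean(x$similarity),
    min_similarity = min(x$similarity),
    n_a = attr(x, "n_a"),
    n_b = attr(x, "n_b"),
    n_bins = attr(x, "n_bins")
  )
}

#' Aggregate similarity reports over emission points
#'
#' Per-feature mean and standard deviation of the similarity across a set
#' of reports (one per emission point), plus an `overall` row averaging the
#' six features.
#'
#' @param reports A list of [similarity_report()] objects.
#' @return A tibble with columns `feature, mean_similarity, sd_similarity`.
#' @export
summarize_over_grid <- function(reports) {
  if (length(reports) == 0) stop("no reports to summarize")
  all <- dplyr::bind_rows(purrr::map(reports, tibble::as_tibble))
  per_feature <- dplyr::summarise(
    dplyr::group_by(all, .data$feature),
    mean_similarity = mean(.data$similarity),
    sd_similarity = stats::sd(.data$similarity),
    .groups = "drop"
  )
  overall_means <- purrr::map_dbl(reports, ~ mean(.x$similarity))
  dplyr::bind_rows(
    per_feature,
    tibble::tibble(feature = "overall",
                   mean_similarity = mean(overall_means),
                   sd_similarity = stats::sd(overall_means))
  )
}

#' Sensitivity of the similarity to the histogram binning
#'
#' Recomputes the JS distance of two samples for several bin counts.
#'
#' @param sample_a,sample_b Numeric vectors.
#' @param bin_counts Integer vector of bin counts (each >= 2).
#' @return A tibble with columns `n_bins, distance, similarity` and a
#'   `spread` attribute (max minus min similarity).
#' @export
binning_sensitivity <- function(sample_a, sample_b, bin_counts = c(50, 100, 200)) {
  d <- purrr::map_dbl(bin_counts, ~ histogram_jsd(sample_a, sample_b, .x))
  out <- tibble::tibble(n_bins = as.integer(bin_counts),
                        distance = d, similarity = 1 - d)
  attr(out, "spread") <- max(out$similarity) - min(out$similarity)
  out
}
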