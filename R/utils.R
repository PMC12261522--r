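#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @keywords internal
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

# set.seed only when the caller supplies one; NULL leaves the RNG stream alone
with_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == trunc(x)
}
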