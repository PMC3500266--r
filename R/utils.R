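#' @importFrom rlang %||% .data abort
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
# `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

as_regulon <- function(x, name = "regulon") {
  if (inherits(x, "regulon")) x else regulon(x, name = name)
}
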