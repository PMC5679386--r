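# broom-style methods: tidy() returns the per-unit tibble, glance() the
# one-row summary.

#' @export
tidy.radcea_cohort <- function(x, ...) x$trajectory

#' @export
glance.radcea_cohort <- function(x, ...) {
  dplyr::mutate(x$totals, cycles = x$cycles)
}

#' @export
tidy.radcea_cea <- function(x, ...) x$table

#' @export
glance.radcea_cea <- function(x, ...) {
  best <- x$table[x$table$strategy == x$preferred_by_nmb, ]
  tibble(
    n_strategies = nrow(x$table),
    wtp = x$wtp,
    preferred_by_nmb = x$preferred_by_nmb,
    max_nmb = best$nmb,
    any_dominant = any(x$pairwise$classification == "dominant")
  )
}

#' @export
tidy.radcea_tornado <- function(x, ...) as_tibble(x)

#' @export
tidy.radcea_threshold <- function(x, ...) as_tibble(x)

#' @export
tidy.radcea_sweep <- function(x, ...) as_tibble(x)
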