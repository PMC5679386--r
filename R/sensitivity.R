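#' One-way sensitivity range
#'
#' @param param_path Dotted config path to a numeric scalar (see
#'   [config_get()]; `*` segments address the same parameter in several
#'   strategies at once).
#' @param low,high Range endpoints (`low < high`).
#' @param n_points Number of equally spaced evaluation points (>= 2).
#' @return A list of class `radcea_range`.
#' @export
sensitivity_range <- function(param_path, low, high, n_points = 11L) {
  if (!is_scalar_num(low) || !is_scalar_num(high) || low >= high) {
    abort("sensitivity range requires low < high", class = "radcea_validation_error")
  }
  if (n_points < 2L) {
    abort("n_points must be >= 2", class = "radcea_validation_error")
  }
  structure(list(param_path = param_path, low = low, high = high,
                 n_points = as.integer(n_points)),
            class = "radcea_range")
}

#' One-way parameter sweep
#'
#' Evaluates the full pipeline (dose weighting, cohort engine, CEA) at
#' `n_points` equally spaced values of one parameter, all other parameters at
#' baseline, and returns each strategy's NMB at each point.
#'
#' @param config A `radcea_config`.
#' @param range A [sensitivity_range()]; alternatively give `param_path`,
#'   `low`, `high`, `n_points` directly.
#' @param param_path,low,high,n_points Used when `range` is `NULL`.
#' @return A tibble of class `radcea_sweep`: `param_path`, `value`,
#'   `strategy`, `nmb`.
#' @export
one_way_sweep <- function(config, range = NULL, param_path = NULL,
                          low = NULL, high = NULL, n_points = 11L) {
  if (is.null(range)) {
    range <- sensitivity_range(param_path, low, high, n_points)
  }
  values <- seq(range$low, range$high, length.out = range$n_points)
  rows <- purrr::map(values, function(v) {
    cfg <- config_set(config, range$param_path, v)
    nmbs <- config_nmb(cfg, context = sprintf("at %s = %g", range$param_path, v))
    tibble(param_path = range$param_path, value = v,
           strategy = names(nmbs), nmb = unname(nmbs))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("radcea_sweep", class(out))
  out
}

#' Tornado analysis: rank parameters by NMB spread
#'
#' Evaluates each range at its endpoints and orders parameters by the spread
#' of the baseline NMB-preferred strategy's NMB, descending — the ordering of
#' bars in a tornado diagram.
#'
#' @param config A `radcea_config`.
#' @param ranges List of [sensitivity_range()]s.
#' @return A tibble of class `radcea_tornado`: `param_path`, `nmb_at_low`,
#'   `nmb_at_high`, `spread`, sorted by descending spread; the followed
#'   strategy is in attribute `"strategy"` and column `strategy`.
#' @export
tornado <- function(config, ranges) {
  if (length(ranges) < 1L) {
    abort("at least one sensitivity range is required",
          class = "radcea_validation_error")
  }
  baseline <- config_nmb(config)
  followed <- names(baseline)[which.max(baseline)]
  rows <- purrr::map(ranges, function(r) {
    sw <- one_way_sweep(config, sensitivity_range(r$param_path, r$low, r$high, 2L))
    lo <- sw$nmb[sw$strategy == followed & sw$value == r$low]
    hi <- sw$nmb[sw$strategy == followed & sw$value == r$high]
    tibble(param_path = r$param_path, strategy = followed,
           low = r$low, high = r$high,
           nmb_at_low = lo, nmb_at_high = hi, spread = abs(hi - lo))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$spread))
  attr(out, "strategy") <- followed
  class(out) <- c("radcea_tornado", class(out))
  out
}

#' Find the parameter value at which the NMB-preferred strategy flips
#'
#' Scans the NMB difference between two strategies over `bounds` at 64
#' equally spaced points, then bisects the (single) sign-change bracket until
#' it is narrower than `tolerance`. With no sign change the result is
#' "none in range"; multiple sign changes raise an ambiguity error listing
#' the brackets.
#'
#' @param config A `radcea_config`.
#' @param param_path Dotted config path (see [config_get()]).
#' @param bounds Length-2 numeric `c(low, high)`.
#' @param tolerance Bracket width at which bisection stops; default
#'   `1e-6 * diff(bounds)`.
#' @param strategies Length-2 character: the strategies whose NMB difference
#'   is tracked (default: the first two in the config).
#' @param n_scan Coarse-scan resolution (default 64).
#' @return A tibble of class `radcea_threshold`: `param_path`, `threshold`
#'   (`NA` when none in range), `tolerance`, `preferred_below`,
#'   `preferred_above`.
#' @export
find_threshold <- function(config, param_path, bounds,
                           tolerance = NULL, strategies = NULL,
                           n_scan = 64L) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  tolerance <- tolerance %||% (1e-6 * diff(bounds))
  strategies <- strategies %||% names(config$strategies)[1:2]
  delta <- function(v) {
    nmbs <- config_nmb(config_set(config, param_path, v),
                       context = sprintf("at %s = %g", param_path, v))
    unname(nmbs[strategies[1]] - nmbs[strategies[2]])
  }
  xs <- seq(bounds[1], bounds[2], length.out = n_scan)
  ds <- vapply(xs, delta, numeric(1))
  sign_change <- which(ds[-length(ds)] * ds[-1] < 0 |
                         (ds[-length(ds)] != 0 & ds[-1] == 0))
  pref <- function(d) if (d >= 0) strategies[1] else strategies[2]
  if (length(sign_change) == 0L) {
    return(structure(
      tibble(param_path = param_path, threshold = NA_real_,
             tolerance = tolerance,
             preferred_below = pref(ds[1]), preferred_above = pref(ds[length(ds)])),
      class = c("radcea_threshold", class(tibble()))
    ))
  }
  if (length(sign_change) > 1L) {
    brackets <- paste(sprintf("[%g, %g]", xs[sign_change], xs[sign_change + 1L]),
                      collapse = ", ")
    abort(paste0("multiple NMB sign changes in bounds; brackets: ", brackets),
          class = "radcea_ambiguity_error")
  }
  lo <- xs[sign_change]; hi <- xs[sign_change + 1L]
  d_lo <- ds[sign_change]
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    d_mid <- delta(mid)
    if (d_mid == 0) {
      lo <- mid - tolerance / 2; hi <- mid + tolerance / 2
      break
    }
    if (sign(d_mid) == sign(d_lo)) {
      lo <- mid; d_lo <- d_mid
    } else {
      hi <- mid
    }
  }
  structure(
    tibble(param_path = param_path, threshold = (lo + hi) / 2,
           tolerance = tolerance,
           preferred_below = pref(ds[1]), preferred_above = pref(ds[length(ds)])),
    class = c("radcea_threshold", class(tibble()))
  )
}
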