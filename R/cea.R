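#' Net monetary benefit
#'
#' `NMB = total_qalys * wtp - total_cost`: lifetime QALYs valued at the
#' willingness-to-pay threshold, less lifetime cost. The strategy with the
#' highest NMB is the most cost-effective at that threshold.
#'
#' @param total_cost Discounted lifetime cost, USD.
#' @param total_qalys Lifetime QALYs.
#' @param wtp Willingness to pay, USD per QALY.
#' @return NMB in USD (may be negative); vectorized.
#' @export
#' @examples
#' nmb(53179, 17.86, 50000)
nmb <- function(total_cost, total_qalys, wtp) {
  stopifnot(all(total_cost >= 0), all(total_qalys >= 0), all(wtp >= 0))
  total_qalys * wtp - total_cost
}

#' Cost per QALY
#'
#' @param total_cost Lifetime cost, USD.
#' @param total_qalys Lifetime QALYs (> 0).
#' @return USD per QALY; vectorized.
#' @export
#' @examples
#' cost_per_qaly(53179, 17.86)
cost_per_qaly <- function(total_cost, total_qalys) {
  if (any(total_qalys <= 0)) {
    abort("cost per QALY undefined for non-positive QALY totals",
          class = "radcea_domain_error")
  }
  total_cost / total_qalys
}

result_pair <- function(x) {
  if (inherits(x, "radcea_cohort")) x <- x$totals
  list(cost = x$total_cost, qalys = x$total_qalys)
}

#' Classify the dominance relation between two strategies
#'
#' Strategy `a` dominates `b` when it is no worse on both axes (cost no
#' higher, QALYs no lower) and strictly better on at least one; `"tie"` when
#' both are equal; `"tradeoff"` otherwise (an ICER is then meaningful).
#'
#' @param a,b Strategy results: anything with `total_cost` and `total_qalys`
#'   fields (a [run_cohort()] result or its `totals` row).
#' @return One of `"dominant"`, `"dominated"`, `"tradeoff"`, `"tie"`
#'   (classification of `a` relative to `b`).
#' @export
classify_dominance <- function(a, b) {
  a <- result_pair(a); b <- result_pair(b)
  if (a$cost == b$cost && a$qalys == b$qalys) return("tie")
  a_no_worse <- a$cost <= b$cost && a$qalys >= b$qalys
  b_no_worse <- b$cost <= a$cost && b$qalys >= a$qalys
  if (a_no_worse) "dominant" else if (b_no_worse) "dominated" else "tradeoff"
}

#' Compare strategies: dominance, cost per QALY, ICER and NMB
#'
#' @param results Named list of strategy results ([run_cohort()] cohorts or
#'   `totals` rows), or a tibble with columns `strategy`, `total_cost`,
#'   `total_qalys`.
#' @param econ An [economic_settings()] (supplies the WTP).
#' @return An object of class `radcea_cea`: `table` (per-strategy tibble with
#'   cost_per_qaly and nmb), `pairwise` (all ordered pairs with dominance
#'   classification, increments and ICER for tradeoff pairs),
#'   `preferred_by_nmb`, and `wtp`.
#' @export
compare_strategies <- function(results, econ) {
  if (is.data.frame(results)) {
    tab <- as_tibble(results)
  } else {
    tab <- dplyr::bind_rows(lapply(results, function(x) {
      if (inherits(x, "radcea_cohort")) x$totals else as_tibble(x)
    }))
  }
  if (nrow(tab) < 2L) {
    abort("at least two strategies are required", class = "radcea_validation_error")
  }
  if (anyDuplicated(tab$strategy)) {
    abort("duplicate strategy names", class = "radcea_reference_error")
  }
  tab <- dplyr::mutate(
    tab,
    cost_per_qaly = cost_per_qaly(.data$total_cost, .data$total_qalys),
    nmb = nmb(.data$total_cost, .data$total_qalys, econ$wtp)
  )
  pairs <- expand.grid(a = tab$strategy, b = tab$strategy,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  pairwise <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    ra <- tab[tab$strategy == pairs$a[i], ]
    rb <- tab[tab$strategy == pairs$b[i], ]
    cls <- classify_dominance(ra, rb)
    dc <- ra$total_cost - rb$total_cost
    dq <- ra$total_qalys - rb$total_qalys
    tibble(
      a = pairs$a[i], b = pairs$b[i], classification = cls,
      incremental_cost = dc, incremental_qalys = dq,
      icer = if (cls == "tradeoff" && dq != 0) dc / dq else NA_real_
    )
  }))
  structure(
    list(table = tab, pairwise = pairwise,
         preferred_by_nmb = tab$strategy[which.max(tab$nmb)],
         wtp = econ$wtp),
    class = "radcea_cea"
  )
}

#' Display-rounded comparison table
#'
#' Rounds for reporting the way published tables usually do: dollars to the
#' nearest integer, QALYs to two decimals, cost/QALY to the nearest dollar.
#' Internal arithmetic is never rounded, which is why an NMB recomputed from
#' the rounded columns can differ from the displayed NMB by a few dollars.
#'
#' @param cea A `radcea_cea`.
#' @return A tibble with rounded display columns.
#' @export
format_cea_table <- function(cea) {
  dplyr::transmute(
    cea$table,
    strategy = .data$strategy,
    direct_cost = round(.data$total_cost),
    qalys = round(.data$total_qalys, 2),
    cost_per_qaly = round(.data$cost_per_qaly),
    nmb = round(.data$nmb)
  )
}

#' @export
print.radcea_cea <- function(x, ...) {
  cat(sprintf("<radcea_cea> WTP = $%s/QALY, preferred by NMB: %s\n",
              format(x$wtp, big.mark = ","), x$preferred_by_nmb))
  print(format_cea_table(x))
  invisible(x)
}
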