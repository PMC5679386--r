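#' Budget impact of adopting the cheaper strategy system-wide
#'
#' Scales per-patient lifetime savings (and, optionally, a per-patient
#' indirect-cost difference) by the annual number of eligible cases.
#'
#' @param annual_cases Eligible patients per year.
#' @param per_patient_saving Direct lifetime saving per patient, USD.
#' @param per_patient_indirect_delta Indirect cost difference per patient,
#'   USD (default 0).
#' @return A one-row tibble with `direct_total` and `indirect_total` (USD).
#' @export
#' @examples
#' budget_impact(60000, 10500, 1520)
budget_impact <- function(annual_cases, per_patient_saving,
                          per_patient_indirect_delta = 0) {
  if (any(c(annual_cases, per_patient_saving, per_patient_indirect_delta) < 0)) {
    abort("budget impact inputs must be >= 0", class = "radcea_validation_error")
  }
  tibble(
    annual_cases = annual_cases,
    direct_total = annual_cases * per_patient_saving,
    indirect_total = annual_cases * per_patient_indirect_delta
  )
}

md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) format(x, big.mark = ",", trim = TRUE, scientific = FALSE) else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Run a complete analysis and write a report bundle
#'
#' Evaluates a configuration end to end and writes, under `output_dir`:
#' the comparison table (`comparison.csv`, plus a Markdown report with a
#' display-rounding footer), one trajectory CSV per strategy, tornado and
#' threshold tables, an optional budget-impact summary, and a run log
#' recording the config hash and package version. Numeric outputs are fully
#' deterministic: rerunning on the same inputs reproduces them byte for byte.
#'
#' @param config A `radcea_config` or path to a config file.
#' @param output_dir Directory for the bundle (created if needed).
#' @param ranges Named list of [sensitivity_range()]s for the tornado table
#'   (default none).
#' @param thresholds Named list of `list(param_path, bounds, tolerance)` for
#'   threshold searches (default none).
#' @param budget Optional arguments for [budget_impact()] as a list.
#' @return Invisibly, a list with the computed `cea`, `tornado`, `thresholds`
#'   and `budget` objects.
#' @export
run_analysis <- function(config, output_dir, ranges = NULL,
                         thresholds = NULL, budget = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output dir '%s'", output_dir),
                   class = "radcea_io_error")
  }
  res <- evaluate_config(config)
  tab <- format_cea_table(res$cea)
  dom <- dplyr::filter(res$cea$pairwise, .data$classification == "dominant")
  tab$dominant <- tab$strategy %in% dom$a
  tab$preferred_by_nmb <- tab$strategy == res$cea$preferred_by_nmb
  write.csv(tab, file.path(output_dir, "comparison.csv"), row.names = FALSE)
  for (nm in names(res$cohorts)) {
    write.csv(res$cohorts[[nm]]$trajectory,
              file.path(output_dir, sprintf("trajectory-%s.csv", nm)),
              row.names = FALSE)
  }
  torn <- NULL
  if (!is.null(ranges) && length(ranges) > 0L) {
    torn <- tornado(config, ranges)
    write.csv(as.data.frame(torn), file.path(output_dir, "tornado.csv"),
              row.names = FALSE)
  }
  thr <- NULL
  if (!is.null(thresholds) && length(thresholds) > 0L) {
    thr <- dplyr::bind_rows(lapply(thresholds, function(th) {
      do.call(find_threshold, c(list(config = config), th))
    }))
    write.csv(as.data.frame(thr), file.path(output_dir, "thresholds.csv"),
              row.names = FALSE)
  }
  bud <- NULL
  if (!is.null(budget)) {
    bud <- do.call(budget_impact, budget)
    write.csv(bud, file.path(output_dir, "budget_impact.csv"), row.names = FALSE)
  }

  lines <- c(
    "# Cost-effectiveness report", "",
    sprintf("Willingness to pay: $%s per QALY.",
            format(res$cea$wtp, big.mark = ",")), "",
    md_table(tab), "",
    sprintf("Preferred by net monetary benefit: **%s**.", res$cea$preferred_by_nmb), ""
  )
  if (!is.null(torn)) {
    lines <- c(lines, "## Tornado (one-way NMB spread)", "",
               md_table(as.data.frame(torn)), "")
  }
  if (!is.null(thr)) {
    lines <- c(lines, "## Threshold analysis", "",
               md_table(as.data.frame(thr)), "")
  }
  if (!is.null(bud)) {
    lines <- c(lines, "## Budget impact", "", md_table(bud), "")
  }
  lines <- c(lines,
             paste("Display rounding: dollars to the nearest integer, QALYs to two",
                   "decimals, cost/QALY to the nearest dollar; all arithmetic is",
                   "performed at full precision, so benefit figures recomputed from",
                   "the rounded columns may differ by a few dollars."))
  writeLines(lines, file.path(output_dir, "report.md"))
  writeLines(
    c(sprintf("config_hash: %s", rlang::hash(config_to_list(config))),
      sprintf("package_version: %s", as.character(utils::packageVersion("radcea")))),
    file.path(output_dir, "run_log.txt")
  )
  invisible(list(cea = res$cea, tornado = torn, thresholds = thr, budget = bud))
}
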