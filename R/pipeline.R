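#' Evaluate a full configuration
#'
#' The end-to-end pipeline: derive each strategy's late-complication state
#' from its dose profile ([build_strategy()]), run the cohort engine for each
#' strategy ([run_cohort()]), and compare the results ([compare_strategies()]).
#'
#' @param config A `radcea_config`.
#' @param cycles Passed to [run_cohort()] (default `"auto"`).
#' @param validate Check the configuration first (default `TRUE`); an invalid
#'   configuration raises a validation error naming the violations.
#' @return A list with `cohorts` (named list of `radcea_cohort`) and `cea`
#'   (a `radcea_cea`).
#' @export
#' @examples
#' res <- evaluate_config(iort_ebrt_fixture())
#' res$cea
evaluate_config <- function(config, cycles = "auto", validate = TRUE) {
  if (validate) {
    viol <- validate_config(config)
    if (nrow(viol) > 0L) {
      abort(paste0("invalid configuration:\n",
                   paste0("- [", viol$strategy, "] ", viol$element, ": ",
                          viol$message, collapse = "\n")),
            class = "radcea_validation_error")
    }
  }
  cohorts <- lapply(config$strategies, function(strat) {
    run_cohort(build_strategy(strat, config), config$economics, cycles = cycles)
  })
  list(cohorts = cohorts,
       cea = compare_strategies(cohorts, config$economics))
}

# NMB per strategy for a (possibly perturbed) config; shared by the
# sensitivity machinery. Validation failures are reported with the parameter
# context attached.
config_nmb <- function(config, context = NULL) {
  res <- tryCatch(
    evaluate_config(config),
    radcea_validation_error = function(e) {
      msg <- conditionMessage(e)
      if (!is.null(context)) msg <- paste0(context, ": ", msg)
      abort(msg, class = "radcea_validation_error")
    }
  )
  setNames(res$cea$table$nmb, res$cea$table$strategy)
}
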