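#' Scenario specification
#'
#' A named set of overrides applied on top of the base case. Supported
#' override names: `horizon_years`, `discount_rate`, `bevacizumab_unit_cost`
#' (e.g. the biosimilar price), `utilities` (list with `pfs_combo`,
#' `pfs_sorafenib`, `pd`), and `survival` (nested list
#' `arm -> endpoint -> parametric_survival` substituting alternative —
#' e.g. suboptimal — fitted distributions).
#'
#' @param name Scenario label.
#' @param overrides Named list of overrides (see above); empty = base case.
#' @param outcome_measure `"QALY"` (default) or `"LY"` — denominator of the
#'   headline ICER.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list(),
                          outcome_measure = c("QALY", "LY")) {
  outcome_measure <- match.arg(outcome_measure)
  known <- c("horizon_years", "discount_rate", "bevacizumab_unit_cost",
             "utilities", "survival")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    stop("unknown scenario override(s): ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, overrides = overrides,
                 outcome_measure = outcome_measure),
            class = "scenario_spec")
}

#' Run one scenario
#'
#' Re-runs the full deterministic pipeline with the spec's overrides
#' applied; everything else identical to the base case.
#'
#' @param spec A [scenario_spec()].
#' @param params An [hcc_parameters()] object.
#' @param config A [model_config()].
#' @return A `cea_outcome` (see [run_base_case()]); `$headline_icer` holds
#'   the ICER in the scenario's outcome measure.
#' @export
run_scenario <- function(spec, params, config = model_config()) {
  ov <- spec$overrides
  if (!is.null(ov$horizon_years)) config$horizon_years <- ov$horizon_years
  if (!is.null(ov$discount_rate)) config$discount_rate <- ov$discount_rate
  if (!is.null(ov$bevacizumab_unit_cost)) {
    params$drugs$bevacizumab$unit_cost$value <- ov$bevacizumab_unit_cost
  }
  if (!is.null(ov$utilities)) {
    u <- ov$utilities
    params$utilities$pfs_by_arm <- list(combo = u$pfs_combo,
                                        sorafenib = u$pfs_sorafenib)
    if (!is.null(u$pd)) params$utilities$pd$value <- u$pd
  }
  strategies <- build_strategies(params, config)
  if (!is.null(ov$survival)) {
    for (arm in names(ov$survival)) {
      if (!arm %in% names(strategies)) stop("unknown arm in override: ", arm)
      for (ep in names(ov$survival[[arm]])) {
        if (!ep %in% c("os", "pfs")) stop("unknown endpoint: ", ep)
        stopifnot(inherits(ov$survival[[arm]][[ep]], "parametric_survival"))
        strategies[[arm]][[ep]] <- ov$survival[[arm]][[ep]]
      }
    }
  }
  out <- run_base_case(params, config, strategies = strategies)
  out$scenario <- spec$name
  out$headline_icer <- if (spec$outcome_measure == "LY") {
    out$incremental$icer_per_ly
  } else {
    out$incremental$icer_per_qaly
  }
  out
}

#' Run the full scenario battery
#'
#' Reproduces the published scenario table: base case; 5-, 15- and 20-year
#' horizons; alternative health-state utilities (0.78/0.77 PFS by arm,
#' 0.74 PD); bevacizumab biosimilar price ($139.85/100 mg); and the
#' life-year-denominated ICER. An extrapolation-sensitivity row using
#' alternative (suboptimal) survival distributions is included only when
#' `suboptimal` supplies the substitute fits.
#'
#' @param params An [hcc_parameters()] object.
#' @param config A [model_config()].
#' @param suboptimal Optional nested list `arm -> endpoint ->
#'   parametric_survival` of alternative distributions.
#' @return `data.frame` in the published table's layout: one row per
#'   strategy per scenario with total cost, LYs, QALYs and ICERs.
#' @export
scenario_battery <- function(params, config = model_config(),
                             suboptimal = NULL) {
  specs <- list(
    scenario_spec("Base case"),
    scenario_spec("Time horizon = 5 years", list(horizon_years = 5)),
    scenario_spec("Time horizon = 15 years", list(horizon_years = 15)),
    scenario_spec("Time horizon = 20 years", list(horizon_years = 20)),
    scenario_spec("Alternative utility values",
                  list(utilities = list(pfs_combo = 0.78,
                                        pfs_sorafenib = 0.77, pd = 0.74))),
    scenario_spec("Bevacizumab biosimilar",
                  list(bevacizumab_unit_cost = 139.85)),
    scenario_spec("Effectiveness measured in LYs", outcome_measure = "LY"))
  if (!is.null(suboptimal)) {
    specs <- append(specs, list(scenario_spec(
      "Suboptimal survival distributions",
      list(survival = suboptimal))), after = 4)
  }
  rows <- lapply(specs, function(sp) {
    res <- run_scenario(sp, params, config)
    tab <- res$table
    tab$scenario <- sp$name
    tab$headline_icer <- c(NA, res$headline_icer)
    tab[, c("scenario", "strategy", "total_cost", "ly", "qaly",
            "icer_per_ly", "icer_per_qaly", "headline_icer")]
  })
  do.call(rbind, rows)
}
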