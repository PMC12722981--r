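#' Drug component of a regimen
#'
#' @param name Drug name.
#' @param unit_mg Milligrams per priced unit (vial/tablet).
#' @param unit_cost USD per priced unit.
#' @param dose_rule One of `"fixed_mg_per_cycle"`, `"mg_per_kg_per_cycle"`,
#'   `"mg_per_day"`.
#' @param dose_value mg, mg/kg or mg/day according to `dose_rule`.
#' @param days_on_fraction For `mg_per_day` drugs with intermittent dosing,
#'   the fraction of days on drug (regorafenib: 21 of 28).
#' @param iv Intravenous? Drives per-infusion administration fees.
#' @param max_cycles Cap on the number of cycles the component is given.
#' @return Object of class `drug_component`.
#' @export
drug_component <- function(name, unit_mg, unit_cost, dose_rule, dose_value,
                           days_on_fraction = 1, iv = FALSE,
                           max_cycles = Inf) {
  stopifnot(unit_cost >= 0, dose_value > 0, unit_mg > 0,
            is.infinite(max_cycles) || max_cycles >= 1)
  if (!dose_rule %in% c("fixed_mg_per_cycle", "mg_per_kg_per_cycle",
                        "mg_per_day")) {
    stop("unknown dose_rule: ", dose_rule)
  }
  structure(list(name = name, unit_mg = unit_mg, unit_cost = unit_cost,
                 dose_rule = dose_rule, dose_value = dose_value,
                 days_on_fraction = days_on_fraction, iv = iv,
                 max_cycles = max_cycles),
            class = "drug_component")
}

#' Drug acquisition cost for one cycle
#'
#' Unit price times administered dose, fractional units allowed (no drug
#' wastage).
#'
#' @param component A [drug_component()].
#' @param weight_kg Patient weight (kg), used by `mg_per_kg_per_cycle`.
#' @param cycle_days Cycle length in days, used by `mg_per_day`.
#' @return USD per cycle.
#' @export
#' @examples
#' bev <- drug_component("bevacizumab", 100, 155.02, "mg_per_kg_per_cycle",
#'                       15, iv = TRUE)
#' cycle_drug_cost(bev, weight_kg = 65, cycle_days = 21)  # 1511.445
cycle_drug_cost <- function(component, weight_kg, cycle_days) {
  stopifnot(weight_kg > 0, cycle_days > 0)
  mg <- switch(component$dose_rule,
               fixed_mg_per_cycle = component$dose_value,
               mg_per_kg_per_cycle = component$dose_value * weight_kg,
               mg_per_day = component$dose_value * cycle_days *
                 component$days_on_fraction,
               stop("unknown dose_rule: ", component$dose_rule))
  mg / component$unit_mg * component$unit_cost
}

#' Assemble the two strategy definitions from a parameter set
#'
#' Builds the comparator pair: toripalimab (240 mg, up to 35 cycles) plus
#' bevacizumab (15 mg/kg) versus sorafenib (400 mg twice daily), each with
#' its survival curves, adverse-event profile, subsequent-therapy mix and
#' the shared monitoring/administration/end-of-life unit costs.
#'
#' @param params An [hcc_parameters()] object.
#' @param config A [model_config()].
#' @return Named list with elements `combo` and `sorafenib`, each of class
#'   `strategy_definition`.
#' @export
build_strategies <- function(params, config = model_config()) {
  mk_comp <- function(key, dose_override = NULL) {
    d <- params$drugs[[key]]
    drug_component(key, d$unit_mg, d$unit_cost$value,
                   dose_rule = dose_override$rule %||% d$dose_rule,
                   dose_value = dose_override$value %||% d$dose_value,
                   days_on_fraction = d$days_on_fraction %||% 1,
                   iv = isTRUE(d$iv),
                   max_cycles = d$max_cycles %||% Inf)
  }
  pem <- if (config$pembrolizumab_flat) mk_comp("pembrolizumab")
         else mk_comp("pembrolizumab",
                      list(rule = "mg_per_kg_per_cycle", value = 2))
  econ <- list(
    administration_per_infusion = params$costs$administration_per_infusion$value,
    followup_pfs = params$costs$followup_pfs_per_cycle$value,
    followup_pd = params$costs$followup_pd_per_cycle$value,
    bsc_per_cycle = params$costs$bsc_per_cycle$value,
    end_of_life = params$costs$end_of_life$value)
  mk_strategy <- function(arm, label, components) {
    surv <- params$survival[[arm]]
    structure(list(
      name = label, arm = arm,
      components = components,
      weight_kg = params$weight_kg$value,
      ae = ae_profile(params, arm),
      subsequent = lapply(params$subsequent[[arm]], `[[`, "value"),
      second_line = list(targeted = mk_comp("regorafenib"),
                         immunotherapy = pem),
      econ = econ,
      os = parametric_survival(surv$os$family,
                               c(meanlog = surv$os$meanlog,
                                 sdlog = surv$os$sdlog)),
      pfs = parametric_survival(surv$pfs$family,
                                c(meanlog = surv$pfs$meanlog,
                                  sdlog = surv$pfs$sdlog))),
      class = "strategy_definition")
  }
  list(
    combo = mk_strategy("combo", "Toripalimab plus bevacizumab",
                        list(mk_comp("toripalimab"), mk_comp("bevacizumab"))),
    sorafenib = mk_strategy("sorafenib", "Sorafenib",
                            list(mk_comp("sorafenib"))))
}

#' @export
print.strategy_definition <- function(x, ...) {
  cat("<strategy_definition> ", x$name, ": ",
      paste(vapply(x$components, `[[`, "", "name"), collapse = " + "),
      "\n", sep = "")
  invisible(x)
}

#' Total adverse-event management cost
#'
#' Management cost per event times incidence, summed over the arm's roster;
#' applied once at model entry.
#'
#' @param profile AE profile `data.frame` with columns `incidence` and
#'   `cost_per_event`.
#' @return USD (scalar >= 0).
#' @export
ae_total_cost <- function(profile) {
  if (is.null(profile) || nrow(profile) == 0) return(0)
  sum(profile$cost_per_event * profile$incidence)
}

#' Discounted first-line treatment cost
#'
#' Per cycle, PFS occupancy times the sum of component drug costs (each
#' respecting its `max_cycles` cap), per-infusion administration fees for
#' the components still being infused, and PFS follow-up/monitoring.
#'
#' @param trace A `psm_trace`.
#' @param strategy A `strategy_definition`.
#' @param config The matching `psm_config`.
#' @return USD (discounted).
#' @export
first_line_cost <- function(trace, strategy, config) {
  n <- nrow(trace)
  per_cycle <- rep(strategy$econ$followup_pfs, n)
  for (comp in strategy$components) {
    active <- trace$cycle <= comp$max_cycles
    cc <- cycle_drug_cost(comp, strategy$weight_kg, config$cycle_days)
    admin <- if (comp$iv) strategy$econ$administration_per_infusion else 0
    per_cycle <- per_cycle + active * (cc + admin)
  }
  sum(trace$occupancy_pfs * per_cycle * trace$discount_factor)
}

# effective arm-level fractions receiving each second-line drug class
subsequent_fractions <- function(strategy, config) {
  sub <- strategy$subsequent
  if (config$share_mode == "raw") {
    f <- c(targeted = sub$targeted, immunotherapy = sub$immunotherapy)
  } else {
    tot <- sub$targeted + sub$immunotherapy
    if (tot <= 0 && sub$p_any_systemic > 0) {
      stop("share normalization impossible: zero targeted+immunotherapy share")
    }
    f <- c(targeted = sub$p_any_systemic * sub$targeted / tot,
           immunotherapy = sub$p_any_systemic * sub$immunotherapy / tot)
  }
  if (any(f < 0) || sub$bsc < 0) stop("negative subsequent-therapy fraction")
  f
}

#' Discounted post-progression (subsequent-therapy) cost
#'
#' Second-line drug cost is a lump per PFS-leaving cohort: the effective
#' fraction on each drug receives `second_line_duration_cycles` cycles of
#' it, discounted at the progression time. Best supportive care accrues per
#' cycle on the BSC fraction of PD occupancy, and PD monitoring on all PD
#' occupancy, for the full progressed-state duration.
#'
#' @inheritParams first_line_cost
#' @return USD (discounted).
#' @export
subsequent_cost <- function(trace, strategy, config) {
  f <- subsequent_fractions(strategy, config)
  econ <- strategy$econ
  sl_cost_cycle <- 0
  for (cls in names(f)) {
    comp <- strategy$second_line[[cls]]
    cc <- cycle_drug_cost(comp, strategy$weight_kg, config$cycle_days)
    if (comp$iv) cc <- cc + econ$administration_per_infusion
    sl_cost_cycle <- sl_cost_cycle + f[[cls]] * cc
  }
  entrants <- sum(trace$pfs_exits * trace$discount_factor)
  pd_cycles <- sum(trace$occupancy_pd * trace$discount_factor)
  entrants * config$second_line_duration_cycles * sl_cost_cycle +
    pd_cycles * (strategy$subsequent$bsc * econ$bsc_per_cycle +
                   econ$followup_pd)
}

#' Discounted end-of-life care cost
#'
#' @param trace A `psm_trace`.
#' @param eol_cost USD per death.
#' @return USD (discounted over incident deaths).
#' @export
terminal_cost <- function(trace, eol_cost) {
  sum(trace$incident_deaths * trace$discount_factor * eol_cost)
}

#' Total discounted cost of a strategy
#'
#' First-line + subsequent-therapy/BSC + adverse-event management +
#' end-of-life care.
#'
#' @inheritParams first_line_cost
#' @return USD; attribute `"components"` carries the breakdown.
#' @export
strategy_total_cost <- function(trace, strategy, config) {
  parts <- c(first_line = first_line_cost(trace, strategy, config),
             subsequent = subsequent_cost(trace, strategy, config),
             adverse_events = ae_total_cost(strategy$ae),
             end_of_life = terminal_cost(trace, strategy$econ$end_of_life))
  structure(sum(parts), components = parts)
}

#' Incremental cost-effectiveness from per-strategy totals
#'
#' @param summary_df `data.frame` with columns `strategy`, `total_cost`,
#'   `ly`, `qaly`; the reference (comparator) strategy first.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return Object of class `cea_outcome`: the Table-layout `data.frame`
#'   (`$table`) plus `$incremental` (Δcost, ΔLY, ΔQALY, ICERs, verdict).
#'   ICERs are computed from unrounded values; a non-positive ΔQALY flags
#'   dominance and leaves the ICER undefined (`NA`).
#' @export
compute_cea <- function(summary_df, wtp = 40334) {
  stopifnot(nrow(summary_df) == 2,
            all(c("strategy", "total_cost", "ly", "qaly") %in%
                  names(summary_df)))
  d_cost <- summary_df$total_cost[2] - summary_df$total_cost[1]
  d_ly <- summary_df$ly[2] - summary_df$ly[1]
  d_qaly <- summary_df$qaly[2] - summary_df$qaly[1]
  icer_q <- if (d_qaly > 0) d_cost / d_qaly else NA_real_
  icer_l <- if (d_ly > 0) d_cost / d_ly else NA_real_
  tab <- summary_df
  tab$icer_per_ly <- c(NA, icer_l)
  tab$icer_per_qaly <- c(NA, icer_q)
  structure(list(
    table = tab,
    incremental = list(
      cost = d_cost, ly = d_ly, qaly = d_qaly,
      icer_per_qaly = icer_q, icer_per_ly = icer_l,
      dominant = d_qaly > 0 && d_cost <= 0,
      dominated = d_qaly <= 0 && d_cost >= 0 && (d_qaly < 0 || d_cost > 0),
      wtp = wtp,
      cost_effective = if (d_qaly > 0) icer_q < wtp else d_cost < 0)),
    class = "cea_outcome")
}

#' @export
print.cea_outcome <- function(x, ...) {
  tab <- x$table
  tab$total_cost <- sprintf("%.2f", tab$total_cost)
  tab$ly <- sprintf("%.2f", tab$ly)
  tab$qaly <- sprintf("%.2f", tab$qaly)
  tab$icer_per_ly <- ifelse(is.na(tab$icer_per_ly), "NA",
                            sprintf("%.2f", tab$icer_per_ly))
  tab$icer_per_qaly <- ifelse(is.na(tab$icer_per_qaly), "NA",
                              sprintf("%.2f", tab$icer_per_qaly))
  print.data.frame(tab, row.names = FALSE)
  inc <- x$incremental
  cat(sprintf("incremental: cost %.2f, LY %.3f, QALY %.3f; ICER %s/QALY (WTP %s): %s\n",
              inc$cost, inc$ly, inc$qaly,
              ifelse(is.na(inc$icer_per_qaly), "undefined",
                     sprintf("%.2f", inc$icer_per_qaly)),
              format(inc$wtp, big.mark = ","),
              if (isTRUE(inc$cost_effective)) "cost-effective"
              else "not cost-effective"))
  invisible(x)
}

#' Run the deterministic base case
#'
#' Builds both strategies from the parameter set, traces their three-state
#' occupancy over the horizon, accrues discounted costs, life-years and
#' QALYs, and computes the incremental comparison (combination minus
#' sorafenib).
#'
#' @param params An [hcc_parameters()] object.
#' @param config A [model_config()].
#' @param strategies Optional pre-built strategies (internal reuse).
#' @param traces Optional pre-built traces (internal reuse, e.g. by
#'   [run_psa()] where survival curves are not resampled).
#' @return A `cea_outcome` with extra elements `$traces`, `$strategies` and
#'   `$cost_components`.
#' @export
#' @examples
#' res <- run_base_case(hcc_parameters())
#' res$incremental$icer_per_qaly
run_base_case <- function(params, config = model_config(),
                          strategies = NULL, traces = NULL) {
  strategies <- strategies %||% build_strategies(params, config)
  traces <- traces %||% lapply(strategies, function(s) {
    build_trace(s$os, s$pfs, config)
  })
  u <- params$utilities
  rows <- list()
  comp <- list()
  for (arm in c("sorafenib", "combo")) {
    s <- strategies[[arm]]
    tr <- traces[[arm]]
    total <- strategy_total_cost(tr, s, config)
    us <- utility_set(u_pfs = if (is.null(u$pfs_by_arm)) u$pfs$value
                              else u$pfs_by_arm[[arm]],
                      u_pd = u$pd$value, validate = FALSE)
    rows[[arm]] <- data.frame(
      strategy = s$name,
      total_cost = as.numeric(total),
      ly = accrue_life_years(tr, config),
      qaly = accrue_qalys(tr, us, ae_qaly_loss(s$ae), config))
    comp[[arm]] <- attr(total, "components")
  }
  out <- compute_cea(rbind(rows$sorafenib, rows$combo),
                     wtp = config$wtp_per_qaly)
  out$traces <- traces
  out$strategies <- strategies
  out$cost_components <- comp
  out
}
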