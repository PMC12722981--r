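#' Structural conventions of the partitioned survival model
#'
#' Collects the cycle structure, horizon, discounting and the frozen
#' costing/utility conventions. Defaults reproduce the base case of the
#' published analysis this package re-implements; see the methods vignette
#' for how each convention was fixed.
#'
#' @param cycle_days Model cycle length in days (21, the dosing interval).
#' @param horizon_years Time horizon; the last partial cycle is truncated.
#' @param discount_rate Annual discount rate for costs and effects.
#' @param days_per_month Calendar conversion (30.4375 = 365.25/12).
#' @param eval_point Where within each cycle state occupancy is evaluated:
#'   `"end"` (right endpoint; the default, calibrated against the published
#'   discounted life-years), `"mid"` (half-cycle correction) or `"start"`.
#' @param wtp_per_qaly Willingness-to-pay threshold (USD/QALY).
#' @param share_mode Interpretation of the subsequent-therapy table rows:
#'   `"raw"` uses the published targeted/immunotherapy percentages directly
#'   as arm-level fractions; `"normalized"` rescales them to sum to
#'   `p_any_systemic`.
#' @param pembrolizumab_flat If `TRUE` (default) pembrolizumab is costed at
#'   its labeled 200 mg flat dose; if `FALSE` at 2 mg/kg.
#' @param second_line_duration_cycles Mean number of 21-day cycles of
#'   second-line drug therapy per treated patient (the single calibrated
#'   cost knob; default 12.23, frozen — see vignette). Administration fees
#'   are charged per infusion event: one per active intravenous component
#'   in each cycle, none for oral drugs.
#' @return Object of class `psm_config`.
#' @export
model_config <- function(cycle_days = 21,
                         horizon_years = 10,
                         discount_rate = 0.05,
                         days_per_month = 30.4375,
                         eval_point = c("end", "mid", "start"),
                         wtp_per_qaly = 40334,
                         share_mode = c("raw", "normalized"),
                         pembrolizumab_flat = TRUE,
                         second_line_duration_cycles = 12.23) {
  eval_point <- match.arg(eval_point)
  share_mode <- match.arg(share_mode)
  stopifnot(cycle_days > 0, horizon_years > 0,
            discount_rate >= 0, discount_rate <= 1,
            second_line_duration_cycles > 0)
  structure(list(cycle_days = cycle_days, horizon_years = horizon_years,
                 discount_rate = discount_rate,
                 days_per_month = days_per_month, eval_point = eval_point,
                 wtp_per_qaly = wtp_per_qaly, share_mode = share_mode,
                 pembrolizumab_flat = pembrolizumab_flat,
                 second_line_duration_cycles = second_line_duration_cycles),
            class = "psm_config")
}

#' @export
print.psm_config <- function(x, ...) {
  cat("<psm_config> ", x$cycle_days, "-day cycles, ", x$horizon_years,
      "y horizon (", n_cycles(x), " cycles), ", 100 * x$discount_rate,
      "% discount, occupancy at cycle ", x$eval_point, "\n", sep = "")
  invisible(x)
}

#' Number of full cycles within the horizon
#' @param config A `psm_config`.
#' @export
n_cycles <- function(config) {
  floor(config$horizon_years * 365.25 / config$cycle_days)
}

cycle_months <- function(config) config$cycle_days / config$days_per_month

cycle_years <- function(config) config$cycle_days / 365.25

#' Discount factor at time t
#'
#' @param t_years Time from model entry in years (>= 0).
#' @param r Annual discount rate.
#' @return `(1 + r)^(-t_years)`.
#' @export
discount_factor <- function(t_years, r) {
  if (any(t_years < 0)) stop("t_years must be >= 0")
  (1 + r)^(-t_years)
}

#' Build the per-cycle three-state occupancy trace
#'
#' Partitions each evaluation time t into the three states directly from
#' the overlaid curves: PFS occupancy `min(S_pfs, S_os)`, progressed-disease
#' occupancy `max(S_os - S_pfs, 0)` (clamped where extrapolated curves
#' cross), dead `1 - S_os`.
#'
#' @param os,pfs `parametric_survival` objects (time in months).
#' @param config A [model_config()].
#' @return `data.frame` of class `psm_trace` with one row per cycle:
#'   `cycle`, `t_start_months`, `t_eval_months`, `occupancy_pfs`,
#'   `occupancy_pd`, `occupancy_dead`, `incident_deaths`, `pfs_exits`
#'   (occupancy newly leaving PFS this cycle) and `discount_factor`.
#' @export
build_trace <- function(os, pfs, config = model_config()) {
  stopifnot(inherits(os, "parametric_survival"),
            inherits(pfs, "parametric_survival"))
  if (!identical(os$time_unit, pfs$time_unit)) {
    stop("OS and PFS curves use different time units")
  }
  n <- n_cycles(config)
  cyc <- seq_len(n)
  t_start <- (cyc - 1) * cycle_months(config)
  t_eval <- switch(config$eval_point,
                   start = t_start,
                   mid = t_start + cycle_months(config) / 2,
                   end = cyc * cycle_months(config))
  s_os <- survival_probability(os, t_eval)
  s_pfs <- survival_probability(pfs, t_eval)
  occ_pfs <- pmin(s_pfs, s_os)
  occ_pd <- pmax(s_os - s_pfs, 0)
  occ_dead <- 1 - s_os
  df <- discount_factor(t_eval / 12, config$discount_rate)
  out <- data.frame(cycle = cyc, t_start_months = t_start,
                    t_eval_months = t_eval,
                    occupancy_pfs = occ_pfs, occupancy_pd = occ_pd,
                    occupancy_dead = occ_dead,
                    incident_deaths = diff(c(0, occ_dead)),
                    pfs_exits = pmax(0, -diff(c(1, occ_pfs))),
                    discount_factor = df)
  class(out) <- c("psm_trace", "data.frame")
  out
}

#' Accrue (discounted) life-years over the trace
#'
#' Sums person-time alive (PFS + PD occupancy) per cycle, weighted by the
#' discount factor at the cycle's evaluation point.
#'
#' @param trace A `psm_trace`.
#' @param config The matching `psm_config`.
#' @param discounted Set `FALSE` for undiscounted life-years.
#' @return Life-years (scalar).
#' @export
accrue_life_years <- function(trace, config, discounted = TRUE) {
  w <- if (discounted) trace$discount_factor else 1
  sum((trace$occupancy_pfs + trace$occupancy_pd) * w) * cycle_years(config)
}

#' Health-state utilities with adverse-event disutilities
#'
#' @param u_pfs,u_pd State utilities, `0 <= u_pd <= u_pfs <= 1`.
#' @param ae_disutility Optional named vector of per-event utility
#'   decrements (>= 0).
#' @param validate Internal switch: probabilistic draws bypass the ordering
#'   check (joint sampling does not enforce it).
#' @return Object of class `utility_set`.
#' @export
utility_set <- function(u_pfs = 0.76, u_pd = 0.68, ae_disutility = NULL,
                        validate = TRUE) {
  if (validate) {
    if (!(u_pd <= u_pfs && u_pfs <= 1 && u_pd >= 0)) {
      stop("utilities must satisfy 0 <= u_pd <= u_pfs <= 1")
    }
    if (any(ae_disutility < 0)) stop("disutilities must be >= 0")
  }
  structure(list(u_pfs = u_pfs, u_pd = u_pd,
                 ae_disutility = ae_disutility),
            class = "utility_set")
}

#' One-off QALY loss from adverse events
#'
#' Sum over the arm's AE roster of disutility times incidence; applied once,
#' undiscounted, in the first model cycle.
#'
#' @param profile AE profile `data.frame` with columns `incidence` and
#'   `disutility` (see [ae_profile()] internals / strategy objects).
#' @return QALY loss (scalar >= 0).
#' @export
ae_qaly_loss <- function(profile) {
  sum(profile$disutility * profile$incidence)
}

#' Accrue discounted QALYs over the trace
#'
#' @param trace A `psm_trace`.
#' @param utilities A [utility_set()].
#' @param ae_loss One-off AE QALY loss (>= 0), subtracted undiscounted at
#'   model entry.
#' @param config The matching `psm_config`.
#' @return QALYs (scalar); a negative result signals inconsistent inputs
#'   and raises an error.
#' @export
accrue_qalys <- function(trace, utilities, ae_loss = 0, config) {
  if (ae_loss < 0) stop("ae_loss must be >= 0")
  q <- sum((utilities$u_pfs * trace$occupancy_pfs +
              utilities$u_pd * trace$occupancy_pd) *
             trace$discount_factor) * cycle_years(config) - ae_loss
  if (q < 0) stop("negative QALY total: inconsistent utility/AE inputs")
  q
}

#' Write a state trace as CSV
#' @param trace A `psm_trace`.
#' @param path Output file.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
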