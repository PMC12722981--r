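#' Simulate pseudo individual-patient survival data with known ground truth
#'
#' Draws event times from a chosen parametric law and applies administrative
#' and/or random (exponential) censoring, yielding the same `time`/`event`
#' layout produced by [reconstruct_ipd()]. Used to validate the
#' reconstruction and fitting stages end to end against a known truth.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param family Survival family (any of the seven supported by
#'   [fit_parametric()]).
#' @param params Named numeric vector of distribution parameters in the
#'   `flexsurv` parameterization (e.g. `c(meanlog = 2.68, sdlog = 1.08)`).
#' @param censoring One of `"none"`, `"administrative"`, `"exponential"`, or
#'   `"both"`.
#' @param admin_time Administrative censoring time (months), required for
#'   `"administrative"`/`"both"`.
#' @param cens_rate Rate (per month) of the exponential censoring law,
#'   required for `"exponential"`/`"both"`.
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return A `data.frame` with columns `time` (months, > 0) and `event`
#'   (1 = event, 0 = censored).
#' @export
#' @examples
#' ipd <- simulate_ipd(100, "log-normal", c(meanlog = 2.68, sdlog = 1.08),
#'                     censoring = "administrative", admin_time = 30, seed = 1)
#' mean(ipd$event)
simulate_ipd <- function(n_subjects, family = "log-normal",
                         params = c(meanlog = 2.6781, sdlog = 1.0775),
                         censoring = c("none", "administrative", "exponential", "both"),
                         admin_time = NULL, cens_rate = NULL, seed = NULL) {
  censoring <- match.arg(censoring)
  stopifnot(n_subjects >= 2)
  if (!is.null(seed)) set.seed(seed)
  dist <- canonical_family(family)
  rfun <- flexsurv_rfun(dist)
  t_event <- do.call(rfun, c(list(n = n_subjects), as.list(params)))
  t_cens <- rep(Inf, n_subjects)
  if (censoring %in% c("exponential", "both")) {
    if (is.null(cens_rate) || cens_rate < 0) stop("cens_rate required (>= 0)")
    if (cens_rate > 0) t_cens <- rexp(n_subjects, rate = cens_rate)
  }
  if (censoring %in% c("administrative", "both")) {
    if (is.null(admin_time) || admin_time <= 0) stop("admin_time required (> 0)")
    t_cens <- pmin(t_cens, admin_time)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  # guard against zero times from extreme draws
  time <- pmax(time, .Machine$double.eps)
  data.frame(time = time, event = event)
}

#' Digitize a Kaplan-Meier curve from individual-patient data
#'
#' Computes the product-limit estimate and emits the step coordinates plus a
#' number-at-risk table on a regular grid, i.e. the artifacts a plot
#' digitizer would extract from a published figure. Optional uniform jitter
#' emulates digitizer resolution noise.
#'
#' @param ipd `data.frame` with `time` and `event` columns.
#' @param interval Risk-table spacing in months.
#' @param jitter Half-width of uniform jitter added to survival coordinates
#'   (0 = exact). Jittered curves are re-projected to be monotone by
#'   [km_digitized()].
#' @param seed Optional seed for the jitter.
#' @return A [km_digitized()] object.
#' @export
km_digitize <- function(ipd, interval = 3, jitter = 0, seed = NULL) {
  stopifnot(nrow(ipd) > 0, interval > 0)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  ev <- fit$n.event > 0
  times <- c(0, fit$time[ev])
  surv <- c(1, fit$surv[ev])
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    noise <- runif(length(surv) - 1, -jitter, jitter)
    surv <- c(1, pmin(1, pmax(0, surv[-1] + noise)))
  }
  grid <- seq(0, max(ipd$time), by = interval)
  sm <- summary(fit, times = grid, extend = TRUE)
  km_digitized(times = times, survival = surv,
               risk_times = grid, n_at_risk = sm$n.risk,
               total_events = sum(ipd$event))
}

#' Digitized Kaplan-Meier curve with number-at-risk table
#'
#' Container for the coordinates extracted from a published survival figure:
#' the (time, survival) step coordinates and the number-at-risk table printed
#' beneath it. Mild non-monotonicity (digitizer noise, up to `tol`) is
#' repaired by an isotonic non-increasing projection; larger violations are
#' rejected.
#'
#' @param times Non-decreasing vector of months, starting at 0.
#' @param survival Survival probabilities, `survival[1]` must be 1.
#' @param risk_times Months at which the number at risk is reported.
#' @param n_at_risk Non-increasing non-negative counts, same length as
#'   `risk_times`.
#' @param total_events Optional total event count reported by the source;
#'   when present, [reconstruct_ipd()] applies the final rescaling step.
#' @param tol Largest tolerated upward step in `survival` before the input
#'   is rejected rather than projected.
#' @return An object of class `km_digitized`.
#' @export
km_digitized <- function(times, survival, risk_times, n_at_risk,
                         total_events = NULL, tol = 0.02) {
  if (length(times) != length(survival)) {
    stop("times and survival must have equal length")
  }
  if (length(risk_times) != length(n_at_risk) || length(risk_times) < 2) {
    stop("risk table needs at least 2 entries of equal length")
  }
  if (is.unsorted(times)) stop("times must be non-decreasing")
  if (times[1] != 0 || abs(survival[1] - 1) > 1e-9) {
    stop("curve must start at (0, 1)")
  }
  if (any(survival < -1e-9 | survival > 1 + 1e-9)) {
    stop("survival probabilities outside [0,1]")
  }
  up <- diff(survival)
  if (any(up > tol)) {
    stop("survival is non-monotone beyond tolerance (max upward step ",
         signif(max(up), 3), ")")
  }
  survival <- cummin(pmin(pmax(survival, 0), 1))   # isotonic projection
  if (any(diff(n_at_risk) > 0)) stop("n_at_risk must be non-increasing")
  if (any(n_at_risk < 0) || any(n_at_risk != round(n_at_risk))) {
    stop("n_at_risk must be non-negative integers")
  }
  structure(list(times = as.numeric(times), survival = as.numeric(survival),
                 risk_times = as.numeric(risk_times),
                 n_at_risk = as.integer(n_at_risk),
                 total_events = total_events),
            class = "km_digitized")
}

#' @export
print.km_digitized <- function(x, ...) {
  cat("<km_digitized> ", length(x$times), " coordinates, n0 = ",
      x$n_at_risk[1], ", ", length(x$risk_times), " risk-table entries\n",
      sep = "")
  invisible(x)
}

# ---- family name plumbing shared with the fitting module ----

.family_table <- data.frame(
  canonical = c("exponential", "weibull", "gompertz", "gamma",
                "generalized-gamma", "log-normal", "log-logistic"),
  flexsurv = c("exp", "weibull", "gompertz", "gamma",
               "gengamma", "lnorm", "llogis"),
  stringsAsFactors = FALSE
)

# accept canonical, flexsurv, or common alias spellings; return canonical
canonical_family <- function(family) {
  f <- tolower(gsub("[ _]", "-", family))
  alias <- c(exp = "exponential", lnorm = "log-normal", lognormal = "log-normal",
             llogis = "log-logistic", loglogistic = "log-logistic",
             gengamma = "generalized-gamma", "gen-gamma" = "generalized-gamma")
  if (f %in% names(alias)) f <- alias[[f]]
  if (!f %in% .family_table$canonical) {
    stop("unknown survival family: ", family, " (supported: ",
         paste(.family_table$canonical, collapse = ", "), ")")
  }
  f
}

flexsurv_dist <- function(family) {
  .family_table$flexsurv[.family_table$canonical == canonical_family(family)]
}

flexsurv_rfun <- function(family) {
  switch(flexsurv_dist(family),
         exp = stats::rexp, weibull = stats::rweibull, gamma = stats::rgamma,
         lnorm = stats::rlnorm, gompertz = flexsurv::rgompertz,
         gengamma = flexsurv::rgengamma, llogis = flexsurv::rllogis)
}

flexsurv_pfun <- function(family) {
  switch(flexsurv_dist(family),
         exp = stats::pexp, weibull = stats::pweibull, gamma = stats::pgamma,
         lnorm = stats::plnorm, gompertz = flexsurv::pgompertz,
         gengamma = flexsurv::pgengamma, llogis = flexsurv::pllogis)
}

flexsurv_qfun <- function(family) {
  switch(flexsurv_dist(family),
         exp = stats::qexp, weibull = stats::qweibull, gamma = stats::qgamma,
         lnorm = stats::qlnorm, gompertz = flexsurv::qgompertz,
         gengamma = flexsurv::qgengamma, llogis = flexsurv::qllogis)
}
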