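#' Parametric survival distribution
#'
#' Container for a fitted or assumed parametric survival law: family,
#' natural-scale parameters, and (when fitted) log-likelihood and
#' information criteria. Time is in months throughout.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"gamma"`, `"generalized-gamma"`, `"log-normal"`, `"log-logistic"`
#'   (common aliases accepted).
#' @param params Named numeric vector in the `flexsurv` parameterization
#'   (e.g. `c(meanlog = 2.94, sdlog = 1.14)`; Weibull shape/scale; Gompertz
#'   shape/rate; generalized gamma mu/sigma/Q).
#' @param loglik,n,events Fit metadata; `NA` for assumed distributions.
#' @return An object of class `parametric_survival`.
#' @export
#' @examples
#' os <- parametric_survival("log-normal", c(meanlog = 2.6781, sdlog = 1.0775))
#' survival_probability(os, exp(2.6781))  # 0.5: the median
parametric_survival <- function(family, params, loglik = NA_real_,
                                n = NA_integer_, events = NA_integer_) {
  family <- canonical_family(family)
  params <- unlist(params)
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    stop("params must be a fully named vector")
  }
  k <- length(params)
  aic <- if (is.na(loglik)) NA_real_ else 2 * k - 2 * loglik
  bic <- if (is.na(loglik) || is.na(n)) NA_real_ else k * log(n) - 2 * loglik
  structure(list(family = family, params = params, n_params = k,
                 loglik = loglik, aic = aic, bic = bic,
                 n = n, events = events, time_unit = "months"),
            class = "parametric_survival")
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat("<parametric_survival> ", x$family, ": ",
      paste(names(x$params), signif(x$params, 5), sep = "=", collapse = ", "),
      sep = "")
  if (!is.na(x$loglik)) {
    cat(sprintf("  (loglik %.2f, AIC %.2f, BIC %.2f, n=%d, events=%d)",
                x$loglik, x$aic, x$bic, x$n, x$events))
  }
  cat("\n")
  invisible(x)
}

#' Fit one parametric family to pseudo-IPD by maximum likelihood
#'
#' Fits the named family to right-censored `time`/`event` data via
#' [flexsurv::flexsurvreg()] and wraps the result with its log-likelihood,
#' AIC and BIC (`BIC = k log n - 2 logLik`).
#'
#' @param ipd `data.frame` with columns `time` (> 0) and `event` (0/1);
#'   callers should supply at least a handful of records and at least one
#'   event.
#' @param family Survival family name (see [parametric_survival()]).
#' @return A `parametric_survival` object.
#' @export
fit_parametric <- function(ipd, family) {
  family <- canonical_family(family)
  if (nrow(ipd) < 2) stop("need at least 2 records to fit")
  if (sum(ipd$event) < 1) stop("cannot fit ", family, ": all records censored")
  if (any(ipd$time <= 0)) stop("all times must be positive")
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                          dist = flexsurv_dist(family)),
    error = function(e) {
      stop("fit of family '", family, "' failed to converge: ",
           conditionMessage(e))
    })
  params <- fit$res[, "est"]
  names(params) <- rownames(fit$res)
  parametric_survival(family, params, loglik = fit$loglik,
                      n = nrow(ipd), events = sum(ipd$event))
}

#' Fit all seven candidate families
#'
#' @param ipd Pseudo-IPD `data.frame`.
#' @param families Character vector of families (default: all seven).
#' @return Named list of `parametric_survival` fits; families that fail to
#'   converge are dropped with a warning.
#' @export
fit_all_families <- function(ipd, families = .family_table$canonical) {
  fits <- list()
  for (f in families) {
    fits[[f]] <- tryCatch(fit_parametric(ipd, f), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  Filter(Negate(is.null), fits)
}

#' Select the best-fitting distribution by AIC (BIC tie-break)
#'
#' Returns the fit with the lowest AIC. When AIC and BIC disagree on the
#' winner a message notes it (the visual-plausibility check remains a human
#' step); exact AIC ties are broken by the lower BIC.
#'
#' @param fits List of `parametric_survival` objects fitted to the same data.
#' @return The selected `parametric_survival`.
#' @export
select_best <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits to select among")
  ns <- vapply(fits, function(f) as.integer(f$n), integer(1))
  if (length(unique(ns)) != 1) {
    stop("fits come from different datasets (n = ",
         paste(unique(ns), collapse = ", "), ")")
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  cand <- which(aic <= min(aic) + 1e-9)
  pick <- cand[which.min(bic[cand])]
  if (which.min(aic) != which.min(bic)) {
    message("AIC and BIC disagree (AIC -> ", fits[[which.min(aic)]]$family,
            ", BIC -> ", fits[[which.min(bic)]]$family, "); AIC governs")
  }
  fits[[pick]]
}

#' Survival probability S(t) of a parametric distribution
#'
#' For the log-normal family this is `1 - pnorm((log(t) - meanlog)/sdlog)`;
#' other families use their standard survival forms.
#'
#' @param dist A `parametric_survival`.
#' @param t Time(s) in months, >= 0.
#' @return Vector of survival probabilities; S(0) = 1.
#' @export
survival_probability <- function(dist, t) {
  stopifnot(inherits(dist, "parametric_survival"))
  if (any(t < 0)) stop("t must be >= 0")
  pfun <- flexsurv_pfun(dist$family)
  s <- do.call(pfun, c(list(q = t), as.list(dist$params),
                       list(lower.tail = FALSE)))
  s[t == 0] <- 1
  pmin(pmax(s, 0), 1)
}

#' Median survival time of a parametric distribution
#' @param dist A `parametric_survival`.
#' @return Months at which S(t) = 0.5.
#' @export
surv_median <- function(dist) {
  qfun <- flexsurv_qfun(dist$family)
  do.call(qfun, c(list(p = 0.5), as.list(dist$params)))
}

#' Write fit summaries as JSON
#'
#' @param fits List of `parametric_survival` fits.
#' @param path Output JSON path.
#' @export
write_fit_json <- function(fits, path) {
  out <- lapply(fits, function(f) {
    list(family = f$family, params = as.list(f$params), loglik = f$loglik,
         aic = f$aic, bic = f$bic, n = f$n, events = f$events)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a survival curve as a (t, S) table
#'
#' @param dist A `parametric_survival`.
#' @param t_max Upper end of the grid (months).
#' @param by Grid spacing (months).
#' @return `data.frame` with columns `t_months`, `survival`.
#' @export
survival_curve <- function(dist, t_max = 120, by = 0.5) {
  t <- seq(0, t_max, by = by)
  data.frame(t_months = t, survival = survival_probability(dist, t))
}
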