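#' Enumerate the uncertain parameters with their ranges and distributions
#'
#' Flattens the parameter bundle into one row per sensitivity-analysis
#' parameter: unit costs (gamma), adverse-event incidences, disutilities,
#' utilities and subsequent-therapy proportions (beta), patient weight
#' (gamma) and the discount rate (fixed in PSA, varied 0-8% in one-way
#' analysis). Parameters listed without a range (zero incidences and
#' zero disutilities) are excluded. The best-supportive-care proportion is
#' not an independent row: it is `1 - p_any_systemic` by construction and
#' moves with it.
#'
#' @param params An [hcc_parameters()] object.
#' @return `data.frame` with columns `name` (a dotted accessor path),
#'   `baseline`, `low`, `high`, `distribution`, `role`.
#' @export
parameter_table <- function(params) {
  rows <- list()
  add <- function(name, x, role) {
    if (identical(x$dist, "fixed") && role != "rate") return()
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, baseline = x$value,
      low = x$low %||% NA_real_, high = x$high %||% NA_real_,
      distribution = x$dist, role = role)
  }
  for (d in names(params$drugs)) {
    add(paste0("drugs.", d, ".unit_cost"), params$drugs[[d]]$unit_cost, "cost")
  }
  for (cst in names(params$costs)) {
    add(paste0("costs.", cst), params$costs[[cst]], "cost")
  }
  for (ae in params$adverse_events) {
    add(paste0("ae.", ae$name, ".cost"), ae$cost, "cost")
    add(paste0("ae.", ae$name, ".disutility"), ae$disutility, "utility")
    for (arm in c("combo", "sorafenib")) {
      add(paste0("ae.", ae$name, ".incidence.", arm),
          ae$incidence[[arm]], "probability")
    }
  }
  for (arm in c("combo", "sorafenib")) {
    for (fld in c("p_any_systemic", "targeted", "immunotherapy")) {
      add(paste0("subsequent.", arm, ".", fld),
          params$subsequent[[arm]][[fld]], "probability")
    }
  }
  add("utilities.pfs", params$utilities$pfs, "utility")
  add("utilities.pd", params$utilities$pd, "utility")
  add("weight_kg", params$weight_kg, "weight")
  add("discount_rate", params$discount_rate, "rate")
  do.call(rbind, rows)
}

# set one parameter (dotted path from parameter_table) to a new value;
# returns the modified bundle. "discount_rate" is handled by the callers
# (it lives in the model config).
apply_override <- function(params, name, value) {
  value <- unname(value)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  root <- parts[1]
  if (root == "drugs") {
    params$drugs[[parts[2]]]$unit_cost$value <- value
  } else if (root == "costs") {
    params$costs[[parts[2]]]$value <- value
  } else if (root == "ae") {
    idx <- which(vapply(params$adverse_events, `[[`, "", "name") == parts[2])
    if (!length(idx)) stop("unknown adverse event: ", parts[2])
    if (parts[3] == "cost") {
      params$adverse_events[[idx]]$cost$value <- value
    } else if (parts[3] == "disutility") {
      params$adverse_events[[idx]]$disutility$value <- value
    } else if (parts[3] == "incidence") {
      params$adverse_events[[idx]]$incidence[[parts[4]]]$value <- value
    } else stop("unknown AE field: ", parts[3])
  } else if (root == "subsequent") {
    params$subsequent[[parts[2]]][[parts[3]]]$value <- value
    if (parts[3] == "p_any_systemic") {
      params$subsequent[[parts[2]]]$bsc$value <- 1 - value
    }
  } else if (root == "utilities") {
    params$utilities[[parts[2]]]$value <- value
  } else if (root == "weight_kg") {
    params$weight_kg$value <- value
  } else {
    stop("unknown parameter path: ", name)
  }
  params
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full deterministic model twice per parameter — once at its
#' lower and once at its upper bound, all other inputs at baseline — and
#' orders parameters by the width of the resulting ICER interval. A model
#' failure at a bound is recorded for that parameter and the sweep
#' continues.
#'
#' @param params An [hcc_parameters()] object.
#' @param config A [model_config()].
#' @param specs Parameter rows to sweep; default [parameter_table()].
#' @return `data.frame` sorted by descending `span`
#'   (`|icer_high - icer_low|`) with the per-bound ICERs; attribute
#'   `base_icer` carries the baseline ICER.
#' @export
one_way_dsa <- function(params, config = model_config(),
                        specs = parameter_table(params)) {
  base_icer <- run_base_case(params, config)$incremental$icer_per_qaly
  eval_at <- function(name, value) {
    tryCatch({
      if (name == "discount_rate") {
        cfg <- config
        cfg$discount_rate <- value
        run_base_case(params, cfg)$incremental$icer_per_qaly
      } else {
        run_base_case(apply_override(params, name, value),
                      config)$incremental$icer_per_qaly
      }
    }, error = function(e) {
      warning("DSA evaluation failed for ", name, " = ", value, ": ",
              conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  out <- specs[, c("name", "role", "baseline", "low", "high")]
  out$icer_low <- mapply(eval_at, specs$name, specs$low)
  out$icer_high <- mapply(eval_at, specs$name, specs$high)
  out$span <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  out
}

#' Sampling distribution for probabilistic sensitivity analysis
#'
#' Moment-matched to mean = baseline and SD = 10% of baseline: gamma for
#' costs/weight (shape 100, scale baseline/100), beta for probabilities and
#' utilities (`alpha = m[(m(1-m))/s^2 - 1]`, `beta = alpha(1-m)/m`), or a
#' degenerate point mass for `fixed` parameters.
#'
#' @param spec One row of [parameter_table()] (or a list with `baseline`
#'   and `distribution`).
#' @return List with `type`, the distribution parameters, and `r`, a
#'   function drawing `n` deviates.
#' @export
specify_distribution <- function(spec) {
  m <- spec$baseline
  type <- spec$distribution
  if (type == "fixed") {
    return(list(type = "fixed", baseline = m,
                r = function(n) rep(m, n)))
  }
  if (type == "gamma") {
    if (m <= 0) stop("gamma distribution requires baseline > 0")
    shape <- 100                      # (m / 0.1 m)^2
    scale <- m / shape
    return(list(type = "gamma", shape = shape, scale = scale,
                r = function(n) rgamma(n, shape = shape, scale = scale)))
  }
  if (type == "beta") {
    if (m <= 0 || m >= 1) stop("beta distribution requires baseline in (0,1)")
    s <- 0.1 * m
    alpha <- m * ((m * (1 - m)) / s^2 - 1)
    beta <- alpha * (1 - m) / m
    return(list(type = "beta", alpha = alpha, beta = beta,
                r = function(n) rbeta(n, alpha, beta)))
  }
  stop("unknown distribution type: ", type)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo resampling of all uncertain parameters from their
#' moment-matched distributions (SE = 10% of baseline), with the full
#' deterministic model evaluated per draw. Survival-distribution parameters
#' and the discount rate are not varied (they carry no sampling
#' distribution). Draws outside a distribution's support would be resampled
#' and counted; gamma/beta sampling keeps all draws in-support by
#' construction.
#'
#' @param params An [hcc_parameters()] object.
#' @param config A [model_config()].
#' @param n_iter Number of iterations (default 5000).
#' @param seed Integer seed; the full result is reproducible given the seed.
#' @param specs Parameter rows to sample (default [parameter_table()]);
#'   rows with distribution `"fixed"` are held at baseline.
#' @return Object of class `psa_result`: `$iterations` (iteration,
#'   delta_cost, delta_qaly), `$mean_icer` (mean Δcost / mean ΔQALY),
#'   `$n_iter`, `$seed`, `$n_resampled`.
#' @export
run_psa <- function(params, config = model_config(), n_iter = 5000,
                    seed = 1, specs = parameter_table(params)) {
  if (n_iter < 1) stop("n_iter must be a positive integer")
  specs <- specs[specs$distribution != "fixed", , drop = FALSE]
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_iter, ncol = nrow(specs),
                  dimnames = list(NULL, specs$name))
  n_resampled <- 0L
  for (j in seq_len(nrow(specs))) {
    d <- specify_distribution(specs[j, ])
    x <- d$r(n_iter)
    bad <- !is.finite(x) | (d$type == "beta" & (x <= 0 | x >= 1))
    while (any(bad)) {             # defensive; practically never triggered
      n_resampled <- n_resampled + sum(bad)
      x[bad] <- d$r(sum(bad))
      bad <- !is.finite(x) | (d$type == "beta" & (x <= 0 | x >= 1))
    }
    draws[, j] <- x
  }
  # survival curves and discounting are fixed across draws: trace once
  base_strat <- build_strategies(params, config)
  traces <- lapply(base_strat, function(s) build_trace(s$os, s$pfs, config))
  dc <- dq <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    p_i <- params
    for (j in seq_len(ncol(draws))) {
      p_i <- apply_override(p_i, specs$name[j], draws[i, j])
    }
    res <- run_base_case(p_i, config, traces = traces)
    dc[i] <- res$incremental$cost
    dq[i] <- res$incremental$qaly
  }
  structure(list(iterations = data.frame(iteration = seq_len(n_iter),
                                         delta_cost = dc, delta_qaly = dq),
                 n_iter = n_iter, seed = seed,
                 mean_icer = mean(dc) / mean(dq),
                 n_resampled = n_resampled,
                 wtp = config$wtp_per_qaly),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_iter, " iterations (seed ", x$seed, ")\n",
      "  mean ICER: ", sprintf("%.2f", x$mean_icer), "/QALY\n",
      "  P(cost-effective at ", format(x$wtp, big.mark = ","), "/QALY): ",
      sprintf("%.2f%%", 100 * prob_cost_effective(x, x$wtp)), "\n", sep = "")
  invisible(x)
}

#' Probability the intervention is cost-effective at a threshold
#'
#' Fraction of PSA iterations with strictly positive net monetary benefit
#' `wtp * dQALY - dcost` (ties count as not cost-effective).
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay threshold(s), USD/QALY.
#' @return Probability (same length as `wtp`).
#' @export
prob_cost_effective <- function(psa, wtp) {
  it <- psa$iterations
  vapply(wtp, function(w) {
    mean(w * it$delta_qaly - it$delta_cost > 0)
  }, numeric(1))
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Thresholds at which to evaluate the acceptability
#'   probability.
#' @return `data.frame` with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  if (psa$n_iter < 1) stop("empty PSA result")
  data.frame(wtp = wtp_grid,
             probability = prob_cost_effective(psa, wtp_grid))
}

#' Threshold at which the acceptability probability crosses a level
#'
#' Linear interpolation on the CEAC; `NA` when the level is never reached.
#'
#' @param psa A `psa_result`.
#' @param level Probability level (default 0.5).
#' @param wtp_grid Search grid.
#' @return WTP (USD/QALY) at the crossing.
#' @export
ceac_crossing <- function(psa, level = 0.5,
                          wtp_grid = seq(0, 100000, by = 250)) {
  cc <- ceac(psa, wtp_grid)
  above <- which(cc$probability >= level)
  if (!length(above) || above[1] == 1) return(cc$wtp[above[1]] %||% NA_real_)
  i <- above[1]
  x0 <- cc$wtp[i - 1]; x1 <- cc$wtp[i]
  y0 <- cc$probability[i - 1]; y1 <- cc$probability[i]
  x0 + (level - y0) / (y1 - y0) * (x1 - x0)
}
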