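#' Load the bundled model input set
#'
#' Reads the YAML bundle of model inputs for the advanced-HCC first-line
#' comparison: log-normal survival parameters per arm and endpoint, unit
#' prices, adverse-event incidences/costs/disutilities, health-state
#' utilities, subsequent-therapy proportions, patient weight, discount rate
#' and the willingness-to-pay threshold, each with its sensitivity-analysis
#' range and sampling family.
#'
#' @param path Path to a parameter YAML file. Default: the bundle shipped
#'   with the package.
#' @return A validated list of class `hcc_params`.
#' @export
#' @examples
#' p <- hcc_parameters()
#' p$survival$sorafenib$os$meanlog   # 2.6781
hcc_parameters <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hcc_params.yaml", package = "hccpsm")
  if (!nzchar(path) || !file.exists(path)) {
    stop("parameter file not found: ", path)
  }
  p <- yaml::read_yaml(path)
  validate_hcc_params(p)
  class(p) <- c("hcc_params", "list")
  attr(p, "source") <- path
  p
}

validate_hcc_params <- function(p) {
  need <- c("weight_kg", "discount_rate", "wtp_per_qaly", "survival", "drugs",
            "costs", "adverse_events", "subsequent", "utilities")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("parameter file is missing required field(s): ",
         paste(miss, collapse = ", "))
  }
  for (arm in c("combo", "sorafenib")) {
    for (ep in c("os", "pfs")) {
      s <- p$survival[[arm]][[ep]]
      if (is.null(s$meanlog) || is.null(s$sdlog) || s$sdlog <= 0) {
        stop("invalid survival parameters for ", arm, " ", ep)
      }
    }
  }
  for (d in names(p$drugs)) {
    dr <- p$drugs[[d]]
    if (dr$unit_cost$value < 0) stop("negative unit cost for ", d)
    if (dr$dose_value <= 0) stop("non-positive dose for ", d)
  }
  for (ae in p$adverse_events) {
    for (arm in c("combo", "sorafenib")) {
      inc <- ae$incidence[[arm]]$value
      if (inc < 0 || inc > 1) stop("AE incidence outside [0,1]: ", ae$name)
    }
    if (ae$cost$value < 0) stop("negative AE cost: ", ae$name)
    if (ae$disutility$value < 0) stop("negative AE disutility: ", ae$name)
  }
  u <- p$utilities
  if (!(u$pd$value <= u$pfs$value && u$pfs$value <= 1 && u$pd$value >= 0)) {
    stop("utilities must satisfy 0 <= u_pd <= u_pfs <= 1")
  }
  for (arm in c("combo", "sorafenib")) {
    sub <- p$subsequent[[arm]]
    pv <- vapply(sub, function(x) x$value, numeric(1))
    if (any(pv < 0 | pv > 1)) stop("subsequent-therapy proportion outside [0,1]")
    if (abs(sub$bsc$value - (1 - sub$p_any_systemic$value)) > 1e-6) {
      stop("bsc proportion must equal 1 - p_any_systemic (", arm, ")")
    }
  }
  if (p$discount_rate$value < 0 || p$discount_rate$value > 1) {
    stop("discount rate outside [0,1]")
  }
  invisible(TRUE)
}

#' @export
print.hcc_params <- function(x, ...) {
  cat("<hcc_params> ", x$label %||% "", "\n", sep = "")
  cat("  arms: combo (toripalimab + bevacizumab), sorafenib\n")
  cat("  adverse events:", length(x$adverse_events),
      "| weight:", x$weight_kg$value, "kg",
      "| discount:", x$discount_rate$value,
      "| WTP:", x$wtp_per_qaly, "USD/QALY\n")
  invisible(x)
}

# AE profile for one arm as a data.frame (name, incidence, cost, disutility)
ae_profile <- function(params, arm = c("combo", "sorafenib")) {
  arm <- match.arg(arm)
  do.call(rbind, lapply(params$adverse_events, function(ae) {
    data.frame(name = ae$name,
               incidence = ae$incidence[[arm]]$value,
               cost_per_event = ae$cost$value,
               disutility = ae$disutility$value)
  }))
}
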