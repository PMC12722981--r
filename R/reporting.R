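#' Run manifest for reproducibility
#'
#' Records the package version, an MD5 digest of the effective configuration
#' and parameter bundle, the seed, and the frozen modeling conventions, so
#' every artifact can be traced to the run that produced it.
#'
#' @param config A `psm_config`.
#' @param params An `hcc_params` bundle.
#' @param seed Seed used for any stochastic step (`NA` for deterministic
#'   runs).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, params, seed = NA_integer_) {
  digest <- function(x) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    saveRDS(x, f, version = 2)
    unname(tools::md5sum(f))
  }
  structure(list(
    package = "hccpsm",
    version = as.character(utils::packageVersion("hccpsm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = digest(unclass(config)),
    params_hash = digest(unclass(params)),
    conventions = list(
      eval_point = config$eval_point,
      share_mode = config$share_mode,
      pembrolizumab_flat = config$pembrolizumab_flat,
      second_line_duration_cycles = config$second_line_duration_cycles),
    currency = "USD"), class = "run_manifest")
}

round_money <- function(df, cols) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], 2)
  df
}

#' Write a CEA results table (strategy rows, Table-2 layout) as CSV
#' @param x A `cea_outcome` or a battery `data.frame`.
#' @param path Output file.
#' @export
write_cea_csv <- function(x, path) {
  tab <- if (inherits(x, "cea_outcome")) x$table else x
  tab <- round_money(tab, c("total_cost", "icer_per_ly", "icer_per_qaly",
                            "headline_icer"))
  write.csv(tab, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a tornado (one-way DSA) table as CSV
#' @param dsa Output of [one_way_dsa()].
#' @param path Output file.
#' @export
write_tornado_csv <- function(dsa, path) {
  write.csv(round_money(dsa, c("icer_low", "icer_high", "span")), path,
            row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the PSA scatter cloud as CSV
#' @param psa A `psa_result`.
#' @param path Output file.
#' @export
write_psa_csv <- function(psa, path) {
  write.csv(round_money(psa$iterations, "delta_cost"), path,
            row.names = FALSE)
  invisible(path)
}

#' Write a CEAC as CSV
#' @param cc Output of [ceac()].
#' @param path Output file.
#' @export
write_ceac_csv <- function(cc, path) {
  write.csv(cc, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest as JSON
#' @param manifest A `run_manifest`.
#' @param path Output file.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Tornado diagram (base graphics)
#' @param dsa Output of [one_way_dsa()].
#' @param top Number of parameters shown.
#' @export
plot_tornado <- function(dsa, top = 10) {
  d <- head(dsa[order(-dsa$span), ], top)
  d <- d[nrow(d):1, ]
  base <- attr(dsa, "base_icer")
  lo <- pmin(d$icer_low, d$icer_high)
  hi <- pmax(d$icer_low, d$icer_high)
  old <- graphics::par(mar = c(4, 14, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICER (USD/QALY)", ylab = "",
                 main = "One-way sensitivity analysis")
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "steelblue")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$name, las = 1,
                 cex.axis = 0.7)
  invisible(d)
}

#' Incremental cost-effectiveness scatter plot (base graphics)
#' @param psa A `psa_result`.
#' @param wtp Threshold line (USD/QALY).
#' @export
plot_psa_scatter <- function(psa, wtp = psa$wtp) {
  it <- psa$iterations
  graphics::plot(it$delta_qaly, it$delta_cost, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "Incremental QALYs", ylab = "Incremental cost (USD)",
                 main = "Probabilistic sensitivity analysis")
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(psa)
}

#' Cost-effectiveness acceptability curve plot (base graphics)
#' @param cc Output of [ceac()].
#' @export
plot_ceac <- function(cc) {
  graphics::plot(cc$wtp, cc$probability, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "Willingness to pay (USD/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability")
  graphics::abline(h = 0.5, lty = 3)
  invisible(cc)
}

#' Configuration-driven model runner
#'
#' Thin driver behind the command-line wrapper: validates inputs, runs the
#' requested analysis and writes its artifacts (CSV/JSON plus a manifest)
#' into `out_dir`.
#'
#' @param command One of `"base-case"`, `"scenarios"`, `"dsa"`, `"psa"`,
#'   `"reconstruct"`, `"fit"`.
#' @param config_path Optional parameter YAML (default: bundled set).
#' @param out_dir Output directory (created if needed).
#' @param n_iter PSA iterations.
#' @param seed Seed for stochastic commands.
#' @param curve_file,risk_file Digitized KM inputs for `"reconstruct"`.
#' @param ipd_file IPD CSV for `"fit"`.
#' @param family Family for `"fit"` (`"all"` = all seven).
#' @param horizon_years,discount_rate Optional convention overrides.
#' @return Invisibly, a list with the computed objects and file paths.
#' @export
cli_run <- function(command = c("base-case", "scenarios", "dsa", "psa",
                                "reconstruct", "fit"),
                    config_path = NULL, out_dir = ".", n_iter = 5000,
                    seed = 1, curve_file = NULL, risk_file = NULL,
                    ipd_file = NULL, family = "all",
                    horizon_years = NULL, discount_rate = NULL) {
  command <- match.arg(command)
  params <- hcc_parameters(config_path)
  config <- model_config()
  if (!is.null(horizon_years)) config$horizon_years <- horizon_years
  if (!is.null(discount_rate)) config$discount_rate <- discount_rate
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  manifest <- run_manifest(config, params,
                           seed = if (command == "psa") seed else NA)
  files <- character(0)
  out <- NULL

  if (command == "base-case") {
    out <- run_base_case(params, config)
    write_cea_csv(out, pth("base_case.csv"))
    for (arm in names(out$traces)) {
      write_trace_csv(out$traces[[arm]], pth(paste0("trace_", arm, ".csv")))
    }
    files <- c("base_case.csv", paste0("trace_", names(out$traces), ".csv"))
  } else if (command == "scenarios") {
    out <- scenario_battery(params, config)
    write_cea_csv(out, pth("scenarios.csv"))
    files <- "scenarios.csv"
  } else if (command == "dsa") {
    out <- one_way_dsa(params, config)
    write_tornado_csv(out, pth("tornado.csv"))
    grDevices::png(pth("tornado.png"), width = 900, height = 600)
    plot_tornado(out)
    grDevices::dev.off()
    files <- c("tornado.csv", "tornado.png")
  } else if (command == "psa") {
    if (n_iter < 1) stop("psa requires n_iter >= 1")
    out <- run_psa(params, config, n_iter = n_iter, seed = seed)
    cc <- ceac(out)
    write_psa_csv(out, pth("psa_scatter.csv"))
    write_ceac_csv(cc, pth("ceac.csv"))
    grDevices::png(pth("psa_scatter.png"), width = 800, height = 600)
    plot_psa_scatter(out)
    grDevices::dev.off()
    grDevices::png(pth("ceac.png"), width = 800, height = 600)
    plot_ceac(cc)
    grDevices::dev.off()
    files <- c("psa_scatter.csv", "ceac.csv", "psa_scatter.png", "ceac.png")
  } else if (command == "reconstruct") {
    if (is.null(curve_file) || is.null(risk_file)) {
      stop("reconstruct requires curve_file and risk_file")
    }
    km <- read_km_csv(curve_file, risk_file)
    out <- reconstruct_ipd(km)
    write_ipd_csv(out, pth("ipd.csv"))
    files <- "ipd.csv"
  } else if (command == "fit") {
    if (is.null(ipd_file)) stop("fit requires ipd_file")
    ipd <- read_ipd_csv(ipd_file)
    out <- if (identical(family, "all")) fit_all_families(ipd)
           else list(fit_parametric(ipd, family))
    write_fit_json(out, pth("fits.json"))
    files <- "fits.json"
  }

  write_manifest_json(manifest, pth("manifest.json"))
  files <- c(files, "manifest.json")
  invisible(list(result = out, manifest = manifest,
                 files = file.path(out_dir, files)))
}
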