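test_that("uncensored maximum-likelihood fits match the closed forms", {
  ipd <- data.frame(time = 1:4, event = 1)
  f_exp <- fit_parametric(ipd, "exponential")
  expect_equal(unname(f_exp$params["rate"]), 4 / 10, tolerance = 1e-4)

  set.seed(21)
  t <- rlnorm(40, 2, 0.8)
  f_ln <- fit_parametric(data.frame(time = t, event = 1), "log-normal")
  expect_equal(unname(f_ln$params["meanlog"]), mean(log(t)), tolerance = 1e-4)
  expect_equal(unname(f_ln$params["sdlog"]),
               sqrt(mean((log(t) - mean(log(t)))^2)), tolerance = 1e-4)
})

test_that("log-normal parameters are recovered within 3 standard errors", {
  ipd <- simulate_ipd(500, "log-normal", c(meanlog = 2.6781, sdlog = 1.0775),
                      seed = 11)
  fit <- fit_parametric(ipd, "log-normal")
  # standard errors of the uncensored MLE: sigma/sqrt(n), sigma/sqrt(2n)
  se_mu <- 1.0775 / sqrt(500)
  se_sd <- 1.0775 / sqrt(2 * 500)
  expect_lt(abs(fit$params[["meanlog"]] - 2.6781), 3 * se_mu)
  expect_lt(abs(fit$params[["sdlog"]] - 1.0775), 3 * se_sd)
})

test_that("degenerate fitting inputs are rejected", {
  expect_error(fit_parametric(data.frame(time = c(3, 5), event = c(0, 0)),
                              "weibull"), "censored")
  expect_error(fit_parametric(data.frame(time = 1:5, event = 1), "cauchy"),
               "unknown survival family")
})

test_that("information-criterion identities hold for every family", {
  ipd <- simulate_ipd(120, "log-normal", c(meanlog = 2.7, sdlog = 1.0),
                      censoring = "exponential", cens_rate = 0.02, seed = 5)
  fits <- suppressWarnings(fit_all_families(ipd))
  expect_gte(length(fits), 6)
  for (f in fits) {
    expect_equal(f$aic, 2 * f$n_params - 2 * f$loglik, tolerance = 1e-10)
    expect_equal(f$bic, f$n_params * log(f$n) - 2 * f$loglik,
                 tolerance = 1e-10)
  }
})

test_that("selection minimizes AIC with a BIC tie-break", {
  mk <- function(family, pars, loglik, n) {
    parametric_survival(family, pars, loglik = loglik, n = n, events = n)
  }
  # AIC 100, 90, 95 -> pick the 90
  fits <- list(mk("exponential", c(rate = 0.1), -49, 100),
               mk("weibull", c(shape = 1, scale = 10), -43, 100),
               mk("log-normal", c(meanlog = 2, sdlog = 1), -45.5, 100))
  expect_equal(vapply(fits, function(f) f$aic, 1), c(100, 90, 95))
  expect_equal(select_best(fits)$family, "weibull")

  # equal AIC: fewer parameters -> lower BIC wins
  tie <- list(mk("weibull", c(shape = 1, scale = 10), -48, 100),
              mk("exponential", c(rate = 0.1), -49, 100))
  expect_equal(tie[[1]]$aic, tie[[2]]$aic)
  expect_equal(select_best(tie)$family, "exponential")

  expect_error(select_best(list(mk("exponential", c(rate = .1), -49, 100),
                                mk("weibull", c(shape = 1, scale = 9),
                                   -43, 90))),
               "different datasets")
})

test_that("the generating family is recovered in most seeded replicates", {
  wins <- vapply(1:20, function(r) {
    ipd <- simulate_ipd(500, "log-normal",
                        c(meanlog = 2.6781, sdlog = 1.0775), seed = 100 + r)
    suppressMessages(select_best(suppressWarnings(fit_all_families(ipd))))$family
  }, character(1))
  expect_gt(mean(wins == "log-normal"), 0.5)
})

test_that("survival probabilities follow the standard survival forms", {
  # log-normal median: S(exp(meanlog)) = 0.5
  expect_equal(survival_probability(sora_os, exp(2.6781)), 0.5)
  # direct standard-normal-CDF evaluation as oracle
  expect_equal(survival_probability(combo_os, 12),
               1 - pnorm((log(12) - 2.9363) / 1.1358))
  expect_error(survival_probability(sora_os, -1), ">= 0")
})

test_that("S(t) is 1 at zero, bounded, and non-increasing for all families", {
  shapes <- list(
    exponential = c(rate = 0.08),
    weibull = c(shape = 1.3, scale = 18),
    gompertz = c(shape = 0.05, rate = 0.04),
    gamma = c(shape = 1.5, rate = 0.1),
    `generalized-gamma` = c(mu = 2.8, sigma = 1.1, Q = 0.5),
    `log-normal` = c(meanlog = 2.9, sdlog = 1.1),
    `log-logistic` = c(shape = 1.6, scale = 15))
  grid <- seq(0, 240, by = 0.25)
  for (fam in names(shapes)) {
    d <- parametric_survival(fam, shapes[[fam]])
    s <- survival_probability(d, grid)
    expect_equal(s[1], 1)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12), label = paste(fam, "monotone"))
  }
})

test_that("fitted log-normal medians reproduce exp(meanlog) for all arms", {
  expect_equal(round(surv_median(combo_os), 2), 18.85)
  expect_equal(round(surv_median(combo_pfs), 2), 5.29)
  expect_equal(round(surv_median(sora_os), 2), 14.56)
  expect_equal(round(surv_median(sora_pfs), 2), 3.86)
})

test_that("fit summaries serialize to JSON with their criteria", {
  ipd <- simulate_ipd(80, "log-normal", c(meanlog = 2.7, sdlog = 1.0),
                      seed = 2)
  fits <- suppressWarnings(fit_all_families(
    ipd, families = c("exponential", "log-normal")))
  f <- tempfile(fileext = ".json")
  write_fit_json(fits, f)
  back <- jsonlite::read_json(f)
  expect_equal(length(back), 2)
  expect_equal(back[["log-normal"]]$n, 80)
  expect_equal(back[["log-normal"]]$aic,
               fits[["log-normal"]]$aic, tolerance = 1e-12)
  unlink(f)
})
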