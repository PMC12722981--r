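test_that("occupancy decomposes survival areas and conserves the cohort", {
  tr <- build_trace(combo_os, combo_pfs, cfg)
  # partition: PFS + PD + dead = 1 at every cycle, death monotone
  expect_true(all(abs(tr$occupancy_pfs + tr$occupancy_pd +
                        tr$occupancy_dead - 1) < 1e-9))
  expect_true(all(diff(tr$occupancy_dead) >= -1e-12))
  expect_true(all(tr$occupancy_pd >= 0))
  expect_equal(sum(tr$incident_deaths),
               tr$occupancy_dead[nrow(tr)], tolerance = 1e-12)

  # PD is the area between the curves
  s_os <- survival_probability(combo_os, tr$t_eval_months)
  s_pfs <- survival_probability(combo_pfs, tr$t_eval_months)
  expect_equal(tr$occupancy_pd, pmax(s_os - s_pfs, 0))

  # everyone starts progression-free
  tr0 <- build_trace(combo_os, combo_pfs,
                     model_config(eval_point = "start"))
  expect_equal(tr0$t_eval_months[1], 0)
  expect_equal(unlist(tr0[1, c("occupancy_pfs", "occupancy_pd",
                               "occupancy_dead")], use.names = FALSE),
               c(1, 0, 0))
})

test_that("crossing extrapolated curves clamp PD at zero", {
  # PFS curve above OS: gamma with long tail vs fast exponential
  os <- parametric_survival("exponential", c(rate = 0.3))
  pfs <- parametric_survival("log-normal", c(meanlog = 3, sdlog = 1))
  tr <- build_trace(os, pfs, cfg)
  i <- which(survival_probability(pfs, tr$t_eval_months) >
               survival_probability(os, tr$t_eval_months))
  expect_gt(length(i), 0)
  expect_true(all(tr$occupancy_pd[i] == 0))
  expect_equal(tr$occupancy_pfs[i],
               survival_probability(os, tr$t_eval_months[i]))
})

test_that("discounting follows (1+r)^-t", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(3, 0), 1)
  expect_equal(discount_factor(1, 0.05), 1 / 1.05)
  expect_error(discount_factor(-1, 0.05), ">= 0")
})

test_that("life-year accrual matches closed forms and quadrature", {
  # immortal cohort, no discounting: LY = full horizon (up to truncation)
  cfg2 <- model_config(horizon_years = 2, discount_rate = 0)
  immortal <- parametric_survival("exponential", c(rate = 1e-12))
  tr <- build_trace(immortal, immortal, cfg2)
  expect_equal(accrue_life_years(tr, cfg2), n_cycles(cfg2) * 21 / 365.25)
  expect_lt(abs(accrue_life_years(tr, cfg2) - 2), 21 / 365.25)

  # exponential survival, long horizon: LY -> 1/lambda
  lam <- 0.1  # per month
  cfg3 <- model_config(horizon_years = 50 / lam / 12, discount_rate = 0)
  expo <- parametric_survival("exponential", c(rate = lam))
  tr3 <- build_trace(expo, expo, cfg3)
  expect_equal(accrue_life_years(tr3, cfg3), 1 / lam / 12,
               tolerance = 21 / 30.4375 / (1 / lam) / 2)

  # adaptive quadrature as oracle for the discounted combination-arm LYs;
  # the right-endpoint (cycle-end) rule under-integrates a decreasing
  # integrand by at most one cycle's area h*(f(0) - f(T)) <= h
  tr4 <- build_trace(combo_os, combo_pfs, cfg)
  oracle <- integrate(function(tm) {
    survival_probability(combo_os, tm) * 1.05^(-tm / 12)
  }, 0, 120, rel.tol = 1e-10)$value / 12
  ly4 <- accrue_life_years(tr4, cfg)
  expect_lt(abs(ly4 - oracle), 21 / 365.25)
  expect_lte(ly4, oracle + 1e-12)

  # discounting can only shrink, longer horizons only grow
  expect_lte(accrue_life_years(tr4, cfg),
             accrue_life_years(tr4, cfg, discounted = FALSE))
  cfg5 <- model_config(horizon_years = 5)
  tr5 <- build_trace(combo_os, combo_pfs, cfg5)
  expect_lte(accrue_life_years(tr5, cfg5), accrue_life_years(tr4, cfg))
})

test_that("QALYs reduce to LYs at unit utility and subtract AE losses once", {
  tr <- build_trace(sora_os, sora_pfs, cfg)
  u1 <- utility_set(1, 1)
  expect_equal(accrue_qalys(tr, u1, 0, cfg), accrue_life_years(tr, cfg))

  u <- utility_set(0.76, 0.68)
  q0 <- accrue_qalys(tr, u, 0, cfg)
  expect_equal(accrue_qalys(tr, u, 0.0261, cfg), q0 - 0.0261)
  expect_error(accrue_qalys(tr, u, -1, cfg), ">= 0")
  expect_error(accrue_qalys(tr, u, q0 + 1, cfg), "negative QALY")
})

test_that("AE disutility-times-incidence sums match the published rosters", {
  loss_combo <- ae_qaly_loss(hccpsm:::ae_profile(params, "combo"))
  loss_sora <- ae_qaly_loss(hccpsm:::ae_profile(params, "sorafenib"))
  expect_equal(loss_combo,
               0.073 * 0.06 + 0.016 * 0.16 + 0.12 * 0.05 + 0.05 * 0.10 +
                 0.05 * 0.01)
  expect_equal(loss_sora,
               0.073 * 0.04 + 0.016 * 0.12 + 0.12 * 0.01 + 0.05 * 0.03 +
                 0.05 * 0.07 + 0.15 * 0.10)
  expect_equal(round(loss_combo, 4), 0.0184)
  expect_equal(round(loss_sora, 4), 0.026)
})

test_that("utility sets enforce their ordering unless explicitly bypassed", {
  expect_error(utility_set(0.6, 0.7), "u_pd <= u_pfs")
  expect_silent(utility_set(0.6, 0.7, validate = FALSE))
})

test_that("traces export to CSV with full per-cycle detail", {
  tr <- build_trace(sora_os, sora_pfs, model_config(horizon_years = 1))
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read.csv(f)
  expect_equal(nrow(back), n_cycles(model_config(horizon_years = 1)))
  expect_true(all(c("cycle", "occupancy_pfs", "occupancy_pd",
                    "occupancy_dead", "incident_deaths",
                    "discount_factor") %in% names(back)))
  expect_equal(back$occupancy_dead, tr$occupancy_dead)
  unlink(f)
})
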