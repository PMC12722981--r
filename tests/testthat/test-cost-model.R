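strategies <- build_strategies(params, cfg)

test_that("per-cycle drug costs follow dose rules without wastage", {
  comp <- function(arm, nm) {
    cs <- strategies[[arm]]$components
    cs[[which(vapply(cs, `[[`, "", "name") == nm)]]
  }
  expect_equal(cycle_drug_cost(comp("combo", "bevacizumab"), 65, 21),
               9.75 * 155.02)                      # 1511.445
  expect_equal(cycle_drug_cost(comp("combo", "toripalimab"), 65, 21), 264.66)
  expect_equal(cycle_drug_cost(comp("sorafenib", "sorafenib"), 65, 21),
               84 * 3.38)                          # 283.92
  # regorafenib: 160 mg/day on 21 of 28 days, prorated to the 21-day cycle
  expect_equal(cycle_drug_cost(strategies$combo$second_line$targeted, 65, 21),
               84 * 7.62 * (21 / 28))              # 480.06
  # pembrolizumab: 200 mg flat by default, 2 mg/kg behind the config switch
  expect_equal(cycle_drug_cost(strategies$combo$second_line$immunotherapy,
                               65, 21), 2 * 2515.97)
  s2 <- build_strategies(params, model_config(pembrolizumab_flat = FALSE))
  expect_equal(cycle_drug_cost(s2$combo$second_line$immunotherapy, 65, 21),
               1.3 * 2515.97)                      # 3270.761
  expect_error(drug_component("x", 100, 10, "per_fortnight", 1),
               "unknown dose_rule")
})

test_that("adverse-event management cost is incidence-weighted", {
  expect_equal(ae_total_cost(NULL), 0)
  expect_equal(ae_total_cost(strategies$sorafenib$ae),
               605.33 * 0.04 + 35.53 * 0.12 + 106.29 * 0.01 +
                 3434.29 * 0.03 + 180.02 * 0.05 + 107.70 * 0.03 +
                 89.02 * 0.05 + 195.74 * 0.07 + 16.96 * 0.10)
  expect_equal(round(ae_total_cost(strategies$sorafenib$ae), 2), 164.65)
  expect_equal(ae_total_cost(strategies$combo$ae),
               605.33 * 0.06 + 35.53 * 0.16 + 106.29 * 0.05 +
                 3434.29 * 0.10 + 180.02 * 0.01 + 107.70 * 0.05 +
                 89.02 * 0.01 + 195.74 * 0.01)
})

test_that("a single progression-free cycle of the combination costs $1,894.62", {
  tr <- toy_trace(pfs = 1)
  expect_equal(first_line_cost(tr, strategies$combo, cfg),
               264.66 + 1511.445 + 2 * 17.69 + 83.13)
  # occupancy zero after cycle 0: only the first cycle contributes
  tr2 <- toy_trace(pfs = c(1, 0, 0))
  expect_equal(first_line_cost(tr2, strategies$combo, cfg),
               first_line_cost(tr, strategies$combo, cfg))
})

test_that("toripalimab stops at its 35-cycle cap while bevacizumab continues", {
  p2 <- unclass(params)
  p2$drugs$bevacizumab$max_cycles <- NULL       # uncapped regimen partner
  class(p2) <- class(params)
  s2 <- build_strategies(p2, cfg)$combo
  flat40 <- toy_trace(pfs = rep(1, 40))
  got <- first_line_cost(flat40, s2, cfg)
  tori_infusion <- 264.66 + 17.69
  bev_infusion <- 1511.445 + 17.69
  expect_equal(got, 35 * tori_infusion + 40 * (bev_infusion + 83.13))
})

test_that("subsequent-therapy cost reduces to BSC in the no-systemic limit", {
  p0 <- params
  for (fld in c("p_any_systemic", "targeted", "immunotherapy")) {
    p0 <- hccpsm:::apply_override(p0, paste0("subsequent.combo.", fld), 0)
  }
  s0 <- build_strategies(p0, cfg)$combo
  tr <- build_trace(s0$os, s0$pfs, cfg)
  expect_equal(subsequent_cost(tr, s0, cfg),
               sum(tr$occupancy_pd * (366.63 + 153.05) * tr$discount_factor))
})

test_that("share interpretations give the documented effective fractions", {
  f_raw <- hccpsm:::subsequent_fractions(strategies$sorafenib, cfg)
  expect_equal(unname(f_raw), c(0.579, 0.445))
  f_norm <- hccpsm:::subsequent_fractions(
    strategies$sorafenib, model_config(share_mode = "normalized"))
  expect_equal(unname(f_norm),
               0.689 * c(0.579, 0.445) / (0.579 + 0.445))
})

test_that("end-of-life cost follows incident deaths", {
  nobody <- toy_trace(pfs = rep(0.4, 5), pd = rep(0.6, 5))
  expect_equal(terminal_cost(nobody, 1914.99), 0)
  everyone <- toy_trace(pfs = 0)   # all dead in the first cycle
  expect_equal(terminal_cost(everyone, 1914.99), 1914.99)
  # fixture arm: bracketed by full and discounted-terminal mass
  tr <- build_trace(sora_os, sora_pfs, cfg)
  tc <- terminal_cost(tr, 1914.99)
  n <- nrow(tr)
  expect_lte(tc, 1914.99)
  expect_gte(tc, 1914.99 * tr$occupancy_dead[n] * tr$discount_factor[n])
})

test_that("strategy cost is the sum of its components", {
  tr <- build_trace(combo_os, combo_pfs, cfg)
  tot <- strategy_total_cost(tr, strategies$combo, cfg)
  parts <- attr(tot, "components")
  expect_equal(as.numeric(tot), sum(parts))
  expect_equal(sum(parts),
               first_line_cost(tr, strategies$combo, cfg) +
                 subsequent_cost(tr, strategies$combo, cfg) +
                 ae_total_cost(strategies$combo$ae) +
                 terminal_cost(tr, 1914.99))
  # degenerate: no occupancy and no transitions -> only the AE cost remains
  empty <- toy_trace(pfs = 0)
  empty$incident_deaths <- 0
  empty$pfs_exits <- 0
  expect_equal(as.numeric(strategy_total_cost(empty, strategies$combo, cfg)),
               ae_total_cost(strategies$combo$ae))
})

test_that("raising a unit cost weakly raises the strategy total", {
  base <- run_base_case(params, cfg)
  up_bev <- run_base_case(
    hccpsm:::apply_override(params, "drugs.bevacizumab.unit_cost", 200), cfg)
  expect_gt(up_bev$table$total_cost[2], base$table$total_cost[2])
  expect_equal(up_bev$table$total_cost[1], base$table$total_cost[1])
  up_eol <- run_base_case(
    hccpsm:::apply_override(params, "costs.end_of_life", 2500), cfg)
  expect_gte(up_eol$table$total_cost[1], base$table$total_cost[1])
  expect_gte(up_eol$table$total_cost[2], base$table$total_cost[2])
})

test_that("incremental comparison handles dominance and undefined ICERs", {
  df <- data.frame(strategy = c("a", "b"), total_cost = c(1000, 2000),
                   ly = c(1, 1.6), qaly = c(1, 1.5))
  out <- compute_cea(df, wtp = 40334)
  expect_equal(out$incremental$icer_per_qaly, 2000)
  expect_true(out$incremental$cost_effective)

  same <- data.frame(strategy = c("a", "b"), total_cost = c(1000, 1000),
                     ly = c(1, 1), qaly = c(1, 1))
  out2 <- compute_cea(same)
  expect_true(is.na(out2$incremental$icer_per_qaly))
  expect_false(out2$incremental$dominant)

  dom <- data.frame(strategy = c("a", "b"), total_cost = c(1000, 900),
                    ly = c(1, 1.2), qaly = c(1, 1.2))
  expect_true(compute_cea(dom)$incremental$dominant)
})
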