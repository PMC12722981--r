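# shared fixtures: parameter bundle, config, and a hand-built trace helper
params <- hcc_parameters()
cfg <- model_config()

# minimal trace with explicit occupancy, for closed-form cost checks
toy_trace <- function(pfs, pd = rep(0, length(pfs)), df = rep(1, length(pfs))) {
  dead <- 1 - pfs - pd
  data.frame(cycle = seq_along(pfs),
             t_start_months = (seq_along(pfs) - 1) * 21 / 30.4375,
             t_eval_months = seq_along(pfs) * 21 / 30.4375,
             occupancy_pfs = pfs, occupancy_pd = pd, occupancy_dead = dead,
             incident_deaths = diff(c(0, dead)),
             pfs_exits = pmax(0, -diff(c(1, pfs))),
             discount_factor = df)
}

lnorm_surv <- function(meanlog, sdlog) {
  parametric_survival("log-normal", c(meanlog = meanlog, sdlog = sdlog))
}

combo_os <- lnorm_surv(2.9363, 1.1358)
combo_pfs <- lnorm_surv(1.6667, 1.1352)
sora_os <- lnorm_surv(2.6781, 1.0775)
sora_pfs <- lnorm_surv(1.3500, 0.8960)
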