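#' Effect-recovery harness over simulated cohorts
#'
#' Generates one cohort per seed under the supplied configuration, collapses
#' to participant means, fits the hierarchical regressions, and records the
#' fitted coefficients for the generator's nonzero effects along with the
#' age-only variance explained. Averaging the columns over many cohorts
#' checks that the analysis recovers the generating effect sizes.
#'
#' @param seeds Integer vector of cohort seeds (one simulated cohort each).
#' @param config A [cohort_config()].
#' @param effects An [effect_config()].
#' @return `data.frame`, one row per cohort: `seed`, `srt_age` (ms/yr),
#'   `ueso_age` (ms/yr), `lvc_age` (ms/yr), `uesdiam_age` (%(C2-4)/yr),
#'   `sip_sex` (ml), `hyb_sip` (ms/ml), `parest_age`, `parest_sex`,
#'   `ueso_r2_age` (stage-1 R-squared for UES opening duration).
#' @export
effect_recovery <- function(seeds = 1:200, config = cohort_config(),
                            effects = effect_config()) {
  rows <- lapply(seeds, function(s) {
    co <- generate_cohort(config, seed = s)
    truth <- generate_parameters(co, effects, config, seed = s)
    pm <- participant_means(truth, co)
    stage1 <- function(oc) {
      f <- hlm(oc, pm, alpha = 0.05)
      list(coef = unname(coef(f, stage = 1)["age"]),
           r2 = f$stages$stage1$r_squared)
    }
    f_sip <- hlm("sip_volume", pm, alpha = 0.05)
    f_hyb <- hlm("hyb_to_ueso", pm, alpha = 0.05)
    f_parest <- hlm("pa_rest", pm, alpha = 0.05, include_sip = FALSE)
    ueso <- stage1("ueso_duration")
    data.frame(
      seed = s,
      srt_age = stage1("swallow_reaction_time")$coef,
      ueso_age = ueso$coef,
      lvc_age = stage1("lvc_duration")$coef,
      uesdiam_age = stage1("ues_diameter")$coef,
      sip_sex = unname(coef(f_sip, stage = 2)["sex_male"]),
      hyb_sip = unname(coef(f_hyb, stage = 3)["sip_volume"]),
      parest_age = unname(coef(f_parest, stage = 1)["age"]),
      parest_sex = unname(coef(f_parest, stage = 2)["sex_male"]),
      ueso_r2_age = ueso$r2
    )
  })
  do.call(rbind, rows)
}
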