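test_that("cohort generation is deterministic, sex-balanced and in range", {
  cfg <- cohort_config()
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$age, c$age))
  expect_identical(sum(a$sex == "male"), 38L)
  expect_identical(sum(a$sex == "female"), 38L)
  expect_true(all(a$age >= 21 & a$age <= 82))
})

test_that("large cohorts match the age distribution mean", {
  cfg <- cohort_config(n = 1000)
  co <- generate_cohort(cfg, seed = 77)
  se <- sqrt(diff(cfg$age_range)^2 / 12 / 1000)
  expect_lt(abs(mean(co$age) - mean(cfg$age_range)), 2 * se)
})

test_that("zero slopes and zero noise reduce every parameter to its intercept", {
  cfg <- cohort_config(n = 6, boluses = 2)
  eff <- effect_config()
  eff$table$slope_age <- 0; eff$table$sex_effect <- 0; eff$table$slope_sip <- 0
  eff$table$sigma_pm <- 1e-12
  co <- generate_cohort(cfg, seed = 1)
  truth <- generate_parameters(co, eff, cfg, seed = 2)
  for (i in seq_len(nrow(eff$table))) {
    p <- eff$table$parameter[i]
    expected <- eff$table$intercept[i]
    if (p %in% c("swallow_reaction_time", "hyb_to_ueso", "ueso_duration",
                 "time_to_lvc", "lvc_duration", "hyoid_burst_duration"))
      expected <- snap_ms_to_grid(expected, fps = cfg$fps)$ms
    expect_lt(max(abs(truth[[p]] - expected)), 1e-6,
              label = paste("parameter", p, "spread"))
  }
})

test_that("generated parameters are deterministic in the seed and truncation is rare", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 11)
  a <- generate_parameters(co, effect_config(), cfg, seed = 12)
  b <- generate_parameters(co, effect_config(), cfg, seed = 12)
  expect_identical(a, b)
  expect_lt(attr(a, "truncation_rate"), 0.05)
  nonneg <- setdiff(continuous_parameters(), "swallow_reaction_time")
  for (p in nonneg) expect_true(all(a[[p]] >= 0), label = p)
  expect_equal(a$residue_total,
               a$residue_valleculae + a$residue_pyriform + a$residue_other)
})

test_that("an invalid correlation matrix is rejected with a PSD hint", {
  R <- default_correlations()
  R["swallow_reaction_time", "hyb_to_ueso"] <- 2
  R["hyb_to_ueso", "swallow_reaction_time"] <- 2
  expect_error(effect_config(correlations = R), "positive semi-definite")
  R2 <- default_correlations()
  R2[1, 2] <- 0.5  # asymmetric
  expect_error(effect_config(correlations = R2), "symmetric")
})

test_that("generated timings sit on the frame grid and synthesis realizes them", {
  cfg <- cohort_config(n = 10)
  co <- generate_cohort(cfg, seed = 21)
  truth <- generate_parameters(co, effect_config(), cfg, seed = 22)
  for (p in c("hyb_to_ueso", "ueso_duration", "time_to_lvc", "lvc_duration"))
    expect_true(all(truth[[p]] == vapply(truth[[p]], function(v)
      as.numeric(snap_ms_to_grid(v, fps = 30)$ms), numeric(1))), label = p)
  # a 500 ms UES opening duration must span exactly 15 frames at 30 fps
  rec <- truth[1, ]
  rec$ueso_duration <- 500
  ann <- synthesize_annotations(rec, cfg, seed = 3)
  expect_identical(ann$events$ues_close - ann$events$ues_open, 15L)
  # zero residue yields empty polygons
  rec$residue_valleculae <- 0; rec$residue_pyriform <- 0; rec$residue_other <- 0
  rec$residue_total <- 0
  ann0 <- synthesize_annotations(rec, cfg, seed = 4)
  expect_null(ann0$contours$residue_valleculae)
  expect_null(ann0$contours$residue_pyriform)
  expect_null(ann0$contours$residue_other)
  expect_equal(summarize_bolus(ann0)$residue_total, 0)
})

test_that("off-grid or negative-duration records are rejected by synthesis", {
  cfg <- cohort_config(n = 2, boluses = 1)
  co <- generate_cohort(cfg, seed = 41)
  truth <- generate_parameters(co, effect_config(), cfg, seed = 42)
  rec <- truth[1, ]
  rec$ueso_duration <- 123  # not on the 30 fps grid
  expect_error(synthesize_annotations(rec, cfg, seed = 1), "grid")
  rec2 <- truth[1, ]
  rec2$hyb_to_ueso <- -100
  expect_error(synthesize_annotations(rec2, cfg, seed = 1), "unrepresentable")
})

test_that("correlated residuals reproduce the intended cross-parameter link", {
  cfg <- cohort_config(n = 500)
  co <- generate_cohort(cfg, seed = 51)
  truth <- generate_parameters(co, effect_config(), cfg, seed = 52)
  pm <- participant_means(truth, co)
  r <- cor(pm$time_to_lvc, pm$hyb_to_ueso)
  expect_gt(r, 0.35); expect_lt(r, 0.65)
  r2 <- cor(pm$time_to_lvc, pm$lvc_duration)
  expect_lt(r2, -0.4)
})

test_that("a noiseless rater reproduces the annotation exactly", {
  cfg <- cohort_config(n = 2, boluses = 1, frame_jitter_sd = 0,
                       coord_jitter_sd = 0, pas_flip_prob = 0, lvc_flip_prob = 0)
  co <- generate_cohort(cfg, seed = 61)
  truth <- generate_parameters(co, effect_config(), cfg, seed = 62)
  ann <- synthesize_annotations(truth[1, ], cfg, seed = 63)
  cp <- simulate_rater(ann, cfg, seed = 64, rater_id = "A")
  expect_identical(unlist(cp$events), unlist(ann$events))
  expect_equal(cp$hyoid$positions, ann$hyoid$positions)
  expect_equal(summarize_bolus(cp)[continuous_parameters()],
               summarize_bolus(ann)[continuous_parameters()],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PAS agreement between two default-noise raters is near 94 percent", {
  cfg <- cohort_config(n = 100, boluses = 2)
  co <- generate_cohort(cfg, seed = 71)
  truth <- generate_parameters(co, effect_config(), cfg, seed = 72)
  anns <- lapply(seq_len(nrow(truth)), function(i)
    synthesize_annotations(truth[i, ], cfg, seed = 1000 + i))
  pas_a <- pas_b <- integer(length(anns))
  for (i in seq_along(anns)) {
    pas_a[i] <- simulate_rater(anns[[i]], cfg, seed = 2000 + i)$pas_max
    pas_b[i] <- simulate_rater(anns[[i]], cfg, seed = 3000 + i)$pas_max
  }
  agree <- percent_agreement(pas_a, pas_b, tolerance = 0)
  # two raters each flipping with probability 0.03: expected (1-p)^2 + small
  expect_gt(agree, 89); expect_lt(agree, 99)
})

test_that("frame jitter produces the folded-normal mean absolute difference", {
  cfg <- cohort_config(n = 60, boluses = 2, coord_jitter_sd = 0,
                       pas_flip_prob = 0, lvc_flip_prob = 0)
  co <- generate_cohort(cfg, seed = 81)
  truth <- generate_parameters(co, effect_config(), cfg, seed = 82)
  anns <- lapply(seq_len(nrow(truth)), function(i)
    synthesize_annotations(truth[i, ], cfg, seed = 4000 + i))
  # use an interior event unaffected by the ordering repairs
  fa <- fb <- integer(length(anns))
  for (i in seq_along(anns)) {
    fa[i] <- simulate_rater(anns[[i]], cfg, seed = 5000 + i)$events$max_pharyngeal_constriction
    fb[i] <- simulate_rater(anns[[i]], cfg, seed = 6000 + i)$events$max_pharyngeal_constriction
  }
  mad <- mean_absolute_difference(fa, fb)
  # oracle: |round(X) - round(Y)|, X,Y ~ N(0,1), by direct simulation
  set.seed(99)
  oracle <- mean(abs(round(rnorm(2e5)) - round(rnorm(2e5))))
  expect_lt(abs(mad - oracle), 0.2)
})
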