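test_that("percent agreement counts matches within tolerance", {
  x <- c(1, 5, 3, 8, 2)
  expect_equal(percent_agreement(x, x), 100)
  # PAS vectors differing in 6 of 100 pairs -> 94%
  a <- rep(1L, 100)
  b <- a; b[c(3, 10, 25, 40, 77, 91)] <- 2L
  expect_equal(percent_agreement(a, b, tolerance = 0), 94)
  # brute-force counting oracle on random frame pairs
  set.seed(21)
  fa <- sample(0:80, 200, replace = TRUE)
  fb <- fa + sample(-6:6, 200, replace = TRUE)
  expect_equal(percent_agreement(fa, fb, tolerance = 3),
               100 * sum(abs(fa - fb) <= 3) / 200)
  expect_equal(percent_agreement(c("a", "b"), c("a", "c")), 50)
  expect_error(percent_agreement(numeric(), numeric()), "empty")
})

test_that("mean absolute difference is the direct mean of |a-b|", {
  expect_equal(mean_absolute_difference(1:10, 1:10), 0)
  expect_equal(mean_absolute_difference(c(10, 20, 30), c(15, 25, 35)), 5)
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(mean_absolute_difference(a, b), mean(abs(a - b)))
  expect_error(mean_absolute_difference(numeric(), numeric()), "empty")
})

test_that("ICC(2,1) is 1 on identical ratings and penalizes rater shifts", {
  a <- c(3, 9, 14, 20, 28, 33, 41, 52, 60, 75)
  expect_equal(icc(a, a), 1)
  # absolute agreement: a constant shift lowers the ICC, monotonically
  shifts <- c(1, 3, 6, 12)
  vals <- vapply(shifts, function(s) icc(a, a + s), numeric(1))
  expect_true(all(vals < 1))
  expect_true(all(diff(vals) < 0))
  expect_warning(v <- icc(rep(5, 10), rep(5, 10)), "zero total variance")
  expect_true(is.na(v))
  expect_error(icc(1:2, 1:2), "at least 3")
})

test_that("ICC matches the variance-components ratio in simulation", {
  set.seed(42)
  sigma_b <- 10; sigma_e <- 3
  truth <- sigma_b^2 / (sigma_b^2 + sigma_e^2)
  item <- rnorm(3000, 50, sigma_b)
  a <- item + rnorm(3000, 0, sigma_e)
  b <- item + rnorm(3000, 0, sigma_e)
  expect_equal(icc(a, b), truth, tolerance = 0.02)
})

test_that("ICC agrees with an ANOVA mean-squares oracle", {
  set.seed(9)
  n <- 40
  a <- rnorm(n, 100, 12) ; b <- a + rnorm(n, 0.8, 4)
  y <- c(a, b)
  item <- factor(rep(seq_len(n), 2)); rater <- factor(rep(1:2, each = n))
  ms <- anova(stats::lm(y ~ item + rater))
  msr <- ms["item", "Mean Sq"]; msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + mse + 2 / n * (msc - mse))
  expect_equal(icc(a, b), oracle, tolerance = 1e-6)
})

test_that("discrepancy flags appear exactly when thresholds are exceeded", {
  a <- make_fixture_annotation()
  expect_identical(nrow(flag_discrepancies(a, a)), 0L)
  b <- a
  b$events$ues_open <- a$events$ues_open + 4L  # threshold is 3 frames
  fl <- flag_discrepancies(a, b)
  expect_identical(nrow(fl), 1L)
  expect_identical(fl$item, "ues_open")
  expect_equal(fl$abs_diff, 4)
  b$events$ues_open <- a$events$ues_open + 3L  # inside threshold
  expect_identical(nrow(flag_discrepancies(a, b)), 0L)
  expect_error(flag_discrepancies(a, a, thresholds = list(ues_open = 3)),
               "no threshold")
})

test_that("flag count plus within-threshold count covers all compared items", {
  cfg <- cohort_config(n = 4, boluses = 1)
  co <- generate_cohort(cfg, seed = 31)
  truth <- generate_parameters(co, effect_config(), cfg, seed = 32)
  thr <- default_thresholds()
  for (i in seq_len(nrow(truth))) {
    ann <- synthesize_annotations(truth[i, ], cfg, seed = 300 + i)
    ra <- simulate_rater(ann, cfg, seed = 400 + i, rater_id = "A")
    rb <- simulate_rater(ann, cfg, seed = 500 + i, rater_id = "B")
    fl <- flag_discrepancies(ra, rb, thr)
    ia <- aspektr:::comparable_items(ra)
    ib <- aspektr:::comparable_items(rb)
    within <- 0L
    for (it in names(ia)) {
      va <- ia[[it]]; vb <- ib[[it]]
      ok <- if (is.numeric(va)) abs(va - vb) <= thr[[it]] else va == vb
      within <- within + as.integer(ok)
    }
    expect_identical(within + nrow(fl), length(ia))
  }
})

test_that("consensus merging follows the resolution and rounded-mean rules", {
  a <- make_fixture_annotation()
  # identical ratings, no flags: consensus equals either rating
  cs <- consensus_merge(a, a)
  expect_equal(summarize_bolus(cs)[continuous_parameters()],
               summarize_bolus(a)[continuous_parameters()], tolerance = 1e-9)
  # unflagged 3-frame difference: rounded mean, round-half-to-even
  b <- a
  b$events$ues_close <- 47L  # a has 44 -> mean 45.5 -> 46
  cs2 <- consensus_merge(a, b)
  expect_identical(cs2$events$ues_close, 46L)
  b$events$ues_close <- 43L  # pair (44, 43): mean 43.5 -> 44 (even)
  expect_identical(consensus_merge(a, b)$events$ues_close, 44L)
  # flagged event without a resolution errors; with one, it is carried
  b$events$ues_close <- 50L
  expect_error(consensus_merge(a, b), "unresolved.*ues_close")
  cs3 <- consensus_merge(a, b, resolutions = list(ues_close = 48))
  expect_identical(cs3$events$ues_close, 48L)
})

test_that("the agreement report summarizes items across pairs", {
  cfg <- cohort_config(n = 6, boluses = 2)
  co <- generate_cohort(cfg, seed = 61)
  truth <- generate_parameters(co, effect_config(), cfg, seed = 62)
  anns <- lapply(seq_len(nrow(truth)), function(i)
    synthesize_annotations(truth[i, ], cfg, seed = 600 + i))
  ra <- lapply(seq_along(anns), function(i)
    simulate_rater(anns[[i]], cfg, seed = 700 + i, "A"))
  rb <- lapply(seq_along(anns), function(i)
    simulate_rater(anns[[i]], cfg, seed = 800 + i, "B"))
  rep <- agreement_report(ra, rb)
  expect_true(all(rep$pct_agreement >= 0 & rep$pct_agreement <= 100, na.rm = TRUE))
  expect_true(all(rep$mean_abs_diff >= 0, na.rm = TRUE))
  expect_true(all(rep$icc >= -1 & rep$icc <= 1, na.rm = TRUE))
  expect_identical(unique(rep$n_pairs), nrow(truth))
  # perfect raters: identical lists give 100% agreement and zero differences
  rep0 <- agreement_report(ra, ra)
  cont <- rep0$kind == "continuous"
  expect_true(all(rep0$pct_agreement == 100))
  expect_true(all(rep0$mean_abs_diff[cont] == 0))
})

test_that("noisier raters have lower expected ICC", {
  set.seed(77)
  item <- rnorm(120, 100, 10)
  sds <- c(1, 4, 10, 25)
  vals <- vapply(sds, function(s) {
    mean(vapply(1:30, function(i)
      icc(item + rnorm(120, 0, s), item + rnorm(120, 0, s)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})
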