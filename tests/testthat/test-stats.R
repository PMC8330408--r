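test_that("quartile descriptives use linear interpolation between order statistics", {
  expect_equal(descriptives(1:5), c(p25 = 2, median = 3, p75 = 4))
  expect_equal(descriptives(rep(7, 9)), c(p25 = 7, median = 7, p75 = 7))
  set.seed(5)
  x <- rnorm(37)
  # direct sort-and-interpolate oracle (type 7): h = (n-1) p + 1
  oracle <- function(p) {
    s <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }
  expect_equal(unname(descriptives(x)),
               c(oracle(0.25), oracle(0.5), oracle(0.75)))
  expect_error(descriptives(numeric()), "no finite")
})

test_that("family alphas follow the rounded Bonferroni rule", {
  expect_identical(family_alpha(3), 0.017)
  expect_identical(family_alpha(5), 0.01)
  expect_identical(family_alpha(1), 0.05)
  m <- 1:12
  a <- vapply(m, family_alpha, numeric(1))
  expect_true(all(diff(a) <= 0))          # non-increasing in family size
  expect_true(all(a <= 0.05))
  expect_error(family_alpha(0), "m must be >= 1")
  fams <- default_families()
  expect_equal(fams$early_timing$alpha, 0.017)
  expect_equal(fams$opening_kinematics$alpha, 0.01)
  expect_equal(fams$area_residue$alpha, 0.01)
  expect_equal(outcome_alpha("time_to_lvc"), 0.017)
  expect_equal(outcome_alpha("residue_total"), 0.01)
  expect_equal(outcome_alpha("sip_volume"), 0.05)
})

test_that("correlation screen reports strong pairs and skips constants", {
  set.seed(8)
  d <- data.frame(ueso_duration = rnorm(40), lvc_duration = rnorm(40))
  d$ues_diameter <- d$ueso_duration  # r = 1 exactly
  out <- correlation_screen(d, parameters = names(d))
  expect_true(any(out$param_a == "ueso_duration" & out$param_b == "ues_diameter" |
                  out$param_a == "ues_diameter" & out$param_b == "ueso_duration"))
  expect_equal(max(abs(out$r)), 1)
  expect_true(all(diff(abs(out$r)) <= 0))  # sorted by |r| descending
  d$pa_rest <- 5
  expect_warning(correlation_screen(d, parameters = names(d)), "constant column")
})

test_that("null columns trigger reports at the theoretical rate", {
  set.seed(13)
  n <- 76; reps <- 400
  hits <- vapply(seq_len(reps), function(i) {
    r <- cor(rnorm(n), rnorm(n))
    abs(r) > 0.25
  }, logical(1))
  tstat <- 0.25 * sqrt(n - 2) / sqrt(1 - 0.25^2)
  p_null <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  se <- sqrt(p_null * (1 - p_null) / reps)
  expect_lt(abs(mean(hits) - p_null), 3 * se)
})

test_that("hierarchical regression is exact on a deterministic outcome", {
  set.seed(2)
  d <- data.frame(participant_id = sprintf("P%02d", 1:40),
                  age = runif(40, 21, 82),
                  sex_male = rep(0:1, 20),
                  sip_volume = runif(40, 5, 25))
  d$y <- 2 * d$age
  fit <- hlm("y", d, alpha = 0.05)
  expect_equal(unname(coef(fit, stage = 1)["age"]), 2, tolerance = 1e-9)
  expect_equal(fit$stages$stage1$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$effects[["age"]])
})

test_that("R-squared never decreases across hierarchical stages", {
  cfg <- cohort_config(n = 40)
  for (seed in 1:5) {
    co <- generate_cohort(cfg, seed = seed)
    truth <- generate_parameters(co, effect_config(), cfg, seed = seed + 50)
    pm <- participant_means(truth, co)
    for (oc in c("swallow_reaction_time", "ueso_duration", "ues_diameter",
                 "hyb_to_ueso", "peak_xy_hyoid")) {
      fit <- hlm(oc, pm, alpha = 0.05)
      r2 <- vapply(fit$stages, `[[`, numeric(1), "r_squared")
      dr2 <- vapply(fit$stages, `[[`, numeric(1), "delta_r2")
      expect_true(all(diff(r2) >= -1e-12))
      expect_true(all(dr2 >= -1e-12))
      expect_equal(sum(dr2), r2[[length(r2)]], tolerance = 1e-9)
    }
  }
})

test_that("OLS stages agree with a normal-equations oracle at 1e-6", {
  set.seed(19)
  d <- data.frame(age = runif(60, 21, 82), sex_male = rbinom(60, 1, 0.5),
                  sip_volume = runif(60, 5, 25))
  d$y <- 100 + 1.5 * d$age + 4 * d$sex_male - 2 * d$sip_volume + rnorm(60, 0, 20)
  fit <- hlm("y", d, alpha = 0.05)
  X <- cbind(1, d$age, d$sex_male, d$sip_volume)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(coef(fit, stage = 3)), c(beta), tolerance = 1e-6)
  yhat <- X %*% beta
  r2 <- 1 - sum((d$y - yhat)^2) / sum((d$y - mean(d$y))^2)
  expect_equal(fit$stages$stage3$r_squared, r2, tolerance = 1e-6)
})

test_that("the sip stage is omitted for rest measures and sip volume itself", {
  set.seed(4)
  d <- data.frame(age = runif(30, 21, 82), sex_male = rbinom(30, 1, 0.5),
                  sip_volume = runif(30, 5, 25))
  d$pa_rest <- 60 + 0.3 * d$age + rnorm(30, 0, 10)
  fit <- hlm("pa_rest", d, alpha = 0.01, include_sip = FALSE)
  expect_identical(length(fit$stages), 2L)
  expect_true(is.na(fit$effects[["sip"]]))
  fit2 <- hlm("sip_volume", d, alpha = 0.05)
  expect_identical(length(fit2$stages), 2L)
})

test_that("singular designs raise a collinearity error", {
  d <- data.frame(age = rep(50, 20), sex_male = rbinom(20, 1, 0.5),
                  sip_volume = runif(20, 5, 25), y = rnorm(20))
  d$age <- d$sip_volume  # age duplicates sip volume at stage 3
  expect_error(hlm("y", d, alpha = 0.05), "singular|collinear")
})

test_that("stage-1 age test holds its type-I error rate under the null", {
  cfg <- cohort_config(n = 76, boluses = 3)
  eff <- effect_config()
  eff$table$slope_age <- 0; eff$table$sex_effect <- 0; eff$table$slope_sip <- 0
  reps <- 500
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    co <- generate_cohort(cfg, seed = 9000 + i)
    truth <- generate_parameters(co, eff, cfg, seed = 19000 + i)
    pm <- participant_means(truth, co)
    fit <- hlm("time_to_lvc", pm, alpha = 0.05)
    rej[i] <- fit$stages$stage1$terms$p_value[
      fit$stages$stage1$terms$term == "age"] < 0.05
  }
  band <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), band)
})

test_that("logistic fits match a hand-rolled Newton-Raphson oracle", {
  set.seed(23)
  n <- 300
  d <- data.frame(age = runif(n, 21, 82), sex_male = rbinom(n, 1, 0.5),
                  sip_volume = runif(n, 5, 25))
  eta <- -2 + 0.09 * (d$sip_volume - 14)
  d$multiple_swallows <- runif(n) < plogis(eta)
  fit <- binary_logistic(d)
  X <- cbind(1, d$age, d$sex_male, d$sip_volume)
  y <- as.numeric(d$multiple_swallows)
  beta <- rep(0, 4)
  for (it in 1:50) {
    p <- plogis(drop(X %*% beta))
    W <- p * (1 - p)
    step <- solve(crossprod(X, X * W), crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  expect_equal(fit$estimate, beta, tolerance = 1e-6)
  expect_equal(fit$odds_ratio, exp(beta), tolerance = 1e-6)
})

test_that("logistic regression refuses a single-class outcome", {
  d <- data.frame(age = runif(30, 21, 82), sex_male = 0,
                  sip_volume = runif(30, 5, 25), multiple_swallows = FALSE)
  expect_error(binary_logistic(d), "both outcome classes")
})

test_that("null-predictor logistic coefficients are near zero", {
  set.seed(33)
  n <- 4000
  d <- data.frame(age = runif(n, 21, 82), sex_male = rbinom(n, 1, 0.5),
                  sip_volume = runif(n, 5, 25),
                  multiple_swallows = runif(n) < 0.2)
  fit <- binary_logistic(d)
  expect_lt(max(abs(fit$estimate[fit$term != "(Intercept)"])), 0.05)
})

test_that("2x2 odds ratios follow the Woolf formula and its symmetries", {
  r <- two_by_two_or(10, 10, 10, 10)
  expect_equal(r$or, 1)
  expect_lt(r$ci_lower, 1); expect_gt(r$ci_upper, 1)
  r2 <- two_by_two_or(20, 10, 10, 20)
  expect_equal(r2$or, 4)
  se <- sqrt(1/20 + 1/10 + 1/10 + 1/20)
  expect_equal(r2$ci_lower, exp(log(4) - qnorm(0.975) * se))
  expect_equal(r2$ci_upper, exp(log(4) + qnorm(0.975) * se))
  # swapping the rows inverts the odds ratio
  r3 <- two_by_two_or(10, 20, 20, 10)
  expect_equal(r3$or, 1 / r2$or)
  # zero cell: Haldane-Anscombe correction kicks in
  r4 <- two_by_two_or(0, 10, 10, 10)
  expect_true(r4$corrected)
  expect_equal(r4$or, (0.5 * 10.5) / (10.5 * 10.5))
  expect_error(two_by_two_or(0, 0, 5, 5), "margin")
})

test_that("sip dichotomization tallies the 2x2 table by strict cut", {
  d <- data.frame(sip_volume = c(20, 18, 17, 16, 15, 10, 25, 9),
                  n_swallows = c(2, 1, 2, 2, 1, 1, 1, 2))
  cnt <- dichotomize_sip(d, cut = 16)
  # >16: 20,18,17,25 -> multiple 20,17 | <=16: 16,15,10,9 -> multiple 16,9
  expect_identical(unname(cnt), c(2L, 2L, 2L, 2L))
  d2 <- data.frame(sip_volume = rep(10, 5), n_swallows = c(1, 2, 1, 1, 2))
  cnt2 <- dichotomize_sip(d2, cut = 16)
  expect_error(do.call(two_by_two_or, as.list(cnt2)), "margin")
})

test_that("larger sips raise the odds of multiple swallows under generator defaults", {
  cfg <- cohort_config(n = 76)
  ors <- vapply(1:10, function(s) {
    co <- generate_cohort(cfg, seed = s)
    truth <- generate_parameters(co, effect_config(), cfg, seed = 100 + s)
    cnt <- dichotomize_sip(truth, cut = 16)
    do.call(two_by_two_or, as.list(cnt))$or
  }, numeric(1))
  expect_gt(mean(ors), 1)
})
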