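# Statistical stage: descriptives, correlation screening, Bonferroni outcome
# families, hierarchical age/sex/sip-volume regression on participant means,
# bolus-level logistic regression and 2x2 odds ratios.

#' Quartile descriptives
#'
#' @param x Numeric vector with at least one finite value.
#' @param type Quantile convention passed to [stats::quantile()] (default 7,
#'   linear interpolation between closest order statistics).
#' @return Named numeric vector `c(p25, median, p75)`.
#' @export
descriptives <- function(x, type = 7) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("undefined statistic: no finite values")
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = type, names = FALSE)
  c(p25 = q[1L], median = q[2L], p75 = q[3L])
}

#' Descriptives table for all continuous parameters
#' @param records Parameter-record `data.frame` (one row per bolus or
#'   participant).
#' @param parameters Columns to summarise (default all continuous parameters
#'   present).
#' @return `data.frame` with `parameter`, `n`, `p25`, `median`, `p75`.
#' @export
descriptives_table <- function(records, parameters = intersect(continuous_parameters(),
                                                               names(records))) {
  rows <- lapply(parameters, function(p) {
    x <- records[[p]]
    d <- descriptives(x)
    data.frame(parameter = p, n = sum(is.finite(x)), p25 = d[["p25"]],
               median = d[["median"]], p75 = d[["p75"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation screen
#'
#' All pairwise Pearson correlations among the given continuous columns,
#' reporting pairs whose absolute correlation exceeds the threshold, sorted by
#' `|r|` descending. Used to decide which outcomes need a shared
#' Bonferroni-corrected alpha.
#'
#' @param data `data.frame` of continuous parameters (participant means).
#' @param parameters Columns to screen (default: all of
#'   [continuous_parameters()] present in `data`).
#' @param threshold Report pairs with `|r|` above this value (default 0.25).
#' @return `data.frame` with `param_a`, `param_b`, `r`, `p`.
#' @export
correlation_screen <- function(data, parameters = intersect(continuous_parameters(),
                                                            names(data)),
                               threshold = 0.25) {
  rows <- list()
  for (i in seq_along(parameters)) for (j in seq_len(i - 1L)) {
    pa <- parameters[[j]]; pb <- parameters[[i]]
    x <- data[[pa]]; y <- data[[pb]]
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3L) next
    if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      warning("constant column in pair (", pa, ", ", pb, "): skipped")
      next
    }
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
    if (abs(ct$estimate) > threshold)
      rows[[length(rows) + 1L]] <- data.frame(param_a = pa, param_b = pb,
                                              r = unname(ct$estimate),
                                              p = ct$p.value,
                                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(param_a = character(), param_b = character(), r = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Bonferroni-corrected family alpha
#'
#' Divides the base alpha by the family size and rounds to the given number
#' of decimals: a family of 3 correlated outcomes gives 0.017, a family of 5
#' gives 0.01.
#'
#' @param m Family size (>= 1).
#' @param base Base alpha (default 0.05).
#' @param decimals Decimals to round to (default 3).
#' @return Corrected alpha.
#' @export
family_alpha <- function(m, base = 0.05, decimals = 3) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1)
    stop("configuration error: family size m must be >= 1")
  round(base / m, decimals)
}

#' Default correlated-outcome families
#'
#' The three families of correlated outcomes sharing a Bonferroni-corrected
#' alpha: the early-timing family (m = 3, alpha 0.017), the
#' opening/kinematics family (m = 5, alpha 0.01) and the area/residue family
#' (m = 5, alpha 0.01). Outcomes in no family use the base alpha.
#'
#' @param base Base alpha (default 0.05).
#' @return Named list of families, each with `members` and `alpha`.
#' @export
default_families <- function(base = 0.05) {
  fams <- list(
    early_timing = c("hyb_to_ueso", "hyoid_burst_duration", "time_to_lvc"),
    opening_kinematics = c("ueso_duration", "lvc_duration", "ues_diameter",
                           "peak_xy_hyoid", "hyoid_xy_speed"),
    area_residue = c("pa_rest", "pa_max_constriction", "residue_valleculae",
                     "residue_pyriform", "residue_other")
  )
  lapply(fams, function(m) list(members = m, alpha = family_alpha(length(m), base)))
}

#' Alpha applicable to an outcome under the family scheme
#' @param outcome Outcome name.
#' @param families Family list as from [default_families()].
#' @param base Base alpha for outcomes outside every family.
#' @return Numeric alpha.
#' @export
outcome_alpha <- function(outcome, families = default_families(), base = 0.05) {
  # total residue is analysed under the residue family's alpha
  if (outcome == "residue_total") outcome <- "residue_valleculae"
  for (f in families) if (outcome %in% f$members) return(f$alpha)
  base
}

#' Participant-mean table
#'
#' Collapses the per-bolus parameter records to one row per participant: the
#' mean of each continuous parameter across the participant's boluses, plus
#' `any_multiple_swallows`, merged with the age/sex covariates.
#'
#' @param records Per-bolus parameter record `data.frame`.
#' @param participants `data.frame` with `participant_id`, `age`, `sex`
#'   (`"male"`/`"female"`).
#' @return One row per participant with covariates, participant means, and
#'   `sex_male` indicator (male = 1, female = 0).
#' @export
participant_means <- function(records, participants) {
  params <- intersect(continuous_parameters(), names(records))
  agg <- stats::aggregate(records[params],
                          by = list(participant_id = records$participant_id),
                          FUN = function(x) mean(x, na.rm = TRUE))
  mult <- stats::aggregate(list(any_multiple_swallows = records$n_swallows > 1L),
                           by = list(participant_id = records$participant_id),
                           FUN = any)
  out <- merge(participants, merge(agg, mult, by = "participant_id"),
               by = "participant_id")
  out$sex_male <- as.integer(out$sex == "male")
  out
}

#' Hierarchical age/sex/sip-volume linear regression
#'
#' Fits ordinary least squares on participant means in stages: (1) age alone,
#' (2) age + sex, (3) age + sex + sip volume; reports per-stage coefficients,
#' R-squared and the R-squared increment, and tests each predictor (at its
#' entry stage) against the supplied family alpha. Sex is coded male = 1,
#' female = 0, so its coefficient is the male-female difference. The
#' sip-volume stage is skipped for outcomes measured at rest (set
#' `include_sip = FALSE`) and when the outcome is sip volume itself.
#'
#' @param outcome Name of the outcome column.
#' @param data Participant-mean `data.frame` with `age`, `sex_male` and (if
#'   used) `sip_volume` columns, >= 10 rows.
#' @param alpha Significance level applied to every stage (the outcome's
#'   family alpha).
#' @param include_sip Whether to fit the sip-volume stage (default `TRUE`;
#'   automatically dropped when the outcome is `sip_volume`).
#' @return Object of class `aspekt_hlm` with elements `outcome`, `alpha`,
#'   `stages` (list of per-stage coefficient tables, `r_squared`,
#'   `adj_r_squared`, `delta_r2`), `effects` (named logical significance
#'   decisions) and `fits` (the underlying `lm` objects).
#' @export
hlm <- function(outcome, data, alpha = 0.05, include_sip = TRUE) {
  if (!outcome %in% names(data)) stop("unknown outcome: ", outcome)
  if (outcome == "sip_volume") include_sip <- FALSE
  preds <- list(stage1 = "age", stage2 = c("age", "sex_male"))
  if (include_sip) preds$stage3 <- c("age", "sex_male", "sip_volume")
  use <- stats::complete.cases(data[c(outcome, unlist(preds[[length(preds)]]))])
  d <- data[use, , drop = FALSE]
  if (nrow(d) < 10L) stop("hierarchical regression requires >= 10 complete participants")
  fits <- list(); stages <- list(); prev_r2 <- 0
  for (s in names(preds)) {
    fml <- stats::reformulate(preds[[s]], response = outcome)
    mm <- stats::model.matrix(fml, d)
    if (qr(mm)$rank < ncol(mm))
      stop("singular design: collinear predictors among ",
           paste(preds[[s]], collapse = ", "))
    fit <- stats::lm(fml, data = d)
    sm <- summary(fit)
    co <- as.data.frame(sm$coefficients)
    names(co) <- c("estimate", "std_error", "t_value", "p_value")
    co$term <- rownames(co); rownames(co) <- NULL
    stages[[s]] <- list(terms = co[, c("term", "estimate", "std_error",
                                       "t_value", "p_value")],
                        r_squared = sm$r.squared,
                        adj_r_squared = sm$adj.r.squared,
                        delta_r2 = sm$r.squared - prev_r2)
    prev_r2 <- sm$r.squared
    fits[[s]] <- fit
  }
  pval <- function(stage, term) {
    tt <- stages[[stage]]$terms
    tt$p_value[match(term, tt$term)]
  }
  effects <- c(age = unname(pval("stage1", "age") < alpha),
               sex = unname(pval("stage2", "sex_male") < alpha),
               sip = if (include_sip) unname(pval("stage3", "sip_volume") < alpha) else NA)
  structure(list(outcome = outcome, alpha = alpha, n = nrow(d),
                 stages = stages, effects = effects, fits = fits),
            class = "aspekt_hlm")
}

#' @export
print.aspekt_hlm <- function(x, ...) {
  cat("Hierarchical regression for", x$outcome, " (n =", x$n,
      ", family alpha =", x$alpha, ")\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %s: R2 = %.3f (delta %.3f)\n", s, st$r_squared, st$delta_r2))
  }
  eff <- x$effects
  cat("  effects at alpha:",
      paste(names(eff), ifelse(is.na(eff), "n/a", ifelse(eff, "yes", "no")),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.aspekt_hlm <- function(object, ...) {
  tabs <- lapply(names(object$stages), function(s) {
    st <- object$stages[[s]]
    cbind(stage = s, st$terms, r_squared = st$r_squared, delta_r2 = st$delta_r2)
  })
  out <- do.call(rbind, tabs)
  attr(out, "outcome") <- object$outcome
  attr(out, "alpha") <- object$alpha
  out
}

#' @export
coef.aspekt_hlm <- function(object, stage = length(object$stages), ...) {
  stats::coef(object$fits[[stage]])
}

#' @export
predict.aspekt_hlm <- function(object, newdata = NULL,
                               stage = length(object$stages), ...) {
  stats::predict(object$fits[[stage]], newdata = newdata, ...)
}

#' @export
residuals.aspekt_hlm <- function(object, stage = length(object$stages), ...) {
  stats::residuals(object$fits[[stage]])
}

#' @export
simulate.aspekt_hlm <- function(object, nsim = 1, seed = NULL,
                                stage = length(object$stages), ...) {
  stats::simulate(object$fits[[stage]], nsim = nsim, seed = seed, ...)
}

#' Bolus-level binary logistic regression
#'
#' Maximum-likelihood logistic fit of a binary outcome (by default, multiple
#' swallows per bolus) on age, sex and sip volume at the bolus level, with
#' Wald tests and odds ratios.
#'
#' @param data Bolus-level `data.frame` with the outcome and predictor
#'   columns.
#' @param outcome Name of the logical/0-1 outcome column (default
#'   `"multiple_swallows"`).
#' @param predictors Predictor column names.
#' @return `data.frame` of terms: `estimate` (log-odds), `std_error`,
#'   `odds_ratio`, `p_value`; plus attributes `fit` (the `glm`) and `n`.
#' @export
binary_logistic <- function(data, outcome = "multiple_swallows",
                            predictors = c("age", "sex_male", "sip_volume")) {
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("both outcome classes must be present for logistic regression")
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::glm(fml, data = data, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)[-1L]) > 15))
    stop("complete or quasi-complete separation detected; ",
         "consider a penalized fit (not applied by default)")
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                    std_error = sm[, 2L], odds_ratio = exp(sm[, 1L]),
                    p_value = sm[, 4L], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  attr(out, "n") <- nrow(fit$model)
  out
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' `OR = ad / bc` with the log-normal (Woolf) 95 percent interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell triggers
#' the Haldane-Anscombe 0.5 continuity correction (applied to all cells and
#' reported).
#'
#' @param a,b,c,d Non-negative counts: `a` exposed cases, `b` exposed
#'   non-cases, `c` unexposed cases, `d` unexposed non-cases.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_lower`, `ci_upper`, `corrected` (logical),
#'   `conf_level`.
#' @export
two_by_two_or <- function(a, b, c, d, conf_level = 0.95) {
  cnt <- c(a = a, b = b, c = c, d = d)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("undefined odds ratio: a table margin is zero")
  corrected <- any(cnt == 0)
  if (corrected) cnt <- cnt + 0.5
  or <- (cnt["a"] * cnt["d"]) / (cnt["b"] * cnt["c"])
  se <- sqrt(sum(1 / cnt))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or),
       ci_lower = unname(exp(log(or) - z * se)),
       ci_upper = unname(exp(log(or) + z * se)),
       corrected = corrected, conf_level = conf_level)
}

#' Dichotomize sip volume against a cut point
#'
#' Builds the 2x2 table of (sip volume strictly greater than the cut) by
#' (multiple swallows per bolus), in the layout [two_by_two_or()] expects:
#' large-sip boluses are the exposed group, multiple swallows the cases.
#'
#' @param records Bolus-level `data.frame` with `sip_volume` and
#'   `n_swallows` (or logical `multiple_swallows`).
#' @param cut Cut point in ml (default 16).
#' @return Named counts `c(a, b, c, d)`.
#' @export
dichotomize_sip <- function(records, cut = 16) {
  mult <- if ("multiple_swallows" %in% names(records)) records$multiple_swallows
          else records$n_swallows > 1L
  keep <- !is.na(records$sip_volume) & !is.na(mult)
  large <- records$sip_volume[keep] > cut
  mult <- mult[keep]
  c(a = sum(large & mult), b = sum(large & !mult),
    c = sum(!large & mult), d = sum(!large & !mult))
}
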