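# Synthetic study generator: cohorts, per-bolus true parameter values with the
# configured effect and correlation structure, raw annotations realizing those
# values, and noisy dual-rater copies. Everything is deterministic given a
# seed, so measurement, agreement and statistics are testable end to end
# without patient data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort generator settings
#'
#' Defaults emulate the study conditions: 76 participants, sex-balanced,
#' ages uniform on 21-82, 3 thin-liquid boluses each, 30 fps recordings,
#' spine lengths around 100 px, and bounded dual-rater annotation noise
#' (1-frame event jitter, 1-px coordinate jitter, 3 percent PAS flip
#' probability).
#'
#' @param n Number of participants (>= 2).
#' @param age_range Length-2 numeric, uniform age range in years.
#' @param boluses Boluses per participant (>= 1).
#' @param fps Recording frame rate.
#' @param spine_length_mean,spine_length_sd C2-C4 pixel length distribution.
#' @param frame_jitter_sd Rater event-frame jitter SD (frames).
#' @param coord_jitter_sd Rater coordinate jitter SD (px).
#' @param pas_flip_prob Per-rater probability of perturbing a PAS score.
#' @param lvc_flip_prob Per-rater probability of perturbing LVC integrity.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 76L, age_range = c(21, 82), boluses = 3L, fps = 30,
                          spine_length_mean = 100, spine_length_sd = 8,
                          frame_jitter_sd = 1, coord_jitter_sd = 1,
                          pas_flip_prob = 0.03, lvc_flip_prob = 0.015) {
  stopifnot(n >= 2L, boluses >= 1L, fps > 0, frame_jitter_sd >= 0,
            coord_jitter_sd >= 0, pas_flip_prob >= 0, lvc_flip_prob >= 0,
            diff(age_range) > 0)
  structure(list(n = as.integer(n), age_range = age_range,
                 boluses = as.integer(boluses), fps = fps,
                 spine_length_mean = spine_length_mean,
                 spine_length_sd = spine_length_sd,
                 frame_jitter_sd = frame_jitter_sd,
                 coord_jitter_sd = coord_jitter_sd,
                 pas_flip_prob = pas_flip_prob, lvc_flip_prob = lvc_flip_prob),
            class = "cohort_config")
}

# Parameters drawn from the correlated linear model, in fixed order.
gen_parameters <- function() {
  c("swallow_reaction_time", "hyb_to_ueso", "ueso_duration", "time_to_lvc",
    "lvc_duration", "hyoid_burst_duration", "peak_xy_hyoid", "hyoid_xy_speed",
    "ues_diameter", "pa_max_constriction", "pa_rest",
    "residue_valleculae", "residue_pyriform", "residue_other")
}

# Residual SD (participant-mean scale) such that the age-only regression on
# participant means explains the target share of variance:
# sigma^2 = slope^2 * Var(age) * (1 - R2) / R2.
calibrate_sigma <- function(slope, r2, var_age) {
  sqrt(slope^2 * var_age * (1 - r2) / r2)
}

default_correlations <- function() {
  p <- gen_parameters()
  R <- diag(length(p)); dimnames(R) <- list(p, p)
  set <- function(a, b, r) {
    R[a, b] <<- r; R[b, a] <<- r
  }
  set("time_to_lvc", "hyb_to_ueso", 0.53)
  set("time_to_lvc", "lvc_duration", -0.60)
  set("lvc_duration", "ueso_duration", 0.40)
  set("lvc_duration", "ues_diameter", 0.25)
  set("ueso_duration", "ues_diameter", 0.22)
  set("ueso_duration", "peak_xy_hyoid", 0.25)
  set("peak_xy_hyoid", "ues_diameter", 0.52)
  set("peak_xy_hyoid", "hyoid_xy_speed", 0.28)
  set("peak_xy_hyoid", "pa_rest", 0.25)
  set("pa_max_constriction", "residue_valleculae", 0.45)
  set("pa_max_constriction", "residue_pyriform", 0.40)
  set("residue_valleculae", "residue_pyriform", 0.40)
  set("residue_valleculae", "residue_other", 0.40)
  set("residue_pyriform", "residue_other", 0.40)
  set("hyoid_burst_duration", "time_to_lvc", 0.30)
  set("hyoid_burst_duration", "hyb_to_ueso", 0.30)
  R
}

#' Effect-size configuration for the generator
#'
#' Per-parameter linear model: value = intercept (anchored at age 70, the
#' older-cohort medians) + age slope * (age - 70) + sex effect * male +
#' sip slope * (sip - 14 ml) + correlated residual. Default slopes encode the
#' study-scale effects: swallow reaction time +4 ms/yr, UES opening duration
#' +1.4 ms/yr, LVC duration +2.4 ms/yr, UES diameter +0.11 %(C2-4)/yr and
#' +0.27 %(C2-4)/ml, pharyngeal area at rest +0.31 %(C2-4)^2/yr and
#' +11 %(C2-4)^2 for males, pharyngeal area at maximum constriction
#' +0.035 %(C2-4)^2/yr, hyoid-burst-to-UES-opening -2.4 ms/ml; sip volume
#' +4.69 ml for males. Residual SDs for the four age-effect parameters with a
#' published variance share are calibrated so the age-only participant-mean
#' regression explains 6 / 12 / 8 / 10 percent of variance; the
#' hyoid-burst-to-UES-opening SD targets a 13 percent sip-volume share.
#'
#' @param age_range Age range used in the residual-SD calibration.
#' @param sip_base Mean sip volume (ml) at which sip effects are centered.
#' @param sip_sd_participant,sip_sd_bolus Between-participant and
#'   within-participant sip volume SDs (ml).
#' @param sip_sex_effect Male-female sip volume difference (ml).
#' @param multiple_logit_intercept,multiple_logit_slope Logistic model for a
#'   multiple-swallow bolus on centered sip volume (log-odds per ml).
#' @param correlations Residual correlation matrix across the drawn
#'   parameters (symmetric PSD, unit diagonal).
#' @return List of class `effect_config` with `table` (per-parameter
#'   intercept, slopes, sigma), sip model and logistic model settings.
#' @export
effect_config <- function(age_range = c(21, 82), sip_base = 14,
                          sip_sd_participant = 4, sip_sd_bolus = 2,
                          sip_sex_effect = 4.69,
                          multiple_logit_intercept = -1.386,
                          multiple_logit_slope = 0.09,
                          correlations = default_correlations()) {
  var_age <- diff(age_range)^2 / 12
  tab <- data.frame(
    parameter = gen_parameters(),
    intercept = c(200, 100, 500, 134, 534, 400, 176, 117, 23, 2, 63, 1.0, 0.5, 0.3),
    slope_age = c(4, 0, 1.4, 0, 2.4, 0, 0, 0, 0.11, 0.035, 0.31, 0, 0, 0),
    sex_effect = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 11, 0, 0, 0),
    slope_sip = c(0, -2.4, 0, 0, 0, 0, 0, 0, 0.27, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  var_sip_pm <- sip_sd_participant^2 + sip_sd_bolus^2 / 3
  sigma <- c(
    swallow_reaction_time = calibrate_sigma(4, 0.06, var_age),
    hyb_to_ueso = calibrate_sigma(2.4, 0.13, var_sip_pm),
    ueso_duration = calibrate_sigma(1.4, 0.12, var_age),
    time_to_lvc = 50,
    lvc_duration = calibrate_sigma(2.4, 0.08, var_age),
    hyoid_burst_duration = 60,
    peak_xy_hyoid = 15,
    hyoid_xy_speed = 25,
    ues_diameter = calibrate_sigma(0.11, 0.10, var_age),
    pa_max_constriction = 1.5,
    pa_rest = calibrate_sigma(0.31, 0.10, var_age),
    residue_valleculae = 0.5,
    residue_pyriform = 0.3,
    residue_other = 0.2
  )
  tab$sigma_pm <- unname(sigma[tab$parameter])
  if (!isTRUE(all.equal(correlations, t(correlations))) ||
      any(diag(correlations) != 1))
    stop("configuration error: correlation matrix must be symmetric with unit diagonal")
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("configuration error: correlation matrix is not positive semi-definite; ",
         "project it to the nearest PSD matrix (e.g. Matrix::nearPD)")
  structure(list(table = tab, sip_base = sip_base,
                 sip_sd_participant = sip_sd_participant,
                 sip_sd_bolus = sip_sd_bolus, sip_sex_effect = sip_sex_effect,
                 multiple_logit_intercept = multiple_logit_intercept,
                 multiple_logit_slope = multiple_logit_slope,
                 correlations = correlations, age_anchor = 70),
            class = "effect_config")
}

#' Generate a participant table
#'
#' Exactly sex-balanced cohort (odd n gives the extra participant to the
#' female group) with ages drawn uniformly from the configured range.
#'
#' @param config A [cohort_config()].
#' @param seed Integer random seed; the table is deterministic given it.
#' @return `data.frame` with `participant_id`, `age`, `sex`, `sex_male`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  with_seed(seed, {
    n <- config$n
    n_male <- n %/% 2L
    sex <- c(rep("male", n_male), rep("female", n - n_male))
    age <- stats::runif(n, config$age_range[1L], config$age_range[2L])
    data.frame(participant_id = sprintf("P%03d", seq_len(n)),
               age = age, sex = sex, sex_male = as.integer(sex == "male"),
               stringsAsFactors = FALSE)
  })
}

#' Generate true per-bolus parameter values
#'
#' Draws sip volumes (participant base + sex effect + two-level noise), then
#' every continuous parameter from its linear model with correlated two-level
#' Gaussian residuals (participant effect carrying 80 percent of the
#' participant-mean residual variance, bolus noise the rest), plus the
#' logistic multiple-swallow outcome, PAS scores and LVC integrity. Negative
#' draws of non-negative parameters are truncated at 0 (the truncation rate
#' is attached as an attribute); timing parameters are snapped onto the frame
#' grid so annotations can realize them exactly.
#'
#' @param participants Table from [generate_cohort()].
#' @param effects An [effect_config()].
#' @param config A [cohort_config()].
#' @param seed Integer random seed.
#' @return Bolus-level `data.frame`: identifiers, covariates, all parameters
#'   of [continuous_parameters()], `multiple_swallows`, `n_swallows`,
#'   `pas_initial`, `pas_max`, `lvc_integrity`, `spine_length_px`. Attribute
#'   `truncation_rate` gives the overall share of truncated draws.
#' @export
generate_parameters <- function(participants, effects = effect_config(),
                                config = cohort_config(), seed = 1L) {
  with_seed(seed, {
    tab <- effects$table
    pars <- tab$parameter
    np <- length(pars)
    n <- nrow(participants)
    nb <- config$boluses
    rows <- n * nb
    idx_p <- rep(seq_len(n), each = nb)

    # sip volume: female base + sex effect + participant + bolus noise
    sip_p <- (effects$sip_base - effects$sip_sex_effect / 2) +
      effects$sip_sex_effect * participants$sex_male +
      stats::rnorm(n, 0, effects$sip_sd_participant)
    sip <- pmax(1, sip_p[idx_p] + stats::rnorm(rows, 0, effects$sip_sd_bolus))

    age_c <- participants$age[idx_p] - effects$age_anchor
    male <- participants$sex_male[idx_p]
    mu <- matrix(rep(tab$intercept, each = rows), nrow = rows) +
      outer(age_c, tab$slope_age) +
      outer(male, tab$sex_effect) +
      outer(sip - effects$sip_base, tab$slope_sip)

    # two-level correlated residuals on the participant-mean scale sigma_pm:
    # Var(participant) = 0.8 sigma^2, Var(bolus) = 0.6 sigma^2, so that
    # Var(mean of 3 boluses) = 0.8 sigma^2 + 0.6 sigma^2 / 3 = sigma^2.
    U <- chol(effects$correlations)
    d_p <- sqrt(0.8) * tab$sigma_pm
    d_w <- sqrt(0.6 * nb / 3) * tab$sigma_pm
    zp <- matrix(stats::rnorm(n * np), n, np) %*% U
    zw <- matrix(stats::rnorm(rows * np), rows, np) %*% U
    eps <- sweep(zp, 2L, d_p, `*`)[idx_p, , drop = FALSE] +
      sweep(zw, 2L, d_w, `*`)
    val <- mu + eps
    colnames(val) <- pars

    nonneg <- pars != "swallow_reaction_time"
    n_trunc <- sum(val[, nonneg] < 0)
    trunc_rate <- n_trunc / (rows * sum(nonneg))
    val[, nonneg][val[, nonneg] < 0] <- 0

    out <- as.data.frame(val)
    # snap timing onto the frame grid (signed for swallow reaction time)
    for (tp in c("swallow_reaction_time", "hyb_to_ueso", "ueso_duration",
                 "time_to_lvc", "lvc_duration", "hyoid_burst_duration"))
      out[[tp]] <- vapply(out[[tp]], function(v)
        as.numeric(snap_ms_to_grid(v, fps = config$fps)$ms), numeric(1L))
    # the burst must last at least one frame for the speed to exist
    min_ms <- frames_to_ms(0L, 1L, fps = config$fps)
    out$hyoid_burst_duration <- pmax(out$hyoid_burst_duration, min_ms)
    # speed low enough that the implied pre-peak minimum stays positive
    cap <- (out$peak_xy_hyoid - 5) / (out$hyoid_burst_duration / 1000)
    out$hyoid_xy_speed <- pmax(1, pmin(out$hyoid_xy_speed, cap))
    out$residue_total <- out$residue_valleculae + out$residue_pyriform +
      out$residue_other

    eta <- effects$multiple_logit_intercept +
      effects$multiple_logit_slope * (sip - effects$sip_base)
    mult <- stats::runif(rows) < stats::plogis(eta)
    pas_i <- sample(1:3, rows, replace = TRUE, prob = c(0.93, 0.06, 0.01))
    pas_m <- pmin(8L, pas_i + stats::rbinom(rows, 1L, 0.05))
    lvc <- sample(c("complete", "partial"), rows, replace = TRUE,
                  prob = c(0.97, 0.03))
    spine <- pmax(60, stats::rnorm(n, config$spine_length_mean,
                                   config$spine_length_sd))

    res <- cbind(
      data.frame(participant_id = participants$participant_id[idx_p],
                 bolus_id = rep(seq_len(nb), times = n),
                 age = participants$age[idx_p],
                 sex = participants$sex[idx_p], sex_male = male,
                 sip_volume = sip, stringsAsFactors = FALSE),
      out,
      data.frame(multiple_swallows = mult, n_swallows = 1L + as.integer(mult),
                 pas_initial = as.integer(pas_i), pas_max = as.integer(pas_m),
                 lvc_integrity = lvc,
                 spine_length_px = spine[idx_p], stringsAsFactors = FALSE)
    )
    attr(res, "truncation_rate") <- trunc_rate
    res
  })
}

# Axis-aligned rectangle (in anatomical coordinates) with the given area,
# centered at `center`, aspect ratio height = 2 * width.
anat_rectangle <- function(area_scaled, center = c(10, 25)) {
  if (area_scaled <= 0) return(NULL)
  a <- 100 * area_scaled           # area in anatomical units^2
  w <- sqrt(a / 2); h <- 2 * w
  rbind(center + c(-w / 2, -h / 2), center + c(w / 2, -h / 2),
        center + c(w / 2, h / 2), center + c(-w / 2, h / 2))
}

#' Construct a raw annotation realizing a true parameter record
#'
#' Inverse of the measurement stage: builds event frames whose durations equal
#' the record's (grid-snapped) timings, a half-cosine radial hyoid trajectory
#' hitting the true peak and speed, a rectangle of the prescribed area for
#' each region and a segment of the prescribed length for the UES diameter,
#' all expressed in a randomly rotated and translated pixel frame with the
#' record's spine length. `summarize_bolus()` of the result reproduces the
#' record (timing exactly, geometry to floating-point precision).
#'
#' @param record One row of the table from [generate_parameters()].
#' @param config A [cohort_config()].
#' @param seed Integer seed for the pixel-frame pose.
#' @return A [bolus_annotation()] object.
#' @export
synthesize_annotations <- function(record, config = cohort_config(), seed = 1L) {
  fps <- config$fps
  k <- function(ms) {
    kk <- snap_ms_to_grid(ms, fps = fps)
    if (abs(kk$ms - ms) > 1e-6)
      stop("synthesis error: timing ", ms, " ms is not on the ", fps, " fps grid")
    kk$frames
  }
  k_srt <- k(record$swallow_reaction_time)
  k_hyb <- k(record$hyb_to_ueso)
  k_ueso <- k(record$ueso_duration)
  k_ttlvc <- k(record$time_to_lvc)
  k_lvc <- k(record$lvc_duration)
  k_burst <- k(record$hyoid_burst_duration)
  if (min(k_hyb, k_ueso, k_ttlvc, k_lvc) < 0 || k_burst < 1)
    stop("synthesis error: unrepresentable (negative) duration")

  onset <- 0L
  bolus_past <- -k_srt
  ues_open <- onset + k_hyb
  ues_close <- ues_open + k_ueso
  lvc_first <- onset + k_ttlvc
  lvc_off <- lvc_first + k_lvc
  peak_fr <- onset + k_burst
  rest <- max(ues_close, lvc_off, peak_fr) + 6L
  shift <- 12L + max(0L, -min(bolus_past, onset - 10L))
  ev <- event_frames(
    bolus_past_mandible = bolus_past + shift,
    hyoid_burst_onset = onset + shift,
    ues_open = ues_open + shift, ues_close = ues_close + shift,
    lvc_first_frame = lvc_first + shift, lvc_offset = lvc_off + shift,
    max_ues_opening = ues_open + (ues_close - ues_open) %/% 2L + shift,
    max_pharyngeal_constriction = (onset + ues_close) %/% 2L + shift,
    swallow_rest = rest + shift
  )

  burst_s <- record$hyoid_burst_duration / 1000
  r_peak <- record$peak_xy_hyoid
  r_min <- r_peak - record$hyoid_xy_speed * burst_s
  if (r_min < 0) stop("synthesis error: implied minimum hyoid position below 0")

  fr <- seq(onset - 10L, rest + 10L)
  r <- numeric(length(fr))
  asc <- fr >= onset & fr <= peak_fr
  r[fr < onset] <- r_min
  r[asc] <- r_min + (r_peak - r_min) / 2 * (1 - cos(pi * (fr[asc] - onset) / k_burst))
  desc <- fr > peak_fr
  span <- (rest + 10L) - peak_fr
  r[desc] <- r_min + (r_peak - r_min) / 2 * (1 + cos(pi * (fr[desc] - peak_fr) / span))

  with_seed(seed, {
    L <- record$spine_length_px
    theta <- stats::runif(1, 0, 2 * pi)
    c4 <- stats::runif(2, 300, 700)
    c2 <- c4 + L * c(sin(theta), -cos(theta))
    lm <- spine_landmarks(c2ai = c2, c4ai = c4)

    dirv <- c(0.6, 0.8)
    anat_pts <- cbind(r * dirv[1L], r * dirv[2L])
    track <- hyoid_track(fr[1L] + shift,
                         anatomical_untransform(lm, anat_pts))

    seg_a <- c(15, 30)
    seg <- rbind(seg_a, seg_a + c(record$ues_diameter, 0))
    poly_px <- function(p) if (is.null(p)) NULL else anatomical_untransform(lm, p)
    contours <- contour_set(
      pharynx_at_max_constriction = poly_px(anat_rectangle(record$pa_max_constriction, c(8, 40))),
      pharynx_at_rest = poly_px(anat_rectangle(record$pa_rest, c(6, 55))),
      residue_valleculae = poly_px(anat_rectangle(record$residue_valleculae, c(20, 80))),
      residue_pyriform = poly_px(anat_rectangle(record$residue_pyriform, c(18, 10))),
      residue_other = poly_px(anat_rectangle(record$residue_other, c(25, 45))),
      ues_diameter_segment = anatomical_untransform(lm, seg)
    )
    bolus_annotation(
      participant_id = record$participant_id, bolus_id = record$bolus_id,
      rater_id = "truth", fps = fps, sip_volume = record$sip_volume,
      n_swallows = record$n_swallows, pas_initial = record$pas_initial,
      pas_max = record$pas_max, lvc_integrity = record$lvc_integrity,
      events = ev, hyoid = track, contours = contours, landmarks = lm
    )
  })
}

jitter_poly <- function(p, sd) {
  if (is.null(p)) return(NULL)
  p + matrix(stats::rnorm(length(p), 0, sd), nrow = nrow(p))
}

#' Simulate one rater's noisy copy of an annotation
#'
#' Adds discretized normal jitter to the event frames (order-repairing
#' clamps keep the annotation valid), normal jitter to every pixel
#' coordinate, and rare PAS / LVC-integrity perturbations.
#'
#' @param annotation A [bolus_annotation()] (the ground truth).
#' @param config A [cohort_config()] providing the noise settings.
#' @param seed Integer seed; the copy is deterministic given it.
#' @param rater_id Identifier for the simulated rater.
#' @return A jittered [bolus_annotation()].
#' @export
simulate_rater <- function(annotation, config = cohort_config(), seed = 1L,
                           rater_id = "rater") {
  a <- annotation
  with_seed(seed, {
    ev <- unlist(a$events)
    jit <- as.integer(round(stats::rnorm(length(ev), 0, config$frame_jitter_sd)))
    ev <- pmax(0L, ev + jit)
    names(ev) <- event_names()
    # repair ordering invariants the jitter may have broken
    ev["ues_open"] <- max(ev["ues_open"], ev["hyoid_burst_onset"])
    ev["lvc_first_frame"] <- max(ev["lvc_first_frame"], ev["hyoid_burst_onset"])
    ev["ues_close"] <- max(ev["ues_close"], ev["ues_open"])
    ev["max_ues_opening"] <- min(max(ev["max_ues_opening"], ev["ues_open"]),
                                 ev["ues_close"])
    ev["lvc_offset"] <- max(ev["lvc_offset"], ev["lvc_first_frame"])
    ev["swallow_rest"] <- max(ev["swallow_rest"], ev["hyoid_burst_onset"])
    events <- do.call(event_frames, as.list(ev))

    sd_c <- config$coord_jitter_sd
    hy <- if (is.null(a$hyoid)) NULL else
      hyoid_track(a$hyoid$start_frame, jitter_poly(a$hyoid$positions, sd_c))
    ct <- a$contours
    contours <- contour_set(
      pharynx_at_max_constriction = jitter_poly(ct$pharynx_at_max_constriction, sd_c),
      pharynx_at_rest = jitter_poly(ct$pharynx_at_rest, sd_c),
      residue_valleculae = jitter_poly(ct$residue_valleculae, sd_c),
      residue_pyriform = jitter_poly(ct$residue_pyriform, sd_c),
      residue_other = jitter_poly(ct$residue_other, sd_c),
      ues_diameter_segment = if (is.null(ct$ues_diameter_segment)) NULL else
        jitter_poly(ct$ues_diameter_segment, sd_c)
    )
    lm <- spine_landmarks(a$landmarks$c2ai + stats::rnorm(2, 0, sd_c),
                          a$landmarks$c4ai + stats::rnorm(2, 0, sd_c))

    # one misreading event per rater: the worst-swallow score shifts by one
    # scale point; the initial-swallow score only follows if it would exceed it
    pas_i <- a$pas_initial
    pas_m <- a$pas_max
    if (stats::runif(1) < config$pas_flip_prob) {
      pas_m <- if (pas_m >= 8L) pas_m - 1L else pas_m + 1L
      pas_i <- min(pas_i, pas_m)
    }
    lvc <- a$lvc_integrity
    if (stats::runif(1) < config$lvc_flip_prob)
      lvc <- if (lvc == "complete") "partial" else "complete"

    bolus_annotation(
      participant_id = a$participant_id, bolus_id = a$bolus_id,
      rater_id = rater_id, fps = a$fps, sip_volume = a$sip_volume,
      n_swallows = a$n_swallows, pas_initial = pas_i, pas_max = pas_m,
      lvc_integrity = lvc, events = events, hyoid = hy, contours = contours,
      landmarks = lm, anterior = a$anterior
    )
  })
}

#' Simulate a complete dual-rated study
#'
#' Convenience wrapper: cohort, true parameter table, ground-truth
#' annotations, and two noisy rater copies per bolus.
#'
#' @param config A [cohort_config()].
#' @param effects An [effect_config()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return List with `participants`, `truth` (true parameter table),
#'   `annotations` (ground truth), `rater_a`, `rater_b`, and `seed`.
#' @export
simulate_study <- function(config = cohort_config(), effects = effect_config(),
                           seed = 1L) {
  participants <- generate_cohort(config, seed = seed)
  truth <- generate_parameters(participants, effects, config, seed = seed + 1L)
  annotations <- lapply(seq_len(nrow(truth)), function(i)
    synthesize_annotations(truth[i, ], config, seed = seed * 7L + i))
  rater_a <- lapply(seq_along(annotations), function(i)
    simulate_rater(annotations[[i]], config, seed = seed * 11L + i, rater_id = "A"))
  rater_b <- lapply(seq_along(annotations), function(i)
    simulate_rater(annotations[[i]], config, seed = seed * 13L + i, rater_id = "B"))
  list(participants = participants, truth = truth, annotations = annotations,
       rater_a = rater_a, rater_b = rater_b, seed = seed)
}
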