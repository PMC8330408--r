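# Derivation of the per-bolus swallowing parameters from a (consensus)
# annotation: frame-based timing, anatomically scaled hyoid kinematics and
# pixel-geometry measures.

#' Names of the continuous derived parameters
#' @return Character vector of the continuous parameter names in canonical
#'   order (timing in ms, positions/speeds/lengths in %(C2-4), areas in
#'   %(C2-4) squared).
#' @export
continuous_parameters <- function() {
  c("sip_volume", "swallow_reaction_time", "hyb_to_ueso", "ueso_duration",
    "time_to_lvc", "lvc_duration", "hyoid_burst_duration",
    "peak_xy_hyoid", "hyoid_xy_speed", "ues_diameter",
    "pa_max_constriction", "pa_rest",
    "residue_valleculae", "residue_pyriform", "residue_other", "residue_total")
}

#' Timing parameters from event frames
#'
#' Computes the five interval parameters plus the auxiliary hyoid burst
#' duration. Swallow reaction time is signed: a hyoid burst preceding the
#' bolus past the mandibular ramus yields a negative value. Missing events
#' yield `NA` for the parameters that depend on them.
#'
#' @param events An [event_frames()] object.
#' @param hyoid A [hyoid_track()] object (needed only for the burst duration,
#'   whose end is the frame of peak hyoid position) or `NULL`.
#' @param fps Frames per second.
#' @param landmarks,anterior Passed to the anatomical transform for locating
#'   the peak-position frame.
#' @return Named list of signed/unsigned integer millisecond durations:
#'   `swallow_reaction_time`, `hyb_to_ueso`, `ueso_duration`, `time_to_lvc`,
#'   `lvc_duration`, `hyoid_burst_duration`.
#' @export
compute_timing <- function(events, hyoid = NULL, fps = 30, landmarks = NULL,
                           anterior = "left") {
  ev <- events
  dur <- function(a, b) {
    if (is.na(ev[[a]]) || is.na(ev[[b]])) return(NA_integer_)
    frames_to_ms(ev[[a]], ev[[b]], fps = fps, .events = c(a, b))
  }
  out <- list(
    swallow_reaction_time =
      if (is.na(ev$bolus_past_mandible) || is.na(ev$hyoid_burst_onset)) NA_integer_
      else signed_frames_to_ms(ev$bolus_past_mandible, ev$hyoid_burst_onset, fps = fps),
    hyb_to_ueso  = dur("hyoid_burst_onset", "ues_open"),
    ueso_duration = dur("ues_open", "ues_close"),
    time_to_lvc  = dur("hyoid_burst_onset", "lvc_first_frame"),
    lvc_duration = dur("lvc_first_frame", "lvc_offset")
  )
  out$hyoid_burst_duration <- NA_integer_
  if (!is.null(hyoid) && !is.null(landmarks) &&
      !is.na(ev$hyoid_burst_onset) && !is.na(ev$swallow_rest)) {
    pk <- hyoid_peak_frame(hyoid, landmarks, ev, anterior = anterior)
    if (!is.na(pk))
      out$hyoid_burst_duration <- frames_to_ms(ev$hyoid_burst_onset, pk, fps = fps,
                                               .events = c("hyoid_burst_onset", "peak_hyoid"))
  }
  out
}

# Radial (XY) hyoid positions in %(C2-4) for the frames of the track.
hyoid_radial <- function(hyoid, landmarks, anterior = "left") {
  q <- anatomical_transform(landmarks, hyoid$positions, anterior = anterior)
  sqrt(rowSums(q^2))
}

# Frame index of peak radial hyoid position within [burst onset, swallow rest].
hyoid_peak_frame <- function(hyoid, landmarks, events, anterior = "left") {
  fr <- track_frames(hyoid)
  keep <- fr >= events$hyoid_burst_onset & fr <= events$swallow_rest
  if (!any(keep)) return(NA_integer_)
  r <- hyoid_radial(hyoid, landmarks, anterior)[keep]
  fr[keep][which.max(r)]
}

#' Hyoid kinematic parameters
#'
#' Peak XY hyoid position: maximum radial distance of the hyoid from the
#' anatomical origin (anterior-inferior C4) over the analysis window from
#' hyoid burst onset to swallow rest, in %(C2-4). Hyoid XY speed: change from
#' the minimum position (within the burst, i.e. between onset and the peak
#' frame) to the peak, divided by the hyoid burst duration, in %(C2-4)/s.
#'
#' @inheritParams compute_timing
#' @param hyoid A [hyoid_track()] covering the analysis window.
#' @param landmarks A [spine_landmarks()] object.
#' @return List with `peak_xy_hyoid`, `hyoid_xy_speed` and the auxiliary
#'   `hyoid_burst_duration` (ms). A zero-frame burst gives `NA` speed with a
#'   warning.
#' @export
compute_hyoid_kinematics <- function(hyoid, landmarks, events, fps = 30,
                                     anterior = "left") {
  na <- list(peak_xy_hyoid = NA_real_, hyoid_xy_speed = NA_real_,
             hyoid_burst_duration = NA_integer_)
  if (is.null(hyoid) || is.na(events$hyoid_burst_onset) || is.na(events$swallow_rest))
    return(na)
  fr <- track_frames(hyoid)
  keep <- fr >= events$hyoid_burst_onset & fr <= events$swallow_rest
  if (!any(keep)) return(na)
  r <- hyoid_radial(hyoid, landmarks, anterior)
  rw <- r[keep]; frw <- fr[keep]
  i_pk <- which.max(rw)
  peak <- rw[i_pk]
  pk_frame <- frw[i_pk]
  burst_ms <- frames_to_ms(events$hyoid_burst_onset, pk_frame, fps = fps)
  r_min <- min(rw[frw <= pk_frame])
  if (burst_ms == 0L) {
    warning("hyoid burst duration of 0 frames: speed undefined")
    speed <- NA_real_
  } else {
    speed <- (peak - r_min) / (burst_ms / 1000)
  }
  list(peak_xy_hyoid = peak, hyoid_xy_speed = speed,
       hyoid_burst_duration = burst_ms)
}

#' Anatomically scaled pixel-geometry parameters
#'
#' Lengths are scaled by the C2-C4 spine length `L` (100 * px / L, %(C2-4));
#' areas by its square (100 * px^2 / L^2, %(C2-4)^2). Empty polygons
#' contribute area 0.
#'
#' @param contours A [contour_set()] object.
#' @param landmarks A [spine_landmarks()] object.
#' @return List with `ues_diameter`, `pa_max_constriction`, `pa_rest`,
#'   `residue_valleculae`, `residue_pyriform`, `residue_other`,
#'   `residue_total`.
#' @export
compute_scaled_geometry <- function(contours, landmarks) {
  L <- spine_length(landmarks)
  if (L <= 0) stop("geometry error: degenerate spine landmarks")
  seg <- contours$ues_diameter_segment
  ues <- if (is.null(seg)) NA_real_ else 100 * sqrt(sum((seg[1L, ] - seg[2L, ])^2)) / L
  area <- function(poly) 100 * polygon_area(poly) / L^2
  rv <- area(contours$residue_valleculae)
  rp <- area(contours$residue_pyriform)
  ro <- area(contours$residue_other)
  list(ues_diameter = ues,
       pa_max_constriction = area(contours$pharynx_at_max_constriction),
       pa_rest = area(contours$pharynx_at_rest),
       residue_valleculae = rv, residue_pyriform = rp, residue_other = ro,
       residue_total = rv + rp + ro)
}

#' Derive the full parameter record for one bolus
#'
#' Assembles all derived swallowing parameters from a consensus annotation:
#' scalar scores copied through, timing from the event frames, kinematics
#' from the hyoid track, scaled geometry from the contours. Missing inputs
#' propagate as `NA`; nothing is imputed.
#'
#' @param annotation A [bolus_annotation()] object.
#' @return One-row `data.frame` (a parameter record) with identifiers,
#'   `multiple_swallows`, the categorical scores, and all continuous
#'   parameters of [continuous_parameters()].
#' @export
summarize_bolus <- function(annotation) {
  a <- annotation
  tm <- compute_timing(a$events, a$hyoid, fps = a$fps, landmarks = a$landmarks,
                       anterior = a$anterior)
  kin <- compute_hyoid_kinematics(a$hyoid, a$landmarks, a$events, fps = a$fps,
                                  anterior = a$anterior)
  geo <- compute_scaled_geometry(a$contours, a$landmarks)
  data.frame(
    participant_id = a$participant_id, bolus_id = a$bolus_id,
    rater_id = a$rater_id,
    sip_volume = a$sip_volume, n_swallows = a$n_swallows,
    multiple_swallows = a$n_swallows > 1L,
    pas_initial = a$pas_initial, pas_max = a$pas_max,
    lvc_integrity = a$lvc_integrity,
    swallow_reaction_time = tm$swallow_reaction_time,
    hyb_to_ueso = tm$hyb_to_ueso,
    ueso_duration = tm$ueso_duration,
    time_to_lvc = tm$time_to_lvc,
    lvc_duration = tm$lvc_duration,
    hyoid_burst_duration = kin$hyoid_burst_duration,
    peak_xy_hyoid = kin$peak_xy_hyoid,
    hyoid_xy_speed = kin$hyoid_xy_speed,
    ues_diameter = geo$ues_diameter,
    pa_max_constriction = geo$pa_max_constriction,
    pa_rest = geo$pa_rest,
    residue_valleculae = geo$residue_valleculae,
    residue_pyriform = geo$residue_pyriform,
    residue_other = geo$residue_other,
    residue_total = geo$residue_total,
    stringsAsFactors = FALSE
  )
}

#' Measure a list of bolus annotations
#'
#' @param annotations List of [bolus_annotation()] objects.
#' @return `data.frame` of parameter records, one row per bolus.
#' @export
measure_boluses <- function(annotations) {
  if (length(annotations) == 0L)
    stop("measure stage error: no annotations supplied")
  do.call(rbind, lapply(annotations, summarize_bolus))
}
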