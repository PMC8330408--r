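# Domain containers for one rater's annotation of one bolus. Plain lists with
# light S3 classes and strict constructors; measurement code assumes these
# invariants and does not re-check them.

#' Names of the annotated swallow events
#' @return Character vector of the nine event names, in canonical order.
#' @export
event_names <- function() {
  c("bolus_past_mandible", "hyoid_burst_onset", "ues_open", "ues_close",
    "lvc_first_frame", "lvc_offset", "max_ues_opening",
    "max_pharyngeal_constriction", "swallow_rest")
}

#' Key swallow event frames
#'
#' Frame indices (0-based) of the annotated swallow events. `NA` marks an
#' event the rater could not identify; downstream parameters depending on it
#' become missing rather than erroring.
#'
#' @param bolus_past_mandible,hyoid_burst_onset,ues_open,ues_close Frame
#'   indices.
#' @param lvc_first_frame First frame of most-complete laryngeal vestibule
#'   closure.
#' @param lvc_offset,max_ues_opening,max_pharyngeal_constriction,swallow_rest
#'   Frame indices.
#' @return Object of class `event_frames`.
#' @export
event_frames <- function(bolus_past_mandible = NA, hyoid_burst_onset = NA,
                         ues_open = NA, ues_close = NA, lvc_first_frame = NA,
                         lvc_offset = NA, max_ues_opening = NA,
                         max_pharyngeal_constriction = NA, swallow_rest = NA) {
  ev <- list(bolus_past_mandible = bolus_past_mandible,
             hyoid_burst_onset = hyoid_burst_onset,
             ues_open = ues_open, ues_close = ues_close,
             lvc_first_frame = lvc_first_frame, lvc_offset = lvc_offset,
             max_ues_opening = max_ues_opening,
             max_pharyngeal_constriction = max_pharyngeal_constriction,
             swallow_rest = swallow_rest)
  ev <- lapply(ev, function(f) if (is.na(f)) NA_integer_ else as.integer(f))
  chk <- function(cond, msg) if (isFALSE(cond)) stop("event frame invariant violated: ", msg)
  for (nm in names(ev))
    if (!is.na(ev[[nm]]) && ev[[nm]] < 0L) stop("event frame invariant violated: ", nm, " < 0")
  both <- function(a, b) !is.na(ev[[a]]) && !is.na(ev[[b]])
  if (both("ues_open", "max_ues_opening"))
    chk(ev$ues_open <= ev$max_ues_opening, "ues_open > max_ues_opening")
  if (both("max_ues_opening", "ues_close"))
    chk(ev$max_ues_opening <= ev$ues_close, "max_ues_opening > ues_close")
  if (both("ues_open", "ues_close"))
    chk(ev$ues_open <= ev$ues_close, "ues_open > ues_close")
  if (both("lvc_first_frame", "lvc_offset"))
    chk(ev$lvc_first_frame <= ev$lvc_offset, "lvc_first_frame > lvc_offset")
  if (both("hyoid_burst_onset", "swallow_rest"))
    chk(ev$hyoid_burst_onset <= ev$swallow_rest, "hyoid_burst_onset > swallow_rest")
  structure(ev, class = "event_frames")
}

#' Frame-by-frame hyoid track
#'
#' Per-frame pixel positions of the hyoid body, conventionally starting 10
#' frames before hyoid burst onset and ending 10 frames after swallow rest.
#'
#' @param start_frame Frame index of the first tracked position.
#' @param positions n-by-2 matrix of pixel points, one row per frame.
#' @return Object of class `hyoid_track`, or `NULL` if `positions` is empty
#'   (missing-track marker).
#' @export
hyoid_track <- function(start_frame, positions) {
  if (is.null(positions) || NROW(positions) == 0L) return(NULL)
  pos <- as.matrix(positions)
  stopifnot(ncol(pos) == 2L, all(is.finite(pos)), start_frame >= 0)
  colnames(pos) <- c("x", "y")
  structure(list(start_frame = as.integer(start_frame), positions = pos),
            class = "hyoid_track")
}

track_frames <- function(track) {
  track$start_frame + seq_len(nrow(track$positions)) - 1L
}

as_polygon <- function(p) {
  if (is.null(p) || length(p) == 0L) return(NULL)
  m <- as.matrix(p)
  if (!all(is.finite(m))) stop("input error: non-finite polygon coordinates")
  if (nrow(m) < 3L) return(NULL)  # degenerate: treated as empty (area 0)
  colnames(m) <- c("x", "y")
  m
}

#' Pixel contours measured on key frames
#'
#' @param pharynx_at_max_constriction,pharynx_at_rest Polygons (n-by-2 pixel
#'   vertex matrices) of the unobliterated pharyngeal lumen.
#' @param residue_valleculae,residue_pyriform,residue_other Residue polygons;
#'   `NULL` or < 3 vertices means no residue (area 0).
#' @param ues_diameter_segment 2-by-2 matrix: the two endpoints of the maximum
#'   UES opening diameter.
#' @return Object of class `contour_set`.
#' @export
contour_set <- function(pharynx_at_max_constriction = NULL, pharynx_at_rest = NULL,
                        residue_valleculae = NULL, residue_pyriform = NULL,
                        residue_other = NULL, ues_diameter_segment = NULL) {
  if (!is.null(ues_diameter_segment)) {
    ues_diameter_segment <- as.matrix(ues_diameter_segment)
    stopifnot(nrow(ues_diameter_segment) == 2L, ncol(ues_diameter_segment) == 2L,
              all(is.finite(ues_diameter_segment)))
  }
  structure(list(
    pharynx_at_max_constriction = as_polygon(pharynx_at_max_constriction),
    pharynx_at_rest = as_polygon(pharynx_at_rest),
    residue_valleculae = as_polygon(residue_valleculae),
    residue_pyriform = as_polygon(residue_pyriform),
    residue_other = as_polygon(residue_other),
    ues_diameter_segment = ues_diameter_segment
  ), class = "contour_set")
}

#' One rater's complete annotation of one bolus
#'
#' @param participant_id,bolus_id,rater_id Identifiers.
#' @param fps Recording frame rate (default 30).
#' @param sip_volume Sip volume in ml (> 0).
#' @param n_swallows Number of swallows observed for the bolus (>= 1).
#' @param pas_initial,pas_max Penetration-Aspiration Scale scores (1-8) for
#'   the initial swallow and the worst across the bolus' swallows;
#'   `pas_max >= pas_initial`.
#' @param lvc_integrity `"complete"`, `"partial"` or `"incomplete"`.
#' @param events An [event_frames()] object.
#' @param hyoid A [hyoid_track()] object or `NULL` (missing track).
#' @param contours A [contour_set()] object.
#' @param landmarks A [spine_landmarks()] object.
#' @param anterior Image orientation flag passed to the anatomical transform.
#' @return Object of class `bolus_annotation`.
#' @export
bolus_annotation <- function(participant_id, bolus_id, rater_id = "consensus",
                             fps = 30, sip_volume, n_swallows = 1L,
                             pas_initial = 1L, pas_max = pas_initial,
                             lvc_integrity = c("complete", "partial", "incomplete"),
                             events, hyoid = NULL, contours = contour_set(),
                             landmarks, anterior = "left") {
  lvc_integrity <- match.arg(lvc_integrity)
  stopifnot(inherits(events, "event_frames"), inherits(contours, "contour_set"),
            inherits(landmarks, "spine_landmarks"))
  if (!is.null(hyoid)) stopifnot(inherits(hyoid, "hyoid_track"))
  if (!is.numeric(fps) || fps <= 0) stop("invariant violated: fps must be > 0")
  if (!is.numeric(sip_volume) || sip_volume <= 0)
    stop("invariant violated: sip_volume must be > 0")
  n_swallows <- as.integer(n_swallows)
  if (n_swallows < 1L) stop("invariant violated: n_swallows must be >= 1")
  pas_initial <- as.integer(pas_initial); pas_max <- as.integer(pas_max)
  if (pas_initial < 1L || pas_initial > 8L || pas_max < 1L || pas_max > 8L)
    stop("invariant violated: PAS scores must lie in 1..8")
  if (pas_max < pas_initial) stop("invariant violated: pas_max < pas_initial")
  structure(list(participant_id = participant_id, bolus_id = bolus_id,
                 rater_id = rater_id, fps = fps, sip_volume = sip_volume,
                 n_swallows = n_swallows, pas_initial = pas_initial,
                 pas_max = pas_max, lvc_integrity = lvc_integrity,
                 events = events, hyoid = hyoid, contours = contours,
                 landmarks = landmarks, anterior = anterior),
            class = "bolus_annotation")
}

#' @export
print.bolus_annotation <- function(x, ...) {
  cat("<bolus_annotation> participant", x$participant_id, "bolus", x$bolus_id,
      "rater", x$rater_id, "\n")
  cat("  sip", x$sip_volume, "ml,", x$n_swallows, "swallow(s), PAS",
      x$pas_initial, "/", x$pas_max, ", LVC", x$lvc_integrity, "\n")
  ev <- unlist(x$events)
  cat("  events:", paste(names(ev), ev, sep = "=", collapse = " "), "\n")
  cat("  hyoid track:", if (is.null(x$hyoid)) "missing" else
      paste(nrow(x$hyoid$positions), "frames from", x$hyoid$start_frame), "\n")
  invisible(x)
}
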