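# Shared fixtures: a hand-built annotation with known parameter values, and a
# similarity-transform applier for the anatomical-invariance properties.

# Annotation with simple, hand-checkable values: vertical spine of length 100
# px, axis-aligned rectangles, a triangular radial hyoid trajectory.
make_fixture_annotation <- function(fps = 30) {
  lm <- spine_landmarks(c2ai = c(500, 300), c4ai = c(500, 400))  # L = 100 px
  ev <- event_frames(
    bolus_past_mandible = 20, hyoid_burst_onset = 26,  # SRT = 6 fr = 200 ms
    ues_open = 29, ues_close = 44,                     # HYB 3 fr, UESO 15 fr
    lvc_first_frame = 30, lvc_offset = 46,             # ttLVC 4 fr, LVC 16 fr
    max_ues_opening = 36, max_pharyngeal_constriction = 35,
    swallow_rest = 56
  )
  # radial positions: flat 120 before onset, ramp to 176 at frame 41 (peak,
  # 15 frames after onset = 500 ms), back down afterwards
  fr <- seq(16, 66)
  r <- ifelse(fr < 26, 120,
              ifelse(fr <= 41, 120 + 56 * (fr - 26) / 15,
                     pmax(120, 176 - 10 * (fr - 41))))
  dirv <- c(0.6, 0.8)
  track <- hyoid_track(16, anatomical_untransform(lm, cbind(r * dirv[1], r * dirv[2])))
  rect <- function(w, h, cx, cy) {
    px <- rbind(c(cx - w/2, cy - h/2), c(cx + w/2, cy - h/2),
                c(cx + w/2, cy + h/2), c(cx - w/2, cy + h/2))
    px
  }
  # pixel geometry against L = 100: areas in px^2 map to %(C2-4)^2 / 100
  contours <- contour_set(
    pharynx_at_max_constriction = rect(20, 10, 520, 350),  # 200 px^2 -> 2
    pharynx_at_rest = rect(90, 70, 520, 350),              # 6300 px^2 -> 63
    residue_valleculae = rect(10, 10, 540, 330),           # 100 px^2 -> 1
    residue_pyriform = NULL,
    residue_other = NULL,
    ues_diameter_segment = rbind(c(480, 380), c(503, 380)) # 23 px -> 23
  )
  bolus_annotation(
    participant_id = "P001", bolus_id = 1, rater_id = "consensus", fps = fps,
    sip_volume = 14, n_swallows = 1, pas_initial = 1, pas_max = 1,
    lvc_integrity = "complete", events = ev, hyoid = track,
    contours = contours, landmarks = lm
  )
}

# Apply a similarity transform (rotation by theta, uniform scale s,
# translation t, optional y-axis flip) to every pixel coordinate of an
# annotation, landmarks included.
apply_similarity <- function(annotation, theta = 0, s = 1, t = c(0, 0),
                             flip_y = FALSE) {
  R <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  f <- function(p) {
    if (is.null(p)) return(NULL)
    one <- is.null(dim(p))
    m <- if (one) matrix(p, ncol = 2) else as.matrix(p)
    if (flip_y) m[, 2] <- -m[, 2]
    out <- sweep(s * m %*% t(R), 2, t, `+`)
    if (one) c(out) else out
  }
  a <- annotation
  a$landmarks <- spine_landmarks(f(a$landmarks$c2ai), f(a$landmarks$c4ai))
  if (!is.null(a$hyoid)) a$hyoid$positions <- f(a$hyoid$positions)
  ct <- a$contours
  a$contours <- contour_set(
    pharynx_at_max_constriction = f(ct$pharynx_at_max_constriction),
    pharynx_at_rest = f(ct$pharynx_at_rest),
    residue_valleculae = f(ct$residue_valleculae),
    residue_pyriform = f(ct$residue_pyriform),
    residue_other = f(ct$residue_other),
    ues_diameter_segment = f(ct$ues_diameter_segment)
  )
  a
}

# Continuous parameters compared in round-trip checks.
roundtrip_parameters <- function() continuous_parameters()
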