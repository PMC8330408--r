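# Pre-consensus inter-rater agreement statistics, threshold-based discrepancy
# flagging, and consensus merging for dual-rated bolus annotations.

#' Percent absolute agreement
#'
#' Share of paired ratings agreeing within a tolerance: exact match for
#' categorical items (tolerance 0), absolute difference within tolerance for
#' continuous items.
#'
#' @param a,b Equal-length paired rating vectors (numeric, character or
#'   factor).
#' @param tolerance Non-negative tolerance in the items' native units; 0
#'   (default) means exact agreement.
#' @return Percentage in [0, 100].
#' @export
percent_agreement <- function(a, b, tolerance = 0) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) == 0L) stop("undefined statistic: empty input")
  stopifnot(tolerance >= 0)
  ok <- if (is.numeric(a) && is.numeric(b)) abs(a - b) <= tolerance
        else as.character(a) == as.character(b)
  100 * mean(ok)
}

#' Mean absolute difference between paired ratings
#' @param a,b Equal-length paired numeric vectors.
#' @return Mean of `|a - b|`, in the items' native units.
#' @export
mean_absolute_difference <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) == 0L) stop("undefined statistic: empty input")
  mean(abs(a - b))
}

#' Intraclass correlation, two-way random, absolute agreement, single measure
#'
#' ICC(2,1): both items and raters are treated as random samples, and rater
#' mean differences count against agreement. Computed from the two-way ANOVA
#' mean squares (rows = items, columns = raters):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2 raters.
#'
#' @param a,b Paired numeric rating vectors, one element per item, `n >= 3`.
#' @return ICC in [-1, 1]; `NA` with a warning when total variance is zero.
#' @export
icc <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L) stop("icc requires at least 3 complete pairs")
  k <- 2L
  y <- cbind(a, b)
  gm <- mean(y)
  if (all(y == y[1L])) {
    warning("degenerate input: zero total variance, ICC undefined")
    return(NA_real_)
  }
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ss_row <- k * sum((row_m - gm)^2)
  ss_col <- n * sum((col_m - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Default inter-rater discrepancy thresholds
#'
#' Agreement bounds used for discrepancy flagging: event frames within 3
#' frames, UES diameter within 4 %(C2-4), pharyngeal areas within
#' 10 %(C2-4)^2, residue within 1 %(C2-4)^2, and exact match for PAS scores,
#' LVC integrity and swallow count. All configurable.
#'
#' @return Named list mapping item names to thresholds (0 = exact match).
#' @export
default_thresholds <- function() {
  thr <- as.list(c(
    stats::setNames(rep(3, length(event_names())), event_names()),
    ues_diameter = 4,
    pa_max_constriction = 10, pa_rest = 10,
    residue_valleculae = 1, residue_pyriform = 1, residue_other = 1,
    residue_total = 1,
    pas_initial = 0, pas_max = 0, lvc_integrity = 0, n_swallows = 0
  ))
  thr
}

# Extract the comparable item values from one annotation: event frames,
# scalar scores, and the derived geometry measures.
comparable_items <- function(annotation) {
  geo <- compute_scaled_geometry(annotation$contours, annotation$landmarks)
  c(lapply(annotation$events, identity),
    list(pas_initial = annotation$pas_initial, pas_max = annotation$pas_max,
         lvc_integrity = annotation$lvc_integrity,
         n_swallows = annotation$n_swallows),
    geo)
}

#' Flag inter-rater discrepancies exceeding thresholds
#'
#' Compares the two raters' event frames, categorical scores and derived
#' geometry measures item by item; a flag is raised whenever the absolute
#' difference exceeds the item's threshold (continuous) or the values differ
#' (categorical).
#'
#' @param a,b Two [bolus_annotation()] objects for the same bolus.
#' @param thresholds Named threshold list as in [default_thresholds()]; every
#'   compared item must have a threshold.
#' @return `data.frame` of flags (possibly 0 rows) ordered by
#'   (participant, bolus, item): columns `participant_id`, `bolus_id`,
#'   `item`, `value_a`, `value_b`, `abs_diff`, `threshold`.
#' @export
flag_discrepancies <- function(a, b, thresholds = default_thresholds()) {
  stopifnot(a$participant_id == b$participant_id, a$bolus_id == b$bolus_id,
            a$fps == b$fps)
  ia <- comparable_items(a); ib <- comparable_items(b)
  items <- names(ia)
  missing_thr <- setdiff(items, names(thresholds))
  if (length(missing_thr))
    stop("configuration error: no threshold for item(s) ",
         paste(missing_thr, collapse = ", "))
  rows <- lapply(items, function(it) {
    va <- ia[[it]]; vb <- ib[[it]]
    if (is.na(va) || is.na(vb)) return(NULL)
    thr <- thresholds[[it]]
    if (is.numeric(va)) {
      d <- abs(va - vb)
      if (d <= thr) return(NULL)
      data.frame(participant_id = a$participant_id, bolus_id = a$bolus_id,
                 item = it, value_a = as.character(va), value_b = as.character(vb),
                 abs_diff = d, threshold = thr, stringsAsFactors = FALSE)
    } else {
      if (va == vb) return(NULL)
      data.frame(participant_id = a$participant_id, bolus_id = a$bolus_id,
                 item = it, value_a = as.character(va), value_b = as.character(vb),
                 abs_diff = NA_real_, threshold = thr, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(participant_id = character(), bolus_id = character(),
                      item = character(), value_a = character(),
                      value_b = character(), abs_diff = numeric(),
                      threshold = numeric(), stringsAsFactors = FALSE)
  out[order(out$participant_id, out$bolus_id, out$item), , drop = FALSE]
}

# Rounded mean of two frame numbers, round-half-to-even (base round()).
merge_frames <- function(fa, fb) {
  if (is.na(fa) || is.na(fb)) return(if (is.na(fa)) fb else fa)
  as.integer(round((fa + fb) / 2))
}

merge_tracks <- function(ta, tb) {
  if (is.null(ta)) return(tb)
  if (is.null(tb)) return(ta)
  fa <- track_frames(ta); fb <- track_frames(tb)
  all_fr <- seq(min(fa[1L], fb[1L]), max(fa[length(fa)], fb[length(fb)]))
  pos <- matrix(NA_real_, nrow = length(all_fr), ncol = 2L)
  ma <- match(all_fr, fa); mb <- match(all_fr, fb)
  for (i in seq_along(all_fr)) {
    pa <- if (!is.na(ma[i])) ta$positions[ma[i], ] else NULL
    pb <- if (!is.na(mb[i])) tb$positions[mb[i], ] else NULL
    pos[i, ] <- if (!is.null(pa) && !is.null(pb)) (pa + pb) / 2
                else if (!is.null(pa)) pa else pb
  }
  hyoid_track(all_fr[1L], pos)
}

merge_polygons <- function(pa, pb) {
  if (is.null(pa)) return(pb)
  if (is.null(pb)) return(pa)
  if (nrow(pa) == nrow(pb)) (pa + pb) / 2 else pa
}

#' Merge a rating pair into a consensus annotation
#'
#' Flagged items must carry a resolution: a frame/score value for events and
#' categorical items, or `"a"`/`"b"` for derived geometry items (selecting
#' that rater's contours). Unflagged items merge automatically: rounded mean
#' (round-half-to-even) for frames, rater A's value for categorical items,
#' coordinate-wise means for pixel geometry.
#'
#' @inheritParams flag_discrepancies
#' @param resolutions Named list, one entry per flagged item.
#' @return A consensus [bolus_annotation()] (rater id `"consensus"`).
#' @export
consensus_merge <- function(a, b, resolutions = list(),
                            thresholds = default_thresholds()) {
  flags <- flag_discrepancies(a, b, thresholds)
  pending <- setdiff(flags$item, names(resolutions))
  if (length(pending))
    stop("incomplete consensus: unresolved flagged item(s) ",
         paste(pending, collapse = ", "))
  geom_items <- c("ues_diameter", "pa_max_constriction", "pa_rest",
                  "residue_valleculae", "residue_pyriform", "residue_other",
                  "residue_total")
  ev <- stats::setNames(vector("list", length(event_names())), event_names())
  for (nm in event_names()) {
    ev[[nm]] <- if (nm %in% flags$item) as.integer(resolutions[[nm]])
                else merge_frames(a$events[[nm]], b$events[[nm]])
  }
  pick <- function(item, auto) {
    if (item %in% flags$item) resolutions[[item]] else auto
  }
  pas_i <- as.integer(pick("pas_initial", a$pas_initial))
  pas_m <- as.integer(pick("pas_max", a$pas_max))
  # which rater's contours to use where geometry was flagged
  geom_flagged <- intersect(flags$item, geom_items)
  use_b <- length(geom_flagged) > 0L &&
    all(vapply(geom_flagged, function(it) identical(resolutions[[it]], "b"), logical(1L)))
  contours <- if (length(geom_flagged) == 0L) {
    contour_set(
      pharynx_at_max_constriction = merge_polygons(a$contours$pharynx_at_max_constriction,
                                                   b$contours$pharynx_at_max_constriction),
      pharynx_at_rest = merge_polygons(a$contours$pharynx_at_rest, b$contours$pharynx_at_rest),
      residue_valleculae = merge_polygons(a$contours$residue_valleculae,
                                          b$contours$residue_valleculae),
      residue_pyriform = merge_polygons(a$contours$residue_pyriform,
                                        b$contours$residue_pyriform),
      residue_other = merge_polygons(a$contours$residue_other, b$contours$residue_other),
      ues_diameter_segment = {
        sa <- a$contours$ues_diameter_segment; sb <- b$contours$ues_diameter_segment
        if (is.null(sa)) sb else if (is.null(sb)) sa else (sa + sb) / 2
      })
  } else if (use_b) b$contours else a$contours
  lm_c <- spine_landmarks((a$landmarks$c2ai + b$landmarks$c2ai) / 2,
                          (a$landmarks$c4ai + b$landmarks$c4ai) / 2)
  bolus_annotation(
    participant_id = a$participant_id, bolus_id = a$bolus_id,
    rater_id = "consensus", fps = a$fps,
    sip_volume = a$sip_volume,
    n_swallows = as.integer(pick("n_swallows", a$n_swallows)),
    pas_initial = pas_i, pas_max = max(pas_m, pas_i),
    lvc_integrity = as.character(pick("lvc_integrity", a$lvc_integrity)),
    events = do.call(event_frames, ev),
    hyoid = merge_tracks(a$hyoid, b$hyoid),
    contours = contours,
    landmarks = lm_c,
    anterior = a$anterior
  )
}

#' Pre-consensus agreement report across rating pairs
#'
#' For every compared item across all pairs: percent absolute agreement at the
#' item's flagging threshold (0 for categorical), mean absolute difference
#' (continuous items), ICC(2,1) (continuous items), number of pairs and
#' number of flags.
#'
#' @param pairs_a,pairs_b Lists of [bolus_annotation()] objects; element i of
#'   each list is the same bolus rated by rater A and rater B.
#' @param thresholds Named threshold list as in [default_thresholds()].
#' @return `data.frame` with one row per item: `item`, `kind`, `n_pairs`,
#'   `tolerance`, `pct_agreement`, `mean_abs_diff`, `icc`, `n_flagged`.
#' @export
agreement_report <- function(pairs_a, pairs_b, thresholds = default_thresholds()) {
  stopifnot(length(pairs_a) == length(pairs_b), length(pairs_a) > 0L)
  ia <- lapply(pairs_a, comparable_items)
  ib <- lapply(pairs_b, comparable_items)
  items <- names(ia[[1L]])
  rows <- lapply(items, function(it) {
    va <- unlist(lapply(ia, `[[`, it), use.names = FALSE)
    vb <- unlist(lapply(ib, `[[`, it), use.names = FALSE)
    categorical <- !is.numeric(va)
    keep <- !is.na(va) & !is.na(vb)
    va <- va[keep]; vb <- vb[keep]
    thr <- thresholds[[it]]
    tol <- if (categorical) 0 else thr
    n <- length(va)
    if (n == 0L)
      return(data.frame(item = it, kind = if (categorical) "categorical" else "continuous",
                        n_pairs = 0L, tolerance = tol, pct_agreement = NA_real_,
                        mean_abs_diff = NA_real_, icc = NA_real_, n_flagged = 0L,
                        stringsAsFactors = FALSE))
    pct <- percent_agreement(va, vb, tolerance = tol)
    mad <- if (categorical) NA_real_ else mean_absolute_difference(va, vb)
    icc_v <- if (categorical || n < 3L) NA_real_ else
      suppressWarnings(icc(va, vb))
    nfl <- if (categorical) sum(va != vb) else sum(abs(va - vb) > thr)
    data.frame(item = it, kind = if (categorical) "categorical" else "continuous",
               n_pairs = n, tolerance = tol, pct_agreement = pct,
               mean_abs_diff = mad, icc = icc_v, n_flagged = nfl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
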