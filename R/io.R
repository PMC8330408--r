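# File formats and the end-to-end pipeline. Annotations travel as one JSON
# document (nested structure mirrors the in-memory objects); parameter
# records, agreement reports and regression summaries as plain CSV.

ann_to_list <- function(a) {
  list(participant_id = a$participant_id, bolus_id = a$bolus_id,
       rater_id = a$rater_id, fps = a$fps, sip_volume = a$sip_volume,
       n_swallows = a$n_swallows, pas_initial = a$pas_initial,
       pas_max = a$pas_max, lvc_integrity = a$lvc_integrity,
       anterior = a$anterior,
       events = as.list(unclass(a$events)),
       landmarks = list(c2ai = a$landmarks$c2ai, c4ai = a$landmarks$c4ai),
       hyoid = if (is.null(a$hyoid)) NULL else
         list(start_frame = a$hyoid$start_frame,
              positions = unname(a$hyoid$positions)),
       contours = {
         ct <- a$contours
         list(pharynx_at_max_constriction = if (is.null(ct$pharynx_at_max_constriction)) NULL else unname(ct$pharynx_at_max_constriction),
              pharynx_at_rest = if (is.null(ct$pharynx_at_rest)) NULL else unname(ct$pharynx_at_rest),
              residue_valleculae = if (is.null(ct$residue_valleculae)) NULL else unname(ct$residue_valleculae),
              residue_pyriform = if (is.null(ct$residue_pyriform)) NULL else unname(ct$residue_pyriform),
              residue_other = if (is.null(ct$residue_other)) NULL else unname(ct$residue_other),
              ues_diameter_segment = if (is.null(ct$ues_diameter_segment)) NULL else unname(ct$ues_diameter_segment))
       })
}

list_to_ann <- function(x, index = NA) {
  ctx <- paste0("annotation ", index, " (", x$participant_id %||% "?", "/",
                x$bolus_id %||% "?", ")")
  need <- c("participant_id", "bolus_id", "fps", "sip_volume", "events", "landmarks")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("validation error in ", ctx, ": missing field(s) ",
         paste(miss, collapse = ", "))
  unknown <- setdiff(names(x$events), event_names())
  if (length(unknown))
    stop("validation error in ", ctx, ": unknown event name(s) ",
         paste(unknown, collapse = ", "))
  ev <- do.call(event_frames, lapply(x$events, function(f) if (is.null(f)) NA else f))
  mat2 <- function(m, what) {
    if (is.null(m) || length(m) == 0L) return(NULL)
    mm <- if (is.list(m)) {
      rows <- lapply(m, function(r) unlist(r, use.names = FALSE))
      if (any(vapply(rows, length, integer(1L)) != 2L) ||
          !all(vapply(rows, is.numeric, logical(1L))))
        stop("validation error in ", ctx, ": malformed ", what)
      do.call(rbind, rows)
    } else as.matrix(m)
    if (ncol(mm) != 2L || !is.numeric(mm))
      stop("validation error in ", ctx, ": malformed ", what)
    mm
  }
  hy <- NULL
  if (is.null(x$hyoid)) {
    warning("annotation ", ctx, ": hyoid track missing; ",
            "kinematic parameters will be NA")
  } else {
    hy <- hyoid_track(x$hyoid$start_frame, mat2(x$hyoid$positions, "hyoid track"))
  }
  ct <- x$contours %||% list()
  contours <- contour_set(
    pharynx_at_max_constriction = mat2(ct$pharynx_at_max_constriction, "polygon"),
    pharynx_at_rest = mat2(ct$pharynx_at_rest, "polygon"),
    residue_valleculae = mat2(ct$residue_valleculae, "polygon"),
    residue_pyriform = mat2(ct$residue_pyriform, "polygon"),
    residue_other = mat2(ct$residue_other, "polygon"),
    ues_diameter_segment = mat2(ct$ues_diameter_segment, "segment")
  )
  bolus_annotation(
    participant_id = x$participant_id, bolus_id = x$bolus_id,
    rater_id = x$rater_id %||% "unknown", fps = x$fps,
    sip_volume = x$sip_volume, n_swallows = x$n_swallows %||% 1L,
    pas_initial = x$pas_initial %||% 1L,
    pas_max = x$pas_max %||% x$pas_initial %||% 1L,
    lvc_integrity = x$lvc_integrity %||% "complete",
    events = ev, hyoid = hy, contours = contours,
    landmarks = spine_landmarks(unlist(x$landmarks$c2ai), unlist(x$landmarks$c4ai)),
    anterior = x$anterior %||% "left"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write bolus annotations to a JSON file
#' @param annotations List of [bolus_annotation()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  payload <- list(format = "aspektr-annotations", version = 1L,
                  annotations = lapply(annotations, ann_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Read bolus annotations from a JSON file
#'
#' Validates every record against the annotation schema; violations are
#' reported with the offending record and field, never silently coerced.
#' @param path JSON file written by [write_annotations()] (or conforming to
#'   its schema).
#' @return List of [bolus_annotation()] objects.
#' @export
read_annotations <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$annotations)) stop("validation error: no 'annotations' field in ", path)
  lapply(seq_along(x$annotations), function(i) list_to_ann(x$annotations[[i]], i))
}

#' Write parameter records to CSV
#' @param records Parameter-record `data.frame`.
#' @param path Output path.
#' @param units_header Write a second header row with units (default FALSE).
#' @return `path`, invisibly.
#' @export
write_parameter_csv <- function(records, path, units_header = FALSE) {
  if (units_header) {
    units <- vapply(names(records), function(nm) {
      if (nm %in% c("swallow_reaction_time", "hyb_to_ueso", "ueso_duration",
                    "time_to_lvc", "lvc_duration", "hyoid_burst_duration")) "ms"
      else if (nm == "sip_volume") "ml"
      else if (nm %in% c("peak_xy_hyoid", "ues_diameter")) "%(C2-4)"
      else if (nm == "hyoid_xy_speed") "%(C2-4)/s"
      else if (grepl("^(pa_|residue_)", nm)) "%(C2-4)^2"
      else ""
    }, character(1L))
    con <- file(path, "w")
    writeLines(paste(names(records), collapse = ","), con)
    writeLines(paste(units, collapse = ","), con)
    utils::write.table(records, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, qmethod = "double")
    close(con)
  } else {
    utils::write.csv(records, path, row.names = FALSE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis; round-trips losslessly
#' through JSON.
#' @param fps Frame rate.
#' @param thresholds Agreement thresholds ([default_thresholds()]).
#' @param families Bonferroni families ([default_families()]).
#' @param base_alpha Base significance level.
#' @param sip_cut Sip-volume dichotomization cut (ml).
#' @param cohort A [cohort_config()] (used when simulating).
#' @param effects An [effect_config()] (used when simulating).
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 30, thresholds = default_thresholds(),
                            families = default_families(), base_alpha = 0.05,
                            sip_cut = 16, cohort = cohort_config(),
                            effects = effect_config(), seed = 1L) {
  structure(list(fps = fps, thresholds = thresholds, families = families,
                 base_alpha = base_alpha, sip_cut = sip_cut, cohort = cohort,
                 effects = effects, seed = seed),
            class = "pipeline_config")
}

# Automatic resolutions for flagged items: rounded mean for numeric items,
# rater A's value for categorical ones, rater A's contours for geometry.
# (In a live study these come from a consensus meeting.)
auto_resolutions <- function(flags) {
  if (nrow(flags) == 0L) return(list())
  res <- lapply(seq_len(nrow(flags)), function(i) {
    va <- suppressWarnings(as.numeric(flags$value_a[i]))
    vb <- suppressWarnings(as.numeric(flags$value_b[i]))
    it <- flags$item[i]
    if (it %in% event_names() || it %in% c("pas_initial", "pas_max", "n_swallows"))
      round((va + vb) / 2)
    else if (!is.na(va) && !is.na(vb)) "a"   # derived geometry: keep rater A
    else flags$value_a[i]                    # categorical: rater A
  })
  stats::setNames(res, flags$item)
}

#' Run the full analysis pipeline
#'
#' Either simulates a dual-rated study (default) or loads two annotation
#' files, then: agreement statistics and discrepancy flags; consensus
#' merging; parameter measurement; participant means; descriptives;
#' correlation screen; hierarchical regressions for every continuous outcome
#' at its family alpha; bolus-level logistic regression for multiple
#' swallows; and the dichotomized sip-volume odds ratio. Logs one line per
#' stage with record counts.
#'
#' @param config A [pipeline_config()].
#' @param annotations_a,annotations_b Optional lists (or JSON paths) of
#'   paired rater annotations; when omitted the generator supplies them.
#' @param participants Covariate table (`participant_id`, `age`, `sex`);
#'   required when annotations are supplied, generated otherwise.
#' @param out_dir Optional directory; when given, CSV outputs are written.
#' @param quiet Suppress stage logging.
#' @return List with `agreement`, `flags`, `records`, `participant_table`,
#'   `descriptives`, `correlations`, `regressions` (named list of
#'   [hlm()] fits), `regression_summary` (effect flag matrix), `logistic`,
#'   `safety_logistic` (PAS / LVC-integrity fits, `NULL` entries when the
#'   minority class spans fewer than 5 participants), `sip_or`, and `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), annotations_a = NULL,
                         annotations_b = NULL, participants = NULL,
                         out_dir = NULL, quiet = FALSE) {
  log <- character()
  say <- function(...) {
    line <- paste0(...)
    log <<- c(log, line)
    if (!quiet) message(line)
  }
  if (is.character(annotations_a)) annotations_a <- read_annotations(annotations_a)
  if (is.character(annotations_b)) annotations_b <- read_annotations(annotations_b)
  if (is.null(annotations_a)) {
    sim <- simulate_study(config$cohort, config$effects, seed = config$seed)
    annotations_a <- sim$rater_a; annotations_b <- sim$rater_b
    participants <- sim$participants
    say("simulate: ", length(annotations_a), " boluses from ",
        nrow(participants), " participants (seed ", config$seed, ")")
  }
  if (length(annotations_a) == 0L)
    stop("measure stage error: empty annotation input")
  if (is.null(participants))
    stop("participant covariate table (participant_id, age, sex) is required")

  agree <- agreement_report(annotations_a, annotations_b, config$thresholds)
  say("agree: ", nrow(agree), " items over ", length(annotations_a), " pairs")

  consensus <- vector("list", length(annotations_a))
  all_flags <- list()
  for (i in seq_along(annotations_a)) {
    fl <- flag_discrepancies(annotations_a[[i]], annotations_b[[i]],
                             config$thresholds)
    if (nrow(fl)) all_flags[[length(all_flags) + 1L]] <- fl
    consensus[[i]] <- consensus_merge(annotations_a[[i]], annotations_b[[i]],
                                      resolutions = auto_resolutions(fl),
                                      thresholds = config$thresholds)
  }
  flags <- if (length(all_flags)) do.call(rbind, all_flags) else
    flag_discrepancies(annotations_a[[1L]], annotations_a[[1L]], config$thresholds)
  say("consensus: ", length(consensus), " boluses, ", nrow(flags), " flags resolved")

  records <- measure_boluses(consensus)
  say("measure: ", nrow(records), " parameter records")

  pm <- participant_means(records, participants)
  say("participant means: ", nrow(pm), " rows")

  desc <- descriptives_table(records)
  corr <- correlation_screen(pm)
  say("stats: ", nrow(corr), " correlations above threshold")

  outcomes <- setdiff(intersect(continuous_parameters(), names(pm)), "sip_volume")
  regs <- list()
  regs[["sip_volume"]] <- hlm("sip_volume", pm, alpha = config$base_alpha)
  for (oc in outcomes) {
    regs[[oc]] <- hlm(oc, pm,
                      alpha = outcome_alpha(oc, config$families, config$base_alpha),
                      include_sip = oc != "pa_rest")
  }
  reg_summary <- do.call(rbind, lapply(names(regs), function(oc) {
    e <- regs[[oc]]$effects
    data.frame(outcome = oc, alpha = regs[[oc]]$alpha,
               age_effect = e[["age"]], sex_effect = e[["sex"]],
               sip_effect = e[["sip"]], stringsAsFactors = FALSE)
  }))
  say("regressions: ", length(regs), " outcomes")

  rc <- records_with_cov(records, participants)
  logit <- tryCatch(binary_logistic(rc),
                    error = function(e) {
                      say("logistic skipped: ", conditionMessage(e)); NULL
                    })
  # safety outcomes: fitted only when the minority class spans enough
  # participants to support estimation
  rc$pas_impaired <- rc$pas_max >= 3L
  rc$lvc_impaired <- rc$lvc_integrity != "complete"
  safety <- list()
  for (oc in c("pas_impaired", "lvc_impaired")) {
    minority <- min(tapply(rc[[oc]], rc$participant_id, any) |> sum(),
                    tapply(!rc[[oc]], rc$participant_id, all) |> sum())
    if (minority < 5L) {
      say(oc, " logistic skipped: minority class spans ", minority,
          " participant(s) (< 5)")
      safety[[oc]] <- NULL
    } else {
      safety[[oc]] <- tryCatch(binary_logistic(rc, outcome = oc),
                               error = function(e) {
                                 say(oc, " logistic skipped: ",
                                     conditionMessage(e)); NULL
                               })
    }
  }
  or <- tryCatch({
    cnt <- dichotomize_sip(records, cut = config$sip_cut)
    do.call(two_by_two_or, as.list(cnt))
  }, error = function(e) {
    say("odds ratio skipped: ", conditionMessage(e)); NULL
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_parameter_csv(records, file.path(out_dir, "parameter_records.csv"),
                        units_header = TRUE)
    utils::write.csv(agree, file.path(out_dir, "agreement.csv"), row.names = FALSE)
    utils::write.csv(flags, file.path(out_dir, "flags.csv"), row.names = FALSE)
    utils::write.csv(desc, file.path(out_dir, "descriptives.csv"), row.names = FALSE)
    utils::write.csv(corr, file.path(out_dir, "correlations.csv"), row.names = FALSE)
    utils::write.csv(reg_summary, file.path(out_dir, "regression_summary.csv"),
                     row.names = FALSE)
    say("wrote outputs to ", out_dir)
  }
  list(agreement = agree, flags = flags, records = records,
       participant_table = pm, descriptives = desc, correlations = corr,
       regressions = regs, regression_summary = reg_summary,
       logistic = logit, safety_logistic = safety, sip_or = or, log = log)
}

records_with_cov <- function(records, participants) {
  out <- merge(records, participants[c("participant_id", "age", "sex")],
               by = "participant_id")
  out$sex_male <- as.integer(out$sex == "male")
  out
}
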