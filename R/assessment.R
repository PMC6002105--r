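#' Assessment protocol configuration
#'
#' Bundles the thresholds of the kinetic discrimination protocol.  The
#' `"g3"` preset uses a 2.5 Angstrom drift threshold with a 1.4 Angstrom
#' native band (tight, for very rigid complexes); the `"efb"` preset uses
#' 3.2 / 2.5; `"efb_positive"` keeps the 3.2 drift threshold with a
#' 2.0 Angstrom band for calling positives.  Escapes and binding events
#' both require a sustained excursion of `dwell_frames` consecutive
#' frames, so single-frame spikes are never counted.
#'
#' @param drift_threshold Angstrom; drift beyond this from the starting
#'   pose counts as an escape.  Default 2.5.
#' @param native_band Angstrom; RMSD to the reference below this counts
#'   as native. Default 1.4.  Must be below `drift_threshold`.
#' @param dwell_frames consecutive frames required to sustain an escape
#'   or a binding event. Default 5.
#' @param base_temperature K, the room-temperature segment. Default 303.
#' @param ladder_step K per ladder rung. Default 30.
#' @param ladder_dwell ns per elevated rung. Default 12.
#' @param max_temperature K, top of the ladder. Default 390.
#' @param preset optional shorthand: `"g3"`, `"efb"` or `"efb_positive"`;
#'   explicit arguments override preset values.
#' @return object of class `assessment_config`.
#' @export
assessment_config <- function(drift_threshold = 2.5, native_band = 1.4,
                              dwell_frames = 5L, base_temperature = 303,
                              ladder_step = 30, ladder_dwell = 12,
                              max_temperature = 390, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("g3", "efb", "efb_positive"))
    pv <- switch(preset,
      g3           = list(drift_threshold = 2.5, native_band = 1.4),
      efb          = list(drift_threshold = 3.2, native_band = 2.5),
      efb_positive = list(drift_threshold = 3.2, native_band = 2.0))
    if (missing(drift_threshold)) drift_threshold <- pv$drift_threshold
    if (missing(native_band)) native_band <- pv$native_band
  }
  if (!(drift_threshold > native_band && native_band > 0))
    stop("need drift_threshold > native_band > 0")
  if (ladder_step <= 0) stop("ladder_step must be > 0")
  if (max_temperature < base_temperature)
    stop("max_temperature must be >= base_temperature")
  if (dwell_frames < 1L) stop("dwell_frames must be a positive integer")
  structure(list(drift_threshold = drift_threshold, native_band = native_band,
                 dwell_frames = as.integer(dwell_frames),
                 base_temperature = base_temperature,
                 ladder_step = ladder_step, ladder_dwell = ladder_dwell,
                 max_temperature = max_temperature),
            class = "assessment_config")
}

#' Read an assessment config from a YAML key-value file
#' @param path file path; keys mirror the [assessment_config()] arguments.
#' @return an `assessment_config`.
#' @export
read_assessment_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(assessment_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown assessment config keys: ",
                        paste(bad, collapse = ", "))
  do.call(assessment_config, y)
}

# first index where `flag` holds for >= dwell consecutive entries, else NA
first_sustained <- function(flag, dwell) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= dwell)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1L]]
}

#' Classify drift away from the starting pose
#'
#' A pose "escapes" when its RMSD from its own starting structure exceeds
#' `drift_threshold` for at least `dwell_frames` consecutive frames; the
#' escape time is the first frame time of the first qualifying run.
#' Single-frame spikes shorter than the dwell are ignored.
#'
#' @param series an [rmsd_series()] measured against the trajectory's own
#'   frame-0 structure.
#' @param cfg an [assessment_config()].
#' @return list with `escaped` (logical), `escape_time` (ns or `NA`),
#'   `max_drift` (Angstrom).
#' @export
drift_classify <- function(series, cfg = assessment_config()) {
  v <- series$values
  if (length(v) < cfg$dwell_frames)
    stop("series shorter than dwell_frames (", length(v), " < ",
         cfg$dwell_frames, ")")
  i <- first_sustained(v > cfg$drift_threshold, cfg$dwell_frames)
  list(escaped = !is.na(i),
       escape_time = if (is.na(i)) NA_real_ else series$times[i],
       max_drift = max(v))
}

#' Detect a binding event against the reference structure
#'
#' A binding event is the trajectory entering the native band (RMSD to
#' the reference `<= native_band`) and staying there -- for at least
#' `dwell_frames` consecutive frames, with no later sustained exit (an
#' out-of-band run of `dwell_frames` or more).  Brief excursions out of
#' the band are tolerated.  Returns the entry time of the qualifying run,
#' or `NA` if the trajectory never settles in the band.
#'
#' @param series an [rmsd_series()] against the experimental reference.
#' @param cfg an [assessment_config()].
#' @return binding time in ns, or `NA_real_`.
#' @export
detect_binding_event <- function(series, cfg = assessment_config()) {
  v <- series$values
  inside <- v <= cfg$native_band
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok_in <- which(r$values & r$lengths >= cfg$dwell_frames)
  if (!length(ok_in)) return(NA_real_)
  sustained_out_starts <- starts[!r$values & r$lengths >= cfg$dwell_frames]
  for (k in ok_in) {
    if (!any(sustained_out_starts > starts[k]))
      return(series$times[starts[k]])
  }
  NA_real_
}

#' Assess one decoy trajectory
#'
#' Runs the full per-model protocol: drift classification against the
#' starting pose, localisation of the escape on the temperature schedule,
#' and (when a reference is supplied) binding-event detection.  Labels:
#'
#' * `UNSTABLE` -- sustained escape during the base-temperature segment;
#' * `METASTABLE` -- stable at base temperature, escaping only at an
#'   elevated rung (`escape_temperature` records the rung);
#' * `STABLE_CANDIDATE` -- no escape through the full ladder;
#' * `CONVERGED_TO_REFERENCE` -- a binding event was detected and the
#'   final frame lies within the native band.  This label overrides the
#'   others: a pose that slides down the funnel necessarily drifts beyond
#'   the threshold from its (wrong) starting pose first.
#'
#' Without a reference only the first three labels are reachable.
#'
#' @param traj a [trajectory()] carrying a ladder (or flat) schedule.
#' @param initial the starting pose ([structure_model()]); its
#'   coordinates define the drift origin.
#' @param reference the experimental reference model, or `NULL`.
#' @param cfg an [assessment_config()].
#' @param fit_sel,measure_sel selections passed to [rmsd_series()].
#' @return object of class `decoy_verdict`.
#' @export
assess_decoy <- function(traj, initial, reference = NULL,
                         cfg = assessment_config(),
                         fit_sel = "chain A and name CA",
                         measure_sel = "name CA") {
  drift <- rmsd_series(traj, initial, fit_sel, measure_sel)
  dc <- drift_classify(drift, cfg)
  esc_T <- NA_real_
  if (dc$escaped) {
    t_eval <- min(dc$escape_time, traj$schedule$total_ns * (1 - 1e-12))
    esc_T <- temperature_at(traj$schedule, t_eval)
  }
  binding_time <- NA_real_
  final_ref <- NA_real_
  ref_series <- NULL
  if (!is.null(reference)) {
    ref_series <- rmsd_series(traj, reference, fit_sel, measure_sel)
    final_ref <- ref_series$values[length(ref_series$values)]
    bt <- detect_binding_event(ref_series, cfg)
    if (!is.na(bt) && final_ref <= cfg$native_band) binding_time <- bt
  }
  label <- if (!is.na(binding_time)) {
    "CONVERGED_TO_REFERENCE"
  } else if (!dc$escaped) {
    "STABLE_CANDIDATE"
  } else if (esc_T <= cfg$base_temperature) "UNSTABLE" else "METASTABLE"
  structure(list(model_id = traj$model_id, label = label,
                 escape_time = if (dc$escaped) dc$escape_time else NA_real_,
                 escape_temperature = esc_T,
                 binding_time = binding_time,
                 max_drift = dc$max_drift,
                 final_rmsd_to_reference = final_ref,
                 drift_series = drift, reference_series = ref_series,
                 config = cfg),
            class = "decoy_verdict")
}

#' @export
print.decoy_verdict <- function(x, ...) {
  cat("decoy_verdict '", x$model_id, "': ", x$label, sep = "")
  if (!is.na(x$escape_time))
    cat("  (escape ", format(x$escape_time, digits = 3), " ns @ ",
        x$escape_temperature, " K)", sep = "")
  if (!is.na(x$binding_time))
    cat("  (binding ", format(x$binding_time, digits = 3), " ns)", sep = "")
  cat("\n")
  invisible(x)
}

#' Flatten verdicts to a data frame
#' @param verdicts list of `decoy_verdict`.
#' @return data frame, one row per model.
#' @export
verdicts_to_df <- function(verdicts) {
  if (inherits(verdicts, "decoy_verdict")) verdicts <- list(verdicts)
  do.call(rbind, lapply(verdicts, function(v)
    data.frame(model_id = v$model_id, label = v$label,
               escape_time_ns = v$escape_time,
               escape_temperature_K = v$escape_temperature,
               binding_time_ns = v$binding_time,
               max_drift_A = v$max_drift,
               final_rmsd_to_reference_A = v$final_rmsd_to_reference,
               stringsAsFactors = FALSE)))
}

#' Summarize a cohort of verdicts
#'
#' Aggregates per-label counts, escape-time and escape-temperature
#' distributions, and the candidate list (stable and converged models)
#' sorted by final RMSD to the reference and then by maximum drift;
#' converged models are additionally listed in order of binding time.
#'
#' @param verdicts non-empty list of `decoy_verdict`.
#' @return object of class `cohort_summary` with fields `counts`,
#'   `n`, `escape_times`, `escape_temperatures`, `candidates`,
#'   `converged`, `table`.
#' @export
summarize_cohort <- function(verdicts) {
  if (!length(verdicts)) stop("empty verdict list")
  df <- verdicts_to_df(verdicts)
  labels <- c("UNSTABLE", "METASTABLE", "STABLE_CANDIDATE",
              "CONVERGED_TO_REFERENCE")
  counts <- setNames(vapply(labels, function(l) sum(df$label == l),
                            integer(1)), labels)
  cand <- df[df$label %in% c("STABLE_CANDIDATE", "CONVERGED_TO_REFERENCE"), ,
             drop = FALSE]
  if (nrow(cand)) {
    ord <- order(cand$final_rmsd_to_reference, cand$max_drift_A,
                 cand$model_id, na.last = TRUE)
    cand <- cand[ord, , drop = FALSE]
  }
  conv <- df[df$label == "CONVERGED_TO_REFERENCE", , drop = FALSE]
  if (nrow(conv)) conv <- conv[order(conv$binding_time_ns, conv$model_id), ,
                               drop = FALSE]
  structure(list(n = nrow(df), counts = counts,
                 escape_times = df$escape_time_ns[!is.na(df$escape_time_ns)],
                 escape_temperatures =
                   df$escape_temperature_K[!is.na(df$escape_temperature_K)],
                 candidates = cand, converged = conv, table = df),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort of", x$n, "models\n")
  for (l in names(x$counts))
    cat(sprintf("  %-24s %d\n", l, x$counts[[l]]))
  if (length(x$escape_temperatures))
    cat("  escape temperatures (K):",
        paste(sort(unique(x$escape_temperatures)), collapse = ", "), "\n")
  if (nrow(x$candidates)) {
    cat("candidates (best first):\n")
    print(x$candidates[, c("model_id", "label", "final_rmsd_to_reference_A",
                           "max_drift_A")], row.names = FALSE)
  } else cat("no stable or converged candidates\n")
  invisible(x)
}

#' Write a cohort report as markdown
#' @param summary a `cohort_summary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  lines <- c("# Decoy cohort report", "",
             sprintf("Models assessed: %d", summary$n), "", "## Label counts", "")
  lines <- c(lines, sprintf("- %s: %d", names(summary$counts), summary$counts))
  if (length(summary$escape_times)) {
    lines <- c(lines, "", "## Escapes", "",
               sprintf("- escape times (ns): %s",
                       paste(format(sort(summary$escape_times), digits = 3),
                             collapse = ", ")),
               sprintf("- escape temperatures (K): %s",
                       paste(sort(summary$escape_temperatures), collapse = ", ")))
  }
  lines <- c(lines, "", "## Candidates", "")
  if (nrow(summary$candidates)) {
    lines <- c(lines, "model_id | label | final_rmsd_A | max_drift_A",
               "--- | --- | --- | ---",
               sprintf("%s | %s | %s | %.2f",
                       summary$candidates$model_id, summary$candidates$label,
                       ifelse(is.na(summary$candidates$final_rmsd_to_reference_A),
                              "NA",
                              sprintf("%.2f",
                                      summary$candidates$final_rmsd_to_reference_A)),
                       summary$candidates$max_drift_A))
  } else lines <- c(lines, "(none)")
  writeLines(lines, path)
  invisible(path)
}
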