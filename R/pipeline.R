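#' Generate a labelled synthetic cohort on disk
#'
#' End-to-end synthetic-data entry point: builds a labelled benchmark set
#' on a landscape, simulates one trajectory per decoy under the schedule,
#' and writes everything through the public formats -- decoy poses and
#' the rendered reference as multi-model PDB, one plain-text trajectory
#' table per decoy, the schedule and landscape as YAML, and a JSON
#' manifest mapping model ids to ground-truth labels, seeds and files.
#'
#' @param out_dir output directory (created if missing).
#' @param ls a [landscape()], or path to a landscape YAML file.
#' @param n_per_class named counts per ground-truth class (see
#'   [make_benchmark_set()]).
#' @param schedule a [temperature_schedule()] or path to a schedule file.
#' @param seed integer master seed.
#' @param jitter placement jitter, Angstrom.
#' @param params a [sim_params()].
#' @return invisibly, the manifest as a list.
#' @export
pipeline_simulate <- function(out_dir, ls = default_landscape(),
                              n_per_class = c(native = 1, funnel_interior = 2,
                                              trap = 3, unstable = 4),
                              schedule = ladder_schedule(), seed = 1L,
                              jitter = 0.5, params = sim_params()) {
  if (is.character(ls)) ls <- read_landscape(ls)
  if (is.character(schedule)) schedule <- read_schedule(schedule)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bench <- make_benchmark_set(ls, n_per_class, jitter = jitter, seed = seed,
                              params = params, schedule = schedule)
  trajs <- simulate_benchmark(bench)
  write_multimodel_pdb(unname(bench$models), file.path(out_dir, "models.pdb"))
  write_multimodel_pdb(list(bench$reference),
                       file.path(out_dir, "reference.pdb"))
  write_schedule(schedule, file.path(out_dir, "schedule.yaml"))
  write_landscape(ls, file.path(out_dir, "landscape.yaml"))
  entries <- lapply(seq_along(trajs), function(i) {
    fn <- paste0("traj_", names(trajs)[i], ".tsv")
    write_trajectory_table(trajs[[i]], file.path(out_dir, fn))
    list(model_id = names(trajs)[i],
         truth_label = unname(bench$truth_labels[[names(trajs)[i]]]),
         seed = bench$seed + i, trajectory = fn,
         frame_spacing_ns = trajs[[i]]$frame_spacing)
  })
  manifest <- list(tool = paste0("decoysieve ",
                                 as.character(utils::packageVersion("decoysieve"))),
                   seed = as.integer(seed),
                   jitter_A = jitter,
                   n_models = length(trajs),
                   schedule = "schedule.yaml", landscape = "landscape.yaml",
                   models = "models.pdb", reference = "reference.pdb",
                   entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Assess a cohort of decoy trajectories
#'
#' Runs the full discrimination protocol over a cohort: per-model drift
#' classification on the temperature schedule (and binding detection when
#' a reference is given), the cohort summary, and -- with at least two
#' trajectories -- the pairwise convergence table with funnel-signature
#' flags and best-model nominations.  Inputs can be in-memory objects or
#' a directory produced by [pipeline_simulate()] (read back through the
#' manifest).  A model whose trajectory fails to assess is reported and
#' skipped; the run continues.
#'
#' @param input_dir directory holding `manifest.json` (alternative to
#'   passing `models`/`trajs` directly).
#' @param models named list of starting [structure_model()]s.
#' @param trajs named list of [trajectory()] objects (same order).
#' @param reference a [structure_model()]; `NULL` falls back to the
#'   manifest's reference when reading a directory.
#' @param use_reference set `FALSE` to force reference-free assessment
#'   even when a reference is available.
#' @param cfg an [assessment_config()].
#' @param fit_sel,measure_sel selections for all RMSD computations.
#' @param out_dir optional directory for result files (verdicts CSV/JSON,
#'   pair table CSV, nomination JSON, markdown report).
#' @param delta_cutoff funnel-signature delta cutoff, Angstrom (negative).
#' @return list with `verdicts`, `summary`, `pairs`, `nomination`,
#'   `failed` (character vector of model ids that failed).
#' @export
pipeline_assess <- function(input_dir = NULL, models = NULL, trajs = NULL,
                            reference = NULL, cfg = assessment_config(),
                            fit_sel = "chain A and name CA",
                            measure_sel = "name CA", out_dir = NULL,
                            delta_cutoff = -2.0, use_reference = TRUE) {
  if (!is.null(input_dir)) {
    mf_path <- file.path(input_dir, "manifest.json")
    if (!file.exists(mf_path)) stop("no manifest.json in ", input_dir)
    mf <- jsonlite::read_json(mf_path)
    model_list <- read_multimodel_pdb(file.path(input_dir, mf$models))
    schedule <- read_schedule(file.path(input_dir, mf$schedule))
    ids <- vapply(mf$entries, function(e) e$model_id, character(1))
    models <- setNames(model_list[seq_along(ids)], ids)
    for (i in seq_along(models)) models[[i]]$model_id <- ids[i]
    trajs <- setNames(lapply(mf$entries, function(e)
      read_trajectory_table(file.path(input_dir, e$trajectory),
                            models[[e$model_id]],
                            e$frame_spacing_ns, schedule)), ids)
    for (i in seq_along(trajs)) trajs[[i]]$model_id <- ids[i]
    if (use_reference && is.null(reference) && !is.null(mf$reference) &&
        file.exists(file.path(input_dir, mf$reference)))
      reference <- read_multimodel_pdb(file.path(input_dir,
                                                 mf$reference))[[1L]]
  }
  if (!use_reference) reference <- NULL
  if (is.null(models) || is.null(trajs))
    stop("supply either input_dir or both models and trajs")
  if (length(models) != length(trajs))
    stop("models and trajs must have equal length")

  verdicts <- list(); failed <- character(0)
  for (i in seq_along(trajs)) {
    v <- tryCatch(assess_decoy(trajs[[i]], models[[i]], reference, cfg,
                               fit_sel, measure_sel),
                  error = function(e) e)
    if (inherits(v, "error")) {
      warning("assessment failed for '", trajs[[i]]$model_id, "': ",
              conditionMessage(v))
      failed <- c(failed, trajs[[i]]$model_id)
    } else verdicts[[length(verdicts) + 1L]] <- v
  }
  if (!length(verdicts)) stop("no model could be assessed")
  summary <- summarize_cohort(verdicts)

  pairs <- NULL; nomination <- NULL
  ok <- !vapply(trajs, function(tr) tr$model_id %in% failed, logical(1))
  if (sum(ok) >= 2L) {
    pairs <- pair_table(models[ok], trajs[ok], fit_sel, measure_sel)
    pairs <- flag_funnel_signature(pairs, final_cutoff = cfg$native_band,
                                   delta_cutoff = delta_cutoff)
    nomination <- nominate_best_model(pairs, verdicts)
  } else {
    message("pair analysis skipped: fewer than 2 assessable trajectories")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta <- result_metadata(cfg, fit_sel, measure_sel)
    df <- verdicts_to_df(verdicts)
    con <- file(file.path(out_dir, "verdicts.csv"), "w")
    writeLines(meta, con)
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
    close(con)
    jsonlite::write_json(df, file.path(out_dir, "verdicts.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
    write_cohort_report(summary, file.path(out_dir, "report.md"))
    if (!is.null(pairs))
      write_pair_table_csv(pairs, file.path(out_dir, "pair_table.csv"))
    if (!is.null(nomination))
      jsonlite::write_json(list(status = nomination$status,
                                ranking = nomination$ranking),
                           file.path(out_dir, "nomination.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  if (!is.null(nomination) && nomination$status == "ok")
    cat("top nomination:",
        paste(nomination$ranking$model_id[nomination$ranking$rank == 1L],
              collapse = ", "), "\n")
  list(verdicts = verdicts, summary = summary, pairs = pairs,
       nomination = nomination, failed = failed)
}

# metadata comment lines stamped on result tables
result_metadata <- function(cfg, fit_sel, measure_sel) {
  c(paste0("# decoysieve ",
           as.character(utils::packageVersion("decoysieve"))),
    paste0("# fit=[", if (is.character(fit_sel)) fit_sel else
      fit_sel$expression, "] measure=[",
      if (is.character(measure_sel)) measure_sel else
        measure_sel$expression, "]"),
    paste0("# drift_threshold_A=", cfg$drift_threshold,
           " native_band_A=", cfg$native_band,
           " dwell_frames=", cfg$dwell_frames,
           " base_K=", cfg$base_temperature,
           " ladder_step_K=", cfg$ladder_step,
           " max_K=", cfg$max_temperature))
}
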