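#' Pairwise trajectory-convergence table
#'
#' For every unordered pair of models, records the superposed RMSD
#' between the two starting models (`initial_rmsd`), between the two
#' trajectory endpoints (`final_rmsd`), and their difference
#' (`delta_rmsd = final - initial`).  Two trajectories that start from
#' dissimilar poses and end in nearly identical structures (a large
#' negative `delta_rmsd` together with a small `final_rmsd`) indicate a
#' shared attractor -- the funnel signature used to nominate the native
#' basin without a reference structure.
#'
#' @param models list of starting [structure_model()] objects, one per
#'   trajectory.
#' @param trajs list of [trajectory()] objects (same length/order).
#' @param fit_sel,measure_sel selections used for all superpositions.
#' @return data frame of class `pair_table`, columns `model_a`,
#'   `model_b`, `initial_rmsd`, `final_rmsd`, `delta_rmsd`,
#'   `funnel_signature` (initialized `NA`), sorted ascending by
#'   `final_rmsd` with lexicographic (model_a, model_b) tie-break.
#' @export
pair_table <- function(models, trajs, fit_sel = "chain A and name CA",
                       measure_sel = "name CA") {
  if (length(models) != length(trajs))
    stop("need exactly one trajectory per model (", length(models), " vs ",
         length(trajs), ")")
  if (length(models) < 2L) stop("pair analysis needs at least 2 models")
  top <- trajs[[1L]]$topology
  ifit <- select_atoms(top, fit_sel)
  imeas <- select_atoms(top, measure_sel)
  sup_rmsd <- function(x, y) {
    fit <- kabsch_fit(x[ifit, , drop = FALSE], y[ifit, , drop = FALSE])
    moved <- sweep(x[imeas, , drop = FALSE] %*% t(fit$rotation), 2,
                   fit$translation, "+")
    sqrt(sum((moved - y[imeas, , drop = FALSE])^2) / length(imeas))
  }
  ids <- vapply(trajs, function(tr) tr$model_id, character(1))
  starts <- lapply(models, function(m) m$xyz)
  ends <- lapply(trajs, last_frame)
  k <- length(ids)
  rows <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
    ini <- sup_rmsd(starts[[i]], starts[[j]])
    fin <- sup_rmsd(ends[[i]], ends[[j]])
    rows[[length(rows) + 1L]] <- data.frame(
      model_a = a, model_b = b, initial_rmsd = ini, final_rmsd = fin,
      delta_rmsd = fin - ini, funnel_signature = NA,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$final_rmsd, out$model_a, out$model_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Flag the native-funnel signature on a pair table
#'
#' A pair is flagged when its endpoints are close (`final_rmsd <=
#' final_cutoff`) AND the pair has moved considerably toward each other
#' (`delta_rmsd <= delta_cutoff`, with `delta_cutoff` negative).  Pairs
#' of stable near-duplicates -- low final RMSD but almost no RMSD change,
#' the classic false-positive pattern -- are therefore not flagged.
#'
#' @param records a [pair_table()].
#' @param final_cutoff Angstrom, default 1.4 (the tight native band); use
#'   2.5 for looser complexes.
#' @param delta_cutoff Angstrom, negative; default -2.0 separates pairs
#'   that moved considerably from static near-duplicates.
#' @return the table with `funnel_signature` filled in, ordering
#'   preserved.
#' @export
flag_funnel_signature <- function(records, final_cutoff = 1.4,
                                  delta_cutoff = -2.0) {
  if (final_cutoff <= 0) stop("final_cutoff must be > 0")
  if (delta_cutoff >= 0) stop("delta_cutoff must be negative")
  if (!nrow(records)) { records$funnel_signature <- logical(0); return(records) }
  records$funnel_signature <- records$final_rmsd <= final_cutoff &
    records$delta_rmsd <= delta_cutoff
  records
}

#' Nominate the best model from funnel-signature evidence
#'
#' Models are scored by the number of flagged pairs they participate in,
#' ties broken by the lowest mean `final_rmsd` over their flagged pairs.
#' The output is deterministic; with no flagged pairs an explicit
#' "no funnel evidence" status is returned rather than an arbitrary
#' ranking.
#'
#' @param records a flagged [pair_table()] (see [flag_funnel_signature()]).
#' @param verdicts optional list of `decoy_verdict` attached as context
#'   to the nomination (not used for scoring).
#' @return object of class `nomination`: list with `status`
#'   (`"ok"`/`"no funnel evidence"`), `ranking` (data frame `model_id`,
#'   `n_flagged`, `mean_final_rmsd`, `rank`), and `evidence` (the flagged
#'   pairs).
#' @export
nominate_best_model <- function(records, verdicts = NULL) {
  if (any(is.na(records$funnel_signature)))
    stop("run flag_funnel_signature() before nominating")
  flagged <- records[records$funnel_signature, , drop = FALSE]
  if (!nrow(flagged))
    return(structure(list(status = "no funnel evidence",
                          ranking = data.frame(model_id = character(0),
                                               n_flagged = integer(0),
                                               mean_final_rmsd = numeric(0),
                                               rank = integer(0)),
                          evidence = flagged, verdicts = verdicts),
                     class = "nomination"))
  ids <- sort(unique(c(flagged$model_a, flagged$model_b)))
  stats <- do.call(rbind, lapply(ids, function(id) {
    sel <- flagged$model_a == id | flagged$model_b == id
    data.frame(model_id = id, n_flagged = sum(sel),
               mean_final_rmsd = mean(flagged$final_rmsd[sel]),
               stringsAsFactors = FALSE)
  }))
  stats <- stats[order(-stats$n_flagged, stats$mean_final_rmsd,
                       stats$model_id), , drop = FALSE]
  # competition ranking on the (n_flagged, mean_final_rmsd) score
  key <- paste(stats$n_flagged, format(stats$mean_final_rmsd, digits = 12))
  stats$rank <- match(key, unique(key))
  rownames(stats) <- NULL
  structure(list(status = "ok", ranking = stats, evidence = flagged,
                 verdicts = verdicts),
            class = "nomination")
}

#' @export
print.nomination <- function(x, ...) {
  if (x$status != "ok") { cat("nomination:", x$status, "\n"); return(invisible(x)) }
  cat("nomination (", nrow(x$evidence), " flagged pairs):\n", sep = "")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Write a pair table as CSV
#'
#' Machine-readable pairwise convergence table; a comment line records
#' units.  By default the full table is written; `top` additionally
#' returns the mutually closest pairs for display.
#'
#' @param records a [pair_table()].
#' @param path output file.
#' @param top number of top pairs to return (default 10).
#' @return invisibly, the `top` closest pairs.
#' @export
write_pair_table_csv <- function(records, path, top = 10L) {
  con <- file(path, "w")
  writeLines("# pairwise trajectory convergence, RMSD in Angstrom", con)
  utils::write.table(as.data.frame(records), con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(utils::head(as.data.frame(records), top))
}
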