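#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `R %*% mobile + t` and `target`, by SVD of the covariance
#' matrix with the standard reflection correction (the sign of the
#' smallest singular direction is flipped when the determinant of the
#' candidate rotation is negative).  Weights are uniform; no mass
#' weighting is applied.
#'
#' @param mobile,target numeric N x 3 coordinate matrices, N >= 3,
#'   matched row-for-row.
#' @return list of class `fit_result` with `rotation` (3 x 3 proper
#'   orthonormal), `translation` (length-3, Angstrom) and `rmsd`
#'   (Angstrom), such that `mobile %*% t(rotation) + translation`
#'   superposes onto `target`.
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L)
    stop("coordinate sets must be matched N x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 atoms")
  ca <- colMeans(mobile); cb <- colMeans(target)
  a <- sweep(mobile, 2, ca); b <- sweep(target, 2, cb)
  sa <- svd(a, nu = 0, nv = 0)$d
  sb <- svd(b, nu = 0, nv = 0)$d
  if (sa[2] < 1e-9 * max(1, sa[1]) || sb[2] < 1e-9 * max(1, sb[1]))
    stop("degenerate geometry: coordinates are (nearly) collinear")
  h <- crossprod(a, b)             # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(sum((fitted - b)^2) / n)
  structure(list(rotation = rot,
                 translation = as.numeric(cb - rot %*% ca),
                 rmsd = rmsd),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' With `superpose = TRUE` (default) the optimal rigid superposition is
#' removed first ([kabsch_fit()]); otherwise the raw index-wise RMSD is
#' returned.  Symmetric in its arguments in both modes.
#'
#' @param a,b N x 3 coordinate matrices, matched row-for-row.
#' @param superpose remove the optimal rigid-body transform first?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate length mismatch")
  if (superpose) return(kabsch_fit(a, b)$rmsd)
  sqrt(sum((a - b)^2) / nrow(a))
}

#' RMSD time series of a trajectory against a reference model
#'
#' For every frame, the frame is superposed onto `reference` using the
#' `fit_sel` atoms and the RMSD is then measured over the `measure_sel`
#' atoms.  The default convention fits on the receptor chain and measures
#' over all C-alpha atoms, which makes ligand drift visible in the series
#' while the receptor frame stays anchored.  Atom correspondence between
#' the trajectory topology and the reference is by (chain, resid, name)
#' when the topologies differ in order.
#'
#' @param traj a [trajectory()].
#' @param reference a [structure_model()].
#' @param fit_sel selection used for the superposition (string or
#'   [parse_selection()] object).
#' @param measure_sel selection over which the RMSD is measured.
#' @return object of class `rmsd_series`: list with `times` (ns),
#'   `values` (Angstrom), `model_id`, `reference_id`, `fit_selection`,
#'   `measure_selection`.
#' @export
rmsd_series <- function(traj, reference, fit_sel = "name CA",
                        measure_sel = "name CA") {
  fit_sel <- parse_selection(fit_sel); measure_sel <- parse_selection(measure_sel)
  corr <- atom_correspondence(traj$topology, reference)
  ifit <- select_atoms(traj$topology, fit_sel)
  imeas <- select_atoms(traj$topology, measure_sel)
  # map topology indices into the reference's row order
  ref_of <- integer(n_atoms(traj$topology)); ref_of[corr$ia] <- corr$ib
  ref_fit <- reference$xyz[ref_of[ifit], , drop = FALSE]
  ref_meas <- reference$xyz[ref_of[imeas], , drop = FALSE]
  vals <- vapply(traj$frames, function(f) {
    fit <- kabsch_fit(f[ifit, , drop = FALSE], ref_fit)
    moved <- f[imeas, , drop = FALSE] %*% t(fit$rotation)
    moved <- sweep(moved, 2, fit$translation, "+")
    sqrt(sum((moved - ref_meas)^2) / nrow(ref_meas))
  }, numeric(1))
  structure(list(times = frame_times(traj), values = vals,
                 model_id = traj$model_id, reference_id = reference$model_id,
                 fit_selection = fit_sel$expression,
                 measure_selection = measure_sel$expression),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat("rmsd_series '", x$model_id, "' vs '", x$reference_id, "': ",
      length(x$values), " frames, final ",
      format(x$values[length(x$values)], digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Pairwise RMSD between trajectory endpoints
#'
#' Entry (i, j) is the superposed RMSD between the last saved frames of
#' trajectories i and j (fit on `fit_sel`, measured on `measure_sel`).
#' This is the pairwise endpoint comparison used to detect convergence of
#' independent simulations toward the same structure.
#'
#' @param trajs list of [trajectory()] objects sharing a topology.
#' @param fit_sel,measure_sel selections (see [rmsd_series()]).
#' @return symmetric matrix (Angstrom) with model ids as dimnames and a
#'   zero diagonal.
#' @export
pairwise_endpoint_rmsd <- function(trajs, fit_sel = "name CA",
                                   measure_sel = "name CA") {
  stopifnot(length(trajs) >= 1L)
  top <- trajs[[1L]]$topology
  for (tr in trajs[-1L]) {
    if (!same_topology(top, tr$topology))
      stop("heterogeneous topology: trajectory '", tr$model_id, "'")
  }
  ifit <- select_atoms(top, fit_sel)
  imeas <- select_atoms(top, measure_sel)
  ends <- lapply(trajs, last_frame)
  k <- length(trajs)
  m <- matrix(0, k, k)
  ids <- vapply(trajs, function(tr) tr$model_id, character(1))
  dimnames(m) <- list(ids, ids)
  if (k == 1L) return(m)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    fit <- kabsch_fit(ends[[i]][ifit, , drop = FALSE],
                      ends[[j]][ifit, , drop = FALSE])
    moved <- sweep(ends[[i]][imeas, , drop = FALSE] %*% t(fit$rotation),
                   2, fit$translation, "+")
    m[i, j] <- m[j, i] <- sqrt(sum((moved - ends[[j]][imeas, , drop = FALSE])^2) /
                                 length(imeas))
  }
  m
}

#' Minimum interatomic distance between two selections over time
#'
#' Per frame, the minimum Euclidean distance over all atom pairs with one
#' atom from each selection.  No superposition is applied: these are
#' internal distances (e.g. a candidate polar contact across the
#' interface).  Overlapping selections are rejected.
#'
#' @param traj a [trajectory()].
#' @param sel_a,sel_b disjoint selections.
#' @return list with `times` (ns) and `values` (Angstrom).
#' @export
residue_min_distance_series <- function(traj, sel_a, sel_b) {
  ia <- select_atoms(traj$topology, sel_a)
  ib <- select_atoms(traj$topology, sel_b)
  if (length(intersect(ia, ib)))
    stop("overlapping selections: minimum distance needs disjoint atom sets")
  vals <- vapply(traj$frames, function(f) {
    A <- f[ia, , drop = FALSE]; B <- f[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  list(times = frame_times(traj), values = vals)
}

#' Export an RMSD series or pairwise matrix as CSV
#'
#' Series get columns `time_ns,value_A`; matrices get model ids as header
#' row and first column.  A leading comment line records units and, for a
#' series, the fit/measure selections.
#'
#' @param x an `rmsd_series` or a matrix from [pairwise_endpoint_rmsd()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "rmsd_series")) {
    writeLines(paste0("# rmsd_series model=", x$model_id, " reference=",
                      x$reference_id, " fit=[", x$fit_selection,
                      "] measure=[", x$measure_selection,
                      "] units: time ns, value Angstrom"), con)
    utils::write.table(data.frame(time_ns = x$times, value_A = x$values),
                       con, sep = ",", quote = FALSE, row.names = FALSE)
  } else if (is.matrix(x)) {
    writeLines("# pairwise endpoint RMSD, Angstrom", con)
    utils::write.table(data.frame(model_id = rownames(x), x,
                                  check.names = FALSE),
                       con, sep = ",", quote = FALSE, row.names = FALSE)
  } else stop("cannot export object of class ", paste(class(x), collapse = "/"))
  invisible(path)
}
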