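#' Default benchmark landscape
#'
#' A funneled surrogate landscape built from three ingredients: a stiff
#' narrow native well at the origin (the bound minimum, rigid enough
#' that a reference trajectory fluctuates around ~1 Angstrom RMSD), a
#' broad shallow funnel well co-centered with it (the long-range basin
#' that lets off-pose decoys slide home), and two deep narrow traps at
#' wrong positions and orientations (kinetically stable decoy sites),
#' all inside a soft confinement wall.  Depths are set in units of
#' `kB * 303` (thermal energy at the base temperature); widths, centers
#' and friction defaults were fixed once so the designed behaviours
#' occur on the ladder's time scale: unstable poses drift beyond
#' 2.5 Angstrom within a few ns at 303 K, traps hold at 303 K but
#' escape on the upper rungs, and funnel-interior poses reach the
#' native minimum during the simulation.
#'
#' @param trap_depth_kT trap depth in units of kB*303 (default 19).
#' @param native_depth_kT native-well depth in the same units (default 28).
#' @param funnel_depth_kT funnel-well depth in the same units (default 13).
#' @return a [landscape()].
#' @export
default_landscape <- function(trap_depth_kT = 19, native_depth_kT = 28,
                              funnel_depth_kT = 13) {
  kT <- kB * 303
  landscape(list(
    well(c(0, 0, 0), c(1, 0, 0, 0), depth = native_depth_kT * kT,
         width = 2.5, label = "native"),
    well(c(0, 0, 0), c(1, 0, 0, 0), depth = funnel_depth_kT * kT,
         width = 7, label = "funnel"),
    well(c(32, 0, 0), quat_from_axis_angle(c(0, 0, 1), 2.2),
         depth = trap_depth_kT * kT, width = 1.7, label = "trap"),
    well(c(-22, 22, 7), quat_from_axis_angle(c(1, 1, 0), -1.6),
         depth = trap_depth_kT * kT, width = 1.7, label = "trap")),
    lambda = 10, confinement_radius = 54)
}

# draw a state within `jitter` (configuration distance) of a center
jitter_state <- function(center_t, center_q, jitter, lambda) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2)) * 0.7 * jitter * stats::runif(1)^(1/3)
  ang <- 0.7 * jitter / lambda * stats::runif(1)
  dq <- quat_from_axis_angle(stats::rnorm(3), ang)
  rigid_body_state(center_t + u, quat_multiply(center_q, dq))
}

#' Build a labelled benchmark set of decoys
#'
#' Places rigid-body decoy poses on a landscape by ground-truth class and
#' renders them as structure models:
#'
#' * `native` -- at the native well center plus `jitter`;
#' * `funnel_interior` -- inside the native basin at 2-4 basin widths
#'   (configuration distance; the basin width is the funnel well's when
#'   one is present, else the native well's) from the center, the offset
#'   dominated by orientation with a modest translational component:
#'   poses far from the reference in RMSD that can still slide down the
#'   funnel, the way an anchored-but-tilted docking pose pivots home;
#' * `trap` -- at trap well centers (cycled) plus `jitter`;
#' * `unstable` -- uniform over the flat region, at least 5 widths from
#'   every well, with uniform random orientation.
#'
#' Deterministic for a given seed.  Model ids are ranks `r1`, `r2`, ...
#' in placement order; the rendered reference (`"xtal"`, the native well
#' center) is attached.
#'
#' @param ls a [landscape()].
#' @param n_per_class named integer vector with names among
#'   `native`, `funnel_interior`, `trap`, `unstable`.
#' @param jitter Angstrom, placement noise. Default 0.5.
#' @param seed integer seed.
#' @param params a [sim_params()] stored with the set.
#' @param schedule a [temperature_schedule()] stored with the set.
#' @param ligand,receptor rendering templates.
#' @return object of class `benchmark_set`: list with `models`,
#'   `states`, `truth_labels` (named character), `reference`,
#'   `landscape`, `params`, `schedule`.
#' @export
make_benchmark_set <- function(ls,
                               n_per_class = c(native = 1, funnel_interior = 2,
                                               trap = 3, unstable = 4),
                               jitter = 0.5, seed = 1L,
                               params = sim_params(),
                               schedule = ladder_schedule(),
                               ligand = default_ligand_template(),
                               receptor = default_receptor_template()) {
  stopifnot(inherits(ls, "landscape"))
  known <- c("native", "funnel_interior", "trap", "unstable")
  if (!length(n_per_class) || is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% known))
    stop("n_per_class names must be among: ", paste(known, collapse = ", "))
  traps <- trap_wells(ls)
  if ("trap" %in% names(n_per_class) && n_per_class[["trap"]] > 0 &&
      !length(traps))
    stop("trap decoys requested but the landscape has no trap well")
  nat <- native_well(ls)
  set.seed(as.integer(seed))
  states <- list(); labels <- character(0)
  for (cls in known) {
    n <- if (cls %in% names(n_per_class)) as.integer(n_per_class[[cls]]) else 0L
    if (n <= 0L) next
    for (i in seq_len(n)) {
      st <- switch(cls,
        native = jitter_state(nat$center_translation, nat$center_orientation,
                              jitter, ls$lambda),
        funnel_interior = {
          bw <- basin_well(ls)
          d <- stats::runif(1, 2 * bw$width, 4 * bw$width)
          f <- stats::runif(1, 0.15, 0.4)        # translation share
          dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
          th <- min(sqrt(1 - f^2) * d / ls$lambda, pi)
          dq <- quat_from_axis_angle(stats::rnorm(3), th)
          rigid_body_state(bw$center_translation + f * d * dir,
                           quat_multiply(bw$center_orientation, dq))
        },
        trap = {
          if (!length(traps)) stop("no trap well to place trap decoys on")
          tw <- traps[[(i - 1L) %% length(traps) + 1L]]
          jitter_state(tw$center_translation, tw$center_orientation,
                       jitter, ls$lambda)
        },
        unstable = {
          repeat {
            p <- stats::runif(3, -1, 1) * (ls$confinement_radius - 2)
            if (sqrt(sum(p^2)) > ls$confinement_radius - 2) next
            far <- all(vapply(ls$wells, function(w)
              sqrt(sum((p - w$center_translation)^2)) >= 5 * w$width,
              logical(1)))
            if (far) break
          }
          rigid_body_state(p, random_quaternion())
        })
      states[[length(states) + 1L]] <- st
      labels <- c(labels, cls)
    }
  }
  ids <- paste0("r", seq_along(states))
  names(states) <- ids
  models <- lapply(seq_along(states), function(i)
    render_model(states[[i]], ids[i], ligand, receptor))
  names(models) <- ids
  reference <- render_model(rigid_body_state(nat$center_translation,
                                             nat$center_orientation),
                            "xtal", ligand, receptor)
  structure(list(models = models, states = states,
                 truth_labels = setNames(labels, ids),
                 reference = reference, landscape = ls, params = params,
                 schedule = schedule, jitter = jitter,
                 seed = as.integer(seed),
                 ligand = ligand, receptor = receptor),
            class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat("benchmark_set:", length(x$models), "decoys (",
      paste(names(table(x$truth_labels)), table(x$truth_labels),
            sep = "=", collapse = ", "), ") seed", x$seed, "\n")
  invisible(x)
}

#' Simulate every decoy of a benchmark set
#'
#' Runs one trajectory per decoy under the set's schedule and parameters,
#' with per-model seeds `seed + index` so the set is reproducible as a
#' whole.
#'
#' @param bench a [make_benchmark_set()] result.
#' @return named list of [trajectory()] objects; use
#'   [simulate_trajectory()] directly if raw state paths are needed.
#' @export
simulate_benchmark <- function(bench) {
  stopifnot(inherits(bench, "benchmark_set"))
  out <- lapply(seq_along(bench$states), function(i) {
    simulate_trajectory(bench$states[[i]], bench$landscape, bench$params,
                        bench$schedule, model_id = names(bench$states)[i],
                        seed = bench$seed + i,
                        ligand = bench$ligand,
                        receptor = bench$receptor)$trajectory
  })
  names(out) <- names(bench$states)
  out
}

#' Replicate simulations and binding fraction
#'
#' Repeats a simulation from the same starting state with seeds
#' `base_seed, base_seed + 1, ..., base_seed + n - 1` and reports the
#' fraction of replicates showing a binding event against the reference
#' (RMSD entering and staying within the native band).  This is the
#' replicate-ensemble probe of kinetic proximity to the native state:
#' poses inside the funnel bind in a sizeable fraction of replicates,
#' matched-distance trapped poses do not.
#'
#' @param start a [rigid_body_state()].
#' @param ls a [landscape()].
#' @param params a [sim_params()].
#' @param schedule a [temperature_schedule()].
#' @param n number of replicates.
#' @param base_seed first seed.
#' @param reference reference [structure_model()]; default renders the
#'   native well center.
#' @param cfg an [assessment_config()] (native band, dwell).
#' @param ligand,receptor rendering templates.
#' @param keep_trajectories return the trajectory list (default TRUE;
#'   set FALSE to save memory in large sweeps).
#' @return list with `binding_fraction`, `binding_times` (ns, `NA` for
#'   non-binding replicates), and `trajectories`.
#' @export
run_replicates <- function(start, ls, params, schedule, n, base_seed,
                           reference = NULL, cfg = assessment_config(),
                           ligand = default_ligand_template(),
                           receptor = default_receptor_template(),
                           keep_trajectories = TRUE) {
  stopifnot(n >= 1)
  if (is.null(reference)) {
    nat <- native_well(ls)
    reference <- render_model(rigid_body_state(nat$center_translation,
                                               nat$center_orientation),
                              "xtal", ligand, receptor)
  }
  times <- numeric(n); trajs <- if (keep_trajectories) vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_trajectory(start, ls, params, schedule,
                               model_id = paste0("rep", i),
                               seed = base_seed + i - 1L,
                               ligand = ligand, receptor = receptor)
    ser <- rmsd_series(sim$trajectory, reference,
                       fit_sel = "chain A and name CA",
                       measure_sel = "name CA")
    times[i] <- detect_binding_event(ser, cfg)
    if (keep_trajectories) trajs[[i]] <- sim$trajectory
  }
  list(binding_fraction = mean(!is.na(times)), binding_times = times,
       trajectories = trajs)
}
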