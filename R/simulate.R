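#' Boltzmann constant in kcal/(mol K)
#'
#' Temperatures are quoted in K throughout, so the 303/333/363/390 K
#' ladder can be used verbatim; `kB * 303` is about 0.602 kcal/mol.
#' @export
kB <- 0.0019872041

#' Simulation parameters for the overdamped integrator
#'
#' First-order (Brownian) dynamics: per step the translation moves by
#' `-(dt/gamma_t) * grad U` plus Gaussian noise of variance
#' `2 kB T dt / gamma_t` per coordinate, and the orientation by the
#' analogous body-frame rotation-vector increment with `gamma_r`.  The
#' translational diffusion constant is `kB*T/gamma_t` (Angstrom^2/ns).
#'
#' @param dt integration step, ns. Default 5e-4.
#' @param gamma_t translational friction, kcal mol^-1 ns Angstrom^-2.
#'   Default 0.3 (diffusion constant ~2 Angstrom^2/ns at 303 K).
#' @param gamma_r rotational friction, kcal mol^-1 ns rad^-2.
#'   Default 0.7 (rotational diffusion ~0.86 rad^2/ns at 303 K).
#' @param seed integer RNG seed used by [simulate_trajectory()].
#' @param frames_per_save integration steps between saved frames.
#'   Default 200 (0.1 ns per frame at the default `dt`).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(dt = 5e-4, gamma_t = 0.3, gamma_r = 0.7, seed = 1L,
                       frames_per_save = 200L) {
  stopifnot(dt > 0, gamma_t > 0, gamma_r > 0, frames_per_save >= 1L)
  structure(list(dt = dt, gamma_t = gamma_t, gamma_r = gamma_r,
                 seed = as.integer(seed),
                 frames_per_save = as.integer(frames_per_save)),
            class = "sim_params")
}

# step-size validation: both the deterministic drift and the thermal noise
# amplitude per step (in the combined metric, so rotational noise counts as
# lambda * sigma) must stay below width/5 for the narrowest well, else the
# discrete update itself kicks walkers over barriers (max |grad| of a
# Gaussian well of depth D, width w is (D/w) exp(-1/2))
validate_step <- function(params, ls, temperature = 400) {
  noise_t <- sqrt(2 * kB * temperature * params$dt / params$gamma_t)
  noise_r <- ls$lambda * sqrt(2 * kB * temperature * params$dt / params$gamma_r)
  for (w in ls$wells) {
    max_force <- (w$depth / w$width) * exp(-0.5)
    drift <- params$dt / params$gamma_t * max_force
    if (drift >= w$width / 5)
      stop("dt too large: per-step drift ", format(drift, digits = 3),
           " A exceeds width/5 for the ", w$label, " well (width ",
           w$width, " A); reduce dt or widen the well")
    if (max(noise_t, noise_r) >= w$width / 5)
      stop("dt too large: per-step noise ",
           format(max(noise_t, noise_r), digits = 3),
           " A (combined metric, at ", temperature,
           " K) exceeds width/5 for the ", w$label, " well (width ",
           w$width, " A); reduce dt or increase friction")
  }
  invisible(TRUE)
}

#' One overdamped Langevin step
#'
#' Advances a state by a single integration step at fixed temperature,
#' using R's current RNG stream (call `set.seed()` for reproducibility).
#' [simulate_trajectory()] runs the same kernel over a whole schedule.
#'
#' @param state a [rigid_body_state()].
#' @param ls a [landscape()].
#' @param params a [sim_params()].
#' @param temperature K.
#' @return the advanced `rigid_body_state`.
#' @export
langevin_step <- function(state, ls, params, temperature) {
  validate_step(params, ls, temperature)
  ar <- landscape_arrays(ls)
  out <- cpp_langevin_run(state$translation, state$orientation,
                          ar$well_t, ar$well_q, ar$depth, ar$width,
                          ls$lambda, ls$confinement_radius, ls$wall_stiffness,
                          params$dt, params$gamma_t, params$gamma_r, kB,
                          temperature, 1L)
  rigid_body_state(out$translations[2, ], out$quaternions[2, ])
}

#' Pseudo-atom templates for rendering
#'
#' The receptor is a fixed hemispherical patch of 20 pseudo-atoms (lab
#' frame, chain A); the ligand is a non-planar 10-atom body-frame
#' template (chain B) whose inertia is non-degenerate, so orientation
#' differences register in RMSD.  Copies are shipped as PDB files under
#' `inst/extdata/` (`receptor_template.pdb`, `ligand_template.pdb`).
#'
#' @return N x 3 coordinate matrix, Angstrom.
#' @export
default_receptor_template <- function() {
  # 20 points, Fibonacci-spaced on the upper hemisphere of a sphere of
  # radius 10 centered 12 A below the origin, so the native ligand pose
  # (identity state) sits just above the patch
  n <- 20L
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- i / n                       # upper hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(10 * r * cos(phi), 10 * r * sin(phi), 10 * z - 12)
}

#' @rdname default_receptor_template
#' @export
default_ligand_template <- function() {
  # 10 points on a coarse helix, ~8 A extent, centered at the origin
  k <- seq_len(10L) - 1
  xyz <- cbind(3 * cos(0.9 * k), 3 * sin(0.9 * k), 0.9 * k)
  sweep(xyz, 2, colMeans(xyz))
}

#' Render a rigid-body state as a coordinate frame or model
#'
#' The ligand template is rotated by the state's orientation and moved by
#' its translation, then appended to the fixed receptor atoms.  Two
#' states at zero [configuration_distance()] render to identical frames,
#' and rendering the native well center reproduces the reference model
#' exactly.
#'
#' @param state a [rigid_body_state()].
#' @param ligand,receptor template coordinate matrices (body frame / lab
#'   frame), defaults from [default_ligand_template()] and
#'   [default_receptor_template()].
#' @return `render_frame`: an (Nrec + Nlig) x 3 coordinate matrix.
#' @export
render_frame <- function(state, ligand = default_ligand_template(),
                         receptor = default_receptor_template()) {
  R <- quat_to_matrix(state$orientation)
  lig <- sweep(ligand %*% t(R), 2, state$translation, "+")
  rbind(receptor, lig)
}

#' @rdname render_frame
#' @param model_id id for the rendered [structure_model()].
#' @return `render_model`: a `structure_model` (receptor chain A, resid
#'   1..Nrec; ligand chain B, resid 101..; all atoms named CA).
#' @export
render_model <- function(state, model_id, ligand = default_ligand_template(),
                         receptor = default_receptor_template()) {
  structure_model(model_id, template_atom_table(nrow(receptor), nrow(ligand)),
                  render_frame(state, ligand, receptor))
}

template_atom_table <- function(n_rec, n_lig) {
  data.frame(
    serial = seq_len(n_rec + n_lig),
    name = "CA",
    resname = "GLY",
    chain = c(rep("A", n_rec), rep("B", n_lig)),
    resid = c(seq_len(n_rec), 100L + seq_len(n_lig)),
    stringsAsFactors = FALSE)
}

#' Simulate a trajectory on a landscape
#'
#' Runs the overdamped rigid-body dynamics from `start` under the
#' temperature schedule, saving a frame every `frames_per_save` steps,
#' and renders the state path into a [trajectory()] through
#' [render_frame()].  Bit-for-bit reproducible for a given seed.
#'
#' @param start a [rigid_body_state()].
#' @param ls a [landscape()].
#' @param params a [sim_params()]; `params$seed` seeds R's RNG unless
#'   `seed` overrides it.
#' @param schedule a [temperature_schedule()].
#' @param model_id id for the resulting trajectory.
#' @param seed optional integer overriding `params$seed`.
#' @param ligand,receptor rendering templates.
#' @return list with `trajectory` (rendered [trajectory()]), `states`
#'   (list: `translations` F x 3, `quaternions` F x 4, `times` ns) and
#'   `final_state` (a [rigid_body_state()]).
#' @export
simulate_trajectory <- function(start, ls, params, schedule,
                                model_id = "sim", seed = NULL,
                                ligand = default_ligand_template(),
                                receptor = default_receptor_template()) {
  stopifnot(inherits(start, "rigid_body_state"), inherits(ls, "landscape"),
            inherits(params, "sim_params"),
            inherits(schedule, "temperature_schedule"))
  validate_step(params, ls, max(schedule$segments$temperature_K))
  nsteps_seg <- round(schedule$segments$duration_ns / params$dt)
  temps <- rep(schedule$segments$temperature_K, nsteps_seg)
  ar <- landscape_arrays(ls)
  set.seed(if (is.null(seed)) params$seed else seed)
  out <- cpp_langevin_run(start$translation, start$orientation,
                          ar$well_t, ar$well_q, ar$depth, ar$width,
                          ls$lambda, ls$confinement_radius, ls$wall_stiffness,
                          params$dt, params$gamma_t, params$gamma_r, kB,
                          temps, params$frames_per_save)
  nf <- nrow(out$translations)
  frame_spacing <- params$dt * params$frames_per_save
  frames <- lapply(seq_len(nf), function(i) {
    render_frame(rigid_body_state(out$translations[i, ],
                                  out$quaternions[i, ]),
                 ligand, receptor)
  })
  top <- structure_model(model_id,
                         template_atom_table(nrow(receptor), nrow(ligand)),
                         frames[[1L]])
  traj <- trajectory(model_id, frames, frame_spacing, schedule, top)
  list(trajectory = traj,
       states = list(translations = out$translations,
                     quaternions = out$quaternions,
                     times = (seq_len(nf) - 1) * frame_spacing),
       final_state = rigid_body_state(out$translations[nf, ],
                                      out$quaternions[nf, ]))
}
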