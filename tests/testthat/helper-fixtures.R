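# shared fixtures built in code

# 3-residue toy model, chains A/B, backbone-ish atoms
toy_model <- function(id = "toy") {
  atoms <- data.frame(
    serial = 1:6,
    name = c("N", "CA", "CA", "CB", "CA", "O"),
    resname = c("ALA", "ALA", "GLY", "GLY", "SER", "SER"),
    chain = c("A", "A", "A", "A", "B", "B"),
    resid = c(1L, 1L, 2L, 2L, 3L, 3L),
    stringsAsFactors = FALSE)
  xyz <- matrix(c(0, 0, 0,   1.5, 0, 0,   3, 1, 0,
                  3, 2.5, 1, 5, 1, 2,    6, 1, 2), ncol = 3, byrow = TRUE)
  structure_model(id, atoms, xyz)
}

random_rotation <- function() quat_to_matrix(quat_normalize(stats::rnorm(4)))

# rmsd_series object from raw vectors (for classifier unit tests)
make_series <- function(values, spacing = 1, model_id = "m",
                        reference_id = "ref") {
  structure(list(times = (seq_along(values) - 1) * spacing,
                 values = values, model_id = model_id,
                 reference_id = reference_id,
                 fit_selection = "name CA", measure_selection = "name CA"),
            class = "rmsd_series")
}

# trajectory whose ligand follows a prescribed path of rigid-body states
states_trajectory <- function(states, frame_spacing, schedule, id = "traj") {
  frames <- lapply(states, render_frame)
  top <- render_model(states[[1L]], id)
  trajectory(id, frames, frame_spacing, schedule, top)
}

# small fast landscape for simulator tests: one native, one funnel,
# one trap, desk-scale
test_landscape <- function() {
  kT <- kB * 303
  landscape(list(
    well(c(0, 0, 0), c(1, 0, 0, 0), depth = 28 * kT, width = 2.5,
         label = "native"),
    well(c(0, 0, 0), c(1, 0, 0, 0), depth = 13 * kT, width = 7,
         label = "funnel"),
    well(c(20, 0, 0), quat_from_axis_angle(c(0, 0, 1), 2.0),
         depth = 19 * kT, width = 1.7, label = "trap")),
    lambda = 10, confinement_radius = 42)
}
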