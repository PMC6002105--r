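#' Quaternion utilities
#'
#' Orientations are unit quaternions in scalar-first convention,
#' canonicalized to a non-negative scalar part.  `quat_angle` is the
#' geodesic rotation angle between two orientations, computed as
#' `2*acos(|<q1,q2>|)` so the double cover (`q` and `-q` encode the same
#' rotation) collapses to zero distance.
#'
#' @param q,q1,q2 length-4 numeric quaternions.
#' @return `quat_normalize`/`quat_multiply`/`quat_from_axis_angle`:
#'   quaternions; `quat_angle`: radians in `[0, pi]`;
#'   `quat_to_matrix`: a 3 x 3 rotation matrix.
#' @name quaternions
NULL

#' @rdname quaternions
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-300) stop("zero quaternion")
  q <- q / n
  if (q[1] < 0) q <- -q
  q
}

#' @rdname quaternions
#' @export
quat_multiply <- function(q1, q2) {
  c(q1[1]*q2[1] - q1[2]*q2[2] - q1[3]*q2[3] - q1[4]*q2[4],
    q1[1]*q2[2] + q1[2]*q2[1] + q1[3]*q2[4] - q1[4]*q2[3],
    q1[1]*q2[3] - q1[2]*q2[4] + q1[3]*q2[1] + q1[4]*q2[2],
    q1[1]*q2[4] + q1[2]*q2[3] - q1[3]*q2[2] + q1[4]*q2[1])
}

#' @rdname quaternions
#' @param axis length-3 rotation axis (need not be normalized).
#' @param angle rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-14) return(c(1, 0, 0, 0))
  axis <- axis / n
  quat_normalize(c(cos(angle / 2), sin(angle / 2) * axis))
}

#' @rdname quaternions
#' @export
quat_angle <- function(q1, q2) {
  d <- abs(sum(q1 * q2) / sqrt(sum(q1^2) * sum(q2^2)))
  2 * acos(pmin(1, d))
}

#' @rdname quaternions
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Uniform random unit quaternion
#' @return length-4 canonical unit quaternion (uses R's RNG).
#' @export
random_quaternion <- function() {
  quat_normalize(stats::rnorm(4))
}

#' Rigid-body state of the ligand
#'
#' @param translation length-3 numeric, Angstrom (lab frame).
#' @param orientation length-4 unit quaternion (normalized and
#'   canonicalized on construction).
#' @return object of class `rigid_body_state`.
#' @export
rigid_body_state <- function(translation = c(0, 0, 0),
                             orientation = c(1, 0, 0, 0)) {
  stopifnot(length(translation) == 3L, length(orientation) == 4L)
  structure(list(translation = as.numeric(translation),
                 orientation = quat_normalize(as.numeric(orientation))),
            class = "rigid_body_state")
}

#' An attractive well on the landscape
#'
#' Gaussian well in the combined translation-orientation metric: its
#' contribution to the potential is `-depth * exp(-d^2 / (2 width^2))`
#' with `d` the [configuration_distance()] to the well center.
#'
#' @param center_translation length-3, Angstrom.
#' @param center_orientation unit quaternion.
#' @param depth kcal/mol, > 0.
#' @param width Angstrom, > 0.
#' @param label `"native"` (the bound minimum, exactly one per
#'   landscape), `"trap"` (a wrong metastable site), or `"funnel"` (a
#'   broad shallow basin, typically co-centered with the native well,
#'   that gives the bound state its long-range funnel).
#' @return object of class `landscape_well`.
#' @export
well <- function(center_translation, center_orientation = c(1, 0, 0, 0),
                 depth, width, label = c("trap", "native", "funnel")) {
  label <- match.arg(label)
  if (depth <= 0) stop("well depth must be > 0")
  if (width <= 0) stop("well width must be > 0")
  structure(list(center_translation = as.numeric(center_translation),
                 center_orientation = quat_normalize(center_orientation),
                 depth = depth, width = width, label = label),
            class = "landscape_well")
}

#' A surrogate free-energy landscape
#'
#' A set of attractive Gaussian wells (exactly one labelled `native`)
#' plus a soft quartic confinement wall that keeps the ligand in a finite
#' box, so even unbound poses remain analysable.  States with low energy
#' but no confining barrier simply diffuse; deep narrow wells act as
#' kinetic traps; the broad native well is the funnel.
#'
#' @param wells list of [well()] objects, exactly one `native`.
#' @param lambda orientation length scale, Angstrom per radian; converts
#'   rotation angles into the common distance metric. Default 10.
#' @param confinement_radius Angstrom; must exceed the farthest well
#'   center by at least three maximal widths.
#' @param wall_stiffness kcal/mol/Angstrom^4 quartic wall constant,
#'   default 1.
#' @return object of class `landscape`.
#' @export
landscape <- function(wells, lambda = 10, confinement_radius,
                      wall_stiffness = 1) {
  if (inherits(wells, "landscape_well")) wells <- list(wells)
  labs <- vapply(wells, function(w) w$label, character(1))
  if (sum(labs == "native") != 1L)
    stop("landscape needs exactly one native well (got ",
         sum(labs == "native"), ")")
  if (lambda <= 0) stop("lambda must be > 0")
  dmax <- max(vapply(wells, function(w) sqrt(sum(w$center_translation^2)),
                     numeric(1)))
  wmax <- max(vapply(wells, function(w) w$width, numeric(1)))
  if (confinement_radius <= dmax + 3 * wmax)
    stop("confinement_radius (", confinement_radius,
         ") must exceed the farthest well center plus 3 widths (",
         dmax + 3 * wmax, ")")
  structure(list(wells = wells, lambda = lambda,
                 confinement_radius = confinement_radius,
                 wall_stiffness = wall_stiffness),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("landscape:", length(x$wells), "wells, lambda =", x$lambda,
      "A/rad, confinement", x$confinement_radius, "A\n")
  for (w in x$wells)
    cat(sprintf("  %-6s depth %.2f kcal/mol, width %.2f A, center (%s)\n",
                w$label, w$depth, w$width,
                paste(format(w$center_translation, digits = 3),
                      collapse = ", ")))
  invisible(x)
}

# matrix forms consumed by the C++ kernels
landscape_arrays <- function(ls) {
  list(well_t = do.call(rbind, lapply(ls$wells, `[[`, "center_translation")),
       well_q = do.call(rbind, lapply(ls$wells, `[[`, "center_orientation")),
       depth = vapply(ls$wells, `[[`, numeric(1), "depth"),
       width = vapply(ls$wells, `[[`, numeric(1), "width"))
}

native_well <- function(ls) {
  ls$wells[[which(vapply(ls$wells, function(w) w$label, character(1)) ==
                    "native")]]
}

trap_wells <- function(ls) {
  ls$wells[vapply(ls$wells, function(w) w$label, character(1)) == "trap"]
}

# the well defining the native basin's extent: the broad funnel well when
# present, else the native well itself
basin_well <- function(ls) {
  labs <- vapply(ls$wells, function(w) w$label, character(1))
  if (any(labs == "funnel")) {
    fw <- ls$wells[labs == "funnel"]
    fw[[which.max(vapply(fw, `[[`, numeric(1), "width"))]]
  } else native_well(ls)
}

#' Combined translation-orientation distance
#'
#' `sqrt(|t1 - t2|^2 + (lambda * theta)^2)` where `theta` is the geodesic
#' rotation angle between the orientations.  Symmetric, zero iff the two
#' states coincide up to quaternion sign.
#'
#' @param q1,q2 [rigid_body_state()] objects.
#' @param lambda Angstrom per radian.
#' @return distance in Angstrom.
#' @export
configuration_distance <- function(q1, q2, lambda = 10) {
  th <- quat_angle(q1$orientation, q2$orientation)
  sqrt(sum((q1$translation - q2$translation)^2) + (lambda * th)^2)
}

#' Potential energy and gradient on a landscape
#'
#' `potential_energy` evaluates the landscape potential (wells + wall) at
#' a state; `potential_gradient` additionally returns the analytic
#' gradient with respect to the translation and to a body-frame rotation
#' vector increment (the coordinates the integrator steps in).
#'
#' @param state a [rigid_body_state()].
#' @param ls a [landscape()].
#' @return `potential_energy`: kcal/mol. `potential_gradient`: list with
#'   `energy`, `translation` (kcal/mol/Angstrom, length 3) and `rotation`
#'   (kcal/mol/radian, length 3).
#' @export
potential_energy <- function(state, ls) {
  ar <- landscape_arrays(ls)
  cpp_potential(state$translation, state$orientation, ar$well_t, ar$well_q,
                ar$depth, ar$width, ls$lambda, ls$confinement_radius,
                ls$wall_stiffness)
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(state, ls) {
  ar <- landscape_arrays(ls)
  cpp_gradient(state$translation, state$orientation, ar$well_t, ar$well_q,
               ar$depth, ar$width, ls$lambda, ls$confinement_radius,
               ls$wall_stiffness)
}

#' Read/write a landscape specification file
#'
#' YAML document with top-level `lambda`, `confinement_radius`, optional
#' `wall_stiffness`, and a `wells` list whose entries have
#' `center` (3 numbers), optional `orientation` (4 numbers, quaternion),
#' `depth`, `width` and `label`.
#'
#' @param path file path.
#' @return `read_landscape`: a [landscape()].
#' @export
read_landscape <- function(path) {
  if (!file.exists(path)) stop("no such landscape file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$wells) || !length(y$wells))
    stop("landscape file has no wells: ", path)
  wl <- lapply(y$wells, function(w) {
    well(center_translation = as.numeric(w$center),
         center_orientation = if (is.null(w$orientation)) c(1, 0, 0, 0)
                              else as.numeric(w$orientation),
         depth = as.numeric(w$depth), width = as.numeric(w$width),
         label = w$label)
  })
  landscape(wl, lambda = as.numeric(y$lambda),
            confinement_radius = as.numeric(y$confinement_radius),
            wall_stiffness = if (is.null(y$wall_stiffness)) 1
                             else as.numeric(y$wall_stiffness))
}

#' @rdname read_landscape
#' @param ls a [landscape()].
#' @export
write_landscape <- function(ls, path) {
  y <- list(lambda = ls$lambda, confinement_radius = ls$confinement_radius,
            wall_stiffness = ls$wall_stiffness,
            wells = lapply(ls$wells, function(w)
              list(center = as.numeric(w$center_translation),
                   orientation = as.numeric(w$center_orientation),
                   depth = w$depth, width = w$width, label = w$label)))
  yaml::write_yaml(y, path)
  invisible(path)
}
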