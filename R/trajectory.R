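#' Construct a trajectory
#'
#' Ordered coordinate frames for one model, with a fixed frame spacing
#' (ns per saved frame) and an attached [temperature_schedule()].  Frame 0
#' is the starting structure; frame times are `index * frame_spacing`.
#'
#' @param model_id character scalar.
#' @param frames list of N x 3 coordinate matrices, all matching the atom
#'   count of `topology`.
#' @param frame_spacing ns between saved frames (> 0).
#' @param schedule a [temperature_schedule()] covering the frames (at most
#'   one frame_spacing of slack past the schedule end is allowed).
#' @param topology a [structure_model()] giving atom identities.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(model_id, frames, frame_spacing, schedule, topology) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            inherits(schedule, "temperature_schedule"),
            inherits(topology, "structure_model"))
  if (frame_spacing <= 0) stop("frame_spacing must be > 0")
  n <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L || nrow(f) != n)
      stop("frame ", i - 1L, " has wrong shape (expected ", n, " x 3)")
    if (!all(is.finite(f))) stop("non-finite coordinates in frame ", i - 1L)
  }
  span <- length(frames) * frame_spacing
  if (span > schedule$total_ns + frame_spacing + 1e-9)
    stop("trajectory (", span, " ns) overruns its schedule (",
         schedule$total_ns, " ns)")
  structure(list(model_id = model_id, frames = frames,
                 frame_spacing = frame_spacing, schedule = schedule,
                 topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory '", x$model_id, "': ", length(x$frames), " frames x ",
      n_atoms(x$topology), " atoms, ", x$frame_spacing, " ns/frame (",
      (length(x$frames) - 1L) * x$frame_spacing, " ns)\n", sep = "")
  invisible(x)
}

#' Frame times of a trajectory
#' @param traj a [trajectory()].
#' @return numeric vector of frame times in ns (frame index x spacing).
#' @export
frame_times <- function(traj) {
  (seq_along(traj$frames) - 1) * traj$frame_spacing
}

#' Read a plain-text trajectory table
#'
#' The table dialect is one row per atom per frame, whitespace- or
#' comma-separated, with a header line and columns
#' `frame` (0-based, contiguous), `atom` (1-based, 1..N within each
#' frame), `x`, `y`, `z` (Angstrom).  Comment lines starting with `#`
#' are ignored.
#'
#' @param path file path.
#' @param topology [structure_model()] the frames refer to.
#' @param frame_spacing ns per frame.
#' @param schedule attached [temperature_schedule()].
#' @return a [trajectory()].
#' @export
read_trajectory_table <- function(path, topology, frame_spacing, schedule) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")]
  sep <- if (length(first) && any(grepl(",", first, fixed = TRUE))) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE)
  req <- c("frame", "atom", "x", "y", "z")
  if (!all(req %in% names(tab)))
    stop("format error: trajectory table needs columns ",
         paste(req, collapse = ", "))
  if (!nrow(tab)) stop("format error: empty trajectory table ", path)
  n <- n_atoms(topology)
  if (nrow(tab) %% n != 0L)
    stop("format error: ragged table (", nrow(tab),
         " rows is not a multiple of ", n, " atoms)")
  nframes <- nrow(tab) %/% n
  fr <- sort(unique(tab$frame))
  if (!identical(as.integer(fr), seq_len(nframes) - 1L))
    stop("format error: frame indices must be contiguous from 0 (got ",
         paste(utils::head(fr, 8L), collapse = ","), " ...)")
  tab <- tab[order(tab$frame, tab$atom), , drop = FALSE]
  frames <- lapply(seq_len(nframes) - 1L, function(f) {
    blk <- tab[tab$frame == f, , drop = FALSE]
    if (nrow(blk) != n || !identical(as.integer(blk$atom), seq_len(n)))
      stop("format error: frame ", f, " does not list atoms 1..", n)
    unname(as.matrix(blk[, c("x", "y", "z")]))
  })
  trajectory(sub("\\.[^.]*$", "", basename(path)), frames, frame_spacing,
             schedule, topology)
}

#' Write a trajectory as a plain-text table
#'
#' Inverse of [read_trajectory_table()]; coordinates are written with six
#' significant decimals.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(traj, path) {
  n <- n_atoms(traj$topology)
  nf <- length(traj$frames)
  tab <- data.frame(
    frame = rep(seq_len(nf) - 1L, each = n),
    atom  = rep(seq_len(n), nf),
    do.call(rbind, traj$frames))
  names(tab)[3:5] <- c("x", "y", "z")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# trajectory '", traj$model_id, "', frame_spacing_ns=",
                    traj$frame_spacing, ", units Angstrom"), con)
  utils::write.table(format(tab, digits = 6, scientific = FALSE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' Coordinates of the final saved frame
#' @param traj a [trajectory()].
#' @return N x 3 matrix.
#' @export
last_frame <- function(traj) traj$frames[[length(traj$frames)]]

# structure_model view of a trajectory frame
frame_model <- function(traj, i, id = NULL) {
  if (is.null(id)) id <- paste0(traj$model_id, "@", i - 1L)
  structure_model(id, traj$topology$atoms, traj$frames[[i]])
}
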