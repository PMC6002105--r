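#' Read a multi-model PDB file
#'
#' Reads a PDB file holding one or more MODEL/ENDMDL blocks (or a single
#' bare structure) into a list of [structure_model()] objects, one per
#' model, with atom order preserved.  Coordinates are taken from the fixed
#' PDB columns and are in Angstrom.  All models in a file must share the
#' same atom count; a mismatch is reported as a format error rather than
#' silently truncated.  Alternate locations other than blank or "A" are
#' dropped with a warning; no occupancy or header chemistry is interpreted.
#'
#' Parsing is delegated to [bio3d::read.pdb()] after a strict structural
#' scan of the raw lines (model block sizes, coordinate fields).
#'
#' @param path path to a PDB file.
#' @return list of `structure_model`; names are the model ids
#'   (`MODEL` serial numbers as `"1"`, `"2"`, ... or the file stem for a
#'   bare structure).
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("format error: no ATOM records in ", path)

  # coordinate fields must be numeric in the fixed columns 31-54
  atom_idx <- which(is_atom)
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    v <- suppressWarnings(as.numeric(substr(lines[atom_idx], fld[1], fld[2])))
    if (anyNA(v))
      stop("format error: unparseable ATOM line ", atom_idx[which(is.na(v))[1]],
           " in ", path, " (coordinate columns ", fld[1], "-", fld[2], ")")
  }

  # model block structure: equal atom counts across MODEL/ENDMDL blocks
  model_starts <- which(substr(lines, 1, 5) == "MODEL")
  if (length(model_starts) > 0L) {
    block <- findInterval(atom_idx, model_starts)
    if (any(block == 0L))
      stop("format error: ATOM records before the first MODEL line in ", path)
    counts <- tabulate(block, nbins = length(model_starts))
    if (length(unique(counts)) != 1L)
      stop("format error: topology mismatch across models in ", path,
           " (atom counts ", paste(counts, collapse = ", "), ")")
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " alternate-location atoms (altloc != 'A') in ",
            path)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nmod <- nrow(xyz)
  atoms <- data.frame(serial  = at$eleno[keep],
                      name    = at$elety[keep],
                      resname = at$resid[keep],
                      chain   = at$chain[keep],
                      resid   = at$resno[keep],
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  col_keep <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                              3 * which(keep)))
  ids <- if (length(model_starts) > 0L) {
    as.character(seq_len(nmod))
  } else sub("\\.pdb$", "", basename(path))
  models <- lapply(seq_len(nmod), function(i) {
    structure_model(ids[i], atoms,
                    matrix(xyz[i, col_keep], ncol = 3, byrow = TRUE))
  })
  names(models) <- ids
  models
}

#' Write models to a multi-model PDB file
#'
#' Serializes a list of topology-sharing [structure_model()] objects as a
#' MODEL/ENDMDL multi-model PDB with 3-decimal coordinates (the PDB column
#' precision), so that `read_multimodel_pdb(write_multimodel_pdb(x))`
#' reproduces coordinates to 0.001 Angstrom.
#'
#' @param models list of `structure_model`, all sharing topology.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(models, path) {
  if (!length(models)) stop("empty model list")
  if (inherits(models, "structure_model")) models <- list(models)
  top <- models[[1L]]
  for (m in models[-1L]) {
    if (!same_topology(top, m))
      stop("heterogeneous topologies: '", m$model_id,
           "' does not match '", top$model_id, "'")
  }
  xyz <- do.call(rbind, lapply(models, function(m) as.vector(t(m$xyz))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   eleno = top$atoms$serial, elety = top$atoms$name,
                   resid = top$atoms$resname, chain = top$atoms$chain,
                   resno = top$atoms$resid)
  invisible(path)
}
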