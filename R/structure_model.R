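#' Construct a structure model
#'
#' A `structure_model` is one labelled pose of the complex: an atom table
#' (identity) plus an N x 3 coordinate matrix in Angstrom.  Atom order is
#' the canonical correspondence used for RMSD: two models with identical
#' topology are compared index-wise after selection.
#'
#' @param model_id character scalar naming the pose (e.g. `"r37"`, `"xtal"`).
#' @param atoms data frame with columns `serial` (positive integer),
#'   `name` (atom name, e.g. `"CA"`), `resname` (3-letter residue code),
#'   `chain` (1-character chain id), `resid` (integer residue number,
#'   1-based PDB convention).
#' @param xyz numeric N x 3 matrix of coordinates in Angstrom.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(model_id, atoms, xyz) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("serial", "name", "resname", "chain", "resid")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L)
    stop("xyz must be a numeric N x 3 matrix")
  if (nrow(xyz) != nrow(atoms))
    stop("atom table (", nrow(atoms), " rows) and xyz (", nrow(xyz),
         " rows) disagree")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in model '", model_id, "'")
  if (any(!nzchar(atoms$name))) stop("empty atom name in model '", model_id, "'")
  if (any(atoms$resid < 1L)) stop("resid must be >= 1 (1-based PDB numbering)")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, name) triple in model '", model_id, "': ",
         key[duplicated(key)][1L])
  structure(list(model_id = model_id, atoms = atoms, xyz = xyz),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model '", x$model_id, "': ", nrow(x$atoms), " atoms, chains ",
      paste(unique(x$atoms$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `structure_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

# TRUE when two models share (chain, resid, name) sequences index-wise.
same_topology <- function(a, b) {
  nrow(a$atoms) == nrow(b$atoms) &&
    all(a$atoms$chain == b$atoms$chain) &&
    all(a$atoms$resid == b$atoms$resid) &&
    all(a$atoms$name  == b$atoms$name)
}

#' Establish atom correspondence between two models
#'
#' Returns index vectors `ia`, `ib` such that `a$xyz[ia, ]` and
#' `b$xyz[ib, ]` are matched atom-for-atom.  Identical topologies match
#' index-wise; otherwise atoms are matched by their (chain, resid, name)
#' triple, and any atom without a partner is an error -- a silent
#' intersection would corrupt every downstream RMSD.
#'
#' @param a,b `structure_model` objects.
#' @return list with integer vectors `ia` and `ib`.
#' @export
atom_correspondence <- function(a, b) {
  if (same_topology(a, b)) {
    n <- nrow(a$atoms)
    return(list(ia = seq_len(n), ib = seq_len(n)))
  }
  ka <- paste(a$atoms$chain, a$atoms$resid, a$atoms$name)
  kb <- paste(b$atoms$chain, b$atoms$resid, b$atoms$name)
  ib <- match(ka, kb)
  if (anyNA(ib) || length(ka) != length(kb))
    stop("atom correspondence failure between '", a$model_id, "' and '",
         b$model_id, "': topologies do not match atom-for-atom")
  list(ia = seq_along(ka), ib = ib)
}
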