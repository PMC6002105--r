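#' Atom selections
#'
#' Selections are written in a small expression grammar of clauses joined
#' by `and`:
#'
#' * `chain <id>` -- one-character chain identifier, e.g. `chain A`
#' * `name <atom>` -- atom name, e.g. `name CA`
#' * `resid <n>` or `resid <a>-<b>` -- residue number or closed range
#'   (1-based PDB numbering; `resid 2-3` includes both ends)
#' * `all` -- every atom
#'
#' `parse_selection` compiles an expression into a predicate object;
#' parsing is total -- an expression either compiles or raises a parse
#' error naming the offending clause position.  The same expression
#' applied to the same topology is deterministic, and applied to two
#' models with identical topology yields index-aligned atom lists.
#'
#' @param expression selection string, e.g. `"chain A and name CA"`.
#' @return `parse_selection`: an object of class `atom_selection`.
#' @export
parse_selection <- function(expression) {
  if (inherits(expression, "atom_selection")) return(expression)
  stopifnot(is.character(expression), length(expression) == 1L)
  txt <- trimws(expression)
  if (!nzchar(txt)) stop("selection parse error: empty expression")
  clause_txt <- trimws(strsplit(txt, "\\band\\b")[[1L]])
  clauses <- vector("list", length(clause_txt))
  for (i in seq_along(clause_txt)) {
    cl <- clause_txt[i]
    if (!nzchar(cl))
      stop("selection parse error at clause ", i, ": empty clause in '",
           expression, "'")
    toks <- strsplit(cl, "[[:space:]]+")[[1L]]
    kw <- toks[1L]
    if (kw == "all" && length(toks) == 1L) {
      clauses[[i]] <- list(kind = "all")
    } else if (kw == "chain" && length(toks) == 2L && nchar(toks[2L]) == 1L) {
      clauses[[i]] <- list(kind = "chain", value = toks[2L])
    } else if (kw == "name" && length(toks) == 2L) {
      clauses[[i]] <- list(kind = "name", value = toks[2L])
    } else if (kw == "resid" && length(toks) == 2L) {
      rng <- strsplit(toks[2L], "-", fixed = TRUE)[[1L]]
      nums <- suppressWarnings(as.integer(rng))
      if (anyNA(nums) || !length(nums) %in% 1:2 || any(nums < 1L))
        stop("selection parse error at clause ", i, ": bad residue range '",
             toks[2L], "'")
      if (length(nums) == 2L && nums[1L] > nums[2L])
        stop("selection parse error at clause ", i, ": descending range '",
             toks[2L], "'")
      clauses[[i]] <- list(kind = "resid", lo = nums[1L],
                           hi = nums[length(nums)])
    } else {
      stop("selection parse error at clause ", i, ": cannot parse '", cl, "'")
    }
  }
  structure(list(expression = expression, clauses = clauses),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection:", x$expression, "\n")
  invisible(x)
}

#' @rdname parse_selection
#' @param model a [structure_model()] (or trajectory topology).
#' @param sel an `atom_selection` or a selection string.
#' @return `select_atoms`: integer vector of atom indices in ascending
#'   order.  An empty result is an error, never a silent empty vector.
#' @examples
#' \dontrun{select_atoms(model, "chain A and name CA")}
#' @export
select_atoms <- function(model, sel) {
  sel <- parse_selection(sel)
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  for (cl in sel$clauses) {
    keep <- keep & switch(cl$kind,
      all   = TRUE,
      chain = at$chain == cl$value,
      name  = at$name == cl$value,
      resid = at$resid >= cl$lo & at$resid <= cl$hi)
  }
  idx <- which(keep)
  if (!length(idx))
    stop("empty selection: '", sel$expression, "' matches no atoms in model '",
         model$model_id, "'")
  idx
}
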