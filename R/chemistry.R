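# Low-level cheminformatics helpers. All SMILES parsing, canonicalisation and
# property calculation is delegated to Open Babel (through ChemmineR /
# ChemmineOB); this file adds vectorised wrappers, molecular-formula
# arithmetic, and the atom/bond table extraction used by the graft editor.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical form. Invalid strings yield `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' canonical_smiles(c("OCC", "C1=CC=CC=C1"))
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    res <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    res <- sub("[\t\n].*$", "", res)
    if (!nzchar(res)) NA_character_ else res
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Test SMILES validity
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector; `TRUE` where the string parses to a molecule.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

#' Molecular formula of SMILES strings
#'
#' @param smiles Character vector of SMILES. Dummy atoms (`*`) contribute no
#'   element counts.
#' @return Character vector of Hill-order molecular formulas.
#' @export
mol_formula <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  names(smiles) <- paste0("m", seq_along(smiles))
  sdf <- ChemmineR::smiles2sdf(smiles)
  props <- ChemmineR::propOB(sdf)
  as.character(props$formula)
}

# -- molecular-formula arithmetic ------------------------------------------

#' Parse a molecular formula into element counts
#'
#' @param formula A single formula string such as `"C2H5NO2"`.
#' @return Named integer vector of element counts.
#' @export
formula_counts <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("malformed molecular formula: ", formula)
  }
  elems <- sub("[0-9]+$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  tapply(counts, elems, sum)[unique(elems)]
}

#' Render element counts as a Hill-order formula string
#'
#' Carbon first, hydrogen second, remaining elements alphabetical; zero
#' counts dropped.
#'
#' @param counts Named numeric vector of element counts.
#' @return A formula string.
#' @export
formula_string <- function(counts) {
  counts <- counts[counts > 0]
  elems <- names(counts)
  ord <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    n <- counts[[e]]
    if (n == 1) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' Add or subtract molecular formulas
#'
#' @param ... Formula strings to sum.
#' @param subtract Optional character vector of formula strings to subtract.
#' @return A Hill-order formula string.
#' @examples
#' formula_combine("C2H5NO2", "C2H5NO2", subtract = "H2O")
#' @export
formula_combine <- function(..., subtract = character(0)) {
  add <- unlist(list(...))
  all_elems <- character(0)
  pos <- lapply(add, formula_counts)
  neg <- lapply(subtract, formula_counts)
  for (x in c(pos, neg)) all_elems <- union(all_elems, names(x))
  tot <- stats::setNames(numeric(length(all_elems)), all_elems)
  for (x in pos) tot[names(x)] <- tot[names(x)] + x
  for (x in neg) tot[names(x)] <- tot[names(x)] - x
  if (any(tot < 0)) stop("formula subtraction yields negative element count")
  formula_string(tot)
}

#' Heavy-atom count of a SMILES string
#'
#' Counts non-hydrogen atoms; dummy atoms (`*`) are excluded.
#'
#' @param smiles A single SMILES string.
#' @return Integer heavy-atom count.
#' @export
heavy_atom_count <- function(smiles) {
  g <- smiles_graph(smiles)
  sum(g$atoms != "*")
}

# -- molecular graphs -------------------------------------------------------

# Atom/bond table of a molecule; atoms keep SMILES order of appearance.
# Returns list(atoms = element symbols, bonds = data.frame(a1, a2, order)).
smiles_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- sub("_[0-9]+$", "", rownames(ab))
  bonds <- if (nrow(bb) > 0) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  list(atoms = atoms, bonds = bonds)
}

# Serialize an atom/bond table as a V2000 molfile (zero coordinates) and
# return the Open Babel canonical SMILES of the molecule it encodes.
graph_to_smiles <- function(atoms, bonds) {
  stopifnot(length(atoms) >= 1L, length(atoms) <= 999L)
  header <- c("mol", "  chemspan", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    length(atoms), nrow(bonds))
  atom_lines <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    atoms)
  bond_lines <- if (nrow(bonds) > 0) {
    sprintf("%3d%3d%3d  0", bonds$a1, bonds$a2, bonds$order)
  } else character(0)
  mol <- paste(c(header, counts, atom_lines, bond_lines, "M  END", "$$$$", ""),
               collapse = "\n")
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", mol)),
    error = function(e) ""
  )
  res <- sub("[\t\n].*$", "", res)
  if (!nzchar(res)) stop("graph could not be rendered as a valid molecule")
  res
}

# Remove tetrahedral/double-bond stereo annotations from a SMILES string.
strip_stereo_smiles <- function(smiles) {
  s <- gsub("[/\\\\]", "", smiles)
  s <- gsub("@{1,2}", "", s)
  # collapse [CH] left behind by stereocentre removal; for a carbon with
  # three heavy neighbours the asserted H count equals the implicit one
  gsub("\\[CH\\]", "C", s)
}
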