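# Amino-acid and peptide chemistry on SMILES strings. Residue SMILES are
# written backbone-first (N, C-alpha, side chain, carboxyl) so that atom
# indices are stable and the trailing hydroxyl oxygen can be dropped during
# peptide condensation. L-configuration stereocentres are encoded; a strip
# flag removes them.

# code, L-amino-acid SMILES (backbone-first atom order), free-residue
# molecular formula, side-chain attachment atom for covalent grafting
# (1-based index in order of SMILES appearance; NA when not graftable)
# and its element symbol.
AMINO_ACID_TABLE <- data.frame(
  code = c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  smiles = c(
    "N[C@@H](C)C(=O)O",                    # A
    "N[C@@H](CCCN=C(N)N)C(=O)O",           # R
    "N[C@@H](CC(=O)N)C(=O)O",              # N
    "N[C@@H](CC(=O)O)C(=O)O",              # D
    "N[C@@H](CS)C(=O)O",                   # C
    "N[C@@H](CCC(=O)O)C(=O)O",             # E
    "N[C@@H](CCC(=O)N)C(=O)O",             # Q
    "NCC(=O)O",                            # G
    "N[C@@H](Cc1c[nH]cn1)C(=O)O",          # H
    "N[C@@H]([C@@H](C)CC)C(=O)O",          # I
    "N[C@@H](CC(C)C)C(=O)O",               # L
    "N[C@@H](CCCCN)C(=O)O",                # K
    "N[C@@H](CCSC)C(=O)O",                 # M
    "N[C@@H](Cc1ccccc1)C(=O)O",            # F
    "N1CCC[C@H]1C(=O)O",                   # P
    "N[C@@H](CO)C(=O)O",                   # S
    "N[C@@H]([C@H](O)C)C(=O)O",            # T
    "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O",    # W
    "N[C@@H](Cc1ccc(O)cc1)C(=O)O",         # Y
    "N[C@@H](C(C)C)C(=O)O"                 # V
  ),
  formula = c("C3H7NO2", "C6H14N4O2", "C4H8N2O3", "C4H7NO4", "C3H7NO2S",
              "C5H9NO4", "C5H10N2O3", "C2H5NO2", "C6H9N3O2", "C6H13NO2",
              "C6H13NO2", "C6H14N2O2", "C5H11NO2S", "C9H11NO2", "C5H9NO2",
              "C3H7NO3", "C4H9NO3", "C11H12N2O2", "C9H11NO3", "C5H11NO2"),
  # Cys S-gamma; Lys N-zeta; Ser/Thr/Tyr hydroxyl O; His N-epsilon2
  # ([nH]); Asp/Glu side-chain carboxyl OH; Arg N-eta; Trp indole NH.
  # Met is not graftable: its thioether sulfur carries no hydrogen, so a
  # single-bond graft there would create a charged sulfonium.
  reactive_atom = c(NA, 9L, NA, 6L, 4L, 7L, NA, NA, 6L, NA,
                    NA, 7L, NA, NA, NA, 4L, 4L, 6L, 8L, NA),
  reactive_element = c(NA, "N", NA, "O", "S", "O", NA, NA, "N", NA,
                       NA, "N", NA, NA, NA, "O", "O", "N", "O", NA),
  stringsAsFactors = FALSE
)
rownames(AMINO_ACID_TABLE) <- AMINO_ACID_TABLE$code

#' Canonical one-letter amino-acid codes
#'
#' @return Character vector of the 20 canonical codes, alphabetical.
#' @export
amino_acid_codes <- function() sort(AMINO_ACID_TABLE$code)

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty amino-acid sequence")
  codes <- strsplit(sequence, "")[[1]]
  bad <- setdiff(codes, AMINO_ACID_TABLE$code)
  if (length(bad) > 0) {
    stop("non-canonical amino-acid code(s): ", paste(unique(bad), collapse = ", "))
  }
  codes
}

#' SMILES of a free amino acid
#'
#' Returns the SMILES of the free L-amino acid for a one-letter code.
#'
#' @param code One canonical one-letter amino-acid code.
#' @param stereo Keep L-configuration stereocentres? Default `TRUE`.
#' @return A SMILES string.
#' @examples
#' residue_smiles("G")
#' residue_smiles("A", stereo = FALSE)
#' @export
residue_smiles <- function(code, stereo = TRUE) {
  stopifnot(is.character(code), length(code) == 1L)
  if (!code %in% AMINO_ACID_TABLE$code) {
    stop("unknown amino-acid code: '", code, "'")
  }
  s <- AMINO_ACID_TABLE[code, "smiles"]
  if (!stereo) s <- strip_stereo_smiles(s)
  s
}

#' Molecular formula of a free amino acid
#'
#' @param code One canonical one-letter code.
#' @return Formula string of the free residue.
#' @export
residue_formula <- function(code) {
  stopifnot(code %in% AMINO_ACID_TABLE$code)
  AMINO_ACID_TABLE[code, "formula"]
}

#' SMILES of a linear peptide
#'
#' Condenses a sequence of amino acids into the linear peptide SMILES:
#' amide bonds between consecutive residues, one water lost per bond,
#' free amine and free acid termini.
#'
#' @param sequence Non-empty string of canonical one-letter codes.
#' @param stereo Keep stereocentres? Default `TRUE`.
#' @return A SMILES string.
#' @examples
#' peptide_smiles("GG")
#' @export
peptide_smiles <- function(sequence, stereo = TRUE) {
  codes <- check_sequence(sequence)
  units <- vapply(codes, residue_smiles, character(1), stereo = stereo)
  n <- length(units)
  if (n > 1) {
    # every residue SMILES ends in the carboxyl "C(=O)O"; dropping the final
    # hydroxyl O and abutting the next residue's leading N forms the amide
    units[-n] <- substr(units[-n], 1L, nchar(units[-n]) - 1L)
  }
  paste(units, collapse = "")
}

#' SMILES rendering of a masked residue span
#'
#' Renders the chemistry a decoder is asked to produce for a masked span of
#' residues: either the condensed peptide fragment (amide-bonded, default)
#' or the individual residues joined by the `.` disconnection symbol in
#' N-to-C order.
#'
#' @param sequence Non-empty string of canonical one-letter codes.
#' @param mode `"condensed"` or `"per_residue"`.
#' @param stereo Keep stereocentres? Default `TRUE`.
#' @return A SMILES string.
#' @examples
#' span_fragment_smiles("GG", mode = "per_residue")
#' @export
span_fragment_smiles <- function(sequence, mode = c("condensed", "per_residue"),
                                 stereo = TRUE) {
  mode <- match.arg(mode)
  codes <- check_sequence(sequence)
  if (mode == "condensed") {
    peptide_smiles(sequence, stereo = stereo)
  } else {
    paste(vapply(codes, residue_smiles, character(1), stereo = stereo),
          collapse = ".")
  }
}

#' Expected molecular formula of a peptide
#'
#' Closed-form formula arithmetic: sum of free-residue formulas minus one
#' water per peptide bond. Used as the independent check against formulas
#' computed from rendered SMILES.
#'
#' @param sequence Non-empty string of canonical one-letter codes.
#' @return Formula string.
#' @export
peptide_formula <- function(sequence) {
  codes <- check_sequence(sequence)
  fs <- vapply(codes, residue_formula, character(1))
  formula_combine(fs, subtract = rep("H2O", length(codes) - 1L))
}
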