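# Covalent adduct grafting: replace the attachment dummy atom of an adduct
# SMILES with a single bond to a residue's side-chain attachment atom,
# by direct editing of the merged atom/bond tables.

STANDARD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L)

#' Construct and validate an adduct specification
#'
#' An adduct is given as a SMILES string containing exactly one dummy atom
#' (`*` or `[*]`) marking the attachment point. The dummy must take part in
#' exactly one bond, and that bond must be single: doubly-bonded adducts and
#' adducts bridging two residues are rejected.
#'
#' @param smiles SMILES string with one attachment dummy atom.
#' @param name Optional free-text name.
#' @return An object of class `adduct_spec` with fields `smiles`, `name`,
#'   `heavy_atoms` (dummy excluded), `neighbor_fragment` (graph with the
#'   dummy removed, plus the index of the attachment neighbor).
#' @examples
#' adduct_spec("[*]CC#N", name = "cyanoethyl")
#' @export
adduct_spec <- function(smiles, name = "") {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  g <- tryCatch(smiles_graph(smiles), error = function(e) {
    stop("adduct SMILES does not parse: ", smiles)
  })
  dummies <- which(g$atoms == "*")
  if (length(dummies) != 1L) {
    stop("adduct must contain exactly one dummy atom, found ",
         length(dummies), " in '", smiles, "'")
  }
  touching <- which(g$bonds$a1 == dummies | g$bonds$a2 == dummies)
  if (length(touching) != 1L) {
    stop("attachment dummy must take part in exactly one bond (adducts ",
         "bridging two residues are not supported)")
  }
  if (g$bonds$order[touching] != 1L) {
    stop("attachment bond must be single: only singly-bonded adducts are ",
         "supported")
  }
  b <- g$bonds[touching, ]
  neighbor <- if (b$a1 == dummies) b$a2 else b$a1
  structure(
    list(smiles = smiles, name = name, graph = g,
         dummy = dummies, neighbor = neighbor,
         heavy_atoms = sum(g$atoms != "*")),
    class = "adduct_spec"
  )
}

#' @export
print.adduct_spec <- function(x, ...) {
  cat("<adduct_spec>", if (nzchar(x$name)) x$name else "(unnamed)",
      x$smiles, paste0("[", x$heavy_atoms, " heavy atoms]"), "\n")
  invisible(x)
}

as_adduct_spec <- function(x) {
  if (inherits(x, "adduct_spec")) x else adduct_spec(x)
}

#' Residues with a defined side-chain attachment atom
#'
#' @return Character vector of one-letter codes that accept a covalent graft.
#' @export
graftable_codes <- function() {
  AMINO_ACID_TABLE$code[!is.na(AMINO_ACID_TABLE$reactive_atom)]
}

#' Graft a covalent adduct onto an amino-acid side chain
#'
#' Removes the adduct's dummy atom and joins its neighbor to the residue's
#' side-chain attachment atom by a single bond, consuming one implicit
#' hydrogen on the residue side. The edit is performed on the merged
#' atom/bond tables and the product is sanitized and canonicalized.
#' Product SMILES are emitted without stereocentres.
#'
#' @param code One-letter code of a graftable residue (see
#'   [graftable_codes()]).
#' @param adduct An [adduct_spec()] or a SMILES string with one dummy atom.
#' @return An object of class `modified_residue` with fields `base_code`,
#'   `adduct`, and `product_smiles`.
#' @examples
#' graft_adduct("C", "[*]CC#N")
#' @export
graft_adduct <- function(code, adduct) {
  stopifnot(is.character(code), length(code) == 1L)
  if (!code %in% AMINO_ACID_TABLE$code) {
    stop("unknown amino-acid code: '", code, "'")
  }
  adduct <- as_adduct_spec(adduct)
  key <- paste(code, adduct$smiles, sep = "\r")
  cached <- .graft_cache[[key]]
  if (!is.null(cached)) return(cached)

  react <- AMINO_ACID_TABLE[code, "reactive_atom"]
  if (is.na(react)) {
    stop("residue '", code, "' has no side-chain attachment atom defined")
  }
  res <- smiles_graph(strip_stereo_smiles(AMINO_ACID_TABLE[code, "smiles"]))

  # an implicit hydrogen must be available on the attachment atom
  elem <- res$atoms[react]
  used <- sum(res$bonds$order[res$bonds$a1 == react | res$bonds$a2 == react])
  if (used + 1L > STANDARD_VALENCE[[elem]]) {
    stop("attachment atom of residue '", code,
         "' has no available hydrogen (valence exceeded)")
  }

  # merge tables: adduct atoms appended after residue atoms, dummy dropped
  n_res <- length(res$atoms)
  ag <- adduct$graph
  keep <- setdiff(seq_along(ag$atoms), adduct$dummy)
  remap <- integer(length(ag$atoms))
  remap[keep] <- n_res + seq_along(keep)
  atoms <- c(res$atoms, ag$atoms[keep])
  abonds <- ag$bonds[ag$bonds$a1 != adduct$dummy & ag$bonds$a2 != adduct$dummy, ]
  abonds$a1 <- remap[abonds$a1]
  abonds$a2 <- remap[abonds$a2]
  bonds <- rbind(
    res$bonds,
    abonds,
    data.frame(a1 = react, a2 = remap[adduct$neighbor], order = 1L)
  )
  product <- graph_to_smiles(atoms, bonds)

  out <- structure(
    list(base_code = code, adduct = adduct, product_smiles = product),
    class = "modified_residue"
  )
  assign(key, out, envir = .graft_cache)
  out
}

.graft_cache <- new.env(parent = emptyenv())

#' @export
print.modified_residue <- function(x, ...) {
  cat("<modified_residue>", x$base_code, "+",
      x$adduct$smiles, "->", x$product_smiles, "\n")
  invisible(x)
}

#' Read adduct specifications from JSONL
#'
#' One JSON object per line with fields `name` and `smiles`; the attachment
#' point is the dummy atom `[*]` or `*`.
#'
#' @param path Path to a JSONL file.
#' @return List of [adduct_spec()] objects.
#' @export
read_adduct_specs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    adduct_spec(x$smiles, name = if (is.null(x$name)) "" else x$name)
  })
}
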