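# Readers and writers for the plain-text formats the pipeline touches:
# FASTA, reaction SMILES, affinity TSV, JSONL.

#' Read protein sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `id` and `sequence` (uppercased),
#'   record order preserved; zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(id = character(0), sequence = character(0)))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0 && !startsWith(first, ">")) {
    stop("malformed FASTA: sequence line before first header")
  }
  set <- Biostrings::readBStringSet(path)
  data.frame(id = names(set), sequence = toupper(as.character(set)),
             row.names = NULL)
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector, or data frame with `id` and
#'   `sequence` columns.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$id)
  }
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read single-step reactions from reaction-SMILES text
#'
#' One reaction per line in `reactants>reagents>products` form; the
#' reagents field may be empty.
#'
#' @param path Path to the file.
#' @return Data frame with columns `reactants`, `reagents`, `products`.
#' @export
read_reactions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(reactants = character(0), reagents = character(0),
                      products = character(0)))
  }
  n_sep <- lengths(gregexpr(">", lines, fixed = TRUE)) -
    (!grepl(">", lines, fixed = TRUE))
  bad <- which(n_sep != 2L)
  if (length(bad) > 0) {
    stop("line ", bad[1], ": expected 2 '>' separators, found ", n_sep[bad[1]])
  }
  parts <- strsplit(lines, ">", fixed = TRUE)
  parts <- lapply(parts, function(p) c(p, rep("", 3 - length(p)))[1:3])
  m <- do.call(rbind, parts)
  data.frame(reactants = m[, 1], reagents = m[, 2], products = m[, 3])
}

#' Write reactions as reaction-SMILES text
#'
#' @param reactions Data frame with `reactants`, `reagents`, `products`.
#' @param path Output path.
#' @export
write_reactions <- function(reactions, path) {
  writeLines(paste(reactions$reactants, reactions$reagents,
                   reactions$products, sep = ">"), path)
  invisible(path)
}

#' Read a drug-target affinity table
#'
#' Tab-separated with a header carrying at least the columns `smiles`,
#' `sequence`, `affinity`. Rows whose affinity does not parse as a
#' decimal are dropped and counted.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `smiles`, `sequence`, `affinity`
#'   (numeric); the number of dropped rows is in attribute `n_dropped`.
#' @export
read_affinity_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("smiles", "sequence", "affinity")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("affinity table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  aff <- suppressWarnings(as.numeric(df$affinity))
  keep <- !is.na(aff) & nzchar(df$smiles) & nzchar(df$sequence)
  out <- data.frame(smiles = df$smiles[keep], sequence = df$sequence[keep],
                    affinity = aff[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Read JSON-lines records
#'
#' @param path Path to a JSONL file (one JSON object per line).
#' @return List of parsed records; empty lines skipped.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON)
}

#' Write records as JSON lines
#'
#' @param records List of records (each serialized as one JSON object).
#' @param path Output path.
#' @export
write_jsonl <- function(records, path) {
  writeLines(vapply(records, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA)
  }, character(1)), path)
  invisible(path)
}

#' Read covalent-binder records from JSONL
#'
#' Each line carries `protein`, `ligand_smiles`, `position`, and
#' `adduct_smiles` (dummy-atom attachment point).
#'
#' @param path Path to the JSONL file.
#' @return List of [covalent_record()] objects.
#' @export
read_covalent_records <- function(path) {
  lapply(read_jsonl(path), function(x) {
    covalent_record(x$protein, x$ligand_smiles, x$position, x$adduct_smiles)
  })
}
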