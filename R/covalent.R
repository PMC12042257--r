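# Sequence-level covalent-binder tasks: encode a protein + ligand pair as
# a seq2seq example whose target carries the grafted-adduct SMILES bounded
# by <extra_id_99>/<extra_id_98> at the binding position; parse model
# output back; split on unique protein-ligand pairs; mix negatives for the
# balanced classification task.

COVALENT_TAG <- "Covalent:"
COVALENT_SEP <- "|"

#' Construct and validate a covalent-binder record
#'
#' @param protein Amino-acid sequence (canonical codes).
#' @param ligand_smiles Ligand SMILES string.
#' @param position 1-based residue index of the covalent site; the residue
#'   there must be graftable (see [graftable_codes()]).
#' @param adduct An [adduct_spec()] or adduct SMILES with one dummy atom.
#' @return An object of class `covalent_record` with a `pair_key` field
#'   identifying the unique (protein, ligand) pair.
#' @export
covalent_record <- function(protein, ligand_smiles, position, adduct) {
  codes <- check_sequence(protein)
  stopifnot(is.numeric(position), length(position) == 1L)
  if (position != floor(position) || position < 1 || position > length(codes)) {
    stop("position must be a 1-based residue index within the protein")
  }
  code <- codes[position]
  if (!code %in% graftable_codes()) {
    stop("residue '", code, "' at position ", position, " is not graftable")
  }
  adduct <- as_adduct_spec(adduct)
  structure(
    list(protein = protein, ligand_smiles = ligand_smiles,
         position = as.integer(position), adduct = adduct,
         pair_key = paste(protein, ligand_smiles, sep = "\t")),
    class = "covalent_record"
  )
}

#' @export
print.covalent_record <- function(x, ...) {
  cat("<covalent_record>", nchar(x$protein), "aa, site",
      x$position, paste0("(", substr(x$protein, x$position, x$position), ")"),
      "adduct", x$adduct$smiles, "\n")
  invisible(x)
}

#' Encode a covalent record as a seq2seq training example
#'
#' The input is the task tag, the protein's `<P>X` tokens, a literal `|`
#' separator, and the ligand SMILES tokens. The target is the protein
#' sequence with the residue at the covalent site replaced by
#' `<extra_id_99>`, the SMILES tokens of the grafted residue (see
#' [graft_adduct()]), and `<extra_id_98>`.
#'
#' @param record A [covalent_record()].
#' @return List with `input_tokens`, `target_tokens`, and the
#'   `grafted_smiles` the target encodes.
#' @export
build_adduct_example <- function(record) {
  stopifnot(inherits(record, "covalent_record"))
  codes <- strsplit(record$protein, "")[[1]]
  code <- codes[record$position]
  grafted <- graft_adduct(code, record$adduct)
  input <- c(COVALENT_TAG, paste0("<P>", codes), COVALENT_SEP,
             as.character(tokenize(record$ligand_smiles, "smiles")))
  before <- if (record$position > 1) {
    paste0("<P>", codes[seq_len(record$position - 1L)])
  } else character(0)
  after <- if (record$position < length(codes)) {
    paste0("<P>", codes[(record$position + 1L):length(codes)])
  } else character(0)
  target <- c(before, "<extra_id_99>",
              as.character(tokenize(grafted$product_smiles, "smiles")),
              "<extra_id_98>", after, "<eos>")
  list(input_tokens = input, target_tokens = target,
       grafted_smiles = grafted$product_smiles)
}

#' Parse a predicted adduct/position sequence
#'
#' Inverts the target layout of [build_adduct_example()]: the predicted
#' position is one plus the number of amino-acid tokens preceding
#' `<extra_id_99>`, and the predicted adduct SMILES is the detokenized
#' span between `<extra_id_99>` and `<extra_id_98>`. Predictions with
#' missing, repeated, or out-of-order sentinels are flagged malformed
#' (and count as incorrect downstream, never as errors).
#'
#' @param output Either a character vector of tokens or a single string
#'   (tokenized in mixed mode).
#' @return List with `malformed` (logical), and when well-formed
#'   `position` (integer) and `adduct_smiles` (string).
#' @export
parse_adduct_prediction <- function(output) {
  tokens <- if (length(output) == 1L) {
    tryCatch(
      suppressWarnings(as.character(tokenize(output, "mixed"))),
      error = function(e) character(0)
    )
  } else {
    as.character(output)
  }
  tokens <- tokens[tokens != "<eos>"]
  i99 <- which(tokens == "<extra_id_99>")
  i98 <- which(tokens == "<extra_id_98>")
  if (length(i99) != 1L || length(i98) != 1L || i98 <= i99) {
    return(list(malformed = TRUE, position = NA_integer_,
                adduct_smiles = NA_character_))
  }
  before <- tokens[seq_len(i99 - 1L)]
  position <- sum(grepl("^<P>[A-Z]$", before)) + 1L
  inner <- if (i98 - i99 > 1L) tokens[(i99 + 1L):(i98 - 1L)] else character(0)
  if (length(inner) == 0L || any(grepl("^<", inner))) {
    return(list(malformed = TRUE, position = NA_integer_,
                adduct_smiles = NA_character_))
  }
  list(malformed = FALSE, position = as.integer(position),
       adduct_smiles = paste(inner, collapse = ""))
}

#' Split records on unique protein-ligand pairs
#'
#' Records are first reduced to their unique pair keys so that all records
#' sharing a (protein, ligand) pair land in the same partition; keys are
#' then shuffled and partitioned. Validation and test sizes are
#' `round(ratio * n)` each, training takes the remainder (4251 unique
#' pairs under 80/10/10 give 3401/425/425).
#'
#' @param records List of [covalent_record()] objects, or a character
#'   vector of pair keys.
#' @param ratios Train/validation/test fractions summing to 1.
#' @param seed Optional integer seed for the shuffle.
#' @return Object of class `pair_split`: list with `train`, `validation`,
#'   `test` (disjoint character vectors of pair keys) and `assignment`
#'   (named factor over unique keys).
#' @export
make_splits <- function(records, ratios = c(0.8, 0.1, 0.1), seed = NULL) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8, all(ratios > 0))
  keys <- if (is.character(records)) records else {
    vapply(records, function(r) r$pair_key, character(1))
  }
  keys <- unique(keys)
  n <- length(keys)
  if (n < 3L) stop("fewer unique pair keys than partitions")
  with_seed(seed, {
    keys <- sample(keys)
    n_val <- round(ratios[2] * n)
    n_test <- round(ratios[3] * n)
    n_train <- n - n_val - n_test
    stopifnot(n_train >= 1L, n_val >= 1L, n_test >= 1L)
    assignment <- stats::setNames(
      factor(rep(c("train", "validation", "test"),
                 times = c(n_train, n_val, n_test)),
             levels = c("train", "validation", "test")),
      keys
    )
    structure(
      list(train = keys[seq_len(n_train)],
           validation = keys[n_train + seq_len(n_val)],
           test = keys[n_train + n_val + seq_len(n_test)],
           assignment = assignment, ratios = ratios, seed = seed),
      class = "pair_split"
    )
  })
}

#' @export
print.pair_split <- function(x, ...) {
  cat("<pair_split>", length(x$train), "train /", length(x$validation),
      "validation /", length(x$test), "test pair keys\n")
  invisible(x)
}

#' Build a balanced covalent-binder classification set
#'
#' Mixes the positive (covalent) pairs with an equal number of negative
#' (non-covalent) pairs sampled without replacement from a pool.
#'
#' @param positives Data frame with columns `protein` and `ligand_smiles`
#'   (or a list of [covalent_record()]s).
#' @param negative_pool Data frame with columns `protein` and
#'   `ligand_smiles`; must contain at least as many rows as there are
#'   positives.
#' @param seed Optional integer seed.
#' @return Data frame with columns `protein`, `ligand_smiles`, `label`
#'   (1 = covalent, 0 = non-covalent), exactly balanced.
#' @export
mix_negatives <- function(positives, negative_pool, seed = NULL) {
  if (is.list(positives) && !is.data.frame(positives) &&
      all(vapply(positives, inherits, logical(1), "covalent_record"))) {
    positives <- data.frame(
      protein = vapply(positives, function(r) r$protein, character(1)),
      ligand_smiles = vapply(positives, function(r) r$ligand_smiles, character(1))
    )
  }
  stopifnot(is.data.frame(positives), is.data.frame(negative_pool),
            all(c("protein", "ligand_smiles") %in% names(positives)),
            all(c("protein", "ligand_smiles") %in% names(negative_pool)))
  n <- nrow(positives)
  if (nrow(negative_pool) < n) {
    stop("negative pool smaller than the positive set (",
         nrow(negative_pool), " < ", n, ")")
  }
  with_seed(seed, {
    neg <- negative_pool[sample.int(nrow(negative_pool), n), , drop = FALSE]
    out <- rbind(
      data.frame(protein = positives$protein,
                 ligand_smiles = positives$ligand_smiles, label = 1L),
      data.frame(protein = neg$protein,
                 ligand_smiles = neg$ligand_smiles, label = 0L)
    )
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
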