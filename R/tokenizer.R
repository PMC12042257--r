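# Fixed dual-domain vocabulary and reversible character-level tokenization.
# Protein residues are carried as composite <P>X tokens so the model can
# tell amino acids apart from identical SMILES letters; SMILES text is
# strictly character level ('Cl' is two tokens).

SPECIAL_TOKENS <- c("<pad>", "<unk>", "<eos>")
TASK_TAGS <- c("Span-Mask:", "Chem-Mask:")

# Frozen 78-character SMILES inventory: full upper/lower alphabet (covers
# organic-subset and bracket-atom element symbols character by character),
# the ten digits for ring closures and bracket counts, and 16 punctuation
# marks (branches, brackets, bond orders, charges, stereo marks, '%' ring
# labels, the '.' disconnection symbol, the '*' wildcard and ':' for
# aromatic bonds / atom maps).
SMILES_CHARS <- c(LETTERS, letters, as.character(0:9),
                  "(", ")", "[", "]", "=", "#", "-", "+", "/", "\\",
                  "@", "%", ".", "*", ":", "~")

#' Build the fixed dual-domain vocabulary
#'
#' Deterministic 203-token vocabulary: 3 special tokens (`<pad>`, `<unk>`,
#' `<eos>`), 100 sentinel tokens (`<extra_id_0>` ... `<extra_id_99>`), 2
#' task tags (`Span-Mask:`, `Chem-Mask:`), 20 amino-acid tokens (`<P>A`
#' ... `<P>Y`), and a frozen 78-character SMILES inventory.
#'
#' @return An object of class `vocabulary`: list with `tokens` (character
#'   vector of length 203, index = token id position) and `category`
#'   (factor with levels special/sentinel/task/amino_acid/smiles_char).
#' @examples
#' v <- build_vocabulary()
#' length(v$tokens)
#' @export
build_vocabulary <- function() {
  tokens <- c(
    SPECIAL_TOKENS,
    sprintf("<extra_id_%d>", 0:99),
    TASK_TAGS,
    paste0("<P>", amino_acid_codes()),
    SMILES_CHARS
  )
  category <- factor(
    rep(c("special", "sentinel", "task", "amino_acid", "smiles_char"),
        times = c(3L, 100L, 2L, 20L, 78L)),
    levels = c("special", "sentinel", "task", "amino_acid", "smiles_char")
  )
  stopifnot(length(tokens) == 203L, !anyDuplicated(tokens))
  structure(list(tokens = tokens, category = category), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary>", length(x$tokens), "tokens:",
      paste(sprintf("%s=%d", levels(x$category), table(x$category)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Sentinel token for a masked span
#'
#' @param k Integer id between 0 and 99.
#' @return The token string `<extra_id_k>`.
#' @examples
#' sentinel(99)
#' @export
sentinel <- function(k) {
  stopifnot(is.numeric(k), length(k) >= 1L)
  if (any(k != floor(k)) || any(k < 0) || any(k > 99)) {
    stop("sentinel id must be an integer in [0, 99]")
  }
  sprintf("<extra_id_%d>", as.integer(k))
}

# regex matching tokens that must stay atomic inside text
ATOMIC_TOKEN_RE <- "<pad>|<unk>|<eos>|<extra_id_[0-9]{1,2}>|Span-Mask:|Chem-Mask:"
ATOMIC_TOKEN_RE_MIXED <- paste0(ATOMIC_TOKEN_RE, "|<P>[A-Z]")

# split text into atomic special tokens and the plain chunks between them
split_atomic <- function(text, pattern) {
  m <- gregexpr(pattern, text)[[1]]
  if (m[1] == -1L) return(list(text))
  lens <- attr(m, "match.length")
  out <- list()
  pos <- 1L
  for (i in seq_along(m)) {
    if (m[i] > pos) out <- c(out, list(substr(text, pos, m[i] - 1L)))
    out <- c(out, list(structure(substr(text, m[i], m[i] + lens[i] - 1L),
                                 atomic = TRUE)))
    pos <- m[i] + lens[i]
  }
  if (pos <= nchar(text)) out <- c(out, list(substr(text, pos, nchar(text))))
  out
}

#' Tokenize protein or SMILES text
#'
#' Protein text yields one `<P>X` token per residue; SMILES text is split
#' into strict single characters (`Cl` becomes `C`, `l`). Task tags,
#' sentinel and special tokens embedded in the text are emitted as single
#' tokens. In `"mixed"` mode literal `<P>X` tokens in the text are also
#' kept atomic, with remaining characters treated as SMILES. Characters
#' outside the inventory become `<unk>` with a warning.
#'
#' @param text A single non-empty string.
#' @param domain `"protein"`, `"smiles"`, or `"mixed"`.
#' @return Character vector of vocabulary tokens with attribute `domain`.
#' @examples
#' tokenize("MKV", "protein")
#' tokenize("C(Cl)", "smiles")
#' @export
tokenize <- function(text, domain = c("protein", "smiles", "mixed")) {
  domain <- match.arg(domain)
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("cannot tokenize empty text")
  tokens <- if (domain == "protein") {
    chars <- strsplit(text, "")[[1]]
    known <- chars %in% AMINO_ACID_TABLE$code
    if (!all(known)) {
      warning("unknown residue character(s) mapped to <unk>: ",
              paste(unique(chars[!known]), collapse = ", "))
    }
    ifelse(known, paste0("<P>", chars), "<unk>")
  } else {
    pattern <- if (domain == "mixed") ATOMIC_TOKEN_RE_MIXED else ATOMIC_TOKEN_RE
    chunks <- split_atomic(text, pattern)
    unlist(lapply(chunks, function(ch) {
      if (isTRUE(attr(ch, "atomic"))) return(as.character(ch))
      chars <- strsplit(ch, "")[[1]]
      known <- chars %in% SMILES_CHARS
      if (!all(known)) {
        warning("character(s) outside the SMILES inventory mapped to <unk>: ",
                paste(unique(chars[!known]), collapse = ", "))
      }
      ifelse(known, chars, "<unk>")
    }))
  }
  structure(tokens, domain = domain)
}

#' Invert tokenization
#'
#' Exact inverse of [tokenize()] for the same domain: `<P>` prefixes are
#' stripped for protein tokens; SMILES and mixed tokens are concatenated
#' unchanged. Sequences containing `<unk>` cannot be inverted.
#'
#' @param tokens Character vector of tokens (as returned by [tokenize()]).
#' @param domain Domain to invert under; defaults to the `domain`
#'   attribute of `tokens`.
#' @return The source text.
#' @examples
#' detokenize(c("<P>M", "<P>K"), "protein")
#' @export
detokenize <- function(tokens, domain = attr(tokens, "domain")) {
  if (is.null(domain)) stop("domain must be given when tokens carry none")
  domain <- match.arg(domain, c("protein", "smiles", "mixed"))
  if (any(tokens == "<unk>")) {
    stop("sequence contains <unk> and cannot be detokenized")
  }
  if (domain == "protein") {
    if (!all(grepl("^<P>[A-Z]$", tokens))) {
      stop("protein detokenization requires <P>X tokens only")
    }
    paste(sub("^<P>", "", tokens), collapse = "")
  } else {
    paste(tokens, collapse = "")
  }
}

#' Write a vocabulary to disk
#'
#' Plain text, one token per line; the token id is the line number minus
#' one.
#'
#' @param vocab A [build_vocabulary()] object.
#' @param path Output path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "vocabulary"))
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#'
#' Categories are re-derived from the token shapes.
#'
#' @param path Path to the vocabulary file.
#' @return A `vocabulary` object.
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path, warn = FALSE)
  category <- factor(
    ifelse(tokens %in% SPECIAL_TOKENS, "special",
    ifelse(grepl("^<extra_id_[0-9]{1,2}>$", tokens), "sentinel",
    ifelse(tokens %in% TASK_TAGS, "task",
    ifelse(grepl("^<P>[A-Z]$", tokens), "amino_acid", "smiles_char")))),
    levels = c("special", "sentinel", "task", "amino_acid", "smiles_char")
  )
  structure(list(tokens = tokens, category = category), class = "vocabulary")
}

# token -> id lookup (1-based positions in vocab$tokens)
vocab_ids <- function(vocab, tokens) {
  idx <- match(tokens, vocab$tokens)
  if (anyNA(idx)) {
    stop("token(s) outside the vocabulary: ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "))
  }
  idx
}
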