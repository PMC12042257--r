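# Construction of denoising training examples: Span-Mask (SMILES in,
# masked SMILES spans out) and Chem-Mask (protein residues in, the masked
# spans' chemistry out as SMILES). Sentinel ids run descending from 99,
# left to right.

#' Span-corruption configuration
#'
#' @param mask_rate Fraction of source tokens to mask; default 0.15.
#' @param mean_span Mean masked-span length in tokens; default 3.
#' @param max_segment Maximum protein window length in residues; default
#'   128.
#' @param fragment_mode How masked residue spans are rendered as SMILES:
#'   `"condensed"` (amide-bonded peptide fragment, default) or
#'   `"per_residue"` (dot-separated free residues).
#' @param stereo Keep stereocentres in rendered SMILES? Default `TRUE`.
#' @param seed Optional integer seed applied by corpus-level drivers.
#' @return An object of class `corruption_config`.
#' @export
corruption_config <- function(mask_rate = 0.15, mean_span = 3,
                              max_segment = 128,
                              fragment_mode = c("condensed", "per_residue"),
                              stereo = TRUE, seed = NULL) {
  fragment_mode <- match.arg(fragment_mode)
  stopifnot(mask_rate > 0, mask_rate < 1, mean_span >= 1, max_segment >= 1)
  structure(list(mask_rate = mask_rate, mean_span = mean_span,
                 max_segment = max_segment, fragment_mode = fragment_mode,
                 stereo = stereo, seed = seed),
            class = "corruption_config")
}

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Sample masked spans over a token sequence
#'
#' Draws non-overlapping, non-adjacent spans covering approximately
#' `mask_rate` of the tokens with mean length `mean_span`. The number of
#' masked tokens is `round(mask_rate * n_tokens)`; span lengths start from
#' a shifted-Poisson draw (`1 + Poisson(mean_span - 1)`) and are repaired
#' to sum exactly to that budget; spans are placed uniformly with at least
#' one unmasked token between consecutive spans. At most 100 spans are
#' produced (the sentinel budget).
#'
#' @param n_tokens Number of source tokens (>= 1).
#' @param config A [corruption_config()].
#' @param seed Optional seed; when given, sampling is deterministic and
#'   the caller's RNG state is untouched.
#' @return Integer matrix with columns `start` (0-based) and `length`;
#'   zero rows when nothing is masked.
#' @export
sample_spans <- function(n_tokens, config = corruption_config(), seed = NULL) {
  stopifnot(n_tokens >= 1)
  with_seed(seed, {
    n_mask <- round(config$mask_rate * n_tokens)
    empty <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("start", "length")))
    if (n_mask < 1) return(empty)
    k <- max(1L, min(100L, round(n_mask / config$mean_span)))
    # feasibility: k spans need k-1 separating tokens
    while (k > 1L && n_mask + (k - 1L) > n_tokens) k <- k - 1L
    if (n_mask + (k - 1L) > n_tokens) n_mask <- n_tokens  # k == 1
    # span lengths: shifted-Poisson draw repaired to sum to the budget
    lens <- 1L + stats::rpois(k, config$mean_span - 1)
    pick <- function(idx) if (length(idx) == 1L) idx else sample(idx, 1L)
    while (sum(lens) != n_mask) {
      if (sum(lens) > n_mask) {
        i <- pick(which(lens > 1L))
        lens[i] <- lens[i] - 1L
      } else {
        i <- pick(seq_len(k))
        lens[i] <- lens[i] + 1L
      }
    }
    # placement: distribute the free tokens into k+1 gaps (before, between,
    # after the spans); interior gaps get one mandatory separating token
    free <- n_tokens - n_mask
    extra <- free - (k - 1L)
    gaps <- as.integer(stats::rmultinom(1L, extra, rep(1, k + 1L)))
    if (k > 1L) gaps[2:k] <- gaps[2:k] + 1L
    starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0L, lens[-k]))
    cbind(start = as.integer(starts), length = as.integer(lens))
  })
}

# assemble a corruption example from source tokens + spans
build_example <- function(source_tokens, spans, tag, target_runs) {
  k <- nrow(spans)
  sentinels <- if (k > 0) sentinel(99 - seq_len(k) + 1) else character(0)
  input <- character(0)
  pos <- 1L
  if (k > 0) {
    for (i in seq_len(k)) {
      s0 <- spans[i, "start"] + 1L
      if (s0 > pos) input <- c(input, source_tokens[pos:(s0 - 1L)])
      input <- c(input, sentinels[i])
      pos <- s0 + spans[i, "length"]
    }
  }
  if (pos <= length(source_tokens)) {
    input <- c(input, source_tokens[pos:length(source_tokens)])
  }
  target <- character(0)
  for (i in seq_len(k)) target <- c(target, sentinels[i], target_runs[[i]])
  structure(
    list(input_tokens = c(tag, input),
         target_tokens = c(target, "<eos>"),
         spans = spans,
         n_source = length(source_tokens)),
    class = "corruption_example"
  )
}

#' @export
print.corruption_example <- function(x, ...) {
  cat("<corruption_example>", x$n_source, "source tokens,",
      nrow(x$spans), "masked span(s)\n")
  cat("  input: ", paste(utils::head(x$input_tokens, 12), collapse = " "),
      if (length(x$input_tokens) > 12) "..." else "", "\n")
  cat("  target:", paste(utils::head(x$target_tokens, 12), collapse = " "),
      if (length(x$target_tokens) > 12) "..." else "", "\n")
  invisible(x)
}

#' Build a Span-Mask denoising example from a SMILES string
#'
#' The input is the `Span-Mask:` tag followed by the source tokens with
#' each masked span replaced by one sentinel (ids descending from
#' `<extra_id_99>`); the target alternates each sentinel with the tokens
#' it hides and ends with `<eos>`.
#'
#' @param smiles Source SMILES; must tokenize without `<unk>`.
#' @param config A [corruption_config()].
#' @param spans Optional pre-chosen span matrix (columns start, length;
#'   0-based starts); when `NULL`, spans are sampled.
#' @param seed Optional seed forwarded to [sample_spans()].
#' @return A `corruption_example`.
#' @export
corrupt_smiles <- function(smiles, config = corruption_config(),
                           spans = NULL, seed = NULL) {
  tokens <- withCallingHandlers(
    tokenize(smiles, "smiles"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (any(tokens == "<unk>")) {
    stop("SMILES contains characters outside the inventory")
  }
  if (is.null(spans)) spans <- sample_spans(length(tokens), config, seed = seed)
  check_spans(spans, length(tokens))
  runs <- lapply(seq_len(nrow(spans)), function(i) {
    tokens[(spans[i, "start"] + 1L):(spans[i, "start"] + spans[i, "length"])]
  })
  build_example(as.character(tokens), spans, "Span-Mask:", runs)
}

#' Build a Chem-Mask (protein-to-SMILES) example from a protein sequence
#'
#' A contiguous window of at most `max_segment` residues is extracted
#' (uniform random start); masked spans are sampled over the window's
#' residue tokens; the input is the `Chem-Mask:` tag plus `<P>X` tokens
#' with sentinels; the target gives, for each span, its sentinel followed
#' by the SMILES tokens of the masked residues rendered by
#' [span_fragment_smiles()], ending with `<eos>`.
#'
#' @param sequence Protein sequence of canonical one-letter codes.
#' @param config A [corruption_config()].
#' @param spans Optional pre-chosen span matrix over window residues.
#' @param window_start Optional 1-based window start (forces the window).
#' @param seed Optional seed (window choice and span sampling).
#' @return A `corruption_example` with extra field `window` (1-based
#'   first/last residue of the extracted segment).
#' @export
corrupt_protein <- function(sequence, config = corruption_config(),
                            spans = NULL, window_start = NULL, seed = NULL) {
  codes <- check_sequence(sequence)
  n <- length(codes)
  with_seed(seed, {
    wlen <- min(n, config$max_segment)
    if (is.null(window_start)) {
      window_start <- if (n > wlen) sample.int(n - wlen + 1L, 1L) else 1L
    }
    stopifnot(window_start >= 1L, window_start + wlen - 1L <= n)
    window <- codes[window_start:(window_start + wlen - 1L)]
    if (is.null(spans)) spans <- sample_spans(wlen, config)
    check_spans(spans, wlen)
    runs <- lapply(seq_len(nrow(spans)), function(i) {
      span_seq <- paste(window[(spans[i, "start"] + 1L):
                               (spans[i, "start"] + spans[i, "length"])],
                        collapse = "")
      frag <- span_fragment_smiles(span_seq, mode = config$fragment_mode,
                                   stereo = config$stereo)
      as.character(tokenize(frag, "smiles"))
    })
    ex <- build_example(paste0("<P>", window), spans, "Chem-Mask:", runs)
    ex$window <- c(first = window_start, last = window_start + wlen - 1L)
    ex
  })
}

check_spans <- function(spans, n_tokens) {
  stopifnot(is.matrix(spans), ncol(spans) == 2)
  if (nrow(spans) == 0) return(invisible(spans))
  stopifnot(all(spans[, "length"] >= 1),
            all(spans[, "start"] >= 0),
            all(spans[, "start"] + spans[, "length"] <= n_tokens))
  ends <- spans[, "start"] + spans[, "length"]
  if (nrow(spans) > 1 && any(spans[-1, "start"] <= ends[-nrow(spans)])) {
    stop("spans must be sorted, non-overlapping and non-adjacent")
  }
  invisible(spans)
}

#' Empirical masking statistics of a corpus
#'
#' Computes the masked-token fraction and mean span length over the source
#' coordinates of a list of corruption examples.
#'
#' @param examples Non-empty list of `corruption_example` objects.
#' @return List with `masked_fraction`, `mean_span_length` (0 with
#'   `no_spans = TRUE` when the corpus has no spans), `n_tokens`, and
#'   `n_spans`.
#' @export
corpus_mask_stats <- function(examples) {
  if (length(examples) == 0) stop("empty corpus")
  stopifnot(all(vapply(examples, inherits, logical(1), "corruption_example")))
  n_tokens <- sum(vapply(examples, function(e) e$n_source, numeric(1)))
  masked <- sum(vapply(examples, function(e) sum(e$spans[, "length"]), numeric(1)))
  n_spans <- sum(vapply(examples, function(e) nrow(e$spans), numeric(1)))
  list(
    masked_fraction = masked / n_tokens,
    mean_span_length = if (n_spans > 0) masked / n_spans else 0,
    no_spans = n_spans == 0,
    n_tokens = n_tokens,
    n_spans = n_spans
  )
}
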