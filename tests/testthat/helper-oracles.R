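# Independent oracles used against the package implementations. These are
# deliberately naive (loops, enumeration) and share no code with R/.

# reconstruct source tokens by splicing the target runs of a corruption
# example back into its corrupted input
splice_oracle <- function(example) {
  input <- example$input_tokens[-1]             # drop task tag
  target <- example$target_tokens
  target <- target[-length(target)]             # drop <eos>
  is_sent <- grepl("^<extra_id_[0-9]{1,2}>$", target)
  runs <- list()
  cur <- NULL
  for (i in seq_along(target)) {
    if (is_sent[i]) {
      runs[[target[i]]] <- character(0)
      cur <- target[i]
    } else {
      runs[[cur]] <- c(runs[[cur]], target[i])
    }
  }
  out <- character(0)
  for (tok in input) {
    if (grepl("^<extra_id_[0-9]{1,2}>$", tok)) {
      out <- c(out, runs[[tok]])
    } else {
      out <- c(out, tok)
    }
  }
  out
}

# O(n^2) double-loop concordance index
ci_oracle <- function(y_true, y_pred) {
  n <- length(y_true)
  num <- 0
  z <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (y_true[i] > y_true[j]) {
        z <- z + 1
        if (y_pred[i] > y_pred[j]) num <- num + 1
        else if (y_pred[i] == y_pred[j]) num <- num + 0.5
      }
    }
  }
  num / z
}

# exhaustive protein-centric F-max: loops over every distinct score value,
# computes per-item precision/recall with explicit loops
f_max_oracle <- function(truth, scores) {
  truth <- as.matrix(truth) != 0
  scores <- as.matrix(scores)
  best <- 0
  for (t in sort(unique(as.vector(scores)))) {
    precs <- c()
    recs <- c()
    for (i in seq_len(nrow(truth))) {
      pred <- scores[i, ] > t
      if (any(pred)) {
        precs <- c(precs, sum(pred & truth[i, ]) / sum(pred))
      }
      if (any(truth[i, ])) {
        recs <- c(recs, sum(pred & truth[i, ]) / sum(truth[i, ]))
      }
    }
    p <- if (length(precs)) mean(precs) else NA
    r <- mean(recs)
    f <- if (is.na(p) || p + r == 0) 0 else 2 * p * r / (p + r)
    best <- max(best, f)
  }
  best
}

# residues masked by a protein corruption example, as one-letter strings
masked_residues <- function(sequence, example) {
  window <- substr(sequence, example$window["first"], example$window["last"])
  apply(example$spans, 1, function(sp) {
    substr(window, sp["start"] + 1, sp["start"] + sp["length"])
  })
}

# SMILES runs between sentinels in a target token vector
target_runs <- function(target_tokens) {
  target <- target_tokens[target_tokens != "<eos>"]
  is_sent <- grepl("^<extra_id_[0-9]{1,2}>$", target)
  idx <- cumsum(is_sent)
  runs <- split(target[!is_sent], idx[!is_sent])
  vapply(runs, paste, character(1), collapse = "")
}
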