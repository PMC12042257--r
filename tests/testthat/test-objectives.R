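test_that("span sampling is deterministic, sorted, and non-adjacent", {
  expect_identical(sample_spans(200, seed = 7), sample_spans(200, seed = 7))
  sp1 <- sample_spans(1)
  expect_true(nrow(sp1) == 0 || (nrow(sp1) == 1 && sum(sp1[, "length"]) <= 1))
  set.seed(44)
  for (i in 1:100) {
    n <- sample(2:400, 1)
    sp <- sample_spans(n)
    if (nrow(sp) == 0) next
    expect_true(all(sp[, "start"] >= 0))
    expect_true(all(sp[, "start"] + sp[, "length"] <= n))
    if (nrow(sp) > 1) {
      ends <- sp[, "start"] + sp[, "length"]
      # strictly increasing starts with at least one unmasked token between
      expect_true(all(sp[-1, "start"] > ends[-nrow(sp)]))
    }
    expect_lte(nrow(sp), 100)
  }
})

test_that("corruption examples have paired, descending sentinels", {
  ex <- corrupt_smiles(strrep("CO", 10),
                       spans = cbind(start = c(3L, 12L), length = c(3L, 2L)))
  expect_identical(ex$input_tokens[1], "Span-Mask:")
  expect_identical(ex$input_tokens[5], "<extra_id_99>")
  expect_identical(ex$input_tokens[12], "<extra_id_98>")
  expect_identical(ex$target_tokens,
                   c("<extra_id_99>", "O", "C", "O",
                     "<extra_id_98>", "C", "O", "<eos>"))
  set.seed(45)
  for (s in random_smiles(50)) {
    e <- corrupt_smiles(s)
    sents_in <- grep("^<extra_id_", e$input_tokens, value = TRUE)
    sents_tg <- grep("^<extra_id_", e$target_tokens, value = TRUE)
    expect_identical(sents_in, sents_tg)
    ids <- as.integer(sub("^<extra_id_([0-9]+)>$", "\\1", sents_in))
    if (length(ids) > 0) {
      expect_identical(ids, seq(99L, by = -1L, length.out = length(ids)))
    }
  }
})

test_that("splicing targets back into inputs restores the source", {
  set.seed(46)
  for (s in random_smiles(200)) {
    e <- corrupt_smiles(s)
    expect_identical(paste(splice_oracle(e), collapse = ""), s)
  }
})

test_that("zero-span corruption degenerates cleanly", {
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "length")))
  ex <- corrupt_smiles("CCO", spans = empty)
  expect_identical(ex$input_tokens, c("Span-Mask:", "C", "C", "O"))
  expect_identical(ex$target_tokens, "<eos>")
  exp <- corrupt_protein("GAG", spans = empty)
  expect_identical(exp$target_tokens, "<eos>")
})

test_that("protein corruption renders masked spans as their chemistry", {
  ex <- corrupt_protein("GAGG", spans = cbind(start = 1L, length = 2L))
  expect_identical(ex$input_tokens,
                   c("Chem-Mask:", "<P>G", "<extra_id_99>", "<P>G"))
  expect_identical(
    ex$target_tokens,
    c("<extra_id_99>",
      as.character(tokenize(span_fragment_smiles("AG"), "smiles")),
      "<eos>"))
  # per-residue mode renders dot-joined free residues instead
  cfgd <- corruption_config(fragment_mode = "per_residue")
  exd <- corrupt_protein("GAGG", cfgd, spans = cbind(start = 1L, length = 2L))
  expect_identical(
    exd$target_tokens,
    c("<extra_id_99>",
      as.character(tokenize(span_fragment_smiles("AG", "per_residue"),
                            "smiles")),
      "<eos>"))
})

test_that("long proteins are windowed to at most max_segment residues", {
  long <- random_proteins(1, c(300, 300), seed = 47)
  ex <- corrupt_protein(long, seed = 48)
  expect_lte(ex$n_source, 128)
  expect_equal(ex$window["last"] - ex$window["first"] + 1L, ex$n_source,
               ignore_attr = TRUE)
  expect_error(corrupt_protein("GXG"), "X")
})

test_that("masked spans decode to chemically consistent SMILES", {
  prots <- random_proteins(50, c(20, 60), seed = 49)
  for (i in seq_along(prots)) {
    ex <- corrupt_protein(prots[i], seed = 500 + i)
    if (nrow(ex$spans) == 0) next
    frags <- target_runs(ex$target_tokens)
    res <- masked_residues(prots[i], ex)
    expect_identical(unname(mol_formula(frags)),
                     unname(vapply(res, peptide_formula, character(1))))
  }
})

test_that("corpus statistics are exact arithmetic over source coordinates", {
  ex <- corrupt_smiles(strrep("C", 10),
                       spans = cbind(start = 0L, length = 2L))
  st <- corpus_mask_stats(list(ex))
  expect_equal(st$masked_fraction, 0.2)
  expect_equal(st$mean_span_length, 2.0)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "length")))
  st0 <- corpus_mask_stats(list(corrupt_smiles("CCO", spans = empty)))
  expect_equal(st0$mean_span_length, 0)
  expect_true(st0$no_spans)
  expect_error(corpus_mask_stats(list()), "empty")
})
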