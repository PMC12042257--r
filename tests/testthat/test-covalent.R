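test_that("covalent records validate position and graftability", {
  r <- covalent_record("GCG", "CCO", 2, "[*]CC#N")
  expect_s3_class(r, "covalent_record")
  expect_identical(r$pair_key, paste("GCG", "CCO", sep = "\t"))
  expect_error(covalent_record("GCG", "CCO", 0, "[*]CC#N"), "1-based")
  expect_error(covalent_record("GCG", "CCO", 4, "[*]CC#N"), "1-based")
  expect_error(covalent_record("GGG", "CCO", 2, "[*]CC#N"), "not graftable")
})

test_that("adduct examples carry the grafted SMILES bounded by sentinels", {
  r <- covalent_record("GCG", "CCO", 2, "[*]CC#N")
  ex <- build_adduct_example(r)
  grafted <- graft_adduct("C", "[*]CC#N")$product_smiles
  expect_identical(ex$input_tokens,
                   c("Covalent:", "<P>G", "<P>C", "<P>G", "|",
                     "C", "C", "O"))
  expect_identical(ex$target_tokens,
                   c("<P>G", "<extra_id_99>",
                     as.character(tokenize(grafted, "smiles")),
                     "<extra_id_98>", "<P>G", "<eos>"))
  # boundary: single-residue protein yields only the bounded block
  r1 <- covalent_record("C", "CCO", 1, "[*]C")
  ex1 <- build_adduct_example(r1)
  expect_identical(ex1$target_tokens[1], "<extra_id_99>")
  expect_identical(ex1$target_tokens[length(ex1$target_tokens) - 1L],
                   "<extra_id_98>")
})

test_that("predictions parse back to position and adduct, or flag malformed", {
  recs <- synth_covalent_records(60, seed = 50)
  for (r in recs) {
    ex <- build_adduct_example(r)
    parsed <- parse_adduct_prediction(ex$target_tokens)
    expect_false(parsed$malformed)
    expect_identical(parsed$position, r$position)
    expect_identical(canonical_smiles(parsed$adduct_smiles),
                     canonical_smiles(ex$grafted_smiles))
    # string form parses identically
    parsed2 <- parse_adduct_prediction(paste(ex$target_tokens, collapse = ""))
    expect_identical(parsed2$position, r$position)
  }
  expect_true(parse_adduct_prediction(c("<P>G", "<extra_id_99>", "C"))$malformed)
  expect_true(parse_adduct_prediction(
    c("<P>G", "<extra_id_98>", "C", "<extra_id_99>"))$malformed)
  expect_true(parse_adduct_prediction(
    c("<extra_id_99>", "C", "<extra_id_98>", "<extra_id_99>"))$malformed)
})

test_that("pair splits reproduce the 80/10/10 arithmetic and never leak", {
  keys <- sprintf("P%04d\tL%04d", 1:4251, 1:4251)
  sp <- make_splits(keys, seed = 1)
  expect_length(sp$train, 3401)
  expect_length(sp$validation, 425)
  expect_length(sp$test, 425)
  expect_identical(sort(c(sp$train, sp$validation, sp$test)), sort(keys))
  sp10 <- make_splits(sprintf("k%d\tl", 1:10), seed = 2)
  expect_equal(lengths(sp10[c("train", "validation", "test")]),
               c(train = 8L, validation = 1L, test = 1L))
  expect_identical(make_splits(keys, seed = 3)$test,
                   make_splits(keys, seed = 3)$test)
  expect_error(make_splits(c("a", "b"), seed = 1), "fewer unique")
})

test_that("duplicated pair keys land in a single partition", {
  recs <- synth_covalent_records(30, seed = 51)
  dup <- c(recs, recs[1:10])   # duplicates of ten pairs
  sp <- make_splits(dup, seed = 4)
  keys <- unique(vapply(dup, function(r) r$pair_key, character(1)))
  expect_length(c(sp$train, sp$validation, sp$test), length(keys))
  for (r in dup) {
    expect_equal(sum(r$pair_key %in% sp$train,
                     r$pair_key %in% sp$validation,
                     r$pair_key %in% sp$test), 1L)
  }
})

test_that("negative mixing yields an exactly balanced set", {
  pos <- data.frame(protein = sprintf("P%d", 1:5),
                    ligand_smiles = sprintf("C%s", strrep("C", 1:5)))
  pool <- data.frame(protein = sprintf("Q%d", 1:20),
                     ligand_smiles = rep("CCO", 20))
  mixed <- mix_negatives(pos, pool, seed = 5)
  expect_equal(nrow(mixed), 10L)
  expect_equal(sum(mixed$label == 1), 5L)
  expect_equal(sum(mixed$label == 0), 5L)
  expect_identical(mix_negatives(pos, pool, seed = 6),
                   mix_negatives(pos, pool, seed = 6))
  one <- mix_negatives(pos[1, ], pool[1, ], seed = 7)
  expect_setequal(one$label, c(0L, 1L))
  expect_error(mix_negatives(pos, pool[1:3, ]), "smaller")
})
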