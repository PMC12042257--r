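# Reference isomeric SMILES of the canonical L-amino acids (PubChem-style
# depictions, frozen here); equality is checked after canonicalization, so
# both connectivity and configuration must agree.
REFERENCE_RESIDUE_SMILES <- c(
  A = "C[C@@H](C(=O)O)N",
  R = "C(C[C@@H](C(=O)O)N)CN=C(N)N",
  N = "C([C@@H](C(=O)O)N)C(=O)N",
  D = "C([C@@H](C(=O)O)N)C(=O)O",
  C = "C([C@@H](C(=O)O)N)S",
  E = "C(CC(=O)O)[C@@H](C(=O)O)N",
  Q = "C(CC(=O)N)[C@@H](C(=O)O)N",
  G = "C(C(=O)O)N",
  # histidine is encoded as the tele (N-epsilon2-H) tautomer
  H = "OC(=O)[C@@H](N)Cc1c[nH]cn1",
  I = "CC[C@H](C)[C@@H](C(=O)O)N",
  L = "CC(C)C[C@@H](C(=O)O)N",
  K = "C(CCN)C[C@@H](C(=O)O)N",
  M = "CSCC[C@@H](C(=O)O)N",
  F = "C1=CC=C(C=C1)C[C@@H](C(=O)O)N",
  P = "C1C[C@H](NC1)C(=O)O",
  S = "C([C@@H](C(=O)O)N)O",
  T = "C[C@H]([C@@H](C(=O)O)N)O",
  W = "C1=CC=C2C(=C1)C(=CN2)C[C@@H](C(=O)O)N",
  Y = "C1=CC(=CC=C1C[C@@H](C(=O)O)N)O",
  V = "CC(C)[C@@H](C(=O)O)N"
)

test_that("all 20 residues give the correct L-amino acid, by structure and formula", {
  for (code in amino_acid_codes()) {
    mine <- residue_smiles(code)
    expect_identical(canonical_smiles(mine),
                     canonical_smiles(REFERENCE_RESIDUE_SMILES[[code]]),
                     label = paste("residue", code))
    expect_identical(mol_formula(mine), residue_formula(code),
                     label = paste("formula", code))
  }
})

test_that("residue lookup follows the stated contract", {
  expect_identical(canonical_smiles(residue_smiles("G")),
                   canonical_smiles("NCC(=O)O"))
  ala <- residue_smiles("A")
  expect_match(ala, "@@", fixed = TRUE)
  expect_identical(mol_formula(ala), "C3H7NO2")
  expect_error(residue_smiles("B"), "'B'")
  expect_error(residue_smiles("Z"), "'Z'")
})

test_that("stereo stripping keeps the constitution", {
  for (code in c("A", "T", "P", "W")) {
    s <- residue_smiles(code, stereo = FALSE)
    expect_false(grepl("@", s, fixed = TRUE))
    expect_identical(mol_formula(s), residue_formula(code))
  }
})

test_that("peptide condensation conserves the molecular formula", {
  expect_identical(peptide_smiles("G"), residue_smiles("G"))
  expect_identical(mol_formula(peptide_smiles("GG")), "C4H8N2O3")
  # property: toolkit formula of the rendered SMILES equals the arithmetic
  # sum of residues minus one water per bond
  set.seed(71)
  seqs <- random_proteins(25, c(2, 8))
  rendered <- vapply(seqs, peptide_smiles, character(1))
  expect_identical(unname(mol_formula(rendered)),
                   unname(vapply(seqs, peptide_formula, character(1))))
  expect_error(peptide_smiles(""), "empty")
  expect_error(peptide_smiles("GXG"), "X")
})

test_that("span fragments honour both rendering modes", {
  expect_identical(span_fragment_smiles("G", "condensed"), "NCC(=O)O")
  expect_identical(span_fragment_smiles("GG", "per_residue"),
                   "NCC(=O)O.NCC(=O)O")
  ag <- span_fragment_smiles("AG", "condensed")
  expect_true(is_valid_smiles(ag))
  expect_identical(mol_formula(ag),
                   formula_combine("C3H7NO2", "C2H5NO2", subtract = "H2O"))
  # dot-separator count is always length - 1
  set.seed(72)
  for (s in random_proteins(10, c(1, 6))) {
    frag <- span_fragment_smiles(s, "per_residue")
    expect_equal(sum(strsplit(frag, "")[[1]] == "."), nchar(s) - 1L)
  }
})
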