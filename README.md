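# chemspan

Proteins and small molecules are usually modeled by separate sequence
models — amino-acid strings on one side, SMILES on the other — even though
both describe the same atomic matter. `chemspan` provides the data-side
machinery for training and evaluating a *unified* protein/chemical sequence
model in which the two languages share one vocabulary and one denoising
objective family:

* a fixed **203-token dual-domain vocabulary** (3 special tokens, 100
  sentinels `<extra_id_0>`–`<extra_id_99>`, 2 task tags, 20 `<P>X`
  amino-acid tokens, 78 SMILES characters) with reversible character-level
  tokenization;
* **span corruption**: spans covering ≈15% of the tokens (mean length 3)
  are replaced by sentinel tokens in descending id order, and the decoder
  target reproduces the masked runs — for SMILES (`Span-Mask:`) the runs
  come back as SMILES text, for proteins (`Chem-Mask:`) the masked residue
  spans come back as the *chemistry they encode*, i.e. the SMILES of the
  amide-bonded peptide fragment, translating between the two languages;
* **covalent-adduct encoding**: a covalent binder record (protein, ligand,
  binding residue, adduct with one `*` attachment dummy) is rendered as a
  seq2seq example whose target carries the grafted-residue SMILES bounded
  by `<extra_id_99>`/`<extra_id_98>` at the binding position. Grafting is
  direct molecular-graph editing: the dummy atom is deleted, its neighbor
  is single-bonded to the residue's side-chain attachment atom
  (Cys Sγ, Lys Nζ, Ser/Thr/Tyr O, His Nε2, Asp/Glu carboxyl O, Arg Nη,
  Trp indole N), and one implicit hydrogen is consumed;
* leakage-free **dataset assembly**: splits on unique protein–ligand pair
  keys (80/10/10; 4,251 pairs → 3,401/425/425) and balanced negative
  mixing (3,401 positives → 6,802 classification examples);
* an **evaluation suite**: protein-centric F_max
  (max over thresholds t of the harmonic mean of averaged per-protein
  precision and recall), micro-averaged AUPRC, the concordance index
  CI = P(pred_i > pred_j | true_i > true_j) with half credit for ties,
  RMSE, Pearson r, r², the through-origin r0², and
  r_m² = r²·(1 − √(r² − r0²)), plus canonicalization-aware adduct and
  position accuracies;
* a **model harness**: a closed-form parameter count of the full-scale
  encoder–decoder (8+8 layers, 10 heads × 64, d_model 640, d_ff 2048,
  gated FFN, tied 203-token embedding → 102,393,600 ≈ 102 M parameters),
  audited against an instantiated model, and a smoke-scale pure-R
  encoder–decoder (hand-derived backprop, Adam) that demonstrates the
  objectives are learnable;
* **synthetic generators** for proteins, guaranteed-valid SMILES, affinity
  tables with known latent ranking, and covalent records, so everything is
  testable offline.

All SMILES parsing, canonicalization and formula work is delegated to
Open Babel through `ChemmineR`/`ChemmineOB`.

## Worked example

```r
library(chemspan)

# protein-to-chemistry span corruption
ex <- corrupt_protein("GAGG", spans = cbind(start = 1L, length = 2L))
ex$input_tokens
#> [1] "Chem-Mask:"    "<P>G"          "<extra_id_99>" "<P>G"
paste(ex$target_tokens, collapse = " ")
#> [1] "<extra_id_99> N [ C @ @ H ] ( C ) C ( = O ) N C C ( = O ) O <eos>"

# the masked "AG" span is decoded as the Ala-Gly dipeptide fragment
span_fragment_smiles("AG")
#> [1] "N[C@@H](C)C(=O)NCC(=O)O"

# covalent adduct grafting: cyanoethylation of a cysteine thiol
graft_adduct("C", "[*]CC#N")
#> <modified_residue> C + [*]CC#N -> NC(C(=O)O)CSCC#N

# the full-scale architecture audit
count_parameters(architecture_config())
#> [1] 102393600

# split arithmetic on unique protein-ligand pairs
sp <- make_splits(sprintf("P%04d\tL%04d", 1:4251, 1:4251), seed = 1)
lengths(sp[c("train", "validation", "test")])
#>      train validation       test
#>       3401        425        425
```

The tokenized target above reads back as valid chemistry: masking residues
2–3 of `GAGG` asks the decoder for `N[C@@H](C)C(=O)NCC(=O)O`, the
alanyl-glycine fragment (two residues, one amide bond, one water lost).

A thin CLI ships in `inst/cli/chemspan`
(`vocab export`, `corrupt`, `synth`, `covalent build|split`,
`evaluate affinity`, `harness count-params`).

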