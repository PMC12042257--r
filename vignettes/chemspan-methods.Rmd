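---
title: "chemspan: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemspan: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemspan)
```

## The problem

Protein language models read amino-acid strings; chemical language models
read SMILES. A unified model treats both as surface forms of one atomic
language. `chemspan` implements the data-processing, objective
construction, covalent-adduct chemistry, evaluation metrics, and a
smoke-scale training harness for that setting. Everything runs on
synthetic or in-package inputs; no external corpora are required.

## Tokenization and the 203-token vocabulary

Tokenization is strictly character-level for SMILES (`Cl` is two tokens
`C`, `l`; no regex merging of two-letter elements) and residue-level for
proteins, with each residue carried as a composite `<P>X` token so the
model can tell, say, serine `<P>S` apart from the SMILES sulfur `S`.

Only the vocabulary's total size (203) and its category structure are
fixed by the modeling setting; the exact SMILES character inventory is a
design choice here. We freeze 78 characters: the full upper- and
lower-case alphabet (52; covers every element symbol character, aromatic
forms included), ten digits, and 16 punctuation marks
(`( ) [ ] = # - + / \ @ % . * : ~`). With 3 special tokens, 100
sentinels, 2 task tags, and 20 amino-acid tokens this gives exactly
`3 + 100 + 2 + 20 + 78 = 203`. Unknown characters map to `<unk>` with a
warning rather than an error, so corpus scans are robust; `<unk>`
sequences are refused by the detokenizer because the inverse is no longer
well-defined.

## Span corruption

`sample_spans()` masks `round(0.15 * n)` tokens per sequence in
non-overlapping, non-adjacent spans with mean length 3, at most 100 spans
(the sentinel budget). The span-length law is a shifted Poisson
(`1 + Poisson(mean - 1)`) whose draws are randomly repaired to sum
exactly to the masking budget, with the span count fixed at
`round(budget / mean)`. We deliberately do *not* draw lengths until the
budget is exhausted and clip the last draw: renewal overshoot would bias
the realized mean span length visibly below 3 at typical sequence
lengths, and the empirical statistics (15% ± 1 absolute, mean span
3.0 ± 0.1 over ≥10⁵ tokens) are part of the package's contract. Spans
are placed by distributing the free tokens into the k+1 gaps around the
spans, with one mandatory separating token between consecutive spans;
adjacent spans therefore never occur (they would be indistinguishable
from one longer span after sentinel replacement).

Sentinels run in descending id order left to right, `<extra_id_99>`
first. Masking statistics are computed on the extracted window for
proteins, after truncation.

`corrupt_smiles()` produces the `Span-Mask:` objective: the target
reproduces exactly the masked runs, so splicing the target back into the
input is lossless — a property tested on 1,000 random SMILES.

`corrupt_protein()` produces the protein-to-chemistry objective: a
contiguous window of at most 128 residues is extracted (uniform random
start, deterministic under seed), spans are sampled over residue tokens,
and each masked span is decoded as the *SMILES of the chemistry it
encodes*. The decoder target covers only the masked spans
(sentinel-delimited), mirroring the SMILES objective; a whole-sequence
variant would be a trivial extension but breaks the symmetry between the
two objectives and inflates target lengths 20-fold at no informational
gain.

Masked spans are rendered by `span_fragment_smiles()` in one of two
modes. The default, `condensed`, emits the amide-bonded peptide fragment
with free amine/acid termini (no caps; a capped fragment would assert
atoms that are not present in the parent chain ends). `per_residue`
emits dot-joined free residues instead, for consumers that prefer a
trivially alignable target. Condensed is the default because the
fragment then *is* the substructure the masked span contributes to the
protein, up to the terminal H/OH.

## Residue chemistry

Residue SMILES are written backbone-first (`N`, Cα, side chain,
carboxyl) with L-configuration stereocentres (`[C@@H]`; Ile and Thr
carry their second centre, 2S,3S and 2S,3R). A frozen table of reference
isomeric SMILES pins every structure in the tests via canonicalization
equality. Histidine is encoded as the tele (Nε2–H) tautomer and arginine
with the chain-imine guanidine — the conventional neutral depictions,
and for histidine the tautomer whose graftable nitrogen carries the
hydrogen. A `stereo = FALSE` flag strips stereocentres for consumers
that train on achiral targets; the choice is configuration-only and
never changes constitution, which is verified by formula equality.

Peptide condensation is string-level: every residue SMILES ends in
`C(=O)O`, so dropping the final hydroxyl `O` and abutting the next
residue's leading `N` forms the amide. Formula conservation
(Σ residues − (n−1)·H₂O) is verified against Open Babel on random
sequences.

## Covalent adduct grafting

An adduct is a SMILES with exactly one dummy atom (`*`) participating in
exactly one single bond. Doubly-bonded dummies and adducts bridging two
residues are rejected up front — the encoding cannot express them.
Grafting is direct graph editing on the atom/bond tables: delete the
dummy, bond its neighbor to the residue's side-chain attachment atom,
serialize as a V2000 molfile, and let Open Babel sanitize and
canonicalize. The attachment atom must have an implicit hydrogen
available (checked against standard valences), and exactly one hydrogen
is consumed — heavy atoms are conserved exactly, properties tested over
the full residue × adduct library grid.

Attachment atoms are fixed per residue: Cys Sγ, Lys Nζ, Ser/Thr/Tyr
hydroxyl O, His Nε2, Asp/Glu side-chain carboxyl O, Arg Nη, Trp indole
N. Methionine is *not* graftable here: its thioether sulfur carries no
hydrogen, so a single-bond graft would create a charged sulfonium and
break the one-hydrogen bookkeeping that the rest of the pipeline relies
on.

Grafted products are emitted without stereocentres: the merged molecule
is serialized with zero coordinates, where wedge-based stereo perception
is meaningless, so stereo is stripped before editing rather than silently
scrambled. Adduct identity, not configuration, is the learning target.

## Covalent task encoding

The seq2seq input is `Covalent:` + `<P>`-tokens + a literal `|`
separator + ligand SMILES tokens (the separator is a design choice; any
token outside both domains works). The target is the protein sequence
with the binding residue replaced by `<extra_id_99>`, the grafted
residue's SMILES, `<extra_id_98>`. Parsing inverts this and returns a
`malformed` flag — never an error — when sentinels are missing,
repeated, or out of order, because malformed model output is an expected
event that must be *counted*, not crashed on.

Splits operate on unique (protein, ligand) pair keys so replicated
records (e.g. identical chains in a complex) can never leak across
partitions. Validation and test take `round(0.1·n)` keys each and train
the remainder, which reproduces 3,401/425/425 from 4,251. Negative
mixing samples the pool without replacement, uniformly — matching
negatives by protein is a plausible alternative, but uniform sampling is
the simplest defensible default when the pool's provenance is unknown.

## Metrics

F_max follows the protein-centric convention: per threshold, precision
is averaged only over proteins with at least one prediction, recall over
all proteins with at least one true label. Predictions are scores
*strictly above* the threshold; with ≥ the smallest threshold would
predict every label everywhere, and an all-zero score matrix — the
natural encoding of "no predictions" — would not score 0. The sweep
visits every distinct score value; equality with an exhaustive
brute-force sweep is tested on random instances.

AUPRC is micro-averaged over all (protein, class) pairs with step-wise
integration and tie groups collapsed. The concordance index credits 1
for correctly ordered prediction pairs and 0.5 for prediction ties, over
all strictly ordered truth pairs; it is checked against an O(n²) loop
oracle and is invariant under monotone transforms. In the regression
family, r² is the squared Pearson correlation (QSAR convention), r0² the
coefficient of determination of the through-origin regression of
observed on predicted, and r_m² = r²·(1 − √(r² − r0²)) with the radicand
clamped at zero so adversarial inputs cannot produce complex numbers.
Adduct accuracy compares *canonicalized* SMILES, so atom-order rewrites
count as correct; malformed predictions count as wrong on both adduct
and position.

## Model harness

The parameter audit has two independent routes: a closed form (tied
embedding `V·d`; per attention block `4·d·d`; gated feed-forward
`3·d·d_ff`; weight-only RMS norms, 2 per encoder layer, 3 per decoder
layer, 1 final norm per stack; one 32-bucket relative-position bias
table per stack) and an instantiate-and-count over the actual parameter
arrays. At the full-scale configuration both give 102,393,600 ≈ 102 M.
With an ungated two-projection feed-forward the same configuration
yields ≈81 M, which is why the gated block is the default: it is the
reconstruction consistent with the stated layer sizes and the stated
total.

The smoke trainer is a complete encoder–decoder in base R matrix code —
RMS-norm pre-normalization, multi-head attention with T5-style bucketed
relative-position biases (bidirectional in the encoder, causal in the
decoder, none on cross-attention), gated GELU feed-forward, tied output
head, teacher-forced cross-entropy, hand-derived backpropagation and
Adam. Analytic gradients are verified against central finite differences
(tolerance 1e-5) in the test suite. Its purpose is to demonstrate the
objectives are learnable: a 2-layer, width-64 model memorizes a
10-example protein-to-chemistry corpus (proteins of 8–14 residues) to
loss < 0.1 well within 500 full-batch steps, and greedy decoding then
reproduces a training target token-for-token. Problem sizes were chosen
so the whole demonstration runs in well under a minute on one CPU; this
is a learnability proof, not a route to a useful model.

## Synthetic data

Generators are deterministic under a seed and produce objects that
satisfy the invariants of the modules that consume them. Random SMILES
are assembled from a frozen fragment library in which chain fragments
always leave an open valence and terminal fragments may close it, so
validity holds by construction (verified by canonicalizing 1,000
outputs) — real PubChem chemistry is far more diverse (rings beyond
benzene, charges, stereo-dense natural products), so passing tests show
pipeline correctness, not chemical-space coverage. Random proteins draw
residues i.i.d. uniformly; real proteins have skewed composition and
local structure, which none of the tested properties depend on.
Synthetic affinity tables expose their latent ranking so concordance has
an exact ground truth (CI = 1 at zero noise, → 0.5 as noise grows).

## Degenerate inputs and numeric choices

Zero-span corruption yields a bare-tag input and an `<eos>`-only target.
A one-token sequence yields at most one length-1 span. Mean span length
of a span-free corpus is reported as 0 with an explicit flag rather than
NaN. Softmax and log-sum-exp are max-shifted; the causal mask uses an
additive −10⁹; RMS-norm uses ε = 1e-6. Splits refuse fewer unique keys
than partitions; negative mixing refuses pools smaller than the positive
set.

## Known limitations

* Adducts are single-attachment and singly bonded by design; multi-site
  or doubly-bonded chemistry is rejected, not approximated.
* Grafted products are achiral (see above).
* Open Babel is lenient with some malformed SMILES (e.g. unclosed
  branches), so `is_valid_smiles()` inherits that leniency at the
  margins.
* The harness trains only at smoke scale; no claim about full-scale
  benchmark behavior follows from it.
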