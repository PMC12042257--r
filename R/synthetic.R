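# Desk-scale synthetic fixtures with the statistical structure the other
# modules assume: random proteins, guaranteed-valid SMILES assembled from
# a frozen fragment library, affinity tables with known latent ranking,
# and covalent records that always satisfy their invariants.

# Chain fragments leave their last atom able to accept two more single
# bonds; terminal fragments may saturate it. Concatenating start + chains +
# terminal therefore always yields a parseable SMILES.
SMILES_CHAIN_FRAGMENTS <- c("C", "CC", "CCC", "C(C)", "CO", "CN", "CS",
                            "C(F)", "C(Cl)", "CCO", "C(C)C")
SMILES_TERMINAL_FRAGMENTS <- c("C", "O", "N", "C#N", "C(=O)O", "C(=O)N",
                               "c1ccccc1", "C(F)(F)F", "Br", "OC")

# small frozen adduct library (one dummy atom each, singly bonded)
ADDUCT_LIBRARY <- c(
  cyanoethyl     = "[*]CC#N",
  acetyl         = "[*]C(C)=O",
  methyl         = "[*]C",
  acetamidomethyl = "[*]CC(N)=O",
  hydroxyethyl   = "[*]CCO",
  benzyl         = "[*]Cc1ccccc1"
)

#' Frozen adduct SMILES library for synthetic covalent records
#'
#' @return Named character vector of adduct SMILES (one dummy atom each).
#' @export
adduct_library <- function() ADDUCT_LIBRARY

#' Generate random protein sequences
#'
#' Residues drawn i.i.d. uniformly from the 20 canonical codes; lengths
#' uniform over `length_range` or log-normal (protein-database-like) truncated to
#' the range.
#'
#' @param n Number of sequences.
#' @param length_range Integer vector `c(min, max)`.
#' @param seed Optional integer seed.
#' @param lengths `"uniform"` (default) or `"lognormal"`.
#' @return Character vector of sequences.
#' @export
random_proteins <- function(n, length_range = c(50, 200), seed = NULL,
                            lengths = c("uniform", "lognormal")) {
  lengths <- match.arg(lengths)
  stopifnot(n >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  with_seed(seed, {
    lens <- if (lengths == "uniform") {
      sample(length_range[1]:length_range[2], n, replace = TRUE)
    } else {
      l <- round(stats::rlnorm(n, meanlog = log(mean(length_range)), sdlog = 0.5))
      pmin(pmax(l, length_range[1]), length_range[2])
    }
    vapply(lens, function(L) {
      paste(sample(AMINO_ACID_TABLE$code, L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' Generate random valid SMILES strings
#'
#' Molecules are assembled by chaining fragments from a frozen library at
#' open attachment points, so every output parses and canonicalizes
#' without a rejection loop.
#'
#' @param n Number of SMILES.
#' @param n_fragments_range Range of chain-fragment counts per molecule.
#' @param seed Optional integer seed.
#' @return Character vector of valid SMILES.
#' @export
random_smiles <- function(n, n_fragments_range = c(2, 12), seed = NULL) {
  stopifnot(n >= 1, length(SMILES_CHAIN_FRAGMENTS) > 0)
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      k <- sample(n_fragments_range[1]:n_fragments_range[2], 1)
      paste0(
        paste(sample(SMILES_CHAIN_FRAGMENTS, k, replace = TRUE), collapse = ""),
        sample(SMILES_TERMINAL_FRAGMENTS, 1)
      )
    }, character(1))
  })
}

#' Synthetic drug-target affinity table with known latent ranking
#'
#' The latent score is a deterministic function of cheap sequence
#' features (ligand token length, protein hydrophobic fraction and
#' length); the reported affinity adds Gaussian noise. Returning the
#' latent scores gives ranking metrics a known ground truth.
#'
#' @param n Number of pairs.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Optional integer seed.
#' @return Data frame with columns `smiles`, `sequence`, `affinity`, and
#'   `latent`.
#' @export
synth_affinity_dataset <- function(n, noise_sd = 0.5, seed = NULL) {
  with_seed(seed, {
    prot <- random_proteins(n, c(30, 120))
    lig <- random_smiles(n)
    hydrophobic <- vapply(prot, function(p) {
      mean(strsplit(p, "")[[1]] %in% c("A", "V", "L", "I", "F", "M", "W"))
    }, numeric(1))
    latent <- 4 + 0.05 * nchar(lig) + 3 * hydrophobic + 0.005 * nchar(prot)
    affinity <- latent + stats::rnorm(n, sd = noise_sd)
    data.frame(smiles = lig, sequence = prot, affinity = affinity,
               latent = latent, row.names = NULL)
  })
}

#' Synthetic covalent-binder records
#'
#' Random proteins with a graftable residue planted at a random position
#' and an adduct drawn from the frozen [adduct_library()]; every record
#' satisfies the covalent-record invariants and encodes cleanly.
#'
#' @param n Number of records.
#' @param length_range Protein length range.
#' @param seed Optional integer seed.
#' @return List of [covalent_record()] objects.
#' @export
synth_covalent_records <- function(n, length_range = c(20, 60), seed = NULL) {
  with_seed(seed, {
    prot <- random_proteins(n, length_range)
    lig <- random_smiles(n)
    lapply(seq_len(n), function(i) {
      p <- prot[i]
      pos <- sample.int(nchar(p), 1)
      code <- sample(graftable_codes(), 1)
      substr(p, pos, pos) <- code
      ad <- ADDUCT_LIBRARY[[sample.int(length(ADDUCT_LIBRARY), 1)]]
      covalent_record(p, lig[i], pos, ad)
    })
  })
}
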