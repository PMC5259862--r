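#' Simulate a planted-block drug-disease study
#'
#' Generates the three raw inputs of the pipeline with a known planted
#' structure: drugs and diseases are partitioned round-robin into
#' `n_blocks` matched blocks; a drug-disease association is drawn with
#' probability `within_density` when drug and disease belong to matching
#' blocks and `between_density` otherwise; each drug block has a prototype
#' fingerprint whose members copy it with independent bit-flip probability
#' `fp_flip_rate`; each disease block has a nonnegative prototype concept
#' vector whose members copy it with additive noise (negative values
#' clipped at zero). This emulates the guilt-by-association premise the
#' walker exploits: similar drugs treat diseases with similar pathogenesis.
#'
#' The generator is a pure function of its arguments: each component draws
#' from its own stream seeded at a fixed offset from `seed`, so adding a
#' component never perturbs earlier draws and identical seeds give
#' bitwise-identical output.
#'
#' @param n_drugs,n_diseases node counts (each >= n_blocks).
#' @param n_blocks number of planted blocks.
#' @param within_density,between_density association probabilities inside /
#'   outside matching blocks, in [0, 1] with `within_density > between_density`.
#' @param fp_bits fingerprint length.
#' @param fp_flip_rate per-bit flip probability when copying the block
#'   prototype, in [0, 1].
#' @param seed integer seed.
#' @param concept_dim length of the concept vectors (default `fp_bits`).
#' @param concept_noise standard deviation of the additive concept noise.
#' @param concept_signal if `FALSE`, concept vectors are drawn ignoring the
#'   block structure, producing a fixture whose signal lives only in the
#'   fingerprints (complementary-information setting).
#' @return A list with elements `net` ([association_network()]),
#'   `fingerprints` and `concepts` ([feature_matrix()]), plus the block
#'   assignments `drug_blocks`, `disease_blocks`.
#' @examples
#' fx <- simulate_fixture(10, 10, 2, 0.6, 0.05, 64, 0.1, seed = 7)
#' fx$net
#' @export
simulate_fixture <- function(n_drugs, n_diseases, n_blocks,
                             within_density, between_density,
                             fp_bits, fp_flip_rate, seed,
                             concept_dim = fp_bits, concept_noise = 0.1,
                             concept_signal = TRUE) {
  if (n_blocks < 1L || n_blocks > min(n_drugs, n_diseases))
    stop("n_blocks must lie in [1, min(n_drugs, n_diseases)]")
  for (p in c(within_density, between_density, fp_flip_rate))
    if (p < 0 || p > 1) stop("densities and flip rate must lie in [0, 1]")
  if (within_density <= between_density)
    stop("within_density must exceed between_density (planted signal)")
  if (fp_bits < 1L || concept_dim < 1L) stop("feature dimensions must be >= 1")
  seed <- as.integer(seed)

  drug_blocks <- rep_len(seq_len(n_blocks), n_drugs)
  disease_blocks <- rep_len(seq_len(n_blocks), n_diseases)
  drug_ids <- sprintf("drug%03d", seq_len(n_drugs))
  disease_ids <- sprintf("dis%03d", seq_len(n_diseases))

  sub_seed <- function(k) (seed + k) %% .Machine$integer.max

  # adjacency: Bernoulli per pair, density set by block match
  A <- withr::with_seed(sub_seed(1L), {
    match_blk <- outer(drug_blocks, disease_blocks, `==`)
    p <- ifelse(match_blk, within_density, between_density)
    matrix(stats::rbinom(n_drugs * n_diseases, 1L, p), n_drugs, n_diseases)
  })

  fp <- withr::with_seed(sub_seed(2L), {
    proto <- matrix(stats::rbinom(n_blocks * fp_bits, 1L, 0.5),
                    n_blocks, fp_bits)
    flips <- matrix(stats::rbinom(n_drugs * fp_bits, 1L, fp_flip_rate),
                    n_drugs, fp_bits)
    abs(proto[drug_blocks, , drop = FALSE] - flips)
  })

  cv <- withr::with_seed(sub_seed(3L), {
    proto <- matrix(stats::runif(n_blocks * concept_dim), n_blocks, concept_dim)
    base <- if (concept_signal) proto[disease_blocks, , drop = FALSE]
            else matrix(stats::runif(n_diseases * concept_dim),
                        n_diseases, concept_dim)
    noise <- matrix(stats::rnorm(n_diseases * concept_dim, 0, concept_noise),
                    n_diseases, concept_dim)
    pmax(base + noise, 0)
  })

  list(net = association_network(drug_ids, disease_ids, A),
       fingerprints = feature_matrix(drug_ids, fp, kind = "fingerprint"),
       concepts = feature_matrix(disease_ids, cv, kind = "concept"),
       drug_blocks = drug_blocks, disease_blocks = disease_blocks)
}
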