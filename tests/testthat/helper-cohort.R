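# Small-cohort configuration used across tests: set sizes are scaled to the
# reduced gene universe so every generator stage stays valid.
small_config <- function(n_subjects = 200, n_aptamers = 60, seed = 101,
                         planted = default_planted_effects(5, 3, 2),
                         noise = c(glucose = 0.15, insulin = 8), ...) {
  cohort_config(
    n_subjects = n_subjects, n_aptamers = n_aptamers, seed = seed,
    planted_effects = planted,
    gene_sets = default_gene_sets(n_null = 10, null_sizes = c(5, 8, 10),
                                  enriched_sizes = c(8, 10, 12)),
    ogtt_noise_sd = noise,
    ...
  )
}

# IR profiles straight from latent degrees, bypassing the OGTT stage, for
# tests that isolate the linear-model layer from index estimation.
latent_ir_profiles <- function(latents) {
  data.frame(subject_id = latents$subject_id,
             ir_muscle = latents$latent_ir_muscle,
             ir_liver = latents$latent_ir_liver,
             stringsAsFactors = FALSE)
}

# Exhaustive-enumeration oracle for the upper-tail hypergeometric p-value:
# enumerate all C(N, n) draws of n from a universe with K successes and
# count draws with at least k successes.
enum_hyper_tail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}
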