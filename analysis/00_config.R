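# Shared configuration for the analysis scripts: one reference synthetic
# community used by every downstream stage. Three transition events span
# the range of interest — one very recent (2% divergence), one
# intermediate (8%) and one ancient split (25%); libraries are drawn
# between 10,000 and 20,000 reads so every sample survives rarefaction to
# the standard even depth of 9,827 reads per sample.

library(habitatscan)

RESULTS_DIR <- "results/analysis"
COMMUNITY_DIR <- "results/community"
SEED <- 2026L

community_spec <- synthetic_spec(
  n_taxa = 48L,
  alignment_length = 290L,
  n_transitions = 3L,
  transition_divergences = c(0.02, 0.08, 0.25),
  n_marine_samples = 8L,
  n_freshwater_samples = 8L,
  library_size_range = c(10000L, 20000L),
  abundance_lognormal_mu_sigma = c(0, 1.5),
  rare_fraction = 0.25,
  immigrant_weight = 5e-4,
  seed = SEED
)

RAREFACTION_DEPTH <- 9827L
N_SWAP_RANDOMIZATIONS <- 1000L
N_PERMUTATIONS <- 999L

dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

load_community <- function() {
  # deterministic under the community seed, so rebuilding equals reloading
  simulate_community(community_spec)
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
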