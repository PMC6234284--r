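#!/usr/bin/env Rscript

# Stage 4 — shared taxa, sampling saturation, habitat enrichment.
# Shared taxa are identified on the unrarefied table (a single read in
# each habitat suffices), accumulation curves show how sharing grows with
# sites sampled, and fold-enrichment summarizes habitat preference per
# group.

source("analysis/00_config.R")

comm <- load_community()

rep <- find_shared_taxa(comm$counts, comm$metadata, comm$lineage, rank = "phylum")
cat(sprintf("Shared taxa (>=1 read in each habitat, unrarefied): %d of %d\n",
            rep$n_shared, nrow(comm$counts)))
cat(sprintf("Genera with at least two shared taxa: %d\n", rep$genus_tally))
write_tsv(data.frame(taxon_id = rep$shared_taxa), "shared_taxa.tsv")
write_tsv(rep$by_group, "shared_by_group.tsv")
cat("\nPer-phylum sharing:\n")
print(rep$by_group, digits = 3)

for (hb in c("freshwater", "marine")) {
  acc <- accumulation_curve(comm$counts, comm$metadata, axis_habitat = hb,
                            n_orderings = 100, seed = SEED + 20L)
  write_tsv(acc, sprintf("accumulation_%s.tsv", hb))
  cat(sprintf("\nAccumulation over %s sites (mean shared, first -> last):\n  %s\n",
              hb, paste(round(acc$mean_shared, 1), collapse = " ")))
}

fe <- fold_enrichment(comm$counts, comm$lineage, comm$metadata, rank = "phylum")
write_tsv(fe, "fold_enrichment.tsv")
cat("\nHabitat fold-enrichment (log10 freshwater/marine medians):\n")
print(fe, digits = 3)
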