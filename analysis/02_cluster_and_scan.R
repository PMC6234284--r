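#!/usr/bin/env Rscript

# Stage 2 — multi-threshold clustering and the shared-identity scan.
# For each phylum, sequences are clustered by farthest-neighbor linkage at
# every 0.001 distance cutoff, and every marine-freshwater sample pair is
# scanned for the highest identity at which the pair still shares a
# cluster. High medians flag recent habitat transitions; the engineered
# events at 2%, 8% and 25% divergence should surface near identities
# 0.98, 0.92 and 0.75 in their respective groups.

source("analysis/00_config.R")

comm <- load_community()
scan <- group_scan(comm$seqs, comm$counts, comm$metadata, comm$lineage,
                   rank = "phylum", grid_step = 0.001)
tabs <- scan_tables(scan)

write_tsv(tabs$pairs, "scan_pairs.tsv")
write_tsv(tabs$summary, "scan_summary.tsv")

cat("Shared-identity scan by phylum (marine x freshwater sample pairs):\n")
print(tabs$summary, digits = 3)
cat("\nInterpretation: the maximum shared identity is a recency proxy —\n")
cat("groups whose pairs share clusters only below ~0.77 identity split\n")
cat("anciently, while values near 1 indicate recent transitions.\n")
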