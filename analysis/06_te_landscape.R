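#!/usr/bin/env Rscript
# TE landscape statistics: filter the self-alignment hits (70% identity,
# 80 bp), compute copy/family counts, the P_25f/P_75f family saturation
# percentages and the identity histogram of the TE complement.
# Usage: Rscript analysis/06_te_landscape.R [seed]

suppressMessages(library(archevol))
dir.create("results", showWarnings = FALSE)

copies <- utils::read.delim("results/data/te_copies.tsv")
hits <- read_blast_hits("results/data/te_hits.tsv")
prof <- te_profile(copies, hits, species = "spA")

utils::write.table(
  data.frame(species = prof$species, N_c = prof$N_c, N_f = prof$N_f,
             P_25f = prof$P_25f, P_75f = prof$P_75f),
  "results/te_profile.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(prof$histogram, "results/te_identity_histogram.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf(
  "TE complement: %d copies, %d families; P_25f=%.1f%%, P_75f=%.1f%%",
  prof$N_c, prof$N_f, prof$P_25f, prof$P_75f))
top <- prof$histogram[which.max(prof$histogram$count), ]
message(sprintf("identity mode in [%g,%g)%% with %d hits",
                top$bin_low, top$bin_high, top$count))
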