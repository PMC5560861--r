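#!/usr/bin/env Rscript
# Pairwise microsynteny: read the simulated annotations back through the
# GFF3/TSV readers, count collinear single-copy ortholog pairs, run the
# permutation null (100 rounds) and normalize to the synteny ratio matrix.
# Usage: Rscript analysis/02_synteny.R [seed]

suppressMessages({library(archevol); library(ape)})
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

tree <- read_tree("results/data/species_tree.nwk")
og <- read_orthogroups("results/data/orthogroups.tsv")
gm_list <- lapply(tree$tip.label, function(sp)
  read_gene_models(sprintf("results/data/genes_%s.gff3", sp), species = sp))
names(gm_list) <- tree$tip.label

pairs <- synteny_pairs(gm_list, og, n_rounds = 100, seed = seed)
m <- synteny_ratio(pairs)
hc <- cluster_species_by_synteny(m)

utils::write.table(pairs, "results/synteny_pairs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(m, "results/synteny_ratio.tsv", sep = "\t", quote = FALSE)
write(ape::write.tree(ape::as.phylo(hc)), "results/synteny_dendrogram.nwk")

best <- pairs[which.max((pairs$c - pairs$s) / pairs$N), ]
message(sprintf(
  "best-conserved pair %s-%s: c=%d, null mean s=%.2f, N=%d (r=1 reference)",
  best$species_i, best$species_j, best$c, best$s, best$N))
message(sprintf("synteny ratio range %.3f-%.3f across %d pairs",
                min(m, na.rm = TRUE), max(m, na.rm = TRUE), nrow(pairs)))
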