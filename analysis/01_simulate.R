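#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a rooted 8-species tree, rearranged
# single-copy gene orders (written as GFF3 + orthogroup TSV so the readers
# are exercised), intron presence/absence histories, domain-architecture
# histories and a TE landscape. Ground truth is kept by re-simulation from
# the recorded seed; downstream scripts restate it where they need it.
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages({library(archevol); library(ape)})
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

tree <- read.tree(text = paste0(
  "(((A:0.4,B:0.6)N1:0.3,(C:0.5,D:0.4)N2:0.5)N3:0.4,",
  "((E:0.7,F:0.3)N4:0.4,(G:0.5,H:0.6)N5:0.3)N6:0.5)R;"))
write.tree(tree, "results/data/species_tree.nwk")

orders <- simulate_gene_orders(tree, n_genes = 100,
                               breakpoints_per_branch = 3, seed = seed)
for (sp in tree$tip.label) {
  gm <- orders$gene_models[orders$gene_models$species == sp, ]
  gm$cds_segments <- lapply(seq_len(nrow(gm)), function(i)
    cbind(start = gm$start[i], end = gm$end[i]))
  class(gm) <- c("gene_models", "data.frame")
  write_gene_models(gm, sprintf("results/data/genes_%s.gff3", sp))
}
write_orthogroups(orders$orthogroups, "results/data/orthogroups.tsv")
message("gene orders: ", sum(orders$n_rearrangements),
        " rearrangements across ", length(orders$n_rearrangements),
        " branches (seed ", seed, ")")

introns <- simulate_intron_history(tree, n_sites = 2000, gain = 0.15,
                                   loss = 0.25, root_presence_prob = 0.6,
                                   seed = seed + 1)
utils::write.table(introns$extant, "results/data/intron_sites.tsv",
                   sep = "\t", quote = FALSE)
message("introns: ", nrow(introns$extant), " sites, ",
        sum(introns$events$gains), " true gains, ",
        sum(introns$events$losses), " true losses")

te <- simulate_te_landscape(n_families = 12, n_copies = 400, seed = seed + 2)
utils::write.table(te$copies, "results/data/te_copies.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(te$hits, "results/data/te_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)
message("TE landscape: ", nrow(te$copies), " copies in ",
        length(te$family_counts), " families")
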