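#' End-to-end demo pipeline on synthetic data
#'
#' Generates a synthetic dataset (species tree, intron histories, gene
#' orders, domain histories, TE landscape, gene trees), runs every analysis
#' stage on it, and writes one TSV per result under \code{out_dir}. All
#' randomness derives from \code{seed}; the same seed reproduces identical
#' outputs. Every output file starts with comment headers recording the
#' package version, the seed, and the stage configuration.
#'
#' @name pipeline
NULL

demo_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.4,B:0.6)N1:0.3,(C:0.5,D:0.4)N2:0.5)N3:0.4,",
    "((E:0.7,F:0.3)N4:0.4,(G:0.5,H:0.6)N5:0.3)N6:0.5)R;"))
}

write_stage_tsv <- function(df, path, seed, stage) {
  con <- file(path, "w")
  writeLines(c(paste0("# archevol ", as.character(utils::packageVersion("archevol"))),
               paste0("# stage: ", stage), paste0("# seed: ", seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full demo pipeline
#'
#' @param seed integer master seed; per-stage seeds are derived from it
#' @param out_dir output directory (created if absent)
#' @param stages character vector of stages to run; any of "synteny",
#'   "introns", "domains", "networks", "te", "distances" (default all)
#' @param n_sites intron sites to simulate (default 800)
#' @param n_genes genes for the synteny simulation (default 100)
#' @param n_rounds permutation / rewiring / bootstrap rounds (default 100)
#' @return invisibly, a named list of the per-stage result objects
#' @export
run_demo <- function(seed = 1, out_dir = "demo_out",
                     stages = c("synteny", "introns", "domains",
                                "networks", "te", "distances"),
                     n_sites = 800, n_genes = 100, n_rounds = 100) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- demo_tree()
  tips <- tree$tip.label
  res <- list(seed = seed, tree = tree)
  ape::write.tree(tree, file.path(out_dir, "species_tree.nwk"))

  if ("synteny" %in% stages) {
    sim <- simulate_gene_orders(tree, n_genes,
                                breakpoints_per_branch = 3, seed = seed + 11)
    gm_list <- lapply(split(sim$gene_models, sim$gene_models$species),
                      function(d) {
      d$cds_segments <- lapply(seq_len(nrow(d)), function(i)
        cbind(start = d$start[i], end = d$end[i]))
      class(d) <- c("gene_models", "data.frame")
      d
    })
    pairs <- synteny_pairs(gm_list, sim$orthogroups,
                           n_rounds = n_rounds, seed = seed + 12)
    m <- synteny_ratio(pairs)
    write_stage_tsv(pairs, file.path(out_dir, "synteny_pairs.tsv"),
                    seed, "synteny")
    write_stage_tsv(as.data.frame(m), file.path(out_dir, "synteny_ratio.tsv"),
                    seed, "synteny")
    res$synteny <- list(pairs = pairs, ratio = m,
                        clustering = cluster_species_by_synteny(m))
  }

  if ("introns" %in% stages) {
    sim <- simulate_intron_history(tree, n_sites, gain = 0.15, loss = 0.25,
                                   root_presence_prob = 0.6, seed = seed + 21)
    mat <- sim$extant[rowSums(sim$extant) > 0, , drop = FALSE]
    fit <- fit_gain_loss_model(mat, tree)
    recon <- reconstruct_ancestral_sites(mat, tree, fit)
    summ <- branch_event_summary(recon, cds_kbp = n_sites * 0.45)
    vmr <- bootstrap_vmr(mat, tree, fit, n_reps = n_rounds, seed = seed + 22)
    summ$vmr <- vmr$vmr[summ$node]
    write_stage_tsv(summ, file.path(out_dir, "intron_node_summary.tsv"),
                    seed, "introns")
    res$introns <- list(sim = sim, fit = fit, recon = recon, summary = summ,
                        profile_clustering =
                          cluster_presence_profiles(t(recon$posterior)))
  }

  if ("domains" %in% stages || "networks" %in% stages) {
    sim <- simulate_domain_histories(tree, n_orthoclusters = 40,
                                     n_domains = 20, seed = seed + 31)
    profile <- build_pair_profile(sim$domain_table, sim$orthogroups)
    mat <- pair_presence_matrix(profile, tips)
    hist <- reconstruct_pair_history(mat, tree)
    res$domains <- list(sim = sim, profile = profile, history = hist)
    if ("domains" %in% stages) {
      div <- node_diversification(colSums(hist$calls),
                                  stats::setNames(hist$events$expected_gains,
                                                  hist$events$branch),
                                  stats::setNames(hist$events$expected_losses,
                                                  hist$events$branch))
      write_stage_tsv(div, file.path(out_dir, "domain_diversification.tsv"),
                      seed, "domains")
      res$domains$diversification <- div
    }
    if ("networks" %in% stages) {
      stats_rows <- lapply(tips, function(sp) {
        net <- build_network(profile[profile$species == sp, ], label = sp)
        cm <- community_modularity(net, seed = seed + 41)
        null <- rewire_null(net, n_reps = n_rounds, seed = seed + 42)
        data.frame(genome = sp, Q = cm$Q, n_communities = cm$n_communities,
                   mean_domains_per_community = cm$mean_domains_per_community,
                   null_mean_Q = mean(null$Q), null_sd_Q = stats::sd(null$Q))
      })
      st <- do.call(rbind, stats_rows)
      corr <- modularity_vs_community_size(st$Q,
                                           st$mean_domains_per_community)
      write_stage_tsv(st, file.path(out_dir, "network_stats.tsv"),
                      seed, "networks")
      res$networks <- list(stats = st, correlation = corr)
    }
  }

  if ("te" %in% stages) {
    sim <- simulate_te_landscape(n_families = 12, n_copies = 400,
                                 seed = seed + 51)
    prof <- te_profile(sim$copies, sim$hits, species = "spA")
    write_stage_tsv(data.frame(species = prof$species, N_c = prof$N_c,
                               N_f = prof$N_f, P_25f = prof$P_25f,
                               P_75f = prof$P_75f),
                    file.path(out_dir, "te_profile.tsv"), seed, "te")
    write_stage_tsv(prof$histogram,
                    file.path(out_dir, "te_identity_histogram.tsv"),
                    seed, "te")
    res$te <- list(sim = sim, profile = prof)
  }

  if ("distances" %in% stages) {
    set.seed(seed + 61)
    trees <- lapply(1:20, function(i) {
      t <- demo_tree()
      t$edge.length <- t$edge.length * stats::rlnorm(length(t$edge.length),
                                                     0, 0.4)
      t
    })
    d <- collect_distances(trees)
    cmp <- compare_lineage_distances(d, "A", c("C", "D"), c("G", "H"))
    write_stage_tsv(d, file.path(out_dir, "cophenetic_distances.tsv"),
                    seed, "distances")
    write_stage_tsv(data.frame(statistic = cmp$statistic, p = cmp$p,
                               n1 = cmp$n1, n2 = cmp$n2,
                               median1 = cmp$median1, median2 = cmp$median2),
                    file.path(out_dir, "distance_comparison.tsv"),
                    seed, "distances")
    res$distances <- list(distances = d, comparison = cmp)
  }
  invisible(res)
}
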