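#' Intron content evolution
#'
#' Maps intron positions onto protein alignments as homologous sites
#' (alignment column + codon phase), classifies sites by alignment quality,
#' reconstructs gain/loss histories with the two-state Markov machinery
#' (\code{\link{fit_gain_loss_model}}, \code{\link{reconstruct_ancestral_sites}}),
#' and summarizes each tree node: expected gains and losses, intron density
#' per kbp of coding sequence, gain and loss percentages, the signed log10
#' gain/loss ratio, and a bootstrap variance-to-mean ratio flagging
#' unreliable ancestral counts.
#'
#' @name intron-evolution
NULL

#' Select marker orthoclusters for intron analysis
#'
#' Keeps orthoclusters that are single-copy in at least \code{min_fraction}
#' of the species, tolerating paralogs in at most \code{max_paralog_species}
#' species. Where paralogs are tolerated, the best-scoring copy is kept
#' (highest \code{paralog_scores}; ties broken by lexicographic gene id);
#' if no scores are supplied the longest protein is kept, with a warning.
#'
#' @param orthogroups an \code{ortholog_table}
#' @param species character vector of the species under consideration
#' @param min_fraction minimum fraction of species with exactly one gene
#'   (default 0.8)
#' @param max_paralog_species maximum number of species allowed to carry
#'   paralogs (default 1)
#' @param paralog_scores optional named numeric vector, gene id -> score
#' @param protein_lengths optional named vector, gene id -> protein length,
#'   used as fallback when scores are absent
#' @return named list orthogroup -> (named list species -> single gene id)
#'   for the selected markers
#' @export
select_marker_orthoclusters <- function(orthogroups, species,
                                        min_fraction = 0.8,
                                        max_paralog_species = 1,
                                        paralog_scores = NULL,
                                        protein_lengths = NULL) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  warn_len <- FALSE
  pick <- function(genes) {
    if (length(genes) == 1) return(genes)
    sc <- if (!is.null(paralog_scores)) paralog_scores[genes]
          else if (!is.null(protein_lengths)) { warn_len <<- TRUE; protein_lengths[genes] }
          else { warn_len <<- TRUE; rep(0, length(genes)) }
    sc[is.na(sc)] <- -Inf
    genes[order(-sc, genes)][1]
  }
  out <- list()
  for (id in names(orthogroups)) {
    counts <- vapply(species, function(s) length(orthogroups[[id]][[s]]), integer(1))
    if (sum(counts == 1) / length(species) < min_fraction) next
    if (sum(counts > 1) > max_paralog_species) next
    kept <- lapply(species[counts >= 1], function(s) pick(orthogroups[[id]][[s]]))
    names(kept) <- species[counts >= 1]
    out[[id]] <- kept
  }
  if (warn_len && is.null(paralog_scores))
    warning("paralogs present but no scores supplied; kept longest protein (or first by id)")
  out
}

# residue index (1-based, ungapped) -> alignment column for one aligned seq
ungapped_to_column <- function(aligned_seq) {
  ch <- strsplit(aligned_seq, "")[[1]]
  which(ch != "-")
}

#' Map introns onto protein alignment columns
#'
#' An intron interrupting a codon (phase 1 or 2) maps to the alignment
#' column of the amino acid whose codon contains it; a phase-0 intron maps
#' to the amino acid immediately 3' of the intron. With p coding
#' nucleotides 5' of the intron, the residue index is floor(p/3) + 1 in
#' both cases. Sites are merged across species on (column, phase); the
#' same column with different phases yields distinct sites (independent
#' gains).
#'
#' @param gm \code{gene_models} covering the aligned genes
#' @param alignment named character vector of aligned amino-acid sequences
#'   (names = species), gaps as "-"
#' @param gene_of named character vector species -> gene id used in the
#'   alignment
#' @param orthocluster id attached to the resulting sites
#' @return data.frame(orthocluster, column, phase, species, present);
#'   one row per (site, species) presence; genes whose CDS length is not a
#'   multiple of 3 are excluded with a warning
#' @export
map_intron_sites <- function(gm, alignment, gene_of,
                             orthocluster = NA_character_) {
  rows <- list()
  for (sp in names(alignment)) {
    g <- gm[gm$gene_id == gene_of[[sp]], , drop = FALSE]
    if (!nrow(g)) next
    if (g$partial[1]) {
      warning("gene ", g$gene_id[1], " CDS not divisible by 3; excluded")
      next
    }
    colmap <- ungapped_to_column(alignment[[sp]])
    if (length(colmap) != g$protein_length[1])
      stop("aligned length mismatch for ", g$gene_id[1])
    intr <- gene_introns(g)
    if (!nrow(intr)) next
    residue <- intr$coding_nt_before %/% 3 + 1
    # a phase-0 intron after the final codon has no 3' residue; skip it
    ok <- residue <= length(colmap)
    rows[[sp]] <- data.frame(orthocluster = orthocluster,
                             column = colmap[residue[ok]],
                             phase = intr$phase[ok], species = sp,
                             present = TRUE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(orthocluster = character(0), column = integer(0),
                      phase = integer(0), species = character(0),
                      present = logical(0))
  rownames(out) <- NULL
  out
}

#' Classify intron sites by alignment quality
#'
#' A site is \emph{conserved} when every column of the 3-column window
#' centred on its alignment column has gap fraction at most
#' \code{max_gap_fraction} and the orthocluster covers at least
#' \code{min_presence} of the species set; \emph{ambiguous} when the gap
#' criterion fails; \emph{unclassifiable} when the window is effectively
#' unaligned (some window column is gapped in more than half the rows).
#'
#' @param sites data.frame from \code{\link{map_intron_sites}}
#' @param alignment named character vector of aligned sequences
#' @param n_species_total total species in the dataset (for coverage)
#' @param min_presence minimum species coverage of the orthocluster
#' @param max_gap_fraction maximum gap fraction per window column
#' @param window odd window width in columns (default 3)
#' @return the unique sites (orthocluster, column, phase) with a
#'   \code{classification} column
#' @export
classify_sites <- function(sites, alignment, n_species_total,
                           min_presence = 0.8, max_gap_fraction = 0.1,
                           window = 3) {
  stopifnot(min_presence > 0, min_presence <= 1,
            max_gap_fraction > 0, max_gap_fraction <= 1)
  aln <- do.call(rbind, strsplit(unname(unlist(alignment)), ""))
  gapfrac <- colMeans(aln == "-")
  half <- window %/% 2
  coverage <- length(alignment) / n_species_total
  u <- unique(sites[, c("orthocluster", "column", "phase")])
  u$classification <- vapply(u$column, function(col) {
    w <- max(1, col - half):min(ncol(aln), col + half)
    if (any(gapfrac[w] > 0.5)) return("unclassifiable")
    if (any(gapfrac[w] > max_gap_fraction)) return("ambiguous")
    if (coverage >= min_presence) "conserved" else "ambiguous"
  }, character(1))
  rownames(u) <- NULL
  u
}

#' Presence/absence site matrix from mapped sites
#'
#' @param sites data.frame from \code{\link{map_intron_sites}} (possibly
#'   restricted to conserved sites)
#' @param species all species; species in the orthocluster without the
#'   intron are 0, species absent from the orthocluster are NA (missing)
#' @param covered named list orthocluster -> species present in that
#'   cluster (defaults to all species covered)
#' @return sites x species 0/1/NA matrix with informative rownames
#' @export
site_matrix <- function(sites, species, covered = NULL) {
  key <- paste(sites$orthocluster, sites$column, sites$phase, sep = ":")
  uk <- unique(key)
  m <- matrix(0, length(uk), length(species),
              dimnames = list(uk, species))
  if (!is.null(covered)) {
    for (k in seq_along(uk)) {
      oc <- sites$orthocluster[match(uk[k], key)]
      m[k, setdiff(species, covered[[oc]])] <- NA
    }
  }
  for (i in seq_len(nrow(sites))) m[key[i], sites$species[i]] <- 1
  m
}

#' Signed log10 gain/loss ratio of a node
#'
#' r = log10((p_G + eps)/(p_L + eps)); positive when gains dominate,
#' negative when losses dominate, 0 when balanced. The pseudo-count eps
#' handles zero percentages.
#'
#' @param p_gain,p_loss gain and loss percentages (>= 0)
#' @param eps pseudo-count (default 1e-6)
#' @return signed log10 ratio
#' @export
gain_loss_ratio <- function(p_gain, p_loss, eps = 1e-6) {
  stopifnot(all(p_gain >= 0, na.rm = TRUE), all(p_loss >= 0, na.rm = TRUE))
  log10((p_gain + eps) / (p_loss + eps))
}

#' Intron density at a node
#'
#' @param node_count expected introns at the node (sum of posterior
#'   presence over the marker sites; observed count at extant nodes)
#' @param cds_kbp total coding length of the marker set in kbp
#' @return introns per kbp of coding sequence
#' @export
intron_density <- function(node_count, cds_kbp) {
  if (any(cds_kbp <= 0)) stop("total CDS length must be > 0")
  node_count / cds_kbp
}

#' Bootstrap variance-to-mean ratio of ancestral intron counts
#'
#' Resamples sites with replacement, recomputes the expected intron count
#' at every node under fixed rates, and reports the per-node
#' variance-to-mean ratio (values above 1 flag less reliable inferences).
#'
#' @param mat extant site matrix (sites x species)
#' @param tree rooted \code{phylo}
#' @param rates a \code{gainloss_rates} (typically a fitted model)
#' @param n_reps bootstrap replicates (default 100, >= 2)
#' @param seed integer seed
#' @return list(vmr = named per-node ratio, counts = n_reps x nodes matrix)
#' @export
bootstrap_vmr <- function(mat, tree, rates, n_reps = 100, seed = 1) {
  stopifnot(n_reps >= 2)
  set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(r) {
    res <- mat[sample.int(nrow(mat), replace = TRUE), , drop = FALSE]
    reconstruct_ancestral_sites(res, tree, rates)$node_counts
  })
  counts <- do.call(rbind, reps)
  mu <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  vmr <- v / mu
  if (any(mu == 0)) {
    warning("zero mean bootstrap count at some nodes; VMR reported as NaN")
    vmr[mu == 0] <- NaN
  }
  list(vmr = vmr, counts = counts)
}

#' Per-node summary of intron evolution
#'
#' Combines reconstruction output into one row per node: expected gains and
#' losses on the branch above it, expected introns, intron density, gain and
#' loss percentages (relative to the introns at the node), and the signed
#' log10 gain/loss ratio.
#'
#' @param recon output of \code{\link{reconstruct_ancestral_sites}}
#' @param cds_kbp total marker coding length in kbp
#' @return data.frame(node, expected_introns, gains, losses, density,
#'   p_gain, p_loss, ratio); the root has NA gains/losses
#' @export
branch_event_summary <- function(recon, cds_kbp) {
  nodes <- names(recon$node_counts)
  ev <- recon$events
  g <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  l <- g
  g[ev$branch] <- ev$expected_gains
  l[ev$branch] <- ev$expected_losses
  cnt <- recon$node_counts
  data.frame(node = nodes, expected_introns = unname(cnt),
             gains = unname(g), losses = unname(l),
             density = unname(intron_density(cnt, cds_kbp)),
             p_gain = unname(100 * g / cnt), p_loss = unname(100 * l / cnt),
             ratio = unname(gain_loss_ratio(100 * g / cnt, 100 * l / cnt)),
             row.names = NULL)
}

#' Ward clustering of presence-probability profiles
#'
#' Distance between two nodes is 1 - Spearman correlation of their per-site
#' presence profiles; agglomeration is Ward. Rows with zero variance have
#' undefined correlation; their distances are set to 1 with a warning. Rows
#' are ordered by node name before clustering for determinism.
#'
#' @param profiles nodes x sites numeric matrix (rows are clustered)
#' @return an \code{hclust} object
#' @export
cluster_presence_profiles <- function(profiles) {
  stopifnot(nrow(profiles) >= 3)
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  suppressWarnings(rho <- stats::cor(t(profiles), method = "spearman"))
  if (any(is.na(rho))) {
    warning("constant profiles: undefined correlations set to 0 (distance 1)")
    rho[is.na(rho)] <- 0
  }
  d <- stats::as.dist(1 - rho)
  stats::hclust(d, method = "ward.D2")
}

# overlap length of interval [s1,e1) with [s2,e2), 0-based half-open
interval_overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Phylostratigraphy versus regulatory-site association
#'
#' Classifies introns as regulatory-bearing when some regulatory interval
#' overlaps the intron by at least \code{overlap_fraction} of the
#' interval's own length, then tests the 2x2 association between age class
#' (recent vs ancestral) and regulatory status with a two-sided Fisher
#' exact test.
#'
#' @param introns data.frame(chrom, start, end, age) with 0-based half-open
#'   intron intervals and age in \{"recent", "ancestral"\}
#' @param regulatory data.frame(chrom, start, end), 0-based half-open (BED)
#' @param overlap_fraction minimum fraction of the regulatory interval
#'   overlapped (default 0.5)
#' @return list(table = 2x2 matrix rows recent/ancestral, cols
#'   without/with sites; p = two-sided Fisher p; odds_ratio)
#' @export
phylostratigraphy_test <- function(introns, regulatory, overlap_fraction = 0.5) {
  stopifnot(all(introns$age %in% c("recent", "ancestral")))
  if (!all(c("recent", "ancestral") %in% introns$age))
    stop("empty age class: both recent and ancestral introns are required")
  has_reg <- vapply(seq_len(nrow(introns)), function(i) {
    r <- regulatory[regulatory$chrom == introns$chrom[i], , drop = FALSE]
    if (!nrow(r)) return(FALSE)
    ov <- interval_overlap(introns$start[i], introns$end[i], r$start, r$end)
    any(ov >= overlap_fraction * (r$end - r$start))
  }, logical(1))
  tab <- matrix(c(sum(introns$age == "recent" & !has_reg),
                  sum(introns$age == "ancestral" & !has_reg),
                  sum(introns$age == "recent" & has_reg),
                  sum(introns$age == "ancestral" & has_reg)),
                nrow = 2,
                dimnames = list(c("recent", "ancestral"),
                                c("without_sites", "with_sites")))
  fisher_2x2(tab)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' @param tab 2x2 integer matrix
#' @return list(table, p, odds_ratio)
#' @export
fisher_2x2 <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in 2x2 table; p = 1")
    return(list(table = tab, p = 1, odds_ratio = NA_real_))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p = ft$p.value, odds_ratio = unname(ft$estimate))
}
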