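#' Synthetic data with recorded ground truth
#'
#' Generators that emulate the statistical structure of the comparative
#' analyses: intron presence/absence histories evolved under the two-state
#' Markov chain on a tree, single-copy gene orders rearranged by inversions
#' and translocations, ordered domain architectures gaining and losing
#' domains along branches, and transposable-element landscapes with
#' family-structured identity distributions. Every generator records the
#' true history so downstream inferences can be checked against it. No
#' nucleotide or amino-acid sequence is simulated.
#'
#' All generators are deterministic given their seed.
#'
#' @name synthetic-data
NULL

#' Simulate intron presence/absence histories on a tree
#'
#' Draws each site's root state from \code{root_presence_prob}, then applies
#' the two-state transition along every branch using that branch's gain and
#' loss rates. State changes (parent absent to child present and vice versa)
#' are recorded per branch as the true gain/loss counts.
#'
#' @param tree rooted \code{phylo}
#' @param n_sites number of independent sites, >= 1
#' @param gain,loss per-branch rates: named vectors (branch child-node
#'   names) or a single number for all branches
#' @param root_presence_prob probability a site is present at the root
#' @param seed integer seed
#' @return list with
#'   \item{states}{sites x nodes 0/1 matrix over all nodes (extant + ancestral)}
#'   \item{extant}{sites x tips submatrix}
#'   \item{events}{data.frame(branch, gains, losses) of true state changes}
#'   \item{rates}{the \code{gainloss_rates} used}
#' @export
simulate_intron_history <- function(tree, n_sites, gain, loss,
                                    root_presence_prob = 0.5, seed = 1) {
  stopifnot(n_sites >= 1)
  rates <- gainloss_rates(tree, gain, loss, root_presence_prob)
  ix <- index_tree(tree)
  set.seed(seed)
  st <- matrix(0L, n_sites, ix$n_node, dimnames = list(NULL, ix$names))
  st[, ix$root] <- stats::rbinom(n_sites, 1, root_presence_prob)
  M <- branch_matrices(ix, rates)
  gains <- losses <- stats::setNames(rep(0L, ix$n_node), ix$names)
  for (v in ix$preorder) {
    if (v == ix$root) next
    p <- st[, ix$parent[v]]
    pr_present <- ifelse(p == 1L, M[[v]][2, 2], M[[v]][1, 2])
    st[, v] <- stats::rbinom(n_sites, 1, pr_present)
    gains[v] <- sum(p == 0L & st[, v] == 1L)
    losses[v] <- sum(p == 1L & st[, v] == 0L)
  }
  brs <- setdiff(seq_len(ix$n_node), ix$root)
  list(states = st,
       extant = st[, seq_len(ix$n_tip), drop = FALSE],
       events = data.frame(branch = ix$names[brs], gains = as.integer(gains[brs]),
                           losses = as.integer(losses[brs]), row.names = NULL),
       rates = rates)
}

# one rearrangement applied to an integer gene-order vector
rearrange_once <- function(ord) {
  n <- length(ord)
  i <- sort(sample.int(n, 2))
  block <- ord[i[1]:i[2]]
  if (stats::runif(1) < 0.5 || i[2] - i[1] + 1 >= n) {
    ord[i[1]:i[2]] <- rev(block)                     # inversion
  } else {                                           # translocation
    rest <- ord[-(i[1]:i[2])]
    pos <- sample.int(length(rest) + 1, 1)
    ord <- append(rest, block, after = pos - 1)
  }
  ord
}

#' Simulate single-copy gene orders under rearrangement
#'
#' The ancestral order is genes 1..n on one scaffold. Along each branch a
#' Poisson-distributed number of rearrangements (inversions and block
#' translocations, equally likely) is applied. All genes are single-copy in
#' every species, matching the premise of the collinearity statistic.
#'
#' @param tree rooted \code{phylo}
#' @param n_genes number of genes, >= 3
#' @param breakpoints_per_branch per-branch expected rearrangement count:
#'   named vector (branch child names) or single number
#' @param seed integer seed
#' @return list with
#'   \item{orders}{named list, node name -> integer gene order}
#'   \item{gene_models}{data.frame of synthetic gene models for the tips
#'     (gene_id, species, scaffold, strand, start, end)}
#'   \item{orthogroups}{\code{OrthologTable}: one single-copy orthogroup per gene}
#'   \item{n_rearrangements}{named vector of events applied per branch}
#' @export
simulate_gene_orders <- function(tree, n_genes, breakpoints_per_branch, seed = 1) {
  stopifnot(n_genes >= 3)
  ix <- index_tree(tree)
  br <- ix$names[setdiff(seq_len(ix$n_node), ix$root)]
  rate <- breakpoints_per_branch
  if (length(rate) == 1 && is.null(names(rate)))
    rate <- stats::setNames(rep(rate, length(br)), br)
  stopifnot(all(br %in% names(rate)))
  set.seed(seed)
  orders <- vector("list", ix$n_node)
  orders[[ix$root]] <- seq_len(n_genes)
  nev <- stats::setNames(integer(length(br)), br)
  for (v in ix$preorder) {
    if (v == ix$root) next
    ord <- orders[[ix$parent[v]]]
    k <- stats::rpois(1, rate[[ix$names[v]]])
    nev[ix$names[v]] <- k
    for (e in seq_len(k)) ord <- rearrange_once(ord)
    orders[[v]] <- ord
  }
  names(orders) <- ix$names
  tips <- ix$names[seq_len(ix$n_tip)]
  gm <- do.call(rbind, lapply(tips, function(sp) {
    ord <- orders[[sp]]
    data.frame(gene_id = paste0(sp, "_g", ord), species = sp,
               scaffold = "scf1", strand = "+",
               start = (seq_along(ord) - 1) * 1000 + 1,
               end = (seq_along(ord) - 1) * 1000 + 900)
  }))
  og <- lapply(seq_len(n_genes), function(g)
    stats::setNames(lapply(tips, function(sp) paste0(sp, "_g", g)), tips))
  names(og) <- sprintf("OG%04d", seq_len(n_genes))
  list(orders = orders, gene_models = gm,
       orthogroups = structure(og, class = "ortholog_table"),
       n_rearrangements = nev)
}

#' Simulate domain-architecture histories on a tree
#'
#' Each orthocluster starts at the root with a random ordered architecture
#' of 2 domains. Along each branch, Poisson(gain_rate * t) gain events each
#' append a random domain (from a pool of \code{n_domains}) at a random
#' position, and Poisson(loss_rate * t) loss events each delete a random
#' domain (architectures are never reduced below one domain). The true
#' architecture, and hence the true directed-pair presence, is recorded at
#' every node.
#'
#' @param tree rooted \code{phylo}
#' @param n_orthoclusters number of gene families
#' @param n_domains size of the domain pool
#' @param gain_rate,loss_rate events per unit branch length
#' @param seed integer seed
#' @return list with
#'   \item{architectures}{list: node name -> list orthocluster -> character
#'     vector of ordered domain ids}
#'   \item{domain_table}{data.frame(protein_id, domain_id, ali_start,
#'     ali_end, species) for the tips}
#'   \item{orthogroups}{\code{OrthologTable} mapping each tip protein to its cluster}
#'   \item{pair_truth}{data.frame(node, orthocluster, pair) of true directed
#'     pairs present at every node}
#' @export
simulate_domain_histories <- function(tree, n_orthoclusters = 20, n_domains = 15,
                                      gain_rate = 0.3, loss_rate = 0.2, seed = 1) {
  stopifnot(n_domains >= 2)
  ix <- index_tree(tree)
  set.seed(seed)
  pool <- sprintf("D%02d", seq_len(n_domains))
  ogs <- sprintf("OG%03d", seq_len(n_orthoclusters))
  arch <- vector("list", ix$n_node)
  arch[[ix$root]] <- lapply(seq_len(n_orthoclusters),
                            function(i) sample(pool, 2, replace = FALSE))
  names(arch[[ix$root]]) <- ogs
  for (v in ix$preorder) {
    if (v == ix$root) next
    t <- ix$blen[v]
    a <- arch[[ix$parent[v]]]
    for (og in ogs) {
      d <- a[[og]]
      for (e in seq_len(stats::rpois(1, gain_rate * t)))
        d <- append(d, sample(pool, 1), after = sample.int(length(d) + 1, 1) - 1)
      for (e in seq_len(stats::rpois(1, loss_rate * t)))
        if (length(d) > 1) d <- d[-sample.int(length(d), 1)]
      a[[og]] <- d
    }
    arch[[v]] <- a
  }
  names(arch) <- ix$names
  tips <- ix$names[seq_len(ix$n_tip)]
  dt <- do.call(rbind, lapply(tips, function(sp) {
    do.call(rbind, lapply(ogs, function(og) {
      d <- arch[[sp]][[og]]
      data.frame(protein_id = paste0(sp, "_", og), domain_id = d,
                 ali_start = seq_along(d) * 100 - 99,
                 ali_end = seq_along(d) * 100 - 50, species = sp)
    }))
  }))
  og_tab <- lapply(ogs, function(og)
    stats::setNames(lapply(tips, function(sp) paste0(sp, "_", og)), tips))
  names(og_tab) <- ogs
  pt <- do.call(rbind, lapply(ix$names, function(nd) {
    do.call(rbind, lapply(ogs, function(og) {
      pr <- decompose_architecture(arch[[nd]][[og]])
      if (!length(pr)) return(NULL)
      data.frame(node = nd, orthocluster = og, pair = pr)
    }))
  }))
  list(architectures = arch, domain_table = dt,
       orthogroups = structure(og_tab, class = "ortholog_table"),
       pair_truth = pt)
}

#' Simulate a transposable-element landscape
#'
#' Family copy counts follow a discrete power law (probability proportional
#' to rank^-exponent); each family belongs to one amplification burst whose
#' mean pairwise identity and spread are configured. Within-family pairwise
#' identities are drawn Normal(burst mean, spread), truncated to [50, 100].
#' Hits below the downstream filters (70% identity, 80 bp) are still
#' emitted: filtering is the consumer's job.
#'
#' @param n_families number of TE families, >= 1
#' @param n_copies total TE copies across families
#' @param exponent power-law exponent of the copy-count distribution
#' @param burst_identity numeric vector of burst mean identities (%);
#'   families are assigned to bursts cyclically
#' @param burst_sd within-burst identity standard deviation
#' @param species species label
#' @param seed integer seed
#' @return list with
#'   \item{copies}{data.frame(copy_id, family_id, species)}
#'   \item{hits}{data.frame in 12-column tabular BLAST (outfmt 6) dialect}
#'   \item{family_counts}{named true copy count per family}
#' @export
simulate_te_landscape <- function(n_families = 10, n_copies = 500, exponent = 1.5,
                                  burst_identity = c(95, 78), burst_sd = 2,
                                  species = "spA", seed = 1) {
  stopifnot(n_families >= 1, n_copies >= n_families)
  set.seed(seed)
  w <- seq_len(n_families)^(-exponent)
  cnt <- as.vector(stats::rmultinom(1, n_copies - n_families, w / sum(w))) + 1L
  fam <- sprintf("TE%03d", seq_len(n_families))
  burst <- burst_identity[(seq_len(n_families) - 1) %% length(burst_identity) + 1]
  copies <- data.frame(
    copy_id = unlist(lapply(seq_len(n_families),
                            function(i) paste0(fam[i], "_c", seq_len(cnt[i])))),
    family_id = rep(fam, cnt), species = species)
  hits <- do.call(rbind, lapply(seq_len(n_families), function(i) {
    ids <- copies$copy_id[copies$family_id == fam[i]]
    if (length(ids) < 2) return(NULL)
    pr <- t(utils::combn(ids, 2))
    idy <- pmin(100, pmax(50, stats::rnorm(nrow(pr), burst[i], burst_sd)))
    len <- pmax(30L, as.integer(stats::rnbinom(nrow(pr), mu = 300, size = 2)))
    data.frame(qseqid = pr[, 1], sseqid = pr[, 2],
               pident = round(idy, 2), length = len,
               mismatch = as.integer(len * (100 - idy) / 100), gapopen = 0L,
               qstart = 1L, qend = len, sstart = 1L, send = len,
               evalue = 1e-10, bitscore = round(2 * len * idy / 100, 1))
  }))
  list(copies = copies, hits = hits,
       family_counts = stats::setNames(as.integer(cnt), fam))
}
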