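#' Protein domain architecture evolution
#'
#' Decomposes ordered domain architectures into directed binary domain
#' pairs within orthoclusters, reconstructs pair presence histories on the
#' species tree with the shared two-state machinery, places single-domain
#' gains and losses by Dollo parsimony, and summarizes per-node
#' diversification with an enrichment test for domain subsets among gains.
#'
#' @name domain-evolution
NULL

#' Decompose a domain architecture into directed binary pairs
#'
#' Consecutive runs of the same domain are collapsed first; then all
#' ordered pairs (d_i, d_j) with i < j over the collapsed sequence are
#' emitted, deduplicated. From A-B-B-C this yields A-B, A-C and B-C.
#' Non-consecutive repeats yield self-pairs: A-B-A gives A-B, A-A, B-A.
#'
#' @param arch character vector of domain ids, N- to C-terminal
#' @return character vector of "X->Y" directed pair keys (possibly empty)
#' @export
decompose_architecture <- function(arch) {
  if (length(arch) < 2) return(character(0))
  collapsed <- arch[c(TRUE, arch[-1] != arch[-length(arch)])]
  k <- length(collapsed)
  if (k < 2) return(character(0))
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  unique(paste0(collapsed[idx[, "row"]], "->", collapsed[idx[, "col"]]))
}

#' Build a pair-in-orthocluster profile
#'
#' Counts, per species, occurrences of each (directed pair, orthocluster)
#' combination over all proteins. A cluster can contain several pairs and a
#' pair can occur in several clusters; proteins outside any orthocluster
#' are ignored (their number is reported in a message).
#'
#' @param domain_table data.frame(protein_id, domain_id, ali_start,
#'   ali_end, species); domain order within a protein follows ali_start
#' @param orthogroups an \code{ortholog_table}
#' @return data.frame(pair, orthocluster, species, count), one row per
#'   non-zero combination
#' @export
build_pair_profile <- function(domain_table, orthogroups) {
  og_of <- character(0)
  for (id in names(orthogroups))
    for (sp in names(orthogroups[[id]])) {
      genes <- orthogroups[[id]][[sp]]
      og_of[genes] <- id
    }
  dt <- domain_table[order(domain_table$protein_id, domain_table$ali_start), ]
  archs <- split(dt$domain_id, dt$protein_id)
  sp_of <- vapply(split(dt$species, dt$protein_id), `[`, character(1), 1)
  outside <- sum(!(names(archs) %in% names(og_of)))
  if (outside) message(outside, " protein(s) outside any orthocluster ignored")
  rows <- list()
  for (p in names(archs)) {
    oc <- og_of[p]
    if (is.na(oc)) next
    pairs <- decompose_architecture(archs[[p]])
    if (!length(pairs)) next
    rows[[p]] <- data.frame(pair = pairs, orthocluster = unname(oc),
                            species = unname(sp_of[p]))
  }
  d <- do.call(rbind, rows)
  if (is.null(d))
    return(data.frame(pair = character(0), orthocluster = character(0),
                      species = character(0), count = integer(0)))
  agg <- stats::aggregate(list(count = rep(1L, nrow(d))),
                          d[, c("pair", "orthocluster", "species")], sum)
  rownames(agg) <- NULL
  agg
}

#' Presence/absence character matrix from a pair profile
#'
#' Characters are (pair, orthocluster) combinations; a species scores 1
#' when it carries the pair in that cluster at least once.
#'
#' @param profile data.frame from \code{\link{build_pair_profile}}
#' @param species all species (columns)
#' @return characters x species 0/1 matrix, rownames "pair@orthocluster"
#' @export
pair_presence_matrix <- function(profile, species) {
  key <- paste0(profile$pair, "@", profile$orthocluster)
  uk <- unique(key)
  m <- matrix(0, length(uk), length(species), dimnames = list(uk, species))
  m[cbind(match(key, uk), match(profile$species, species))] <- 1
  m
}

#' Reconstruct domain-pair histories on the species tree
#'
#' Fits branch-specific two-state gain/loss rates to the pair presence
#' matrix (conditioning on observability) and reconstructs ancestral
#' presence; ancestral presence is called at posterior >=
#' \code{call_threshold} (default 0.9). A gain is the acquisition of a new
#' pair-in-orthocluster combination; a loss is pair dissociation. Copy
#' number is not modelled.
#'
#' @param mat characters x species 0/1 matrix
#'   (\code{\link{pair_presence_matrix}})
#' @param tree rooted \code{phylo}
#' @param rates optional \code{gainloss_rates}; fitted from the data when NULL
#' @param call_threshold posterior probability for ancestral presence calls
#' @return list(fit, recon, calls = characters x nodes 0/1 matrix,
#'   events = per-branch expected gains/losses)
#' @export
reconstruct_pair_history <- function(mat, tree, rates = NULL,
                                     call_threshold = 0.9) {
  if (is.null(rates)) rates <- fit_gain_loss_model(mat, tree)
  recon <- reconstruct_ancestral_sites(mat, tree, rates)
  calls <- (recon$posterior >= call_threshold) * 1
  list(fit = rates, recon = recon, calls = calls, events = recon$events)
}

#' Dollo parsimony placement of a presence/absence character
#'
#' The character is gained exactly once, at the last common ancestor of all
#' leaves that carry it; losses are placed on the minimal set of branches
#' within that clade explaining every absence (one loss at the root of each
#' maximal all-absent subtree).
#'
#' @param presence named 0/1 vector over tree tips
#' @param tree rooted \code{phylo}
#' @return list(gain_node = name or NA, loss_branches = character vector of
#'   child-node names, n_losses)
#' @export
dollo_reconstruct <- function(presence, tree) {
  ix <- index_tree(tree)
  tips <- ix$names[seq_len(ix$n_tip)]
  stopifnot(all(tips %in% names(presence)))
  pres_tips <- which(presence[tips][tips] == 1)
  if (!length(pres_tips))
    return(list(gain_node = NA_character_, loss_branches = character(0),
                n_losses = 0L))
  # any-presence-below flag per node
  below <- logical(ix$n_node)
  for (v in ix$postorder) {
    below[v] <- if (v <= ix$n_tip) presence[[ix$names[v]]] == 1
                else any(below[ix$children[[v]]])
  }
  # gain node: MRCA of presence leaves
  gain <- if (length(pres_tips) == 1) pres_tips else {
    v <- pres_tips[1]
    anc_set <- integer(0)
    while (!is.na(v)) { anc_set <- c(anc_set, v); v <- ix$parent[v] }
    g <- NA_integer_
    for (a in anc_set) {
      sub_ok <- TRUE
      # a is MRCA iff all presence tips are below a; below[] has that info
      # collect tips below a
      stack <- a; tips_below <- integer(0)
      while (length(stack)) {
        x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        if (x <= ix$n_tip) tips_below <- c(tips_below, x)
        else stack <- c(stack, ix$children[[x]])
      }
      if (all(pres_tips %in% tips_below)) { g <- a; break }
    }
    g
  }
  # losses: maximal all-absent subtrees strictly inside the gain clade
  losses <- character(0)
  stack <- ix$children[[gain]]
  if (gain <= ix$n_tip) stack <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (!below[v]) losses <- c(losses, ix$names[v])
    else if (v > ix$n_tip) stack <- c(stack, ix$children[[v]])
  }
  list(gain_node = ix$names[gain], loss_branches = sort(losses),
       n_losses = length(losses))
}

#' Per-node diversification summary and classification
#'
#' Gains and losses as percentages of the pairs present at the node; a node
#' is gain-biased or loss-biased when the percentages differ by more than
#' \code{bias_margin} points (default 5), and in dynamic stasis otherwise.
#'
#' @param node_pairs named vector: pairs present per node (calls at the
#'   reconstruction threshold, or expected counts)
#' @param gains,losses named per-branch expected gains/losses (child-node
#'   names; the root may be absent)
#' @param bias_margin percentage-point margin for bias classification
#' @return data.frame(node, pairs_present, gains, losses, p_gain, p_loss,
#'   ratio, class); nodes with zero pairs are flagged "undefined"
#' @export
node_diversification <- function(node_pairs, gains, losses, bias_margin = 5) {
  nodes <- names(node_pairs)
  g <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  l <- g
  g[names(gains)] <- gains
  l[names(losses)] <- losses
  pg <- 100 * g / node_pairs
  pl <- 100 * l / node_pairs
  cls <- ifelse(node_pairs == 0, "undefined",
         ifelse(is.na(pg) | is.na(pl), NA_character_,
         ifelse(pg - pl > bias_margin, "gain-biased",
         ifelse(pl - pg > bias_margin, "loss-biased", "stasis"))))
  data.frame(node = nodes, pairs_present = unname(node_pairs),
             gains = unname(g), losses = unname(l),
             p_gain = unname(pg), p_loss = unname(pl),
             ratio = unname(gain_loss_ratio(pmax(pg, 0), pmax(pl, 0))),
             class = unname(cls), row.names = NULL)
}

#' Enrichment of a domain subset among node gains
#'
#' Two-sided Fisher exact test on the 2x2 table of \{gain at the focal node
#' vs elsewhere\} x \{pair contains a subset domain vs not\}. The
#' background is the set of gains at other nodes ("node-local" uses only
#' gains, which is the default; set \code{background} explicitly to use a
#' global gain set).
#'
#' @param focal_gains character vector of pair keys gained at the focal node
#' @param background character vector of pair keys gained elsewhere
#' @param family_domains character vector of domain ids defining the subset
#' @return list(table, p, odds_ratio); empty margins give p = 1 with warning
#' @export
enrichment_test <- function(focal_gains, background, family_domains) {
  if (!length(background)) stop("non-empty background required")
  in_fam <- function(pairs) {
    d <- strsplit(sub("@.*", "", pairs), "->", fixed = TRUE)
    vapply(d, function(x) any(x %in% family_domains), logical(1))
  }
  tab <- matrix(c(sum(in_fam(focal_gains)), sum(!in_fam(focal_gains)),
                  sum(in_fam(background)), sum(!in_fam(background))),
                nrow = 2,
                dimnames = list(c("in_family", "other"),
                                c("focal_node", "elsewhere")))
  fisher_2x2(t(tab))
}
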