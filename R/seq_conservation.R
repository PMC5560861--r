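#' Coding-sequence conservation from gene-tree distances
#'
#' Quantifies sequence conservation as cophenetic distances (sum of branch
#' lengths on the leaf-to-leaf path, in substitutions per alignment
#' position) in per-orthocluster gene trees, and compares distance
#' distributions between lineages with the Wilcoxon rank-sum test.
#'
#' @name seq-conservation
NULL

#' Cophenetic distance matrix of a gene tree
#'
#' @param tree a \code{phylo} with branch lengths on every edge
#' @return symmetric matrix of path-length distances between leaves
#' @export
cophenetic_distances <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("all branch lengths must be present")
  ape::cophenetic.phylo(tree)
}

#' Collect per-species-pair distances over a set of gene trees
#'
#' Distances are pooled across trees by default; \code{per_tree_mean}
#' averages within each tree first.
#'
#' @param trees list of \code{phylo} gene trees
#' @param per_tree_mean logical
#' @return data.frame(species_a, species_b, tree, distance) with
#'   species_a < species_b
#' @export
collect_distances <- function(trees, per_tree_mean = FALSE) {
  rows <- lapply(seq_along(trees), function(i) {
    d <- cophenetic_distances(trees[[i]])
    sp <- rownames(d)
    idx <- which(upper.tri(d), arr.ind = TRUE)
    a <- pmin(sp[idx[, 1]], sp[idx[, 2]])
    b <- pmax(sp[idx[, 1]], sp[idx[, 2]])
    data.frame(species_a = a, species_b = b, tree = i,
               distance = d[idx])
  })
  out <- do.call(rbind, rows)
  if (per_tree_mean)
    out <- stats::aggregate(distance ~ species_a + species_b + tree, out, mean)
  out
}

#' Compare distance distributions between two lineage groups
#'
#' For a focal reference species, gathers its distances to each group and
#' applies the two-sided Wilcoxon rank-sum test (exact when the combined
#' sample is small and tie-free, normal approximation with continuity and
#' tie correction otherwise).
#'
#' @param dist data.frame from \code{\link{collect_distances}}
#' @param focal_reference species whose distances are compared
#' @param group1,group2 character vectors of species
#' @return list(statistic = rank-sum W, p, n1, n2, median1, median2)
#' @export
compare_lineage_distances <- function(dist, focal_reference, group1, group2) {
  get <- function(grp) {
    sel <- (dist$species_a == focal_reference & dist$species_b %in% grp) |
           (dist$species_b == focal_reference & dist$species_a %in% grp)
    dist$distance[sel]
  }
  x <- get(group1); y <- get(group2)
  if (length(x) < 3 || length(y) < 3)
    stop("at least 3 distances per group are required")
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = (length(x) + length(y) <= 25) &&
                                   !anyDuplicated(c(x, y)),
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y),
       median1 = stats::median(x), median2 = stats::median(y))
}
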