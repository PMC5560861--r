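#' Pairwise microsynteny from single-copy ortholog collinearity
#'
#' Microsynteny between two genomes is measured as the number of collinear
#' ortholog pairs: orthogroups with exactly one gene in each species whose
#' two members are adjacent in both genomes, irrespective of gene
#' orientation. A permutation null (random assignment of gene identities to
#' the fixed gene positions of each genome) estimates the spurious count,
#' and the pairwise ratio r is normalized by the best pair of the dataset.
#'
#' "Adjacent" by default means consecutive among the genes that belong to
#' the shared single-copy ortholog set on the same scaffold (intervening
#' non-ortholog genes are ignored); strict genomic adjacency is available
#' via \code{mode = "strict"}.
#'
#' @name synteny
NULL

# per-genome ordered gene lists restricted to `keep` gene ids
ordered_gene_lists <- function(gm, keep, mode = c("orthoset", "strict")) {
  mode <- match.arg(mode)
  gm <- gm[order(gm$scaffold, vapply(gm$cds_segments, function(s)
    min(s[, "start"]), numeric(1))), , drop = FALSE]
  by_scf <- split(gm$gene_id, gm$scaffold)
  if (mode == "orthoset") by_scf <- lapply(by_scf, function(g) g[g %in% keep])
  by_scf
}

# unordered adjacent orthogroup pairs of one genome: set of "og1|og2" keys
adjacency_keys <- function(ordered, og_of) {
  keys <- character(0)
  for (g in ordered) {
    og <- og_of[g]
    if (length(og) < 2) next
    a <- og[-length(og)]; b <- og[-1]
    ok <- !is.na(a) & !is.na(b)
    keys <- c(keys, paste(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]), sep = "|"))
  }
  unique(keys)
}

# orthogroups with exactly one gene in each of two species
single_copy_map <- function(orthogroups, sp_i, sp_j) {
  sel <- vapply(orthogroups, function(og)
    length(og[[sp_i]]) == 1 && length(og[[sp_j]]) == 1, logical(1))
  og <- orthogroups[sel]
  list(ids = names(og),
       gene_i = vapply(og, function(x) x[[sp_i]], character(1)),
       gene_j = vapply(og, function(x) x[[sp_j]], character(1)))
}

#' Count collinear single-copy ortholog pairs between two genomes
#'
#' @param gm_i,gm_j \code{gene_models} for the two species
#' @param orthogroups an \code{ortholog_table}; only orthogroups with
#'   exactly one gene in each species are used
#' @param mode "orthoset" (default): adjacency among single-copy-ortholog
#'   genes only; "strict": genomic adjacency over all annotated genes
#' @return list(c = shared adjacent pair count, N = number of comparable
#'   single-copy ortholog pairs, n_scaffolds_i, n_scaffolds_j)
#' @export
count_collinear_pairs <- function(gm_i, gm_j, orthogroups,
                                  mode = c("orthoset", "strict")) {
  mode <- match.arg(mode)
  if (!nrow(gm_i) || !nrow(gm_j)) stop("species with no annotated genes")
  sp_i <- gm_i$species[1]; sp_j <- gm_j$species[1]
  sc <- single_copy_map(orthogroups, sp_i, sp_j)
  og_of_i <- stats::setNames(sc$ids, sc$gene_i)
  og_of_j <- stats::setNames(sc$ids, sc$gene_j)
  ord_i <- ordered_gene_lists(gm_i, sc$gene_i, mode)
  ord_j <- ordered_gene_lists(gm_j, sc$gene_j, mode)
  ki <- adjacency_keys(ord_i, og_of_i)
  kj <- adjacency_keys(ord_j, og_of_j)
  list(c = length(intersect(ki, kj)), N = length(sc$ids),
       n_scaffolds_i = length(ord_i), n_scaffolds_j = length(ord_j))
}

#' Permutation null for collinear pair counts
#'
#' Per round, gene identities are randomly permuted over the fixed gene
#' positions of each genome (scaffold gene counts preserved), and collinear
#' pairs are re-counted. Returns the mean spurious count.
#'
#' @inheritParams count_collinear_pairs
#' @param n_rounds permutation rounds (default 100)
#' @param seed integer seed
#' @return list(s = mean spurious count, counts = per-round counts)
#' @export
shuffle_null <- function(gm_i, gm_j, orthogroups, n_rounds = 100, seed = 1,
                         mode = c("orthoset", "strict")) {
  mode <- match.arg(mode)
  stopifnot(n_rounds >= 1)
  sp_i <- gm_i$species[1]; sp_j <- gm_j$species[1]
  sc <- single_copy_map(orthogroups, sp_i, sp_j)
  og_of_i <- stats::setNames(sc$ids, sc$gene_i)
  og_of_j <- stats::setNames(sc$ids, sc$gene_j)
  ord_i <- ordered_gene_lists(gm_i, sc$gene_i, mode)
  ord_j <- ordered_gene_lists(gm_j, sc$gene_j, mode)
  set.seed(seed)
  permute <- function(ord) {
    flat <- unlist(ord, use.names = FALSE)
    flat <- sample(flat)
    utils::relist(flat, ord)
  }
  counts <- vapply(seq_len(n_rounds), function(r) {
    ki <- adjacency_keys(permute(ord_i), og_of_i)
    kj <- adjacency_keys(permute(ord_j), og_of_j)
    length(intersect(ki, kj))
  }, numeric(1))
  list(s = mean(counts), counts = counts)
}

#' Pairwise synteny analysis over a set of genomes
#'
#' @param gm_list named list of \code{gene_models}, one per species
#' @param orthogroups an \code{ortholog_table}
#' @param n_rounds permutation rounds for the null
#' @param seed integer seed
#' @param mode adjacency mode, see \code{\link{count_collinear_pairs}}
#' @return data.frame(species_i, species_j, c, s, N) for all unordered pairs
#' @export
synteny_pairs <- function(gm_list, orthogroups, n_rounds = 100, seed = 1,
                          mode = c("orthoset", "strict")) {
  mode <- match.arg(mode)
  sp <- names(gm_list)
  out <- list()
  k <- 0
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (j <= i) next
    k <- k + 1
    cc <- count_collinear_pairs(gm_list[[i]], gm_list[[j]], orthogroups, mode)
    # common random numbers across pairs: identical structure yields an
    # identical null, so equal pairs normalize to equal ratios
    nn <- shuffle_null(gm_list[[i]], gm_list[[j]], orthogroups, n_rounds,
                       seed = seed, mode = mode)
    out[[k]] <- data.frame(species_i = sp[i], species_j = sp[j],
                           c = cc$c, s = nn$s, N = cc$N)
  }
  do.call(rbind, out)
}

#' Normalized synteny ratio matrix
#'
#' r_ij = [(c_ij - s_ij)/N_ij] / [(c_max - s_max)/N_max], where the
#' reference pair maximizes (c - s)/N over the dataset; negative values are
#' clamped to 0, so r lies in [0, 1] with the best pair at exactly 1.
#'
#' @param pairs data.frame as returned by \code{\link{synteny_pairs}}
#' @return symmetric matrix of r values (diagonal NA)
#' @export
synteny_ratio <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  raw <- (pairs$c - pairs$s) / pairs$N
  ref <- max(raw)
  if (ref <= 0) stop("no signal above null: best pair has (c - s) <= 0")
  r <- pmax(raw / ref, 0)
  sp <- sort(unique(c(pairs$species_i, pairs$species_j)))
  m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  for (k in seq_len(nrow(pairs))) {
    m[pairs$species_i[k], pairs$species_j[k]] <- r[k]
    m[pairs$species_j[k], pairs$species_i[k]] <- r[k]
  }
  m
}

#' Ward clustering of species by synteny profile
#'
#' Agglomerative Ward clustering (stats::hclust, "ward.D2") on Euclidean
#' distances between the rows of the ratio matrix. Rows are ordered
#' lexicographically by species name before clustering so the result is
#' deterministic. The diagonal is treated as 1 (a genome is fully syntenic
#' with itself).
#'
#' @param m symmetric synteny ratio matrix
#' @return an \code{hclust} object
#' @export
cluster_species_by_synteny <- function(m) {
  if (any(is.na(m[row(m) != col(m)]))) stop("NaN/NA entries in synteny matrix")
  m <- m[order(rownames(m)), order(colnames(m))]
  diag(m) <- 1
  stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
}
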