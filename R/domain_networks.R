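#' Domain co-occurrence networks
#'
#' Each (extant or ancestral) genome is modelled as an undirected simple
#' graph: vertices are domains, edges link domains that co-occur as a pair
#' within some gene family. Community structure is obtained by Louvain
#' clustering and summarized by Newman modularity Q; a degree-preserving
#' rewiring null (double-edge swaps) calibrates Q against random graphs
#' with the same degree sequence.
#'
#' @name domain-networks
NULL

#' Build a domain co-occurrence network
#'
#' Directed pairs are merged into undirected edges; self-pairs (A,A) are
#' excluded from the edge set but kept as a vertex attribute
#' \code{has_self_pair}. Parallel edges are collapsed; the orthoclusters
#' supporting each edge are recorded in the edge attribute
#' \code{orthoclusters}.
#'
#' @param profile data.frame(pair, orthocluster, ...) as from
#'   \code{\link{build_pair_profile}}, restricted to one genome, or for an
#'   ancestral node the pairs called present at the posterior threshold
#' @param label genome/node label stored on the graph
#' @return an \code{igraph} graph
#' @export
build_network <- function(profile, label = NA_character_) {
  if (!nrow(profile)) stop("non-empty pair set required")
  d <- strsplit(profile$pair, "->", fixed = TRUE)
  a <- vapply(d, `[`, character(1), 1)
  b <- vapply(d, `[`, character(1), 2)
  selfv <- unique(a[a == b])
  keep <- a != b
  ek <- paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), sep = "|")
  oc <- if ("orthocluster" %in% colnames(profile)) profile$orthocluster[keep]
        else rep(NA_character_, sum(keep))
  prov <- lapply(split(oc, ek), function(x) sort(unique(x)))
  uek <- names(prov)
  em <- do.call(rbind, strsplit(uek, "|", fixed = TRUE))
  verts <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2]),
    directed = FALSE, vertices = data.frame(name = verts))
  igraph::E(g)$orthoclusters <- unname(prov)
  igraph::V(g)$has_self_pair <- verts %in% selfv
  g$label <- label
  g
}

#' Louvain community structure and modularity
#'
#' Louvain clustering at resolution 1 with a seeded random vertex
#' permutation (igraph's Louvain depends on vertex order; seeding the
#' shuffle makes the result deterministic per seed). Q is Newman
#' modularity of the returned partition.
#'
#' @param net an \code{igraph} graph with >= 1 edge
#' @param seed integer seed
#' @return list(membership = named community id per vertex, Q,
#'   n_communities, mean_domains_per_community)
#' @export
community_modularity <- function(net, seed = 1) {
  if (igraph::ecount(net) == 0) stop("edgeless graph: no communities to find")
  set.seed(seed)
  perm <- sample(igraph::vcount(net))
  gp <- igraph::permute(net, perm)
  cl <- igraph::cluster_louvain(gp, resolution = 1)
  memb <- igraph::membership(cl)[igraph::V(net)$name]
  list(membership = memb,
       Q = igraph::modularity(net, memb[igraph::V(net)$name]),
       n_communities = length(unique(memb)),
       mean_domains_per_community = igraph::vcount(net) / length(unique(memb)))
}

#' Degree-preserving rewiring null for modularity
#'
#' Each replicate applies double-edge swaps (default 10 x |E| attempts,
#' rejecting swaps that would create self-loops or parallel edges) and
#' recomputes Louvain modularity. Every replicate has exactly the original
#' degree sequence.
#'
#' @param net an \code{igraph} graph with >= 2 edges
#' @param n_reps replicates (default 100)
#' @param seed integer seed
#' @param swaps_per_edge swap attempts per edge (default 10)
#' @return list(Q = numeric vector of replicate modularities,
#'   graphs = list of rewired graphs)
#' @export
rewire_null <- function(net, n_reps = 100, seed = 1, swaps_per_edge = 10) {
  stopifnot(igraph::ecount(net) >= 2)
  set.seed(seed)
  niter <- swaps_per_edge * igraph::ecount(net)
  reps <- lapply(seq_len(n_reps), function(r) {
    g <- igraph::rewire(net, igraph::keeping_degseq(loops = FALSE,
                                                    niter = niter))
    if (identical(igraph::as_edgelist(g), igraph::as_edgelist(net)) &&
        igraph::ecount(net) <= 2)
      warning("graph admits no valid swap; replicate equals original")
    g
  })
  Q <- vapply(seq_along(reps), function(i)
    community_modularity(reps[[i]], seed = seed + i)$Q, numeric(1))
  list(Q = Q, graphs = reps)
}

#' Spearman correlation of modularity against community size
#'
#' Tests the monotonic relationship between network modularity and the mean
#' number of domains per community across genomes. Exact p for n <= 9
#' without ties, t-approximation otherwise (stats::cor.test behaviour).
#'
#' @param Q numeric vector of modularities, one per genome
#' @param mean_community_size matching vector of mean domains per community
#' @return list(rho, p); constant input gives rho = NaN with a warning
#' @export
modularity_vs_community_size <- function(Q, mean_community_size) {
  stopifnot(length(Q) == length(mean_community_size), length(Q) >= 4)
  if (stats::sd(Q) == 0 || stats::sd(mean_community_size) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NaN, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(Q, mean_community_size, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Orthocluster-mediated subnetwork
#'
#' Restricts a network to the edges whose supporting orthoclusters contain
#' at least one of the listed domains (an orthocluster "contains" a domain
#' when some edge it supports touches that domain). Vertex-induced
#' restriction is available with \code{mode = "vertex"}.
#'
#' @param net an \code{igraph} from \code{\link{build_network}}
#' @param domain_list non-empty character vector of domain ids
#' @param mode "orthocluster" (default) or "vertex"
#' @return the restricted \code{igraph} (possibly empty, with a warning)
#' @export
subnetwork <- function(net, domain_list, mode = c("orthocluster", "vertex")) {
  mode <- match.arg(mode)
  stopifnot(length(domain_list) >= 1)
  if (mode == "vertex") {
    keep <- igraph::V(net)$name %in% domain_list
    return(igraph::induced_subgraph(net, which(keep)))
  }
  el <- igraph::as_edgelist(net)
  prov <- igraph::E(net)$orthoclusters
  touched <- unique(unlist(prov[el[, 1] %in% domain_list |
                                el[, 2] %in% domain_list]))
  keep_e <- vapply(prov, function(x) any(x %in% touched), logical(1))
  if (!any(keep_e)) {
    warning("no orthocluster matches the domain list; empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::subgraph_from_edges(net, which(keep_e), delete.vertices = TRUE)
  g
}
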