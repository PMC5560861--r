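# Independent brute-force oracles. These re-derive expected values by
# enumeration or closed form and are deliberately kept free of the package's
# own algorithmic code paths (they use only base R, ape tree bookkeeping and
# igraph's modularity formula where igraph is the established reference).

# --- two-state model: enumeration over all internal-state assignments -----
# pat: named 0/1 vector over tips; gain/loss/blen keyed by child node name.
oracle_twostate <- function(tree, pat, gain, loss, root_p) {
  tree <- archevol:::label_tree_nodes(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  nm <- c(tree$tip.label, tree$node.label)
  parent <- rep(NA_integer_, n_node)
  blen <- rep(NA_real_, n_node)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    blen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  ptrans <- function(a, b, g, l, t) {
    r <- g + l
    if (r == 0) return(as.numeric(a == b))
    f <- 1 - exp(-r * t)
    m <- matrix(c(1 - g / r * f, l / r * f, g / r * f, 1 - l / r * f), 2)
    m[a + 1, b + 1]
  }
  internals <- setdiff(seq_len(n_node), seq_len(n_tip))
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internals))))
  tot <- 0; postsum <- rep(0, n_node)
  gains <- losses <- rep(0, n_node)
  for (gi in seq_len(nrow(grid))) {
    st <- rep(NA_integer_, n_node)
    st[internals] <- grid[gi, ]
    st[seq_len(n_tip)] <- pat[tree$tip.label]
    if (anyNA(st)) next
    p <- if (st[root] == 1) root_p else 1 - root_p
    for (v in seq_len(n_node)) {
      if (v == root) next
      p <- p * ptrans(st[parent[v]], st[v], gain[[nm[v]]], loss[[nm[v]]],
                      blen[v])
    }
    tot <- tot + p
    postsum <- postsum + p * st
    for (v in seq_len(n_node)) {
      if (v == root) next
      if (st[parent[v]] == 0 && st[v] == 1) gains[v] <- gains[v] + p
      if (st[parent[v]] == 1 && st[v] == 0) losses[v] <- losses[v] + p
    }
  }
  list(lik = tot, posterior = stats::setNames(postsum / tot, nm),
       gains = stats::setNames(gains / tot, nm),
       losses = stats::setNames(losses / tot, nm))
}

# --- Dollo: enumerate all state assignments, keep single-gain minimal-loss
oracle_dollo <- function(tree, presence) {
  tree <- archevol:::label_tree_nodes(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  nm <- c(tree$tip.label, tree$node.label)
  parent <- rep(NA_integer_, n_node)
  for (e in seq_len(nrow(tree$edge))) parent[tree$edge[e, 2]] <- tree$edge[e, 1]
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  if (sum(presence[tree$tip.label]) == 0)
    return(list(n_losses = 0L, gain_node = NA_character_))
  internals <- setdiff(seq_len(n_node), seq_len(n_tip))
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internals))))
  best <- Inf; best_gain <- NA_character_
  for (gi in seq_len(nrow(grid))) {
    st <- rep(NA_integer_, n_node)
    st[internals] <- grid[gi, ]
    st[seq_len(n_tip)] <- presence[tree$tip.label]
    gain_edges <- sum(vapply(seq_len(n_node), function(v)
      v != root && st[parent[v]] == 0 && st[v] == 1, logical(1)))
    n_gain <- gain_edges + (st[root] == 1)
    if (n_gain != 1) next
    n_loss <- sum(vapply(seq_len(n_node), function(v)
      v != root && st[parent[v]] == 1 && st[v] == 0, logical(1)))
    if (n_loss < best) {
      best <- n_loss
      gv <- if (st[root] == 1) root else
        which(vapply(seq_len(n_node), function(v)
          v != root && st[parent[v]] == 0 && st[v] == 1, logical(1)))
      best_gain <- nm[gv[1]]
    }
  }
  list(n_losses = as.integer(best), gain_node = best_gain)
}

# --- modularity: exhaustive maximum over all set partitions (n <= 8) ------
all_partitions <- function(n) {
  # restricted growth strings
  out <- list()
  rec <- function(s, mx) {
    k <- length(s)
    if (k == n) { out[[length(out) + 1]] <<- s; return(invisible()) }
    for (v in seq_len(mx + 1)) rec(c(s, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

oracle_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- igraph::modularity(g, p)
    if (q > best) best <- q
  }
  best
}

# --- Fisher two-sided p: hypergeometric enumeration over fixed margins ----
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  prob <- function(a) stats::dhyper(a, r1, r2, c1)
  a_obs <- tab[1, 1]
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  ps <- vapply(lo:hi, prob, numeric(1))
  sum(ps[ps <= prob(a_obs) * (1 + 1e-7)])
}

# --- Wilcoxon exact two-sided p by full permutation enumeration ----------
oracle_wilcox <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  combs <- utils::combn(n, n1)
  W <- apply(combs, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
}

# --- shared adjacencies by direct enumeration ----------------------------
oracle_shared_adjacencies <- function(ordA, ordB) {
  pairs <- function(o) {
    if (length(o) < 2) return(character(0))
    unique(paste(pmin(o[-length(o)], o[-1]), pmax(o[-length(o)], o[-1])))
  }
  length(intersect(pairs(ordA), pairs(ordB)))
}

# --- greedy Ward agglomeration minimizing ESS increase -------------------
oracle_ward_merges <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), function(i) i)
  merges <- list()
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    ctr <- colMeans(m[idx, , drop = FALSE])
    sum(sweep(m[idx, , drop = FALSE], 2, ctr)^2)
  }
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- ess(c(clusters[[i]], clusters[[j]])) -
           ess(clusters[[i]]) - ess(clusters[[j]])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    merges[[length(merges) + 1]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  merges
}

# cluster membership sets from an hclust object, in merge order
hclust_merge_sets <- function(hc) {
  sets <- list()
  out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    s <- sort(c(get(hc$merge[k, 1]), get(hc$merge[k, 2])))
    sets[[k]] <- s
    out[[k]] <- s
  }
  out
}

# small fixture tree used across tests
fixture_tree8 <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.4,B:0.6)N1:0.3,(C:0.5,D:0.4)N2:0.5)N3:0.4,",
    "((E:0.7,F:0.3)N4:0.4,(G:0.5,H:0.6)N5:0.3)N6:0.5)R;"))
}

fixture_tree4 <- function() {
  ape::read.tree(text = "((A:0.3,B:0.7)N1:0.5,(C:0.2,D:1.1)N2:0.4)R;")
}
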