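#' Tree indexing utilities
#'
#' Internal helpers that turn an \code{ape} \code{phylo} object into the flat
#' structures the reconstruction machinery needs: node names, parent/child
#' maps, traversal orders and per-branch lengths keyed by child node.
#'
#' @name tree-utils
#' @keywords internal
NULL

#' Ensure a tree has unique node labels
#'
#' Leaves keep their tip labels; internal nodes without labels are assigned
#' "N<k>" in \code{ape} node numbering order. Zero or missing branch lengths
#' are permitted; missing lengths default to 1 with a warning.
#'
#' @param tree an \code{ape} \code{phylo} object, rooted
#' @return the tree with \code{node.label} set and \code{edge.length} present
#' @keywords internal
label_tree_nodes <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_int <- tree$Nnode
  if (is.null(tree$node.label) || any(is.na(tree$node.label)) ||
      any(!nzchar(tree$node.label))) {
    lab <- tree$node.label
    if (is.null(lab)) lab <- rep("", n_int)
    fill <- paste0("N", seq_len(n_int))
    lab[is.na(lab) | !nzchar(lab)] <- fill[is.na(lab) | !nzchar(lab)]
    tree$node.label <- lab
  }
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    stop("duplicated node names in tree")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 1")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree
}

#' Flat index of a rooted phylo tree
#'
#' @param tree a rooted \code{phylo}; labelled via \code{label_tree_nodes}
#' @return list with components:
#'   \item{tree}{the labelled tree}
#'   \item{n_tip, n_node}{tip count and total node count}
#'   \item{names}{node names indexed by ape node number (tips first)}
#'   \item{root}{root node number}
#'   \item{parent}{parent node number per node (NA at root)}
#'   \item{children}{list of child node numbers per node}
#'   \item{blen}{branch length per node (branch above it; NA at root)}
#'   \item{postorder}{internal+tip node numbers, children before parents}
#'   \item{preorder}{reverse of postorder}
#' @keywords internal
index_tree <- function(tree) {
  tree <- label_tree_nodes(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  nm <- c(tree$tip.label, tree$node.label)
  parent <- rep(NA_integer_, n_node)
  blen <- rep(NA_real_, n_node)
  children <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    parent[ch] <- p
    blen[ch] <- tree$edge.length[e]
    children[[p]] <- c(children[[p]], ch)
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  # postorder via DFS
  post <- integer(0)
  stack <- root
  visited <- logical(n_node)
  order_stack <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    order_stack <- c(order_stack, v)
    stack <- c(stack, children[[v]])
  }
  post <- rev(order_stack)
  list(tree = tree, n_tip = n_tip, n_node = n_node, names = nm, root = root,
       parent = parent, children = children, blen = blen,
       postorder = post, preorder = order_stack)
}

#' Branch names of a tree
#'
#' Branches are identified by the name of the node below them (their child
#' end); the root has no branch.
#'
#' @param tree a rooted \code{phylo}
#' @return character vector of branch (child-node) names
#' @export
branch_names <- function(tree) {
  ix <- index_tree(tree)
  ix$names[setdiff(seq_len(ix$n_node), ix$root)]
}
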