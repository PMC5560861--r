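#' Two-state gain/loss Markov model on a species tree
#'
#' Continuous-time Markov chain on \{absent (0), present (1)\} with
#' branch-specific gain rate g (0 -> 1) and loss rate l (1 -> 0). Used for
#' probabilistic ancestral reconstruction of binary genome-architecture
#' characters: intron presence at homologous sites and domain-pair presence
#' in orthoclusters. Likelihoods are computed by Felsenstein pruning over
#' sites; by default they are conditioned on each site being observable
#' (present in at least one extant species), the ascertainment typical of
#' characters discovered in extant annotations.
#'
#' @name twostate
NULL

#' Transition probability matrix of the two-state chain
#'
#' P(0 -> 1; t) = g/(g+l) * (1 - exp(-(g+l) t)) and symmetrically for loss.
#' When g + l = 0 the identity matrix is returned.
#'
#' @param gain gain rate (events per unit branch length), >= 0
#' @param loss loss rate, >= 0
#' @param t branch length, >= 0
#' @return 2x2 matrix, rows = parent state (0,1), cols = child state (0,1)
#' @export
#' @examples
#' branch_transition(1, 1, 1e6)  # stationary: all rows ~ c(0.5, 0.5)
branch_transition <- function(gain, loss, t) {
  stopifnot(gain >= 0, loss >= 0, t >= 0)
  r <- gain + loss
  if (r == 0 || t == 0) return(diag(2))
  f <- 1 - exp(-r * t)
  p01 <- gain / r * f
  p10 <- loss / r * f
  matrix(c(1 - p01, p10, p01, 1 - p10), nrow = 2)
}

#' Construct a rates object
#'
#' @param tree rooted \code{phylo}
#' @param gain,loss named numeric vectors of per-branch rates (names =
#'   branch child-node names) or a single number recycled to every branch
#' @param root_p probability that a character is present at the root
#' @return object of class \code{gainloss_rates}
#' @export
gainloss_rates <- function(tree, gain, loss, root_p = 0.5) {
  br <- branch_names(tree)
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, length(br)), br)
    if (!all(br %in% names(x))) stop("missing ", what, " rate for some branches")
    x <- x[br]
    if (any(x < 0) || any(!is.finite(x))) stop(what, " rates must be finite and >= 0")
    x
  }
  structure(list(gain = expand(gain, "gain"), loss = expand(loss, "loss"),
                 root_p = root_p, branches = br),
            class = "gainloss_rates")
}

# Collapse a sites x species 0/1/NA matrix into unique patterns + weights.
collapse_patterns <- function(mat) {
  key <- apply(mat, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  u <- !duplicated(key)
  list(pat = mat[u, , drop = FALSE], w = as.vector(table(key)[key[u]]),
       site_of = match(key, key[u]))
}

# Per-branch transition matrices for a rates object on an indexed tree.
branch_matrices <- function(ix, rates) {
  M <- vector("list", ix$n_node)
  for (v in seq_len(ix$n_node)) {
    if (v == ix$root) next
    nm <- ix$names[v]
    M[[v]] <- branch_transition(rates$gain[[nm]], rates$loss[[nm]], ix$blen[v])
  }
  M
}

# Inside (pruning) pass. pat: patterns x species matrix (0/1/NA).
# Returns list(L = list of 2 x P matrices per node, logscale = P vector,
# msg = list of child->parent messages 2 x P).
inside_pass <- function(ix, pat, M) {
  P <- nrow(pat)
  sp_col <- match(ix$names[seq_len(ix$n_tip)], colnames(pat))
  L <- vector("list", ix$n_node)
  msg <- vector("list", ix$n_node)
  logscale <- rep(0, P)
  for (v in ix$postorder) {
    if (v <= ix$n_tip) {
      x <- pat[, sp_col[v]]
      Lv <- rbind(ifelse(is.na(x), 1, 1 - x), ifelse(is.na(x), 1, x))
    } else {
      Lv <- matrix(1, 2, P)
      for (ch in ix$children[[v]]) Lv <- Lv * msg[[ch]]
      sc <- pmax(Lv[1, ], Lv[2, ])
      sc[sc == 0] <- 1
      Lv <- sweep(Lv, 2, sc, "/")
      logscale <- logscale + log(sc)
    }
    L[[v]] <- Lv
    if (v != ix$root) msg[[v]] <- M[[v]] %*% Lv
  }
  list(L = L, msg = msg, logscale = logscale)
}

# Log-likelihood per pattern (unconditioned) and the probability of the
# all-absent pattern, given species present in `species` columns.
pattern_loglik <- function(ix, pat, rates) {
  M <- branch_matrices(ix, rates)
  ins <- inside_pass(ix, pat, M)
  prior <- c(1 - rates$root_p, rates$root_p)
  lik <- prior[1] * ins$L[[ix$root]][1, ] + prior[2] * ins$L[[ix$root]][2, ]
  list(loglik = log(lik) + ins$logscale, inside = ins, M = M)
}

# Probability that a character is absent from every extant species.
prob_all_absent <- function(ix, rates, species) {
  pat0 <- matrix(0, 1, length(species), dimnames = list(NULL, species))
  exp(pattern_loglik(ix, pat0, rates)$loglik)
}

#' Log-likelihood of a presence/absence matrix under a rates object
#'
#' @param mat sites x species matrix with entries 0, 1 or NA (missing)
#' @param tree rooted \code{phylo} whose tip labels match \code{colnames(mat)}
#' @param rates a \code{gainloss_rates} object
#' @param condition_observable if TRUE (default), condition the likelihood on
#'   each site being present in at least one extant species
#' @return total log-likelihood (numeric scalar)
#' @export
gainloss_loglik <- function(mat, tree, rates, condition_observable = TRUE) {
  ix <- index_tree(tree)
  if (!all(ix$names[seq_len(ix$n_tip)] %in% colnames(mat)))
    stop("matrix columns must cover all tree tips")
  cp <- collapse_patterns(mat)
  pl <- pattern_loglik(ix, cp$pat, rates)
  ll <- sum(cp$w * pl$loglik)
  if (condition_observable) {
    p0 <- prob_all_absent(ix, rates, colnames(mat))
    ll <- ll - nrow(mat) * log1p(-p0)
  }
  ll
}

#' Fit branch-specific gain/loss rates by maximum likelihood
#'
#' Maximizes the pruning log-likelihood of an extant presence/absence matrix
#' over per-branch gain and loss rates and the root presence probability,
#' conditioned (by default) on sites being present in at least one extant
#' species. Optimization is quasi-Newton (L-BFGS-B) on log-rates and the
#' logit root probability; convergence is declared when the log-likelihood
#' improves by less than \code{tol} (default 1e-6) between iterations, with
#' at most \code{max_iter} iterations.
#'
#' @inheritParams gainloss_loglik
#' @param init_rate starting value for all rates
#' @param tol log-likelihood convergence tolerance
#' @param max_iter maximum optimizer iterations
#' @return a \code{gainloss_fit}: the fitted \code{gainloss_rates} plus
#'   \code{loglik}, \code{converged}, \code{n_sites}
#' @export
fit_gain_loss_model <- function(mat, tree, condition_observable = TRUE,
                                init_rate = 0.5, tol = 1e-6, max_iter = 1000) {
  if (all(mat == 0 | is.na(mat))) stop("all-absent matrix: nothing to fit")
  ix <- index_tree(tree)
  tips <- ix$names[seq_len(ix$n_tip)]
  if (!all(tips %in% colnames(mat))) stop("matrix columns must cover all tree tips")
  mat <- mat[, tips, drop = FALSE]
  cp <- collapse_patterns(mat)
  br <- ix$names[setdiff(seq_len(ix$n_node), ix$root)]
  B <- length(br)
  n_sites <- nrow(mat)

  unpack <- function(theta) {
    gainloss_rates(ix$tree,
                   gain = stats::setNames(exp(theta[1:B]), br),
                   loss = stats::setNames(exp(theta[B + 1:B]), br),
                   root_p = stats::plogis(theta[2 * B + 1]))
  }
  negll <- function(theta) {
    rates <- unpack(theta)
    pl <- pattern_loglik(ix, cp$pat, rates)
    ll <- sum(cp$w * pl$loglik)
    if (condition_observable) {
      p0 <- prob_all_absent(ix, rates, tips)
      ll <- ll - n_sites * log1p(-p0)
    }
    if (!is.finite(ll))
      stop("non-finite likelihood; parameters: ",
           paste(signif(theta, 4), collapse = ","))
    -ll
  }
  theta0 <- c(rep(log(init_rate), 2 * B), 0)
  opt <- stats::optim(theta0, negll, method = "L-BFGS-B",
                      lower = rep(c(-15, -15, -12), c(B, B, 1)),
                      upper = rep(c(6, 6, 12), c(B, B, 1)),
                      control = list(maxit = max_iter,
                                     factr = tol / .Machine$double.eps))
  rates <- unpack(opt$par)
  structure(list(gain = rates$gain, loss = rates$loss, root_p = rates$root_p,
                 branches = br, loglik = -opt$value,
                 converged = opt$convergence == 0, n_sites = n_sites),
            class = c("gainloss_fit", "gainloss_rates"))
}

#' Ancestral reconstruction and expected branch events
#'
#' Computes, by the up-down (inside-outside) recursion, the per-site
#' posterior presence probability at every node and the expected number of
#' gains (parent absent, child present) and losses per branch, given the
#' observed extant matrix and a rates object. Posteriors are conditional on
#' the observed data, so any ascertainment conditioning used during rate
#' fitting cancels out here.
#'
#' @inheritParams gainloss_loglik
#' @return list with
#'   \item{posterior}{sites x nodes matrix of presence probabilities; leaf
#'     columns equal the data where observed}
#'   \item{events}{data.frame(branch, expected_gains, expected_losses)}
#'   \item{node_counts}{expected intron/character count per node
#'     (column sums of \code{posterior})}
#' @export
reconstruct_ancestral_sites <- function(mat, tree, rates) {
  ix <- index_tree(tree)
  tips <- ix$names[seq_len(ix$n_tip)]
  mat <- mat[, tips, drop = FALSE]
  cp <- collapse_patterns(mat)
  P <- nrow(cp$pat)
  M <- branch_matrices(ix, rates)
  ins <- inside_pass(ix, cp$pat, M)
  prior <- c(1 - rates$root_p, rates$root_p)

  # outside pass: G[[v]] is 2 x P, unnormalized (per-pattern scale cancels
  # in every posterior because we normalize per site at the end)
  G <- vector("list", ix$n_node)
  G[[ix$root]] <- matrix(prior, 2, P)
  post <- matrix(NA_real_, P, ix$n_node)
  gains <- losses <- rep(0, ix$n_node)
  site_tot <- prior[1] * ins$L[[ix$root]][1, ] + prior[2] * ins$L[[ix$root]][2, ]
  for (v in ix$preorder) {
    pv <- G[[v]] * ins$L[[v]]
    post[, v] <- pv[2, ] / (pv[1, ] + pv[2, ])
    for (ch in ix$children[[v]]) {
      sib <- G[[v]]
      for (s in ix$children[[v]]) if (s != ch) sib <- sib * ins$msg[[s]]
      # sib is 2 x P over parent states; joint(a,b) = sib[a,] * M[a,b] * L_ch[b,]
      Mch <- M[[ch]]
      j00 <- sib[1, ] * Mch[1, 1] * ins$L[[ch]][1, ]
      j01 <- sib[1, ] * Mch[1, 2] * ins$L[[ch]][2, ]
      j10 <- sib[2, ] * Mch[2, 1] * ins$L[[ch]][1, ]
      j11 <- sib[2, ] * Mch[2, 2] * ins$L[[ch]][2, ]
      tot <- j00 + j01 + j10 + j11
      gains[ch] <- sum(cp$w * j01 / tot)
      losses[ch] <- sum(cp$w * j10 / tot)
      G[[ch]] <- rbind(sib[1, ] * Mch[1, 1] + sib[2, ] * Mch[2, 1],
                       sib[1, ] * Mch[1, 2] + sib[2, ] * Mch[2, 2])
    }
  }
  posterior <- post[cp$site_of, , drop = FALSE]
  colnames(posterior) <- ix$names
  rownames(posterior) <- rownames(mat)
  brs <- setdiff(seq_len(ix$n_node), ix$root)
  list(posterior = posterior,
       events = data.frame(branch = ix$names[brs],
                           expected_gains = gains[brs],
                           expected_losses = losses[brs],
                           row.names = NULL),
       node_counts = colSums(posterior))
}
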