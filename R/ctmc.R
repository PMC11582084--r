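# Shared continuous-time Markov chain machinery on trees: generator
# diagnostics, eigen-decomposition-based transition propagation (one
# decomposition per generator, reused across branches), Felsenstein pruning
# with per-edge rescaling, and up-down marginal ancestral reconstruction.

# Decompose Q once; propagation along a branch of length b is then
# V diag(exp(lambda b)) V^-1 x. The decomposition is accepted only if it
# reconstructs Q accurately; otherwise each branch falls back to
# scaling-and-squaring (Matrix::expm).
ctmc_decompose <- function(Q) {
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- !is.null(ev) && all(is.finite(Mod(ev$values)))
  if (ok) {
    Vinv <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- Re(ev$vectors %*% (ev$values * Vinv))
      ok <- max(abs(recon - Q)) <= 1e-9 * max(1, max(abs(Q)))
    } else ok <- FALSE
  }
  if (ok) list(Q = Q, V = ev$vectors, Vinv = Vinv, lambda = ev$values,
               eigen = TRUE)
  else list(Q = Q, eigen = FALSE)
}

# P(b) %*% x without forming P(b). The eigen route is exact for
# diagonalisable Q; otherwise uniformization (Poisson-weighted powers of
# the substochastic jump matrix) gives matrix-vector cost per branch.
# Returns NULL when the uniformization rate is absurdly large (treated as
# a zero-likelihood region by the caller).
ctmc_propagate <- function(dec, b, x) {
  if (b == 0) return(x)
  if (dec$eigen) {
    out <- Re(dec$V %*% (exp(dec$lambda * b) * (dec$Vinv %*% x)))
    out[out < 0] <- 0  # clip round-off
    return(out)
  }
  rate <- max(-diag(dec$Q))
  if (rate <= 0) return(x)
  m <- rate * b
  if (m > 5000) return(NULL)
  P <- dec$Q / rate
  diag(P) <- diag(P) + 1
  nterm <- ceiling(m + 12 * sqrt(m) + 25)
  v <- x
  acc <- stats::dpois(0, m) * x
  for (k in seq_len(nterm)) {
    v <- P %*% v
    acc <- acc + stats::dpois(k, m) * v
  }
  out <- as.vector(acc)
  out[out < 0] <- 0
  out
}

# Explicit transition-probability matrix (for the up pass).
ctmc_pmat <- function(dec, b) {
  P <- if (dec$eigen) {
    Re(dec$V %*% (exp(dec$lambda * b) * dec$Vinv))
  } else as.matrix(Matrix::expm(dec$Q * b))
  P[P < 0] <- 0
  P
}

resolve_root_prior <- function(root_prior, D_root) {
  S <- length(D_root)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == S)
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("uniform", "fitzjohn")),
         uniform = rep(1 / S, S),
         fitzjohn = if (sum(D_root) > 0) D_root / sum(D_root)
                    else rep(1 / S, S))
}

#' Felsenstein pruning likelihood of discrete tip states
#'
#' Log-likelihood of tip states under a CTMC generator Q on a rooted tree:
#' per-branch transition matrices exp(Qb) (computed by one
#' eigen-decomposition of Q), conditional likelihoods combined at internal
#' nodes, the root summed against a prior.
#'
#' @param tree A rooted \code{phylo}.
#' @param tip_states Named vector of state labels (matching
#'   \code{rownames(Q)}) or 1-based state indices; names are tip labels.
#' @param Q Generator matrix (rows sum to 0).
#' @param root_prior "uniform" (default), "fitzjohn" (weights proportional
#'   to the root conditional likelihoods), or an explicit numeric prior.
#' @return Log-likelihood (\code{-Inf} for zero-probability data).
#' @export
ctmc_loglik <- function(tree, tip_states, Q, root_prior = "uniform") {
  ctmc_down(tree, tip_states, Q, root_prior)$lnL
}

ctmc_tip_index <- function(tree, tip_states, Q) {
  labs <- rownames(Q)
  if (is.null(names(tip_states)))
    stop("tip_states must be named with tip labels")
  idx0 <- match(normalize_taxon_names(tree$tip.label),
                normalize_taxon_names(names(tip_states)))
  if (anyNA(idx0))
    stop("no state for tips: ",
         paste(tree$tip.label[is.na(idx0)], collapse = ", "))
  st <- tip_states[idx0]
  # with labelled states, values are state labels; otherwise 1-based indices
  if (!is.null(labs)) st <- match(as.character(st), labs)
  st <- as.integer(st)
  if (anyNA(st) || any(st < 1L) || any(st > nrow(Q)))
    stop("tip state outside the model's state space")
  st
}

# Core down pass over a precomputed postorder edge table and tip state
# indices (the fitting loops call this directly to avoid re-matching names
# and re-ordering the tree at every likelihood evaluation).
ctmc_down_core <- function(post, st, Q, root_prior, ntip, n_node,
                           keep = FALSE) {
  S <- nrow(Q)
  dec <- ctmc_decompose(Q)
  D <- matrix(1, S, n_node)
  D[, seq_len(ntip)] <- 0
  D[cbind(st, seq_len(ntip))] <- 1
  logscale <- 0
  msgs <- if (keep) vector("list", nrow(post$edge)) else NULL
  for (k in seq_len(nrow(post$edge))) {
    a <- post$edge[k, 1]; b <- post$edge[k, 2]
    m <- ctmc_propagate(dec, post$edge.length[k], D[, b])
    if (is.null(m)) return(list(lnL = -Inf))
    s <- sum(m)
    if (s <= 0) return(list(lnL = -Inf))
    m <- m / s
    logscale <- logscale + log(s)
    if (keep) msgs[[k]] <- m
    D[, a] <- D[, a] * m
  }
  root <- ntip + 1L
  prior <- resolve_root_prior(root_prior, D[, root])
  lik <- sum(prior * D[, root])
  list(lnL = if (lik > 0) log(lik) + logscale else -Inf,
       D = D, prior = prior, dec = dec, post = post, msgs = msgs,
       ntip = ntip, n_node = n_node)
}

# Down (postorder) pass; returns per-node scaled conditional likelihoods.
ctmc_down <- function(tree, tip_states, Q, root_prior = "uniform",
                      keep = FALSE) {
  st <- ctmc_tip_index(tree, tip_states, Q)
  ntip <- ape::Ntip(tree)
  ctmc_down_core(ape::reorder.phylo(tree, "postorder"), st, Q, root_prior,
                 ntip, ntip + tree$Nnode, keep = keep)
}

#' Marginal ancestral state reconstruction under a CTMC
#'
#' Standard up-down (inside-outside) algorithm: the marginal posterior of
#' each internal node's state given all tip data and the model, under the
#' chosen root prior.
#'
#' @inheritParams ctmc_loglik
#' @return List: \code{prob} (matrix, one row per internal node in ape
#'   numbering, columns = states, rows sum to 1), \code{ml_state} (argmax
#'   state label per node), \code{lnL}.
#' @export
ctmc_ancestral <- function(tree, tip_states, Q, root_prior = "uniform") {
  dn <- ctmc_down(tree, tip_states, Q, root_prior, keep = TRUE)
  if (!is.finite(dn$lnL)) stop("zero-probability data: cannot reconstruct")
  S <- nrow(Q)
  post <- dn$post
  ntip <- dn$ntip
  root <- ntip + 1L
  U <- matrix(NA_real_, S, dn$n_node)
  U[, root] <- dn$prior
  edges_by_parent <- split(seq_len(nrow(post$edge)), post$edge[, 1])
  # preorder over edges = reverse postorder
  for (k in rev(seq_len(nrow(post$edge)))) {
    a <- post$edge[k, 1]; b <- post$edge[k, 2]
    if (b <= ntip) next
    sibs <- setdiff(edges_by_parent[[as.character(a)]], k)
    above <- U[, a]
    for (s_k in sibs) above <- above * dn$msgs[[s_k]]
    P <- ctmc_pmat(dn$dec, post$edge.length[k])
    u <- as.vector(crossprod(P, above))  # sum_i above_i P_ij
    tot <- sum(u)
    U[, b] <- if (tot > 0) u / tot else rep(1 / S, S)
  }
  nodes <- root:dn$n_node
  prob <- t(vapply(nodes, function(v) {
    p <- U[, v] * dn$D[, v]
    p / sum(p)
  }, numeric(S)))
  labs <- rownames(Q)
  if (is.null(labs)) labs <- as.character(seq_len(S))
  colnames(prob) <- labs
  rownames(prob) <- as.character(nodes)
  list(prob = prob, ml_state = labs[max.col(prob)], lnL = dn$lnL)
}
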