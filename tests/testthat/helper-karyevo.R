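# Shared fixtures for the suite: small hand-readable trees and a naive
# Moran-type statistic used as an independent oracle for the signal tests.

tree3 <- function() read_newick("((A:1,B:1):1,C:2);")

tree4_balanced <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")

# independent naive evaluation of (n/S0) * sum_ij w_ij z_i z_j / sum z_i^2
naive_moran <- function(W, y) {
  z <- y - mean(y)
  n <- length(y)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# dense multivariate-normal log-density evaluated the slow direct way
dense_mvn_logdens <- function(y, mean, Sigma) {
  n <- length(y)
  r <- y - mean
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(Sigma, logarithm = TRUE)$modulus +
                       r %*% solve(Sigma, r)))
}

# brute-force CTMC likelihood by enumerating every ancestral assignment,
# with transition probabilities from Matrix::expm (independent of the
# package's eigen propagation)
enum_ctmc_loglik <- function(tree, tip_idx, Q, prior) {
  S <- nrow(Q)
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  internal <- (ntip + 1L):n_node
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internal))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- integer(n_node)
    assign[seq_len(ntip)] <- tip_idx
    assign[internal] <- grid[g, ]
    p <- prior[assign[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * P[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    tot <- tot + p
  }
  log(tot)
}

# per-node marginal posteriors by the same enumeration
enum_ctmc_marginals <- function(tree, tip_idx, Q, prior) {
  S <- nrow(Q)
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  internal <- (ntip + 1L):n_node
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internal))))
  post <- matrix(0, length(internal), S)
  for (g in seq_len(nrow(grid))) {
    assign <- integer(n_node)
    assign[seq_len(ntip)] <- tip_idx
    assign[internal] <- grid[g, ]
    p <- prior[assign[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * P[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    for (v in seq_along(internal))
      post[v, grid[g, v]] <- post[v, grid[g, v]] + p
  }
  sweep(post, 1, rowSums(post), "/")
}
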