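# Phylogenetic-signal statistics with permutation / randomization tests.
# Moran's I uses inverse patristic-distance weights; Abouheif's Cmean uses
# the topology-only nodal-path proximity; Blomberg's K is the
# variance-ratio statistic calibrated to 1 under Brownian motion; Pagel's
# lambda is tested by likelihood ratio against lambda = 0.

new_signal_result <- function(statistic, observed, p_value, n_reps, seed,
                              method) {
  out <- list(statistic = statistic, observed = observed, p_value = p_value,
              n_reps = n_reps, seed = seed, method = method)
  class(out) <- "karyevo_signal"
  out
}

#' @export
print.karyevo_signal <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%s)\n", x$statistic, x$observed,
              x$p_value, x$method))
  invisible(x)
}

check_signal_input <- function(tree, y) {
  y <- match_tips(tree, y)
  if (length(y) < 3L) stop("need at least 3 tips")
  if (stats::var(y) <= 0) stop("trait is constant: signal undefined")
  y
}

# Moran-type autocorrelation with a given weight matrix (diag 0):
# I = (n / S0) * (z' W z) / (z' z), z = y - mean(y).
moran_stat <- function(W, y) {
  z <- y - mean(y)
  n <- length(y)
  (n / sum(W)) * as.numeric(z %*% W %*% z) / sum(z * z)
}

perm_pvalue <- function(obs, W, y, n_reps) {
  exceed <- 0L
  for (r in seq_len(n_reps)) {
    if (moran_stat(W, sample(y)) >= obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + n_reps)
}

#' Moran's I phylogenetic autocorrelation
#'
#' Moran's I with weights \code{w_ij = 1 / d_ij} (inverse patristic
#' distance, diagonal 0) and a one-sided (greater) permutation test over tip
#' relabellings.
#'
#' @param tree A rooted \code{phylo} with branch lengths.
#' @param y Named trait vector.
#' @param n_reps Number of permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @return A \code{karyevo_signal} result.
#' @export
morans_i <- function(tree, y, n_reps = 999L, seed = NULL) {
  y <- check_signal_input(tree, y)
  if (!is.null(seed)) set.seed(seed)
  D <- stats::cophenetic(tree)
  W <- 1 / D
  diag(W) <- 0
  obs <- moran_stat(W, y)
  new_signal_result("Moran's I", obs, perm_pvalue(obs, W, y, n_reps),
                    n_reps, seed, "inverse patristic-distance weights")
}

#' Abouheif proximity matrix
#'
#' \code{a_ij} is the product, over the interior nodes on the nodal path
#' between tips i and j (MRCA included), of 1 / (number of direct
#' descendants of the node). Depends on topology only.
#'
#' @param tree A rooted \code{phylo}.
#' @return Symmetric matrix with zero diagonal.
#' @export
abouheif_proximity <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kids <- tabulate(tree$edge[, 1], nbins = nn)    # direct-descendant counts
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  # internal-node path root -> tip (excluding the tip itself)
  paths <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    p <- integer(0)
    v <- parent[i]
    while (v != 0L) { p <- c(v, p); v <- parent[v] }
    paths[[i]] <- p
  }
  A <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) {
    for (j in (i + 1L):ntip) {
      pi <- paths[[i]]; pj <- paths[[j]]
      ncom <- 0L
      while (ncom < length(pi) && ncom < length(pj) &&
             pi[ncom + 1L] == pj[ncom + 1L]) ncom <- ncom + 1L
      nodes <- c(pi[ncom:length(pi)], pj[-seq_len(ncom)])  # MRCA once
      A[i, j] <- A[j, i] <- prod(1 / kids[nodes])
    }
  }
  A
}

#' Abouheif's Cmean test of phylogenetic signal
#'
#' Moran-type statistic computed with the topology-only
#' [abouheif_proximity()] weights; permutation test as in [morans_i()].
#'
#' @inheritParams morans_i
#' @return A \code{karyevo_signal} result.
#' @export
abouheif_cmean <- function(tree, y, n_reps = 999L, seed = NULL) {
  y <- check_signal_input(tree, y)
  if (!is.null(seed)) set.seed(seed)
  W <- abouheif_proximity(tree)
  obs <- moran_stat(W, y)
  new_signal_result("Abouheif's Cmean", obs, perm_pvalue(obs, W, y, n_reps),
                    n_reps, seed, "nodal-path proximity, MRCA included")
}

#' Blomberg's K
#'
#' The observed-versus-expected variance ratio
#' \deqn{K = \frac{MSE_0 / MSE}{(\mathrm{tr}(C) - n / (1'C^{-1}1)) / (n-1)}}
#' where \eqn{MSE_0} is the mean square of y around the GLS mean and
#' \eqn{MSE} the C-weighted mean square; K is calibrated so Brownian data
#' have expectation ~1. The p-value is a one-sided (greater) tip-shuffling
#' randomization on K.
#'
#' @inheritParams morans_i
#' @return A \code{karyevo_signal} result.
#' @export
blomberg_k <- function(tree, y, n_reps = 999L, seed = NULL) {
  y <- check_signal_input(tree, y)
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv.phylo(tree)
  R <- chol(C)
  z1 <- backsolve(R, rep(1, length(y)), transpose = TRUE)
  denom_scale <- (sum(diag(C)) - length(y) / sum(z1 * z1)) / (length(y) - 1)
  k_stat <- function(yy) {
    zy <- backsolve(R, yy, transpose = TRUE)
    root <- sum(z1 * zy) / sum(z1 * z1)
    r <- yy - root
    mse0 <- sum(r * r) / (length(yy) - 1)
    zr <- zy - root * z1
    mse <- sum(zr * zr) / (length(yy) - 1)
    (mse0 / mse) / denom_scale
  }
  obs <- k_stat(y)
  exceed <- 0L
  for (r in seq_len(n_reps)) if (k_stat(sample(y)) >= obs) exceed <- exceed + 1L
  new_signal_result("Blomberg's K", obs, (1 + exceed) / (1 + n_reps),
                    n_reps, seed, "tip-shuffling randomization")
}

#' Pagel's lambda with likelihood-ratio test
#'
#' ML estimate of lambda on [0, 1] by profile GLS (see
#' [fit_trait_model()]), tested against lambda = 0 (star phylogeny) by a
#' likelihood-ratio test on chi-square with 1 df.
#'
#' @param tree A rooted \code{phylo}.
#' @param y Named trait vector.
#' @return A \code{karyevo_signal} result; the \code{method} field carries
#'   lambda-hat, both log-likelihoods and the LRT statistic in
#'   \code{attr(, "detail")}.
#' @export
pagels_lambda_test <- function(tree, y) {
  y <- check_signal_input(tree, y)
  fit <- fit_trait_model(tree, y, "lambda")
  g0 <- gls_fit(transform_covariance(tree, "lambda", 0), y)
  lr <- lrt_test(g0$lnL, fit$lnL, df = 1L)
  out <- new_signal_result("Pagel's lambda", fit$param, lr$p_value,
                           NA_integer_, NULL, "LRT vs lambda = 0, df = 1")
  attr(out, "detail") <- list(lnL_lambda = fit$lnL, lnL_zero = g0$lnL,
                              statistic = lr$statistic)
  out
}

#' Phylogenetic-signal table over several traits
#'
#' Runs all four signal tests on each trait column, mirroring the layout of
#' published signal tables: one row per trait, columns statistic / p pairs.
#'
#' @param tree A rooted \code{phylo}.
#' @param traits data.frame with a \code{taxon} column and numeric trait
#'   columns (e.g. from [karyotype_trait_table()]).
#' @param n_reps Permutations per test (default 999).
#' @param seed Integer seed (mandatory for reproducibility; split across
#'   tests deterministically).
#' @return data.frame: trait, moran_i, moran_p, cmean, cmean_p, k, k_p,
#'   lambda, lambda_p.
#' @export
signal_table <- function(tree, traits, n_reps = 999L, seed = 1L) {
  stopifnot("taxon" %in% names(traits))
  trait_names <- setdiff(names(traits), "taxon")
  rows <- lapply(seq_along(trait_names), function(i) {
    tn <- trait_names[i]
    y <- stats::setNames(traits[[tn]], traits$taxon)
    mi <- morans_i(tree, y, n_reps, seed + 7L * i)
    cm <- abouheif_cmean(tree, y, n_reps, seed + 7L * i + 1L)
    bk <- blomberg_k(tree, y, n_reps, seed + 7L * i + 2L)
    pl <- pagels_lambda_test(tree, y)
    data.frame(trait = tn,
               moran_i = mi$observed, moran_p = mi$p_value,
               cmean = cm$observed, cmean_p = cm$p_value,
               k = bk$observed, k_p = bk$p_value,
               lambda = pl$observed, lambda_p = pl$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
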