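# The karyograph model: karyotypes live on the bidimensional lattice of
# haploid chromosome number y and haploid arm number x (y <= x <= 2y; a
# chromosome has one or two arms). Moves are Robertsonian fusion (y-1, same
# x), fission (y+1, same x), telocentric->metacentric transitions (x+1),
# the reverse (x-1), and polyploidisation ((y, x) -> (2y, 2x), model M2
# only). The karyotype CTMC is embedded in a multi-state
# speciation-extinction (MuSSE) likelihood with state-independent
# speciation rate lambda and extinction rate mu; because lambda and mu do
# not depend on the karyotype the likelihood factorises exactly into the
# karyotype pruning likelihood plus a birth-death factor, which is
# exploited for fitting and cross-checked against the branch ODE route.

#' Enumerate karyograph states
#'
#' All states (y, x) with 1 <= y <= y_max and y <= x <= 2y, ordered by y
#' then x. State labels are \code{"y/x"}.
#'
#' @param y_max Largest haploid chromosome number represented.
#' @return data.frame: y, x, label.
#' @export
karyograph_states <- function(y_max) {
  if (y_max < 1L) stop("y_max must be >= 1")
  y <- rep(seq_len(y_max), times = seq_len(y_max) + 1L)
  x <- unlist(lapply(seq_len(y_max), function(yy) yy:(2L * yy)))
  data.frame(y = y, x = x, label = paste0(y, "/", x),
             stringsAsFactors = FALSE)
}

#' Build the karyograph generator
#'
#' Per-chromosome rate laws: from (y, x) with u = 2y - x uni-armed and
#' b = x - y bi-armed chromosomes, fusion to (y-1, x) at \code{k1 * u}
#' (requires u >= 2), fission to (y+1, x) at \code{k2 * b},
#' telocentric-to-metacentric transition to (y, x+1) at \code{k3 * u},
#' the reverse to (y, x-1) at \code{k4 * b}, and polyploidisation to
#' (2y, 2x) at \code{k5}. Transitions leaving the lattice are dropped.
#'
#' @param states State table from [karyograph_states()].
#' @param k1,k2,k3,k4,k5 Non-negative rate coefficients (k5 = 0 recovers
#'   model M1).
#' @param multiplier "per_chromosome" (default: rates scale with the count
#'   of eligible chromosomes) or "per_karyotype" (constant per state).
#' @return Generator matrix with state labels as dimnames.
#' @export
build_karyograph_q <- function(states, k1, k2, k3, k4, k5 = 0,
                               multiplier = c("per_chromosome",
                                              "per_karyotype")) {
  multiplier <- match.arg(multiplier)
  if (any(c(k1, k2, k3, k4, k5) < 0)) stop("rate coefficients must be >= 0")
  S <- nrow(states)
  idx <- stats::setNames(seq_len(S), states$label)
  Q <- matrix(0, S, S, dimnames = list(states$label, states$label))
  mult <- function(count) if (multiplier == "per_chromosome") count
                          else as.numeric(count > 0)
  add <- function(i, y, x, rate) {
    j <- idx[paste0(y, "/", x)]
    if (!is.na(j) && rate > 0) Q[i, j] <<- Q[i, j] + rate
  }
  for (i in seq_len(S)) {
    y <- states$y[i]; x <- states$x[i]
    uni <- 2L * y - x; bi <- x - y
    if (uni >= 2L) add(i, y - 1L, x, k1 * mult(uni))
    if (bi >= 1L) add(i, y + 1L, x, k2 * mult(bi))
    if (uni >= 1L) add(i, y, x + 1L, k3 * mult(uni))
    if (bi >= 1L) add(i, y, x - 1L, k4 * mult(bi))
    if (k5 > 0) add(i, 2L * y, 2L * x, k5)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Karyograph tip states from a trait table
#'
#' Maps per-species traits to haploid karyograph coordinates: y = haploid
#' chromosome number n, x = haploid arm number fn / 2 (the package stores
#' fn on the diploid scale).
#'
#' @param traits data.frame with columns taxon, n, fn (e.g. from
#'   [karyotype_trait_table()]).
#' @return Named character vector of state labels.
#' @export
karyograph_tip_states <- function(traits) {
  y <- as.integer(traits$n)
  x <- as.integer(traits$fn / 2)
  bad <- !(y <= x & x <= 2L * y)
  if (any(bad))
    stop("invalid karyograph state for: ",
         paste(traits$taxon[bad], collapse = ", "))
  stats::setNames(paste0(y, "/", x), traits$taxon)
}

default_y_max <- function(tip_labels) {
  ys <- as.integer(sub("/.*", "", tip_labels))
  2L * max(ys) + 2L
}

# Birth-death factor of the state-independent SSE likelihood:
# (n-1) log(lambda) + sum over branches of
#   -(lambda+mu) * len + 2 lambda * int E(s) ds
# with E(s) the extinction probability of a lineage alive at time s before
# the present, obtained from the scalar ODE E' = mu - (lambda+mu) E +
# lambda E^2, E(0) = 0. The lambda = 0 limit drops the speciation factor
# (degenerate no-diversification limit used by the pruning equivalence).
sse_bd_factor <- function(tree, lam, mu, rtol = 1e-10) {
  depth <- node_depths(tree)
  H <- max(depth)
  tfp <- pmax(H - depth, 0)  # time from present per node
  n <- ape::Ntip(tree)
  edge <- tree$edge
  t0 <- tfp[edge[, 2]]; t1 <- tfp[edge[, 1]]
  if (lam == 0 && mu == 0) return(0)
  times <- sort(unique(c(0, t0, t1)))
  sol <- deSolve::lsoda(
    c(E = 0, G = 0), times,
    function(t, yy, p) list(c(mu - (lam + mu) * yy[1] + lam * yy[1]^2,
                              yy[1])),
    parms = NULL, rtol = rtol, atol = 1e-12)
  Ef <- stats::approxfun(sol[, "time"], sol[, "E"], rule = 2)
  Gf <- stats::approxfun(sol[, "time"], sol[, "G"], rule = 2)
  branch_sum <- sum(-(lam + mu) * (t1 - t0) + 2 * lam * (Gf(t1) - Gf(t0)))
  spec <- if (lam > 0) (n - 1) * log(lam) else 0
  spec + branch_sum
}

#' MuSSE log-likelihood of karyograph tip states
#'
#' State-dependent speciation-extinction likelihood of a tree plus discrete
#' karyograph states, with karyotype transitions from
#' [build_karyograph_q()] and state-independent speciation (lambda) and
#' extinction (mu). Two routes:
#' \describe{
#'   \item{ode}{per-branch integration of the standard extinction /
#'     data equations \eqn{E_i' = \mu - (\lambda+\mu+q_i)E_i + \sum_j
#'     q_{ij}E_j + \lambda E_i^2}, \eqn{D_i' = -(\lambda+\mu+q_i)D_i +
#'     \sum_j q_{ij}D_j + 2\lambda E_i D_i}, nodes combined as
#'     \eqn{D \leftarrow \lambda D_L D_R}.}
#'   \item{factorized}{the exact closed decomposition available because
#'     lambda and mu are state-independent: karyotype pruning likelihood
#'     plus a birth-death factor (default; identical up to integration
#'     error).}
#' }
#' At \code{lambda = 0} the speciation factor is dropped so the likelihood
#' reduces to plain CTMC pruning. The root is combined by FitzJohn
#' weighting by default ("flat" averages a uniform prior); no survival
#' conditioning is applied.
#'
#' @param tree Rooted ultrametric \code{phylo}.
#' @param tip_states Named character vector of "y/x" labels.
#' @param pars List with k1..k4 (k5 optional, default 0), lam, mu.
#' @param y_max State-space bound (default 2 * max tip y + 2).
#' @param method "factorized" (default) or "ode".
#' @param root_mode "fitzjohn" (default) or "flat".
#' @param rtol Relative tolerance of the branch ODE integration.
#' @return Log-likelihood.
#' @export
musse_loglik <- function(tree, tip_states, pars, y_max = NULL,
                         method = c("factorized", "ode"),
                         root_mode = c("fitzjohn", "flat"), rtol = 1e-8) {
  method <- match.arg(method)
  root_mode <- match.arg(root_mode)
  if (is.null(y_max)) y_max <- default_y_max(tip_states)
  states <- karyograph_states(y_max)
  Q <- build_karyograph_q(states, pars$k1, pars$k2, pars$k3, pars$k4,
                          pars$k5 %||% 0)
  lam <- pars$lam; mu <- pars$mu
  if (lam < 0 || mu < 0) stop("lam and mu must be >= 0")
  prior <- if (root_mode == "fitzjohn") "fitzjohn" else "uniform"
  if (method == "factorized")
    return(ctmc_loglik(tree, tip_states, Q, root_prior = prior) +
             sse_bd_factor(tree, lam, mu))
  musse_loglik_ode(tree, tip_states, Q, lam, mu, prior, rtol)
}

musse_loglik_ode <- function(tree, tip_states, Q, lam, mu, prior, rtol) {
  S <- nrow(Q)
  st <- ctmc_tip_index(tree, tip_states, Q)
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  D <- matrix(0, S, n_node); E <- matrix(0, S, n_node)
  D[cbind(st, seq_len(ntip))] <- 1
  derivs <- function(t, yy, p) {
    e <- yy[seq_len(S)]; d <- yy[S + seq_len(S)]
    qe <- as.vector(Q %*% e); qd <- as.vector(Q %*% d)
    list(c(mu - (lam + mu) * e + qe + lam * e^2,
           -(lam + mu) * d + qd + 2 * lam * e * d))
  }
  post <- ape::reorder.phylo(tree, "postorder")
  logscale <- 0
  seen <- logical(n_node)
  for (k in seq_len(nrow(post$edge))) {
    a <- post$edge[k, 1]; b <- post$edge[k, 2]
    y0 <- c(E[, b], D[, b])
    len <- post$edge.length[k]
    if (len > 0) {
      sol <- deSolve::lsoda(y0, c(0, len), derivs, parms = NULL,
                            rtol = rtol, atol = 1e-12)
      if (nrow(sol) < 2L) stop("SSE integrator failed on edge to node ", b)
      yy <- sol[2L, -1L]
    } else yy <- y0
    e <- pmin(pmax(yy[seq_len(S)], 0), 1)   # invariant: E in [0, 1]
    d <- pmax(yy[S + seq_len(S)], 0)        # invariant: D >= 0
    s <- sum(d)
    if (s <= 0) return(-Inf)
    logscale <- logscale + log(s)
    d <- d / s
    if (!seen[a]) {
      D[, a] <- d; E[, a] <- e; seen[a] <- TRUE
    } else {
      D[, a] <- D[, a] * d * (if (lam > 0) lam else 1)
      E[, a] <- (E[, a] + e) / 2
    }
  }
  root <- ntip + 1L
  d_root <- D[, root]
  lik <- if (prior == "fitzjohn") {
    if (sum(d_root) > 0) sum(d_root^2) / sum(d_root) else 0
  } else mean(d_root)
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}

#' Fit the karyograph SSE model
#'
#' Maximum-likelihood fit of M1 (k1-k4, lambda, mu) or M2 (adds the
#' polyploidisation rate k5). Because speciation and extinction are
#' state-independent the log-likelihood is additively separable into the
#' karyotype-CTMC part (depends only on k1..k5) and the birth-death part
#' (depends only on lambda, mu), so the joint ML is obtained by optimising
#' the two parts separately (log-scale Nelder-Mead with restarts for the
#' k-rates; 2-D optimisation for lambda, mu).
#'
#' @param tree Rooted ultrametric \code{phylo} (>= 4 tips).
#' @param tip_states Named character vector of "y/x" labels (see
#'   [karyograph_tip_states()]).
#' @param model "M1" (no polyploidisation) or "M2" (with k5).
#' @param y_max State-space bound (default 2 * max tip y + 2).
#' @param root_mode "fitzjohn" (default) or "flat".
#' @param n_starts Optimiser restarts for the k-rates (default 2).
#' @param k_init Optional named starting values for the k-rates.
#' @return A \code{karyevo_ssefit}: pars (k1..k5 as fitted, lam, mu), lnL
#'   (total), lnL_ctmc, lnL_bd, k (free-parameter count), Q, y_max,
#'   root_mode, convergence flag.
#' @export
fit_karyograph <- function(tree, tip_states, model = c("M1", "M2"),
                           y_max = NULL, root_mode = "fitzjohn",
                           n_starts = 2L, k_init = NULL) {
  model <- match.arg(model)
  if (ape::Ntip(tree) < 4L) stop("need at least 4 tips")
  if (is.null(y_max)) y_max <- default_y_max(tip_states)
  states <- karyograph_states(y_max)
  knames <- c("k1", "k2", "k3", "k4", if (model == "M2") "k5")
  nk <- length(knames)
  prior <- if (root_mode == "fitzjohn") "fitzjohn" else "uniform"
  Q0 <- build_karyograph_q(states, 1, 1, 1, 1)
  st <- ctmc_tip_index(tree, tip_states, Q0)
  post <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  ctmc_nll <- function(lpar) {
    if (any(lpar > 12)) return(1e10)
    kk <- stats::setNames(as.list(exp(lpar)), knames)
    Q <- build_karyograph_q(states, kk$k1, kk$k2, kk$k3, kk$k4,
                            kk$k5 %||% 0)
    l <- ctmc_down_core(post, st, Q, prior, ntip, ntip + tree$Nnode)$lnL
    if (!is.finite(l)) 1e10 else -l
  }
  h <- tree_height(tree)
  starts <- lapply(seq_len(n_starts), function(i)
    rep(log(c(0.5, 4)[min(i, 2L)] / h), nk))
  if (!is.null(k_init))
    starts <- c(list(log(pmax(unlist(k_init)[knames], 1e-8))), starts)
  best <- NULL
  for (p0 in starts) {
    op <- stats::optim(p0, ctmc_nll, method = "L-BFGS-B",
                       lower = rep(-10, nk), upper = rep(10, nk),
                       control = list(maxit = 100, factr = 1e8))
    if (is.null(best) || op$value < best$value) best <- op
  }
  kk <- stats::setNames(as.list(exp(best$par)), knames)
  # birth-death part: separable 2-D ML over (log lambda, log mu)
  bd_nll <- function(lp) {
    v <- -sse_bd_factor(tree, exp(lp[1]), exp(lp[2]))
    if (!is.finite(v)) 1e10 else v
  }
  bd_best <- NULL
  for (lp0 in list(log(c(2 / h, 0.5 / h)), log(c(5 / h, 2 / h)))) {
    op <- stats::optim(lp0, bd_nll, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-10))
    if (is.null(bd_best) || op$value < bd_best$value) bd_best <- op
  }
  lam <- exp(bd_best$par[1]); mu <- exp(bd_best$par[2])
  lnl_ctmc <- -best$value
  lnl_bd <- -bd_best$value
  pars <- c(kk, list(lam = lam, mu = mu))  # k5 absent from M1 by design
  Q <- build_karyograph_q(states, pars$k1, pars$k2, pars$k3, pars$k4,
                          pars$k5 %||% 0)
  out <- list(model = model, pars = pars, lnL = lnl_ctmc + lnl_bd,
              lnL_ctmc = lnl_ctmc, lnL_bd = lnl_bd,
              k = nk + 2L, Q = Q, states = states, y_max = y_max,
              root_mode = root_mode,
              converged = best$convergence == 0 && bd_best$convergence == 0)
  class(out) <- "karyevo_ssefit"
  out
}

#' @export
print.karyevo_ssefit <- function(x, ...) {
  cat(sprintf("karyograph SSE fit, model %s (y_max = %d)\n",
              x$model, x$y_max))
  p <- x$pars
  cat(sprintf("  k1 (fusion)      = %.4g\n  k2 (fission)     = %.4g\n",
              p$k1, p$k2))
  cat(sprintf("  k3 (t->m)        = %.4g\n  k4 (m->t)        = %.4g\n",
              p$k3, p$k4))
  if (x$model == "M2") cat(sprintf("  k5 (polyploidy)  = %.4g\n", p$k5))
  cat(sprintf("  lambda = %.4g, mu = %.4g\n", p$lam, p$mu))
  cat(sprintf("lnL = %.4f (karyotype %.4f + birth-death %.4f), k = %d\n",
              x$lnL, x$lnL_ctmc, x$lnL_bd, x$k))
  invisible(x)
}

#' Fit M1 and M2 and compare by likelihood-ratio test
#'
#' M1 (no polyploidisation) is nested in M2 (k5 free) with one extra
#' parameter; M2's optimisation is also started from M1's optimum with a
#' small k5 so the nesting inequality lnL(M2) >= lnL(M1) holds. The LRT
#' uses the chi-square with 1 df as its reference (the boundary-corrected
#' halved p-value is also reported, since k5 = 0 sits on the parameter
#' boundary).
#'
#' @inheritParams fit_karyograph
#' @return List: m1, m2 (both \code{karyevo_ssefit}) and lrt
#'   (from [lrt_test()]).
#' @export
fit_m1_m2 <- function(tree, tip_states, y_max = NULL,
                      root_mode = "fitzjohn", n_starts = 2L) {
  m1 <- fit_karyograph(tree, tip_states, "M1", y_max, root_mode, n_starts)
  init2 <- c(m1$pars[c("k1", "k2", "k3", "k4")], k5 = 1e-6)
  m2 <- fit_karyograph(tree, tip_states, "M2", y_max, root_mode, n_starts,
                       k_init = init2)
  if (m2$lnL < m1$lnL) {
    if (m2$lnL < m1$lnL - 0.05)
      warning("optimizer failure: lnL(M2) < lnL(M1) although M1 is nested")
    # M2's optimum is on the k5 = 0 boundary, i.e. exactly M1
    m2$pars[c("k1", "k2", "k3", "k4")] <- m1$pars[c("k1", "k2", "k3", "k4")]
    m2$pars$k5 <- 0
    m2$pars$lam <- m1$pars$lam; m2$pars$mu <- m1$pars$mu
    m2$lnL <- m1$lnL; m2$lnL_ctmc <- m1$lnL_ctmc; m2$lnL_bd <- m1$lnL_bd
    m2$Q <- m1$Q
  }
  list(m1 = m1, m2 = m2, lrt = lrt_test(m1$lnL, m2$lnL, df = 1L))
}

#' Marginal ancestral karyograph states
#'
#' Marginal posterior distributions over (y, x) at every internal node
#' under a fitted karyograph model. With state-independent lambda and mu
#' these equal the CTMC up-down marginals on the karyotype generator.
#' Reports the posterior mean chromosome number and arm number per node
#' (the quantities mapped on heat-map figures) and the argmax state.
#'
#' @param tree Rooted \code{phylo}.
#' @param tip_states Named character vector of "y/x" labels.
#' @param fit A \code{karyevo_ssefit} from [fit_karyograph()].
#' @return List: prob (nodes x states), mean_y, mean_x, ml_state, lnL.
#' @export
ancestral_karyograph <- function(tree, tip_states, fit) {
  prior <- if (fit$root_mode == "fitzjohn") "fitzjohn" else "uniform"
  anc <- ctmc_ancestral(tree, tip_states, fit$Q, root_prior = prior)
  anc$mean_y <- as.vector(anc$prob %*% fit$states$y)
  anc$mean_x <- as.vector(anc$prob %*% fit$states$x)
  anc
}
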