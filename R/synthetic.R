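# Seeded simulators: birth-death trees, continuous traits under the five
# supported models, discrete karyotype histories under an arbitrary CTMC
# generator, and karyotype-formula tables. Every function is a pure function
# of (arguments, seed): pass seed = NULL to draw from the caller's RNG
# stream instead.

#' Simulate a birth-death tree conditioned on a tip count
#'
#' Forward (Gillespie) simulation from a single lineage; the process is
#' stopped at the instant the (n+1)-th extant lineage would be born, extinct
#' lineages are pruned, and the stem edge is discarded, giving a rooted
#' ultrametric tree with exactly \code{n_tips} extant tips. Under pure birth
#' the expected root height is \eqn{\sum_{k=2}^{n} 1/(k\,birth)}. Runs in
#' which the clade dies out are retried.
#'
#' @param n_tips Number of extant tips (>= 3).
#' @param birth,death Speciation and extinction rates, \code{birth > death >= 0}.
#' @param seed Optional integer seed.
#' @param max_retries Retry bound for whole-tree extinction (default 1000).
#' @return A \code{phylo} object with tips \code{t1..tn}.
#' @export
sim_bd_tree <- function(n_tips, birth, death = 0, seed = NULL,
                        max_retries = 1000L) {
  if (n_tips < 3L) stop("n_tips must be >= 3")
  if (!(birth > death) || death < 0) stop("need birth > death >= 0")
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    tr <- sim_bd_once(n_tips, birth, death)
    if (!is.null(tr)) return(tr)
  }
  stop("birth-death simulation went extinct in every one of ",
       max_retries, " attempts")
}

sim_bd_once <- function(n_tips, birth, death) {
  cap <- 4L * n_tips + 8L
  parent <- integer(cap); t_start <- numeric(cap); t_end <- numeric(cap)
  child1 <- integer(cap); child2 <- integer(cap); dead <- logical(cap)
  n_lin <- 1L; parent[1] <- 0L; t_start[1] <- 0
  alive <- 1L
  t <- 0
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0L) return(NULL)
    total <- n_alive * (birth + death)
    t <- t + stats::rexp(1L, total)
    is_birth <- stats::runif(1L) < birth / (birth + death + 1e-300) ||
      death == 0
    if (is_birth && n_alive == n_tips) break  # stop just before tip n+1
    target <- alive[sample.int(n_alive, 1L)]
    if (is_birth) {
      if (n_lin + 2L > cap) {  # grow storage
        cap <- cap * 2L
        length(parent) <- cap; length(t_start) <- cap; length(t_end) <- cap
        length(child1) <- cap; length(child2) <- cap; length(dead) <- cap
      }
      kids <- n_lin + 1:2
      parent[kids] <- target; t_start[kids] <- t
      child1[target] <- kids[1]; child2[target] <- kids[2]
      t_end[target] <- t
      n_lin <- n_lin + 2L
      alive <- c(setdiff(alive, target), kids)
    } else {
      t_end[target] <- t
      dead[target] <- TRUE
      alive <- setdiff(alive, target)
    }
  }
  t_end[alive] <- t
  tip_id <- 0L
  nwk <- function(i) {
    len <- t_end[i] - t_start[i]
    if (child1[i] == 0L) {
      lab <- if (dead[i]) paste0("x", i) else {
        tip_id <<- tip_id + 1L; paste0("t", tip_id)
      }
      paste0(lab, ":", format(len, digits = 17))
    } else {
      paste0("(", nwk(child1[i]), ",", nwk(child2[i]), "):",
             format(len, digits = 17))
    }
  }
  if (child1[1] == 0L) return(NULL)
  s <- paste0("(", nwk(child1[1]), ",", nwk(child2[1]), ");")
  tr <- ape::read.tree(text = s)
  extinct <- grep("^x", tr$tip.label, value = TRUE)
  if (length(extinct)) {
    if (ape::Ntip(tr) - length(extinct) < n_tips) return(NULL)
    tr <- ape::drop.tip(tr, extinct)
  }
  if (ape::Ntip(tr) != n_tips) return(NULL)
  tr$root.edge <- NULL
  tr
}

#' Simulate a continuous trait on a tree
#'
#' Brownian motion and Ornstein-Uhlenbeck traits are simulated recursively
#' edge by edge (OU uses the exact transition distribution). The lambda,
#' delta and kappa models are simulated as exact multivariate-normal draws
#' from the transformed Brownian covariance, which is the same distribution
#' as Brownian motion on the transformed tree.
#'
#' @param tree A rooted \code{phylo} with branch lengths.
#' @param model One of "BM", "OU", "lambda", "delta", "kappa".
#' @param params List: \code{sigma2} (default 1), \code{root} (default 0);
#'   for OU \code{alpha} and optional \code{theta} (optimum, default root);
#'   for the transformations the parameter of the same name.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values (names = tip labels).
#' @export
sim_continuous <- function(tree, model = "BM", params = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(model, c("BM", "OU", "lambda", "delta", "kappa"))
  sigma2 <- params$sigma2 %||% 1
  root <- params$root %||% 0
  if (sigma2 <= 0) stop("sigma2 must be positive")
  ntip <- ape::Ntip(tree)
  if (model %in% c("lambda", "delta", "kappa")) {
    theta <- params[[model]]
    if (is.null(theta)) stop("missing parameter ", sQuote(model))
    C <- transform_covariance(tree, model, theta)
    L <- chol(sigma2 * C + diag(1e-12, ntip))
    y <- as.vector(root + crossprod(L, stats::rnorm(ntip)))
    return(stats::setNames(y, colnames(C)))
  }
  alpha <- params$alpha %||% 0
  theta_opt <- params$theta %||% root
  edge <- tree$edge
  val <- numeric(ntip + tree$Nnode)
  val[ntip + 1L] <- root
  ord <- ape::reorder.phylo(tree, "postorder")
  eo <- rev(seq_len(nrow(ord$edge)))  # preorder over edges
  for (k in eo) {
    a <- ord$edge[k, 1]; b <- ord$edge[k, 2]
    len <- ord$edge.length[k]
    if (model == "BM" || alpha == 0) {
      val[b] <- val[a] + stats::rnorm(1L, 0, sqrt(sigma2 * len))
    } else {
      m <- theta_opt + (val[a] - theta_opt) * exp(-alpha * len)
      v <- sigma2 * (1 - exp(-2 * alpha * len)) / (2 * alpha)
      val[b] <- stats::rnorm(1L, m, sqrt(v))
    }
  }
  stats::setNames(val[seq_len(ntip)], tree$tip.label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a discrete character history under a CTMC
#'
#' Gillespie simulation along every branch: exponential waiting times at the
#' total exit rate of the current state, jumps proportional to the
#' off-diagonal rates. Returns both tip states and the true internal-node
#' states so estimators can be scored against the generating history.
#'
#' @param tree A rooted \code{phylo}.
#' @param Q Generator matrix (rows sum to 0) with state labels as dimnames.
#' @param root_state State label (or index) at the root.
#' @param seed Optional integer seed.
#' @return List with \code{tip_states} (named character vector),
#'   \code{node_states} (character, internal nodes in ape numbering order),
#'   and \code{n_events} (total number of jumps).
#' @export
sim_discrete <- function(tree, Q, root_state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- rownames(Q)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(Q)))
  if (is.character(root_state)) root_state <- match(root_state, labs)
  if (is.na(root_state) || root_state < 1L || root_state > nrow(Q))
    stop("root_state outside the state space")
  ntip <- ape::Ntip(tree)
  state <- integer(ntip + tree$Nnode)
  state[ntip + 1L] <- root_state
  exit <- -diag(Q)
  n_events <- 0L
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in rev(seq_len(nrow(ord$edge)))) {
    a <- ord$edge[k, 1]; b <- ord$edge[k, 2]
    len <- ord$edge.length[k]
    s <- state[a]; t <- 0
    repeat {
      if (exit[s] <= 0) break
      t <- t + stats::rexp(1L, exit[s])
      if (t >= len) break
      w <- Q[s, ]; w[s] <- 0
      s <- sample.int(length(w), 1L, prob = w)
      n_events <- n_events + 1L
    }
    state[b] <- s
  }
  list(tip_states = stats::setNames(labs[state[seq_len(ntip)]],
                                    tree$tip.label),
       node_states = labs[state[(ntip + 1L):(ntip + tree$Nnode)]],
       n_events = n_events)
}

#' Emit a karyotype formula table from karyograph states
#'
#' Converts haploid karyograph states (y = chromosome number, x = arm
#' number) into diploid karyotype formula strings: the \code{x - y} bi-armed
#' chromosomes are split among m/sm/st by a seeded multinomial, the
#' \code{2y - x} uni-armed chromosomes become t, and counts are doubled to
#' the diploid scale. Round-trips exactly through [parse_karyotype()] and
#' [karyotype_traits()] (which recover y = n and x = fn/2).
#'
#' @param states data.frame with columns \code{y} and \code{x} (one row per
#'   taxon) satisfying \code{y <= x <= 2y}.
#' @param taxa Optional taxon names (default s1..sn).
#' @param seed Optional integer seed.
#' @return data.frame: taxon, y, x, formula.
#' @export
emit_karyotype_table <- function(states, taxa = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(states$y >= 1), all(states$x >= states$y),
            all(states$x <= 2 * states$y))
  n <- nrow(states)
  if (is.null(taxa)) taxa <- paste0("s", seq_len(n))
  formula <- character(n)
  for (i in seq_len(n)) {
    bi <- states$x[i] - states$y[i]
    uni <- 2L * states$y[i] - states$x[i]
    split <- if (bi > 0)
      as.vector(stats::rmultinom(1L, bi, rep(1 / 3, 3))) else c(0L, 0L, 0L)
    counts <- c(m = split[1], sm = split[2], st = split[3], t = uni) * 2L
    formula[i] <- format_karyotype(counts)
  }
  data.frame(taxon = taxa, y = states$y, x = states$x, formula = formula,
             stringsAsFactors = FALSE)
}
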