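# Greedy clade rate-shift detection for a Brownian trait: at each step every
# internal node (except the root) is tried as the stem of a clade evolving
# at its own multiplicative rate; the best candidate is accepted when it
# improves AICc by more than the cut-off (conservative defaults 4 and 9).

#' Scan for clade-level Brownian rate shifts
#'
#' Greedy forward search. The model with shift set S rescales every branch
#' inside each shifted clade (stem branch included) by a clade-specific rate
#' multiplier, background rate 1; nested shifts follow the innermost
#' enclosing clade. At each step the candidate rate is profiled by bounded
#' 1-D ML (previously accepted rates held at their estimates), the best node
#' is accepted if AICc improves by more than \code{cutoff}, and all rates
#' are then re-optimised jointly.
#'
#' @param tree A rooted binary \code{phylo} with >= 4 tips.
#' @param y Named trait vector.
#' @param cutoff Required AICc improvement per accepted shift (> 0;
#'   conventional values 4 and 9).
#' @param max_shifts Maximum number of shifts to accept (default 5; 0 fits
#'   the one-rate model only).
#' @param k_per_shift Parameters charged per accepted shift: 2 (rate +
#'   location, the default) or 1.
#' @param rate_bounds Bounds for the rate multiplier (default c(1e-3, 1e3)).
#' @return A \code{karyevo_shifts} list: \code{base} (one-rate GLS fit),
#'   \code{shift_nodes}, \code{rates}, \code{lnL}, \code{k}, \code{AICc},
#'   and \code{steps}, a per-step data.frame (node, rate, lnL, AICc,
#'   accepted).
#' @export
scan_rate_shifts <- function(tree, y, cutoff = 4, max_shifts = 5L,
                             k_per_shift = 2L, rate_bounds = c(1e-3, 1e3)) {
  if (!ape::is.binary(tree)) stop("tree must be binary (resolve polytomies)")
  if (cutoff <= 0) stop("cutoff must be positive")
  y <- match_tips(tree, y)
  ntip <- ape::Ntip(tree)
  if (ntip < 4L) stop("need at least 4 tips")
  n_node <- ntip + tree$Nnode
  root <- ntip + 1L
  edge <- tree$edge
  elen <- tree$edge.length

  # descendant masks per node: over tips (for covariance contributions)
  # and over all nodes (for clade/edge membership)
  desc <- matrix(FALSE, n_node, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  node_desc <- diag(TRUE, n_node)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(post))) {
    desc[post[k, 1], ] <- desc[post[k, 1], ] | desc[post[k, 2], ]
    node_desc[post[k, 1], ] <- node_desc[post[k, 1], ] |
      node_desc[post[k, 2], ]
  }

  # per-edge covariance contribution uses the child's descendant mask
  edge_mask <- desc[edge[, 2], , drop = FALSE]
  # clade membership of edges: edge belongs to shift node s iff its child
  # is inside s's clade (stem edge of s included since s descends from s)
  edge_in_clade <- function(s) node_desc[s, edge[, 2]]

  candidates <- setdiff((ntip + 1L):n_node, root)
  cov_from_edges <- function(edges, w) {  # sum of w[e] over shared edges
    C <- matrix(0, ntip, ntip)
    for (e in edges) {
      m <- edge_mask[e, ]
      C[m, m] <- C[m, m] + w[e]
    }
    C
  }
  cov_of <- function(mult) cov_from_edges(seq_len(nrow(edge)), elen * mult)
  clade_edges <- lapply(seq_len(n_node), function(s)
    which(node_desc[s, edge[, 2]]))
  # unit-rate covariance contribution of each candidate clade (stem incl.)
  Craw <- lapply(seq_len(n_node), function(s)
    if (s %in% candidates) cov_from_edges(clade_edges[[s]], elen) else NULL)
  # innermost-enclosing-shift assignment: per edge, index into shifts or 0
  assign_regimes <- function(shifts) {
    reg <- integer(nrow(edge))
    if (length(shifts)) {
      sizes <- rowSums(desc)[shifts]
      for (s_i in order(sizes, decreasing = TRUE))  # inner overwrite outer
        reg[edge_in_clade(shifts[s_i])] <- s_i
    }
    reg
  }
  lnl_of <- function(shifts, rates, reg = assign_regimes(shifts)) {
    mult <- rep(1, nrow(edge))
    for (s_i in seq_along(shifts)) mult[reg == s_i] <- rates[s_i]
    tryCatch(gls_fit(cov_of(mult), y)$lnL, error = function(e) -1e10)
  }

  base <- gls_fit(ape::vcv.phylo(tree), y)
  shifts <- integer(0); rates <- numeric(0)
  cur_lnl <- base$lnL
  cur_k <- 2L
  cur_aicc <- aicc(cur_lnl, cur_k, ntip)
  steps <- data.frame(step = integer(0), node = integer(0), rate = numeric(0),
                      lnL = numeric(0), AICc = numeric(0),
                      accepted = logical(0))
  lb <- log(rate_bounds)
  step <- 0L
  while (length(shifts) < max_shifts) {
    step <- step + 1L
    reg_cur <- assign_regimes(shifts)
    mult_cur <- rep(1, nrow(edge))
    for (s_i in seq_along(shifts)) mult_cur[reg_cur == s_i] <- rates[s_i]
    C_cur <- cov_of(mult_cur)
    best <- NULL
    for (s in setdiff(candidates, shifts)) {
      # rescale the candidate clade from its current multipliers to r:
      # C(r) = C_cur - D_s + r * Craw_s
      D_s <- cov_from_edges(clade_edges[[s]], elen * mult_cur)
      C_fix <- C_cur - D_s
      obj <- function(lr)
        tryCatch(gls_fit(C_fix + exp(lr) * Craw[[s]], y)$lnL,
                 error = function(e) -1e10)
      o <- stats::optimize(obj, lb, maximum = TRUE, tol = 1e-6)
      if (is.null(best) || o$objective > best$lnL)
        best <- list(node = s, rate = exp(o$maximum), lnL = o$objective)
    }
    if (is.null(best)) break
    k_new <- 2L + k_per_shift * (length(shifts) + 1L)
    # joint refinement of all rates at the candidate shift set
    trial <- c(shifts, best$node)
    tr_rates <- c(rates, best$rate)
    if (length(tr_rates) > 1L) {
      reg <- assign_regimes(trial)
      op <- stats::optim(log(tr_rates),
                         function(lr) -lnl_of(trial, exp(lr), reg),
                         method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-10))
      if (-op$value > best$lnL) {
        tr_rates <- exp(op$par); best$lnL <- -op$value
      }
    }
    aicc_new <- aicc(best$lnL, k_new, ntip)
    accept <- (cur_aicc - aicc_new) > cutoff
    steps <- rbind(steps, data.frame(
      step = step, node = best$node, rate = tr_rates[length(tr_rates)],
      lnL = best$lnL, AICc = aicc_new, accepted = accept))
    if (!accept) break
    shifts <- trial; rates <- tr_rates
    cur_lnl <- best$lnL; cur_k <- k_new; cur_aicc <- aicc_new
  }
  out <- list(base = base, shift_nodes = shifts, rates = rates,
              lnL = cur_lnl, k = cur_k, AICc = cur_aicc,
              n = ntip, cutoff = cutoff, steps = steps)
  class(out) <- "karyevo_shifts"
  out
}

#' @export
print.karyevo_shifts <- function(x, ...) {
  cat(sprintf("rate-shift scan (cutoff %.1f): %d shift(s) accepted\n",
              x$cutoff, length(x$shift_nodes)))
  if (length(x$shift_nodes))
    cat(paste(sprintf("  node %d: relative rate %.3g", x$shift_nodes,
                      x$rates), collapse = "\n"), "\n")
  cat(sprintf("lnL = %.4f, k = %d, AICc = %.3f\n", x$lnL, x$k, x$AICc))
  invisible(x)
}
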