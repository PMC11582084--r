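# ChromEvol-style models of haploid chromosome-number evolution: a CTMC on
# counts n_min..n_max with single-chromosome gain (ascending dysploidy),
# loss (descending dysploidy), whole-set duplication (polyploidy) and
# demi-duplication (x 1.5), with optionally count-linear gain/loss rates.
# Fitted by ML; compared by AIC; ancestral states by marginal
# reconstruction.

CHROM_RATES <- c("gain", "loss", "dupl", "demi")

#' Build a chromosome-number generator matrix
#'
#' Transitions from haploid count i: i -> i+1 at \code{gain + gain_lin *
#' (i - n_min)} (floored at 0), i -> i-1 at \code{loss + loss_lin *
#' (i - n_min)}, i -> 2i at \code{dupl}, and demi-duplication i -> 1.5i at
#' \code{demi} (for odd i the rate is split equally between floor(1.5i) and
#' ceiling(1.5i)). Transitions leaving \code{[n_min, n_max]} are dropped;
#' the diagonal is minus the row sum.
#'
#' @param rates Named list/vector with any of \code{gain}, \code{loss},
#'   \code{dupl}, \code{demi}, \code{gain_lin}, \code{loss_lin}; omitted
#'   entries are 0.
#' @param n_min,n_max State bounds (haploid counts), \code{n_min >= 1}.
#' @return Generator matrix with state labels as dimnames.
#' @export
build_chrom_q <- function(rates, n_min = 1L, n_max) {
  if (n_min < 1L) stop("n_min must be >= 1")
  if (n_max <= n_min) stop("n_max must exceed n_min")
  r <- function(nm) if (is.null(rates[[nm]]) || is.na(rates[[nm]])) 0
                    else rates[[nm]]
  states <- n_min:n_max
  S <- length(states)
  Q <- matrix(0, S, S, dimnames = list(states, states))
  add <- function(i, j, rate) {  # self-transitions (demi from 1) are no-ops
    if (!is.na(j) && rate > 0 && j != i && j >= 1L && j <= S)
      Q[i, j] <<- Q[i, j] + rate
  }
  for (k in seq_len(S)) {
    i <- states[k]
    g <- max(0, r("gain") + r("gain_lin") * (i - n_min))
    l <- max(0, r("loss") + r("loss_lin") * (i - n_min))
    add(k, k + 1L, g)
    add(k, k - 1L, l)
    add(k, match(2L * i, states), r("dupl"))
    d <- r("demi")
    if (d > 0) {
      if (i %% 2L == 0L) add(k, match(i + i %/% 2L, states), d)
      else {
        add(k, match(i + i %/% 2L, states), d / 2)
        add(k, match(i + i %/% 2L + 1L, states), d / 2)
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

default_chrom_bounds <- function(tip_states) {
  m <- max(as.integer(tip_states))
  c(n_min = 1L, n_max = 2L * m + 2L)
}

#' Fit a chromosome-number CTMC by maximum likelihood
#'
#' Maximises the pruning likelihood over the enabled rates (log scale,
#' Nelder-Mead with restarts). Available rate sets combine constant
#' dysploidy (\code{gain}, \code{loss}) with optional \code{dupl} and/or
#' \code{demi}, and optionally count-linear dysploidy coefficients.
#'
#' @param tree A rooted \code{phylo} (>= 4 tips).
#' @param tip_states Named integer vector of haploid counts.
#' @param rates Character vector of free constant rates (subset of gain,
#'   loss, dupl, demi; default \code{c("gain", "loss")}).
#' @param linear Also estimate \code{gain_lin}, \code{loss_lin} (default
#'   FALSE).
#' @param n_max Upper state bound; default \code{2 * max(tip_states) + 2}.
#' @param root_prior Passed to [ctmc_loglik()].
#' @param n_starts Optimiser restarts (default 3).
#' @return A \code{karyevo_chromfit} list: rates (all six, unused = 0),
#'   free (names of estimated parameters), lnL, k, AIC, AICc, Q, bounds,
#'   convergence flag.
#' @export
fit_chrom_model <- function(tree, tip_states, rates = c("gain", "loss"),
                            linear = FALSE, n_max = NULL,
                            root_prior = "uniform", n_starts = 3L) {
  if (ape::Ntip(tree) < 4L) stop("need at least 4 tips")
  rates <- match.arg(rates, CHROM_RATES, several.ok = TRUE)
  b <- default_chrom_bounds(tip_states)
  if (!is.null(n_max)) b["n_max"] <- n_max
  free <- c(rates, if (linear) c("gain_lin", "loss_lin"))
  nf <- length(free)
  lin_idx <- grepl("_lin$", free)
  to_rates <- function(par) {
    v <- stats::setNames(numeric(6L),
                         c(CHROM_RATES, "gain_lin", "loss_lin"))
    v[free[!lin_idx]] <- exp(par[!lin_idx])
    v[free[lin_idx]] <- par[lin_idx]  # linear coefficients may be negative
    as.list(v)
  }
  Q0 <- build_chrom_q(list(gain = 1), b["n_min"], b["n_max"])
  st <- ctmc_tip_index(tree, tip_states, Q0)
  post <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nll <- function(par) {
    if (any(par[!lin_idx] > 12)) return(1e10)  # guard absurd rates
    Q <- build_chrom_q(to_rates(par), b["n_min"], b["n_max"])
    l <- ctmc_down_core(post, st, Q, root_prior, ntip,
                        ntip + tree$Nnode)$lnL
    if (!is.finite(l)) 1e10 else -l
  }
  h <- tree_height(tree)
  starts <- lapply(seq_len(n_starts), function(i) {
    p <- rep(log(c(0.5, 2, 8)[min(i, 3L)] / h), nf)
    p[lin_idx] <- 0
    p
  })
  lower <- ifelse(lin_idx, -10, -14)
  upper <- ifelse(lin_idx, 10, 12)
  best <- NULL
  for (p0 in starts) {
    op <- stats::optim(p0, nll, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(maxit = 200, factr = 1e7))
    if (is.null(best) || op$value < best$value) best <- op
  }
  est <- to_rates(best$par)
  Q <- build_chrom_q(est, b["n_min"], b["n_max"])
  lnL <- -best$value
  out <- list(rates = est, free = free, lnL = lnL, k = nf,
              AIC = aic(lnL, nf), AICc = aicc(lnL, nf, ape::Ntip(tree)),
              Q = Q, n_min = unname(b["n_min"]), n_max = unname(b["n_max"]),
              root_prior = root_prior,
              converged = best$convergence == 0)
  class(out) <- "karyevo_chromfit"
  out
}

#' @export
print.karyevo_chromfit <- function(x, ...) {
  cat("chromosome-number CTMC fit\n")
  shown <- unlist(x$rates[x$free])
  cat(paste(sprintf("  %s = %.4g", names(shown), shown), collapse = "\n"),
      "\n")
  cat(sprintf("lnL = %.4f, k = %d, AIC = %.3f (states %d..%d)\n",
              x$lnL, x$k, x$AIC, x$n_min, x$n_max))
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

#' Compare chromosome-number model families by AIC
#'
#' Fits the standard family ladder: constant dysploidy only, plus
#' duplication, plus demi-duplication, plus both, and the linear-rate
#' variant of each requested family.
#'
#' @inheritParams fit_chrom_model
#' @param families List of rate-set specifications; the default covers
#'   dysploidy-only, +dupl, +demi, +dupl+demi, and linear dysploidy.
#' @return data.frame ranked by AIC, with the fits in
#'   \code{attr(, "fits")}.
#' @export
chrom_model_table <- function(tree, tip_states, families = NULL,
                              n_max = NULL, root_prior = "uniform") {
  if (is.null(families))
    families <- list(
      const = list(rates = c("gain", "loss"), linear = FALSE),
      const_dupl = list(rates = c("gain", "loss", "dupl"), linear = FALSE),
      const_demi = list(rates = c("gain", "loss", "demi"), linear = FALSE),
      const_dupl_demi = list(rates = CHROM_RATES, linear = FALSE),
      linear = list(rates = c("gain", "loss"), linear = TRUE))
  fits <- lapply(families, function(f)
    fit_chrom_model(tree, tip_states, rates = f$rates, linear = f$linear,
                    n_max = n_max, root_prior = root_prior))
  out <- data.frame(
    family = names(families),
    k = vapply(fits, `[[`, 0L, "k"),
    lnL = vapply(fits, `[[`, 0, "lnL"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$delta_AIC <- out$AIC - min(out$AIC)
  out <- out[order(out$AIC), ]
  attr(out, "fits") <- fits
  out
}

#' Marginal ancestral chromosome numbers
#'
#' Up-down marginal posterior over haploid counts at every internal node
#' under a fitted model, plus the maximum-likelihood state per node.
#'
#' @param tree A rooted \code{phylo}.
#' @param tip_states Named integer vector of haploid counts.
#' @param fit A \code{karyevo_chromfit} from [fit_chrom_model()] (or any
#'   list with elements \code{Q} and \code{root_prior}).
#' @return List as [ctmc_ancestral()], with \code{ml_state} as integers.
#' @export
chrom_ancestral <- function(tree, tip_states, fit) {
  anc <- ctmc_ancestral(tree, tip_states, fit$Q,
                        root_prior = fit$root_prior %||% "uniform")
  anc$ml_state <- as.integer(anc$ml_state)
  anc
}
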