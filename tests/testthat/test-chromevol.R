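test_that("the chromosome-number generator encodes the stated moves", {
  Q <- build_chrom_q(list(gain = 1.5, loss = 0.8, dupl = 0.4, demi = 0.3),
                     1, 40)
  # demi-duplication: even count goes to 1.5x, odd splits equally
  expect_equal(Q["10", "15"], 0.3)
  expect_equal(Q["11", "16"], 0.15)
  expect_equal(Q["11", "17"], 0.15)
  expect_equal(Q["10", "20"], 0.4)
  expect_equal(Q["10", "11"], 1.5)
  expect_equal(Q["10", "9"], 0.8)
  # rows of random generators sum to zero
  set.seed(151)
  for (i in 1:50) {
    r <- list(gain = runif(1, 0, 3), loss = runif(1, 0, 3),
              dupl = runif(1, 0, 1), demi = runif(1, 0, 1),
              gain_lin = runif(1, -0.05, 0.2),
              loss_lin = runif(1, -0.05, 0.2))
    Qi <- build_chrom_q(r, 1, sample(10:50, 1))
    expect_lt(max(abs(rowSums(Qi))), 1e-12)
    expect_gte(min(Qi - diag(diag(Qi))), 0)
  }
})

test_that("transition probabilities are proper for random models", {
  set.seed(153)
  for (i in 1:10) {
    Q <- build_chrom_q(list(gain = runif(1, 0, 2), loss = runif(1, 0, 2),
                            demi = runif(1, 0, 0.5)), 1, 25)
    dec <- karyevo:::ctmc_decompose(Q)
    P <- karyevo:::ctmc_pmat(dec, runif(1, 0.1, 5))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_gte(min(P), 0)
  }
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(157)
  for (i in 1:6) {
    ntips <- sample(3:4, 1)
    tr <- sim_bd_tree(ntips, 1, 0)
    Q <- build_chrom_q(list(gain = runif(1, 0.5, 2), loss = runif(1, 0.5, 2),
                            demi = runif(1, 0, 0.5)), 1, 10)
    tip_idx <- sample(4:8, ntips, replace = TRUE)
    tips <- stats::setNames(rownames(Q)[tip_idx], tr$tip.label)
    ours <- ctmc_loglik(tr, tips, Q)
    prior <- rep(1 / nrow(Q), nrow(Q))
    oracle <- enum_ctmc_loglik(tr, tip_idx, Q, prior)
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
})

test_that("likelihood limits and invariances hold", {
  # branch lengths -> 0 with identical tip states: lnL -> log prior
  tr <- read_newick("(A:1e-9,B:1e-9);")
  Q <- build_chrom_q(list(gain = 1, loss = 1), 1, 8)
  tips <- c(A = "4", B = "4")
  expect_equal(ctmc_loglik(tr, tips, Q), log(1 / 8), tolerance = 1e-6)
  # invariant to tip ordering
  set.seed(159)
  tr2 <- sim_bd_tree(8, 1, 0, seed = 161)
  states <- stats::setNames(as.character(sample(3:7, 8, replace = TRUE)),
                            tr2$tip.label)
  expect_equal(ctmc_loglik(tr2, states, Q),
               ctmc_loglik(tr2, rev(states), Q))
  # all rates zero on variable data: impossible, reported as -Inf
  Q0 <- build_chrom_q(list(gain = 0), 1, 8)
  var_states <- stats::setNames(as.character(rep(c(3, 5), 4)),
                                tr2$tip.label)
  expect_identical(ctmc_loglik(tr2, var_states, Q0), -Inf)
})

test_that("nested rate families order their maximum likelihoods", {
  set.seed(163)
  tr <- sim_bd_tree(40, 1, 0, seed = 165)
  Q <- build_chrom_q(list(gain = 1, loss = 0.5, demi = 0.4), 1, 30)
  sim <- sim_discrete(tr, Q, root_state = "8", seed = 166)
  ts <- stats::setNames(as.integer(sim$tip_states), names(sim$tip_states))
  f2 <- fit_chrom_model(tr, ts, c("gain", "loss"), n_starts = 2)
  f3 <- fit_chrom_model(tr, ts, c("gain", "loss", "demi"), n_starts = 2)
  expect_gte(f3$lnL, f2$lnL - 1e-4)
  expect_equal(f3$k, 3L)
  expect_equal(f3$AIC, 2 * 3 - 2 * f3$lnL)
})

test_that("marginal reconstruction is a proper distribution and is exact
           on a symmetric two-state case", {
  # two states, symmetric rates, one tip in each state: root is 50/50
  tr <- read_newick("(A:1,B:1);")
  Q <- build_chrom_q(list(gain = 0.7, loss = 0.7), 1, 2)
  anc <- ctmc_ancestral(tr, c(A = "1", B = "2"), Q)
  expect_equal(unname(anc$prob[1, ]), c(0.5, 0.5))
  # probabilities sum to one on a bigger instance
  set.seed(167)
  tr2 <- sim_bd_tree(20, 1, 0.2, seed = 169)
  Q2 <- build_chrom_q(list(gain = 1, loss = 0.8), 1, 24)
  sim <- sim_discrete(tr2, Q2, root_state = "9", seed = 170)
  anc2 <- ctmc_ancestral(tr2, sim$tip_states, Q2)
  expect_lt(max(abs(rowSums(anc2$prob) - 1)), 1e-9)
})

test_that("marginal reconstruction matches enumeration on a 4-tip tree", {
  set.seed(171)
  tr <- sim_bd_tree(4, 1, 0, seed = 173)
  Q <- build_chrom_q(list(gain = 1.2, loss = 0.9), 1, 8)
  tip_idx <- c(3L, 4L, 5L, 3L)
  tips <- stats::setNames(rownames(Q)[tip_idx], tr$tip.label)
  anc <- ctmc_ancestral(tr, tips, Q, root_prior = "uniform")
  oracle <- enum_ctmc_marginals(tr, tip_idx, Q, rep(1 / 8, 8))
  expect_equal(unname(anc$prob), oracle, tolerance = 1e-8)
})

test_that("credible sets cover the true simulated history", {
  # coverage of the 95% marginal credible sets under the generating model
  # (plug-in reconstruction under ML estimates is anti-conservative by
  # construction and is not asserted here)
  set.seed(177)
  hits <- 0L; total <- 0L
  for (rep in 1:3) {
    tr <- sim_bd_tree(80, 1, 0)
    Q <- build_chrom_q(list(gain = 1.5, loss = 1), 1, 30)
    sim <- sim_discrete(tr, Q, root_state = "10")
    ts <- stats::setNames(as.integer(sim$tip_states), names(sim$tip_states))
    anc <- ctmc_ancestral(tr, ts, Q)
    for (v in seq_len(nrow(anc$prob))) {
      p <- anc$prob[v, ]
      ord <- order(p, decreasing = TRUE)
      cred <- ord[seq_len(which(cumsum(p[ord]) >= 0.95)[1])]
      truth <- match(sim$node_states[v], colnames(anc$prob))
      hits <- hits + (truth %in% cred)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})
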