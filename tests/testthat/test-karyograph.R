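test_that("state enumeration respects the arm constraint", {
  st <- karyograph_states(3)
  expect_equal(nrow(st), 9)  # 2 + 3 + 4
  expect_true(all(st$y <= st$x & st$x <= 2 * st$y))
  expect_equal(karyograph_states(1)$label, c("1/1", "1/2"))
  expect_identical(karyograph_states(5), karyograph_states(5))
  expect_error(karyograph_states(0))
})

test_that("the karyograph generator applies the per-chromosome rate laws", {
  st <- karyograph_states(6)
  Q <- build_karyograph_q(st, k1 = 0.5, k2 = 0.7, k3 = 0.2, k4 = 0.1,
                          k5 = 0.05)
  # (2,2): two telocentrics fuse at 2*k1; no bi-armed, so no fission
  expect_equal(Q["2/2", "1/2"], 2 * 0.5)
  expect_equal(sum(Q["2/2", ] > 0 &
                     colnames(Q) == "3/2"), 0)
  # (1,2): one metacentric fissions at k2; no fusion possible
  expect_equal(Q["1/2", "2/2"], 0.7)
  # polyploidisation doubles both coordinates
  expect_equal(Q["2/3", "4/6"], 0.05)
  # transitions never leave the y <= x <= 2y region
  pos <- which(Q > 0, arr.ind = TRUE)
  tgt <- st[pos[, 2], ]
  expect_true(all(tgt$y <= tgt$x & tgt$x <= 2 * tgt$y))
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  # per-karyotype multiplier option drops the eligible-count scaling
  Qk <- build_karyograph_q(st, 0.5, 0.7, 0.2, 0.1,
                           multiplier = "per_karyotype")
  expect_equal(Qk["2/2", "1/2"], 0.5)
})

test_that("MuSSE reduces to CTMC pruning when lambda = mu = 0", {
  set.seed(181)
  tr <- sim_bd_tree(8, 1, 0.2, seed = 183)
  st <- karyograph_states(6)
  Q <- build_karyograph_q(st, 0.3, 0.4, 0.5, 0.2)
  sim <- sim_discrete(tr, Q, root_state = "3/4", seed = 184)
  pars0 <- list(k1 = 0.3, k2 = 0.4, k3 = 0.5, k4 = 0.2, lam = 0, mu = 0)
  for (mode in c("fitzjohn", "flat")) {
    prior <- if (mode == "fitzjohn") "fitzjohn" else "uniform"
    ref <- ctmc_loglik(tr, sim$tip_states, Q, root_prior = prior)
    expect_equal(musse_loglik(tr, sim$tip_states, pars0, y_max = 6,
                              method = "ode", root_mode = mode),
                 ref, tolerance = 1e-8)
    expect_equal(musse_loglik(tr, sim$tip_states, pars0, y_max = 6,
                              method = "factorized", root_mode = mode),
                 ref, tolerance = 1e-12)
  }
})

test_that("ODE and factorized likelihoods agree with diversification", {
  set.seed(187)
  tr <- sim_bd_tree(12, 1, 0.3, seed = 189)
  st <- karyograph_states(6)
  Q <- build_karyograph_q(st, 0.2, 0.5, 0.4, 0.1)
  sim <- sim_discrete(tr, Q, root_state = "3/4", seed = 190)
  for (i in 1:4) {
    pars <- list(k1 = runif(1, 0.05, 0.5), k2 = runif(1, 0.05, 0.5),
                 k3 = runif(1, 0.05, 0.5), k4 = runif(1, 0.05, 0.5),
                 k5 = c(0, 0.1)[1 + i %% 2],
                 lam = runif(1, 0.5, 2), mu = runif(1, 0, 0.4))
    lf <- musse_loglik(tr, sim$tip_states, pars, y_max = 6,
                       method = "factorized")
    lo <- musse_loglik(tr, sim$tip_states, pars, y_max = 6,
                       method = "ode")
    expect_equal(lf, lo, tolerance = 1e-6)
  }
})

test_that("a single-cherry likelihood matches the analytic solution", {
  # identical tip states, no karyotype transitions, mu = 0: each branch
  # contributes e^(-lambda h) and the node a factor lambda
  tr <- read_newick("(A:1.5,B:1.5);")
  lam <- 0.8
  pars <- list(k1 = 0, k2 = 0, k3 = 0, k4 = 0, lam = lam, mu = 0)
  tips <- c(A = "3/4", B = "3/4")
  closed <- log(lam) - 2 * lam * 1.5
  expect_equal(musse_loglik(tr, tips, pars, y_max = 4, method = "ode",
                            rtol = 1e-10),
               closed, tolerance = 1e-8)
  expect_equal(musse_loglik(tr, tips, pars, y_max = 4,
                            method = "factorized"),
               closed, tolerance = 1e-8)
})

test_that("with k3 = k4 = 0 the model collapses to a fission-fusion chain", {
  # all tips share arm number x0; x cannot change, so the karyograph
  # likelihood equals a hand-built 1-D chain on y with fusion k1*(2y-x0)
  # and fission k2*(x0-y)
  set.seed(191)
  tr <- sim_bd_tree(10, 1, 0, seed = 193)
  x0 <- 8L
  k1 <- 0.3; k2 <- 0.45
  ys <- 4:8  # y range with y <= x0 <= 2y
  chain <- matrix(0, 5, 5, dimnames = list(paste0(ys, "/", x0),
                                           paste0(ys, "/", x0)))
  for (i in seq_along(ys)) {
    y <- ys[i]
    if (2 * y - x0 >= 2 && i > 1) chain[i, i - 1] <- k1 * (2 * y - x0)
    if (x0 - y >= 1 && i < 5) chain[i, i + 1] <- k2 * (x0 - y)
  }
  diag(chain) <- -rowSums(chain)
  tipy <- sample(5:7, 10, replace = TRUE)
  tips <- stats::setNames(paste0(tipy, "/", x0), tr$tip.label)
  stk <- karyograph_states(10)
  Qk <- build_karyograph_q(stk, k1, k2, 0, 0)
  expect_equal(ctmc_loglik(tr, tips, Qk, root_prior = "fitzjohn"),
               ctmc_loglik(tr, tips, chain, root_prior = "fitzjohn"),
               tolerance = 1e-10)
})

test_that("M1/M2 comparison honours nesting and the LRT identity", {
  expect_equal(lrt_test(-342.2464, -331.4004)$statistic, 21.692,
               tolerance = 1e-10)
  id <- lrt_test(-10, -10)
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)
  set.seed(197)
  tr <- sim_bd_tree(16, 1, 0.2, seed = 199)
  st <- karyograph_states(8)
  Q <- build_karyograph_q(st, 0.15, 0.3, 0.3, 0.15)
  sim <- sim_discrete(tr, Q, root_state = "4/6", seed = 200)
  fits <- fit_m1_m2(tr, sim$tip_states, y_max = 8, n_starts = 1)
  expect_gte(fits$m2$lnL, fits$m1$lnL)
  expect_equal(fits$m1$k, 6L)
  expect_equal(fits$m2$k, 7L)
  expect_equal(fits$lrt$statistic,
               2 * (fits$m2$lnL - fits$m1$lnL))
  expect_equal(fits$lrt$p_boundary, fits$lrt$p_value / 2)
})

test_that("ancestral karyograph reconstruction matches enumeration and
           reports mean coordinates", {
  set.seed(203)
  tr <- sim_bd_tree(4, 1, 0, seed = 205)
  st <- karyograph_states(4)
  Q <- build_karyograph_q(st, 0.3, 0.5, 0.4, 0.2)
  tips <- stats::setNames(c("2/3", "3/4", "3/5", "2/4"), tr$tip.label)
  fit <- list(Q = Q, states = st, root_mode = "flat")
  anc <- ancestral_karyograph(tr, tips, fit)
  expect_lt(max(abs(rowSums(anc$prob) - 1)), 1e-9)
  tip_idx <- match(tips, st$label)
  oracle <- enum_ctmc_marginals(tr, tip_idx, Q,
                                rep(1 / nrow(Q), nrow(Q)))
  expect_equal(unname(anc$prob), oracle, tolerance = 1e-6)
  expect_equal(anc$mean_y, as.vector(oracle %*% st$y), tolerance = 1e-6)
  expect_true(all(anc$mean_x >= anc$mean_y - 1e-9))
  expect_true(all(anc$mean_x <= 2 * anc$mean_y + 1e-9))
})

test_that("karyograph credible sets cover simulated histories", {
  set.seed(207)
  hits <- 0L; total <- 0L
  st <- karyograph_states(8)
  Q <- build_karyograph_q(st, 0.15, 0.3, 0.3, 0.15)
  for (rep in 1:2) {
    tr <- sim_bd_tree(40, 1, 0)
    sim <- sim_discrete(tr, Q, root_state = "4/6")
    anc <- ctmc_ancestral(tr, sim$tip_states, Q, root_prior = "fitzjohn")
    for (v in seq_len(nrow(anc$prob))) {
      p <- anc$prob[v, ]
      ord <- order(p, decreasing = TRUE)
      cred <- ord[seq_len(which(cumsum(p[ord]) >= 0.95)[1])]
      hits <- hits + (match(sim$node_states[v], colnames(anc$prob)) %in%
                        cred)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("tip-state mapping halves the diploid fundamental number", {
  traits <- data.frame(taxon = c("a", "b"), n = c(11, 19), fn = c(44, 74))
  ts <- karyograph_tip_states(traits)
  expect_equal(unname(ts), c("11/22", "19/37"))
  bad <- data.frame(taxon = "z", n = 10, fn = 60)  # x > 2y impossible
  expect_error(karyograph_tip_states(bad), "invalid")
})
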