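test_that("Moran's I matches a naive evaluation and detects clade structure", {
  tr <- tree4_balanced()
  y <- c(A = 1, B = 1, C = -1, D = -1)
  W <- 1 / stats::cophenetic(tr)
  diag(W) <- 0
  res <- morans_i(tr, y, n_reps = 199, seed = 1)
  expect_equal(res$observed,
               naive_moran(W[names(y), names(y)], unname(y)))
  # clade-structured data on a deeper tree give positive autocorrelation
  set.seed(69)
  tr2 <- sim_bd_tree(15, 1, 0, seed = 70)
  y2 <- sim_continuous(tr2, "BM", seed = 71)
  expect_gt(morans_i(tr2, y2, n_reps = 49, seed = 1)$observed, 0)
  # same seed, same p
  res2 <- morans_i(tr, y, n_reps = 199, seed = 1)
  expect_identical(res$p_value, res2$p_value)
  expect_error(morans_i(tr, c(A = 1, B = 1, C = 1, D = 1)), "constant")
})

test_that("Abouheif proximity follows the nodal-path product rule", {
  A <- abouheif_proximity(tree3())
  expect_equal(A["A", "B"], 1 / 2)
  expect_equal(A["A", "C"], 1 / 4)
  expect_equal(A["B", "C"], 1 / 4)
  # topology-only: invariant to branch-length scaling
  tr <- tree4_balanced()
  y <- c(A = 3, B = 2.5, C = -1, D = -2)
  r1 <- abouheif_cmean(tr, y, n_reps = 99, seed = 2)
  tr10 <- tr
  tr10$edge.length <- tr$edge.length * 10
  r2 <- abouheif_cmean(tr10, y, n_reps = 99, seed = 2)
  expect_equal(r1$observed, r2$observed)
  # statistic equals a naive evaluation with the proximity weights
  expect_equal(r1$observed,
               naive_moran(abouheif_proximity(tr)[names(y), names(y)],
                           unname(y)))
})

test_that("signal statistics are invariant to trait location/scale", {
  set.seed(71)
  tr <- sim_bd_tree(15, 1, 0.2, seed = 73)
  y <- sim_continuous(tr, "BM", seed = 74)
  for (f in list(morans_i, abouheif_cmean, blomberg_k)) {
    a <- f(tr, y, n_reps = 49, seed = 3)$observed
    b <- f(tr, 10 + 3 * y, n_reps = 49, seed = 3)$observed
    expect_equal(a, b, tolerance = 1e-10)
  }
  # Blomberg's K also invariant to joint branch-length scaling
  trs <- tr
  trs$edge.length <- tr$edge.length * 5
  expect_equal(blomberg_k(tr, y, 9, seed = 4)$observed,
               blomberg_k(trs, y, 9, seed = 4)$observed, tolerance = 1e-10)
})

test_that("Blomberg's K agrees with an independent implementation", {
  set.seed(79)
  tr <- sim_bd_tree(25, 1, 0.3, seed = 81)
  y <- sim_continuous(tr, "BM", seed = 82)
  ours <- blomberg_k(tr, y, n_reps = 9, seed = 5)$observed
  ref <- phytools::phylosig(tr, y, method = "K")
  expect_equal(ours, as.numeric(ref), tolerance = 1e-8)
})

test_that("permutation p-values respect their bounds", {
  set.seed(83)
  tr <- sim_bd_tree(10, 1, 0, seed = 85)
  y <- sim_continuous(tr, "BM", seed = 86)
  for (nr in c(9, 99)) {
    p <- morans_i(tr, y, n_reps = nr, seed = 6)$p_value
    expect_gte(p, 1 / (1 + nr))
    expect_lte(p, 1)
  }
})

test_that("Pagel's lambda test behaves at its boundaries", {
  # identical nested likelihoods give statistic 0 and p = 1
  id <- lrt_test(-12.3, -12.3)
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)
  set.seed(87)
  tr <- sim_bd_tree(40, 1, 0.2, seed = 89)
  y_bm <- sim_continuous(tr, "BM", seed = 90)
  fit <- pagels_lambda_test(tr, y_bm)
  expect_gt(fit$observed, 0.7)
  expect_lt(fit$p_value, 0.05)
  # iid tips: lambda-hat near 0, LRT statistic near 0
  y_iid <- stats::setNames(rnorm(40), tr$tip.label)
  fit0 <- pagels_lambda_test(tr, y_iid)
  expect_lt(fit0$observed, 0.3)
  expect_gte(attr(fit0, "detail")$statistic, -1e-8)
})

test_that("the signal table covers every trait with all four tests", {
  set.seed(91)
  tr <- sim_bd_tree(12, 1, 0, seed = 93)
  traits <- data.frame(taxon = tr$tip.label,
                       a = sim_continuous(tr, "BM", seed = 94),
                       b = sim_continuous(tr, "BM", seed = 95))
  tab <- signal_table(tr, traits, n_reps = 49, seed = 7)
  expect_equal(tab$trait, c("a", "b"))
  expect_true(all(tab$moran_p > 0 & tab$moran_p <= 1))
  expect_true(all(c("moran_i", "cmean", "k", "lambda") %in% names(tab)))
  # deterministic given the seed
  tab2 <- signal_table(tr, traits, n_reps = 49, seed = 7)
  expect_identical(tab, tab2)
})
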