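test_that("karyotype formulas parse into class counts", {
  expect_equal(parse_karyotype("12 m + 6sm + 4st"),
               c(m = 12L, sm = 6L, st = 4L, t = 0L))
  expect_equal(parse_karyotype("2 m + 6sm + 16st + 14 t"),
               c(m = 2L, sm = 6L, st = 16L, t = 14L))
  expect_equal(parse_karyotype("20 m"),
               c(m = 20L, sm = 0L, st = 0L, t = 0L))
  # acrocentric is recorded as telocentric
  expect_equal(parse_karyotype("4a + 2m")[["t"]], 4L)
  expect_error(parse_karyotype("12x + 3m"), "12x")
  expect_error(parse_karyotype(""), "empty")
  expect_error(parse_karyotype("m + 2sm"), "cannot parse")
})

test_that("format/parse round-trips random karyotypes", {
  set.seed(7)
  for (i in 1:50) {
    counts <- stats::setNames(as.integer(rmultinom(1, 2 * sample(5:25, 1),
                                                   rep(0.25, 4))),
                              c("m", "sm", "st", "t"))
    if (sum(counts) == 0) next
    expect_identical(parse_karyotype(format_karyotype(counts)), counts)
  }
})

test_that("trait derivation reproduces published rows", {
  # Acromyrmex balzani: 12m + 10sm + 14st + 2t
  tv <- karyotype_traits(c(m = 12, sm = 10, st = 14, t = 2))
  expect_equal(tv, c(n = 19, nm = 6, nsm = 5, nst = 7, nt = 1, fn = 74))
  # Amoimyrmex striatus: 20m + 2sm
  tv2 <- karyotype_traits(c(m = 20, sm = 2, st = 0, t = 0))
  expect_equal(tv2[["n"]], 11)
  expect_equal(tv2[["nm"]], 10)
  expect_equal(tv2[["nsm"]], 1)
  expect_equal(tv2[["fn"]], 44)
  expect_error(karyotype_traits(c(m = 0, sm = 0, st = 0, t = 0)), "empty")
  expect_error(karyotype_traits(c(m = 3, sm = 1, st = 0, t = 0)), "odd")
  expect_silent(karyotype_traits(c(m = 3, sm = 1, st = 0, t = 0),
                                 strict = FALSE))
})

test_that("arm-ratio classification follows the Levan bands", {
  expect_identical(classify_arm_ratio(1, 1), "m")
  expect_identical(classify_arm_ratio(2, 1), "sm")
  expect_identical(classify_arm_ratio(5, 1), "st")
  expect_identical(classify_arm_ratio(8, 1), "t")
  expect_identical(classify_arm_ratio(5, 0), "t")
  # band edges: 1.7 and 3 belong to the upper class
  expect_identical(classify_arm_ratio(1.7, 1), "sm")
  expect_identical(classify_arm_ratio(3, 1), "st")
  expect_error(classify_arm_ratio(1, 2), "shorter")
  expect_error(classify_arm_ratio(0, 0))
})

test_that("packaged compilation is internally consistent", {
  k <- leafcutter_karyotypes()
  expect_equal(sum(k$group == "leafcutter"), 30)
  expect_equal(nrow(k), 33)
  # two published records for Acromyrmex ambiguus with different formulae
  amb <- k[k$taxon == "Acromyrmex ambiguus", ]
  expect_equal(nrow(amb), 2)
  expect_length(unique(amb$formula), 2)
  # parsed class counts sum to the printed 2n for every row
  parsed <- vapply(k$formula, function(f) sum(parse_karyotype(f)), 0)
  expect_equal(unname(parsed), k$diploid_2n)
  # derived haploid traits satisfy nm+nsm+nst+nt = n everywhere
  expect_equal(k$nm + k$nsm + k$nst + k$nt, k$n)
  # derived haploid class counts agree with the published columns
  expect_equal(k$nm, k$nm_published)
  expect_equal(k$nsm, k$nsm_published)
  expect_equal(k$nst, k$nst_published)
  expect_equal(k$nt, k$nt_published)
  # rows whose printed fn disagrees with the two-armed-st convention are
  # flagged, not silently accepted: the four Atta rows printing 40 and the
  # Ac. ambiguus (Brazil) row printing 68
  flagged <- k[!k$fn_consistent, ]
  expect_equal(nrow(flagged), 5)
  expect_setequal(unique(flagged$taxon),
                  c("Atta bisphaerica", "Atta colombica", "Atta laevigata",
                    "Atta sexdens", "Acromyrmex ambiguus"))
})

test_that("trait table has one preferred record per species", {
  tt <- karyotype_trait_table()
  expect_false(anyDuplicated(tt$taxon) > 0)
  k <- leafcutter_karyotypes()
  expect_equal(nrow(tt), length(unique(k$taxon)))
  # log(x + 1) transform tolerates the zero counts in Atta / Amoimyrmex
  lt <- karyotype_trait_table(log_transform = TRUE)
  expect_true(all(is.finite(as.matrix(lt[-1]))))
  expect_equal(lt$n, log(tt$n + 1))
})
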