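# Diversity and differentiation statistics against hand values and
# brute-force oracles.

test_that("observed heterozygosity and gene diversity match hand values", {
  ds <- make_ds(list(list(L1 = c(1, 1)), list(L1 = c(1, 2)),
                     list(L1 = c(1, 2))))
  expect_equal(observed_heterozygosity(ds)$per_locus[["L1"]], 2 / 3)
  homs <- make_ds(list(list(L1 = c(1, 1)), list(L1 = c(2, 2))))
  expect_equal(observed_heterozygosity(homs)$mean, 0)

  # 5 individuals, allele counts (5, 3, 2) of 10 genes: H_S = (10/9)(1 - 0.38)
  ds2 <- make_ds(list(list(L1 = c(1, 1)), list(L1 = c(1, 1)),
                      list(L1 = c(1, 2)), list(L1 = c(2, 2)),
                      list(L1 = c(3, 3))))
  expect_equal(gene_diversity(ds2)$per_locus[["L1"]], 10 / 9 * (1 - 0.38),
               tolerance = 1e-12)
  mono <- make_ds(list(list(L1 = c(1, 1)), list(L1 = c(1, 1))))
  expect_equal(gene_diversity(mono)$mean, 0)
  set.seed(2)
  big <- random_hwe_ds(200, list(L1 = c("1" = .5, "2" = .5)))
  expect_equal(gene_diversity(big)$mean, 0.5, tolerance = 0.03)
})

test_that("rarefied allelic richness equals exhaustive subsample enumeration", {
  # 3 individuals, gene copies (1,1,1,1,2,2): counts (4,2)
  ds <- make_ds(list(list(L1 = c(1, 1)), list(L1 = c(1, 1)),
                     list(L1 = c(2, 2))))
  r <- allelic_richness(ds, g = 2)$per_locus[["L1"]]
  expect_equal(r, bf_richness_enum(c(1, 1, 1, 1, 2, 2), 2), tolerance = 1e-12)
  expect_equal(r, (1 - choose(2, 2) / choose(6, 2)) +
                  (1 - choose(4, 2) / choose(6, 2)), tolerance = 1e-12)
  # g = N -> observed allele count; monomorphic -> 1
  expect_equal(allelic_richness(ds, g = 6)$per_locus[["L1"]], 2)
  mono <- make_ds(list(list(L1 = c(7, 7)), list(L1 = c(7, 7))))
  expect_equal(allelic_richness(mono, g = 2)$per_locus[["L1"]], 1)
  expect_error(allelic_richness(ds, g = 8), "exceeds")
  set.seed(4)
  rnd <- random_hwe_ds(6, equifreqs(2, 4))
  rs <- allelic_richness(rnd, g = 5)
  for (l in locus_names(rnd))
    expect_equal(rs$per_locus[[l]],
                 bf_richness_enum(c(rnd$a1[, l], rnd$a2[, l]), 5),
                 tolerance = 1e-10)
})

test_that("Weir-Cockerham F_IS: forced values, HWE calibration, oracle match", {
  allhet <- make_ds(rep(list(list(L1 = c(1, 2))), 10))
  expect_equal(multilocus_fis(allhet)$f, -1)
  set.seed(6)
  fs <- replicate(20, {
    multilocus_fis(random_hwe_ds(60, equifreqs(6, 5)))$f
  })
  expect_lt(abs(mean(fs)), 0.02)
  ds <- random_hwe_ds(9, equifreqs(3, 4))
  expect_equal(multilocus_fis(ds)$f, bf_wc_fis(ds), tolerance = 1e-10)
  mono <- make_ds(list(list(L1 = c(1, 1)), list(L1 = c(1, 1))))
  expect_error(multilocus_fis(mono), "monomorphic")
})

test_that("pairwise theta: fixed difference, label-swap invariance, oracle", {
  fixed <- make_ds(c(rep(list(list(L1 = c(1, 1))), 5),
                     rep(list(list(L1 = c(2, 2))), 5)),
                   stage = rep(c("mature", "juvenile"), each = 5))
  r <- pairwise_fst_amova(fixed, "mature", "juvenile", n_perms = 50,
                          rng_seed = 1)
  expect_equal(r$theta, 1)
  expect_lt(r$p, 0.05)

  set.seed(10)
  ds <- random_hwe_ds(20, equifreqs(4, 4),
                      stage = rep(c("mature", "sapling"), each = 10))
  ra <- pairwise_fst_amova(ds, "mature", "sapling", n_perms = 99, rng_seed = 2)
  rb <- pairwise_fst_amova(ds, "sapling", "mature", n_perms = 99, rng_seed = 2)
  expect_equal(ra$theta, rb$theta, tolerance = 1e-12)
  expect_lt(abs(ra$theta), 0.08)       # identical gene pool
  grp <- ds$info$stage == "mature"
  expect_equal(ra$theta, bf_theta(ds, grp), tolerance = 1e-10)
  expect_true(ra$p >= 1 / 100)

  m <- pairwise_fst_matrix(ds, n_perms = 30, rng_seed = 3)
  expect_equal(m$theta["mature", "sapling"], ra$theta, tolerance = 1e-12)
  expect_equal(m$theta, t(m$theta))
})

test_that("HWE Monte-Carlo exact test: extreme case, enumeration oracle, monomorphic", {
  allhet <- make_ds(rep(list(list(L1 = c(1, 2))), 20))
  r <- hwe_mc_exact_test(allhet, locus = "L1", n_reps = 499, rng_seed = 1)
  expect_lt(r$p, 0.05)
  mono <- make_ds(rep(list(list(L1 = c(1, 1))), 6))
  expect_equal(hwe_mc_exact_test(mono, locus = "L1", n_reps = 10)$p, 1)

  # exhaustive distribution over genotype arrays for 5 individuals with
  # allele counts A = 4, B = 6: arrays indexed by n_AA in 0..2
  lev <- function(naa, nab, nbb) {
    n <- naa + nab + nbb
    exp(lfactorial(n) + lfactorial(4) + lfactorial(6) + nab * log(2) -
          lfactorial(2 * n) - lfactorial(naa) - lfactorial(nab) -
          lfactorial(nbb))
  }
  arrays <- data.frame(naa = 0:2, nab = c(4, 2, 0), nbb = c(1, 2, 3))
  probs <- mapply(lev, arrays$naa, arrays$nab, arrays$nbb)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  obs <- c(1, 2, 2)  # n_AA = 1, n_AB = 2, n_BB = 2
  p_exact <- sum(probs[probs <= lev(1, 2, 2) + 1e-12])
  ds <- make_ds(list(list(L1 = c(1, 1)), list(L1 = c(1, 2)),
                     list(L1 = c(1, 2)), list(L1 = c(2, 2)),
                     list(L1 = c(2, 2))))
  set.seed(55)
  rs <- replicate(8, hwe_mc_exact_test(ds, locus = "L1", n_reps = 400,
                                       rng_seed = NULL)$p)
  se <- sqrt(p_exact * (1 - p_exact) / 400)
  expect_lt(abs(mean(rs) - p_exact), 3 * se)
})

test_that("LD permutation test: duplicated locus, resolution, independence", {
  set.seed(15)
  ds <- random_hwe_ds(40, equifreqs(2, 4))
  dup <- ds
  dup$a1 <- cbind(dup$a1, Dup = dup$a1[, 1])
  dup$a2 <- cbind(dup$a2, Dup = dup$a2[, 1])
  r <- ld_permutation_test(dup, locus_a = "Loc01", locus_b = "Dup",
                           n_reps = 199, rng_seed = 2)
  expect_equal(r$p, 1 / 200)            # minimum attainable p
  r2 <- ld_permutation_test(ds, locus_a = "Loc01", locus_b = "Loc02",
                            n_reps = 99, rng_seed = 3)
  expect_true(r2$p >= 1 / 100 && r2$p <= 1)
  sparse <- make_ds(list(list(L1 = c(1, 2), L2 = c(1, 2)),
                         list(L1 = c(1, 1), L2 = c(2, 2))))
  expect_error(ld_permutation_test(sparse, locus_a = "L1", locus_b = "L2"),
               "fewer than 5")
})

test_that("diversity summary assembles the per-stage table", {
  set.seed(19)
  ds <- random_hwe_ds(60, equifreqs(4, 6),
                      stage = rep(c("mature", "seedling"), each = 30))
  div <- diversity_summary(ds, fis_null = FALSE)
  expect_equal(div$stage, c("seedling", "mature"))
  expect_true(all(div$H_O >= 0 & div$H_O <= 1))
  expect_true(all(div$H_S >= 0 & div$H_S <= 1))
  expect_true(all(div$R_S >= 1))
  expect_true(all(abs(div$F_IS) <= 1))
})
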