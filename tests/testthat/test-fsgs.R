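# Correlograms, the kinship-distance regression, Sp, the mean-F_is test,
# cluster kinship summaries, the Q-matrix reader and Evanno delta-K.

test_that("distance classes are half-open and validated", {
  sch <- distance_class_scheme(c(0, 10, 20))
  expect_equal(sch$breaks, c(0, 10, 20))
  expect_error(distance_class_scheme(c(0, 10, 10)), "increasing")
  set.seed(5)
  ds <- random_hwe_ds(25, equifreqs(4, 5), extent = c(30, 30))
  cor <- fsgs_correlogram(ds, scheme = distance_class_scheme(seq(0, 45, 15)),
                          n_perms = 30, rng_seed = 1)
  # pair counts sum to the number of pairs within range
  D <- pairwise_distances(ds)
  dv <- D[upper.tri(D)]
  expect_equal(sum(cor$n_pairs), sum(dv < 45))
  bins <- findInterval(dv, seq(0, 45, 15))
  expect_equal(cor$n_pairs, as.vector(table(factor(bins, 1:3))))
  expect_true(all(cor$env_lo <= cor$env_hi, na.rm = TRUE))
})

test_that("correlogram detects synthetic limited dispersal in the first class", {
  cfg <- sim_config(n_mature = 80, n_logs = 60, n_loci = 8,
                    alleles_per_locus = c(6, 12), null_freq_range = c(0, 0),
                    missing_rate = 0, seed_kernel = c(a = 5, b = 1),
                    pollen_kernel = c(a = 40, b = 1), m_s = 0.2, m_p = 0.5,
                    n_offspring = c(seedling = 60, sapling = 60),
                    rng_seed = 77)
  mat <- generate_mature_population(cfg)
  off <- simulate_offspring_nm(cfg, mat, generate_landscape(cfg))
  ref <- build_reference_frequencies(mat, off)
  cor <- fsgs_correlogram(off, ref = ref, n_perms = 199, rng_seed = 3)
  expect_gt(cor$mean_fij[1], 0)
  expect_lt(cor$p[1], 0.05)
  expect_gt(cor$mean_fij[1], cor$env_hi[1])
})

test_that("regression slope matches lm() on the pair values and is 0 for flat kinship", {
  set.seed(9)
  ds <- random_hwe_ds(30, equifreqs(5, 6), extent = c(80, 80))
  ref <- allele_frequencies(ds)
  reg <- kinship_distance_regression(ds, ref = ref, n_perms = 50, rng_seed = 2)
  K <- kinship_matrix(ds, ref)
  D <- pairwise_distances(ds)
  ut <- upper.tri(K)
  kv <- K[ut]; dv <- D[ut]
  fit <- lm(kv[dv > 0] ~ log(dv[dv > 0]))
  expect_equal(reg$b_F, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(reg$n_pairs, sum(dv > 0))
  expect_true(reg$p >= 1 / 51 && reg$p <= 1)

  # constant kinship (identical heterozygotes) -> zero slope
  flat <- make_ds(rep(list(list(L1 = c(1, 2), L2 = c(1, 2))), 6),
                  x = c(1, 2, 4, 8, 16, 32), y = rep(0, 6))
  ref2 <- allele_freq_table(list(L1 = c("1" = .5, "2" = .5),
                                 L2 = c("1" = .5, "2" = .5)),
                            c(L1 = Inf, L2 = Inf))
  reg2 <- kinship_distance_regression(flat, ref = ref2, n_perms = 20,
                                      rng_seed = 1)
  expect_equal(reg2$b_F, 0, tolerance = 1e-12)
  one_locus <- subset_loci(flat, keep = "L1")
  expect_error(kinship_distance_regression(one_locus, ref = ref2,
                                           n_perms = 10), ">= 2")
})

test_that("Sp follows its defining identity and edge cases", {
  expect_equal(round(sp_statistic(-0.013, 0.055), 3), 0.014)
  expect_equal(round(sp_statistic(-0.001, -0.004), 3), 0.001)
  expect_equal(sp_statistic(0, 0.3), 0)
  expect_error(sp_statistic(-0.01, 1), "undefined")
  set.seed(14)
  ds <- random_hwe_ds(25, equifreqs(4, 5), extent = c(60, 60))
  fs <- fsgs_summary(ds, scheme = distance_class_scheme(seq(0, 90, 10)),
                     n_perms = 50, rng_seed = 4)
  expect_equal(fs$Sp * (fs$F_1 - 1), fs$b_F, tolerance = 1e-12)
})

test_that("mean F_is test: Bonferroni arithmetic and a selfing-enriched signal", {
  # 50% selfed offspring have expected F_is ~ 0.25
  set.seed(31)
  freqs <- equifreqs(8, 8)
  n <- 120
  a1 <- a2 <- matrix(NA_integer_, n, 8, dimnames = list(NULL, names(freqs)))
  parents1 <- parents2 <- a1
  for (l in names(freqs)) {
    p <- freqs[[l]]
    parents1[, l] <- as.integer(sample(names(p), n, TRUE, prob = p))
    parents2[, l] <- as.integer(sample(names(p), n, TRUE, prob = p))
  }
  selfed <- rep(c(TRUE, FALSE), length.out = n)
  for (i in seq_len(n)) for (li in 1:8) {
    mom <- c(parents1[i, li], parents2[i, li])
    if (selfed[i]) {
      a1[i, li] <- sample(mom, 1); a2[i, li] <- sample(mom, 1)
    } else {
      p <- freqs[[li]]
      a1[i, li] <- sample(mom, 1)
      a2[i, li] <- as.integer(sample(names(p), 1, prob = p))
    }
  }
  info <- data.frame(id = sprintf("s%03d", 1:n), stage = "mature",
                     x = runif(n), y = runif(n), cwd_id = NA, dbh = 30, age = NA)
  ds <- genotype_dataset(info, a1, a2)
  ref <- allele_freq_table(freqs, stats::setNames(rep(Inf, 8), names(freqs)))
  ft <- mean_fis_test(ds, ref = ref, n_perms = 199,
                      n_stages_for_bonferroni = 4, rng_seed = 6)
  # selfed F = 1/2 (two gametes of one outbred parent), so half selfed ~ 0.25
  expect_lt(abs(ft$mean_fis - 0.25), 0.05)
  expect_lt(ft$p, 0.05 / 4)
  expect_equal(ft$p_adj, min(1, ft$p * 4))
  expect_true(ft$significant)
})

test_that("cluster kinship summary: membership threshold and pair counting", {
  set.seed(8)
  ds <- random_hwe_ds(70, equifreqs(4, 6))
  q <- cbind(c(rep(0.95, 59), rep(0.2, 11)))
  q <- cbind(q, 1 - q)
  rownames(q) <- ds$info$id
  ref <- allele_frequencies(ds)
  cs <- cluster_kinship_summary(ds, ref, q, cluster = 1, threshold = 0.9)
  expect_equal(cs$n_members, 59)
  expect_equal(cs$n_pairs, 1711)
  expect_true(is.finite(cs$mean_fij))
  expect_error(cluster_kinship_summary(ds, ref, q, 1, threshold = 1.0),
               "fewer than 2")
  qall <- matrix(1, nrow = 70, ncol = 1, dimnames = list(ds$info$id, NULL))
  qall <- cbind(qall, 0)
  cs2 <- cluster_kinship_summary(ds, ref, qall, 1, threshold = 0.9)
  expect_equal(cs2$n_members, 70)
})

test_that("Q-matrix reader handles both layouts and validates row sums", {
  f <- withr::local_tempfile()
  writeLines(c("  1 ind_a (0)  1 :  0.91 0.09",
               "  2 ind_b (5)  1 :  0.40 0.60"), f)
  q <- read_structure_q(f)
  expect_equal(rownames(q), c("ind_a", "ind_b"))
  expect_equal(q[1, ], c(0.91, 0.09))
  writeLines(c("ind_a 0.5 0.5", "ind_b 0.7 0.4"), f)
  expect_error(read_structure_q(f), "sum to 1")
})

test_that("Evanno delta-K: hand value, linear lnP, and input validation", {
  runs <- data.frame(K = rep(1:3, each = 2), run = rep(1:2, 3),
                     lnP = c(-101, -99, -85, -75, -76, -74))
  dk <- evanno_delta_k(runs)
  # means (-100, -80, -75); sd(K=2) = sd(c(-85, -75)) = 7.0711
  expect_equal(dk$delta_K[2], abs(-75 - 2 * (-80) + (-100)) / sd(c(-85, -75)))
  expect_true(is.na(dk$delta_K[1]) && is.na(dk$delta_K[3]))
  lin <- data.frame(K = rep(1:4, each = 3), run = rep(1:3, 4),
                    lnP = rep(c(-40, -30, -20, -10), each = 3) + rep(c(-1, 0, 1), 4))
  dk2 <- evanno_delta_k(lin)
  expect_equal(dk2$delta_K[2:3], c(0, 0))
  expect_error(evanno_delta_k(data.frame(K = 1:3, run = 1, lnP = 1:3)),
               ">= 2 runs")
  gap <- data.frame(K = rep(c(1, 3, 4), each = 2), run = rep(1:2, 3),
                    lnP = rnorm(6))
  expect_error(evanno_delta_k(gap), "contiguous")
})
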