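# Exponential-power kernel maths and the neighborhood-model likelihood.

test_that("kernel density: closed-form identities and normalisation", {
  r <- c(0, 1, 5, 20)
  # b = 2 reduces to the Gaussian form 1/(pi a^2) exp(-(r/a)^2)
  expect_equal(exp_power_pdf(r, 7, 2), exp(-(r / 7)^2) / (pi * 49),
               tolerance = 1e-12)
  # b = 1 at r = 0: 1/(2 pi a^2)
  expect_equal(exp_power_pdf(0, 3, 1), 1 / (2 * pi * 9), tolerance = 1e-12)
  for (b in c(0.3, 0.7, 1, 2, 4)) {
    integ <- stats::integrate(function(x) 2 * pi * x * exp_power_pdf(x, 10, b),
                              0, Inf, rel.tol = 1e-9)
    expect_equal(integ$value, 1, tolerance = 1e-6)
  }
  expect_error(exp_power_pdf(1, -1, 2), "a > 0")
  expect_error(exp_power_pdf(-1, 1, 2), ">= 0")
  k <- dispersal_kernel(5, 0.6)
  expect_equal(exp_power_pdf(2, k), exp_power_pdf(2, 5, 0.6))
})

test_that("mean dispersal distance: closed form vs quadrature and known values", {
  expect_equal(mean_dispersal_distance(4, 1), 8)   # b=1: d = 2a
  for (b in c(0.2, 0.5, 1, 2, 3.5, 5)) {
    d_cf <- mean_dispersal_distance(10, b)
    # radial integral d = int r * 2 pi r P(r) dr; substituting u = (r/a)^b
    # gives d = a / Gamma(2/b) * int u^(3/b - 1) e^-u du, which adaptive
    # quadrature handles across the whole b range (the raw r-space integrand
    # for b = 0.2 has mass out to ~1e7 m and defeats it)
    d_num <- 10 / gamma(2 / b) * stats::integrate(
      function(u) u^(3 / b - 1) * exp(-u), 0, Inf, rel.tol = 1e-10)$value
    expect_equal(d_cf, d_num, tolerance = 1e-6)
  }
  expect_equal(mean_dispersal_distance(81.816, 3.097), 59.9,
               tolerance = 0.01 * 59.9)
  # extreme small b stays finite through log-gamma
  expect_true(is.finite(mean_dispersal_distance(0.01, 0.08)))
})

test_that("likelihood equals a hand-computed Mendelian product on a 2-locus toy", {
  mat <- make_ds(list(list(L1 = c(1, 2), L2 = c(1, 1)),
                      list(L1 = c(3, 4), L2 = c(1, 2))),
                 stage = "mature", x = c(0, 10), y = c(0, 0), dbh = c(30, 30))
  off <- make_ds(list(list(L1 = c(1, 3), L2 = c(1, 1))),
                 stage = "seedling", x = 5, y = 2)
  bg <- allele_freq_table(list(L1 = c("1" = .25, "2" = .25, "3" = .25, "4" = .25),
                               L2 = c("1" = .5, "2" = .5)),
                          c(L1 = Inf, L2 = Inf))
  params <- list(m_s = 0, m_p = 0, a_s = 10, b_s = 1, a_p = 10, b_p = 1,
                 gamma = 0)
  ll <- nm_offspring_loglik(off, mat, params, background = bg,
                            null_freqs = c(L1 = 0, L2 = 0))
  # with two mature trees each mother has exactly one candidate father, and
  # the transition probability is symmetric, so L = T(o | 1, 2):
  # L1: offspring 1/3 from parents (1,2) x (3,4): (1/2)(1/2) + 0 = 1/4
  # L2: offspring 1/1 from (1,1) x (1,2): 1 * 1/2 = 1/2
  expect_equal(as.numeric(ll), log(0.25 * 0.5), tolerance = 1e-10)
})

test_that("m_s = 1 makes the likelihood independent of kernel parameters", {
  set.seed(41)
  cfg <- sim_config(n_mature = 15, n_logs = 8, n_loci = 3,
                    alleles_per_locus = c(3, 5), null_freq_range = c(0, 0),
                    missing_rate = 0, n_offspring = c(seedling = 10),
                    rng_seed = 42)
  mat <- generate_mature_population(cfg)
  off <- simulate_offspring_nm(cfg, mat, generate_landscape(cfg))
  pc <- nm_precompute(off, mat)
  p1 <- list(m_s = 1, m_p = 0.5, a_s = 5, b_s = 1, a_p = 20, b_p = 1, gamma = 0.5)
  p2 <- utils::modifyList(p1, list(a_s = 50, b_s = 2, a_p = 5, b_p = 0.5))
  expect_equal(as.numeric(nm_offspring_loglik(off, mat, p1, precomp = pc)),
               as.numeric(nm_offspring_loglik(off, mat, p2, precomp = pc)),
               tolerance = 1e-10)
})

test_that("fecundity exponent upweights large-dbh parents (monotone toy)", {
  # two equidistant candidate mothers; only the large tree can be the parent
  mat <- make_ds(list(list(L1 = c(1, 1)), list(L1 = c(2, 2))),
                 stage = "mature", x = c(-5, 5), y = c(0, 0), dbh = c(60, 21))
  off <- make_ds(list(list(L1 = c(1, 1))), stage = "seedling", x = 0, y = 0)
  bg <- allele_freq_table(list(L1 = c("1" = .5, "2" = .5)), c(L1 = Inf))
  lls <- vapply(c(0, 0.5, 1, 2), function(g)
    as.numeric(nm_offspring_loglik(off, mat,
      list(m_s = 0, m_p = 1, a_s = 10, b_s = 1, a_p = 10, b_p = 1, gamma = g),
      background = bg, null_freqs = c(L1 = 0))), 1)
  expect_true(all(diff(lls) > 0))
})

test_that("likelihood is invariant to relabeling of mature individuals", {
  set.seed(43)
  cfg <- sim_config(n_mature = 20, n_logs = 10, n_loci = 4,
                    alleles_per_locus = c(3, 6), null_freq_range = c(0, 0.1),
                    n_offspring = c(seedling = 15), rng_seed = 44)
  mat <- generate_mature_population(cfg)
  off <- simulate_offspring_nm(cfg, mat, generate_landscape(cfg))
  perm <- sample(20)
  mat_p <- subset_individuals(mat, perm)
  p0 <- list(m_s = .3, m_p = .4, a_s = 8, b_s = 1, a_p = 30, b_p = 1.5,
             gamma = 0.7)
  bg <- build_reference_frequencies(mat, off)
  nf <- mat$null_freq
  expect_equal(as.numeric(nm_offspring_loglik(off, mat, p0, bg, nf)),
               as.numeric(nm_offspring_loglik(off, mat_p, p0, bg, nf)),
               tolerance = 1e-9)
})

test_that("degenerate full-immigration data drives fitted m_s to 1 with a flag", {
  cfg <- sim_config(n_mature = 25, n_logs = 12, n_loci = 6,
                    alleles_per_locus = c(5, 8), null_freq_range = c(0, 0),
                    missing_rate = 0, m_s = 1,
                    n_offspring = c(seedling = 60), rng_seed = 45)
  mat <- generate_mature_population(cfg)
  off <- simulate_offspring_nm(cfg, mat, generate_landscape(cfg))
  fit <- suppressWarnings(
    fit_neighborhood_model(off, mat, n_starts = 1, rng_seed = 1,
                           control = list(maxit = 300)))
  expect_gt(fit$estimates$m_s, 0.9)
})
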