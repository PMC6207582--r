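# Stage-wise diversity and differentiation statistics: observed
# heterozygosity, Nei unbiased gene diversity, rarefied allelic richness,
# Weir-Cockerham inbreeding and theta with permutation tests, the Monte-Carlo
# exact HWE test, and the genotypic linkage-disequilibrium permutation test.

.stage_subset <- function(ds, stage) {
  if (!is.null(stage)) ds <- subset_individuals(ds, stage = stage)
  if (n_individuals(ds) == 0) stop("no individuals in requested stage")
  ds
}

#' Observed heterozygosity per locus and multilocus mean
#'
#' Fraction of typed individuals that are heterozygous; the multilocus value
#' is the unweighted mean over loci with at least one typed individual.
#'
#' @param ds a `genotype_dataset`
#' @param stage optional stage filter
#' @return list with `per_locus` (named numeric) and `mean`
#' @export
observed_heterozygosity <- function(ds, stage = NULL) {
  ds <- .stage_subset(ds, stage)
  per <- vapply(locus_names(ds), function(l) {
    typed <- !is.na(ds$a1[, l])
    if (!any(typed)) return(NA_real_)
    mean(ds$a1[typed, l] != ds$a2[typed, l])
  }, 1)
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Nei unbiased gene diversity per locus and multilocus mean
#'
#' `H_S = n_l/(n_l - 1) * (1 - sum_a p_a^2)` with `n_l` the number of typed
#' gene copies at the locus.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus` and `mean`
#' @export
gene_diversity <- function(ds, stage = NULL) {
  ds <- .stage_subset(ds, stage)
  af <- allele_frequencies(ds)
  per <- vapply(names(af$freqs), function(l) {
    p <- af$freqs[[l]]; nl <- af$n[[l]]
    if (nl < 2) return(NA_real_)
    nl / (nl - 1) * (1 - sum(p^2))
  }, 1)
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Rarefied allelic richness per locus and multilocus mean
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: `R_S = sum_a [1 - C(N_l - N_la, g) / C(N_l, g)]`.
#'
#' @inheritParams observed_heterozygosity
#' @param g standard gene count (e.g. 74 genes = 37 diploid individuals)
#' @return list with `per_locus`, `mean`, and `g`
#' @export
allelic_richness <- function(ds, stage = NULL, g) {
  ds <- .stage_subset(ds, stage)
  per <- vapply(locus_names(ds), function(l) {
    gc <- c(ds$a1[, l], ds$a2[, l]); gc <- gc[!is.na(gc)]
    N <- length(gc)
    if (g > N) stop("g = ", g, " exceeds typed gene copies (", N,
                    ") at locus ", l)
    cnt <- table(gc)
    sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
  }, 1)
  list(per_locus = per, mean = mean(per), g = g)
}

# Weir-Cockerham within-population variance components for one sample.
# Returns per locus the summed allele components (b, c); f = 1 - Sc/S(b+c).
.wc_single_components <- function(ds) {
  res <- lapply(locus_names(ds), function(l) {
    typed <- !is.na(ds$a1[, l])
    n <- sum(typed)
    if (n < 2) return(c(b = 0, c = 0))
    x1 <- ds$a1[typed, l]; x2 <- ds$a2[typed, l]
    alleles <- unique(c(x1, x2))
    if (length(alleles) < 2) return(c(b = 0, c = 0))
    bs <- 0; cs <- 0
    for (a in alleles) {
      p <- (sum(x1 == a) + sum(x2 == a)) / (2 * n)
      het <- mean((x1 == a) != (x2 == a))
      b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * het)
      bs <- bs + b; cs <- cs + het / 2
    }
    c(b = bs, c = cs)
  })
  do.call(rbind, res)
}

#' Multilocus Weir-Cockerham inbreeding coefficient
#'
#' `f` from within-population variance components, summed over loci before
#' taking the ratio (the standard multilocus estimator).
#'
#' @inheritParams observed_heterozygosity
#' @return list with `f` (multilocus), `per_locus` (named numeric)
#' @export
multilocus_fis <- function(ds, stage = NULL) {
  ds <- .stage_subset(ds, stage)
  if (n_individuals(ds) < 2) stop("need >= 2 individuals")
  comp <- .wc_single_components(ds)
  tot <- colSums(comp)
  if (tot["b"] + tot["c"] == 0) stop("all loci monomorphic; F_IS undefined")
  per <- ifelse(comp[, "b"] + comp[, "c"] > 0,
                1 - comp[, "c"] / (comp[, "b"] + comp[, "c"]), NA_real_)
  names(per) <- locus_names(ds)
  list(f = unname(1 - tot["c"] / (tot["b"] + tot["c"])), per_locus = per)
}

# Weir-Cockerham theta components for two groups at one locus.
.wc_theta_locus <- function(x1a, x2a, x1b, x2b) {
  r <- 2
  alleles <- unique(c(x1a, x2a, x1b, x2b))
  if (length(alleles) < 2) return(c(a = 0, b = 0, c = 0))
  n1 <- length(x1a); n2 <- length(x1b)
  if (n1 < 1 || n2 < 1) return(c(a = 0, b = 0, c = 0))
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  out <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    p1 <- (sum(x1a == al) + sum(x2a == al)) / (2 * n1)
    p2 <- (sum(x1b == al) + sum(x2b == al)) / (2 * n2)
    h1 <- mean((x1a == al) != (x2a == al))
    h2 <- mean((x1b == al) != (x2b == al))
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    out <- out + c(a = a, b = b, c = cc)
  }
  out
}

# theta over selected loci for a two-group split given by logical `grp`.
.wc_theta <- function(ds, grp, loci) {
  comp <- c(a = 0, b = 0, c = 0)
  for (l in loci) {
    t1 <- grp & !is.na(ds$a1[, l]); t2 <- !grp & !is.na(ds$a1[, l])
    if (sum(t1) < 1 || sum(t2) < 1) next
    comp <- comp + .wc_theta_locus(ds$a1[t1, l], ds$a2[t1, l],
                                   ds$a1[t2, l], ds$a2[t2, l])
  }
  tot <- sum(comp)
  if (tot == 0) return(NA_real_)
  unname(comp["a"] / tot)
}

#' Pairwise F_ST between two stages (Weir-Cockerham theta) with permutation test
#'
#' Theta from variance components summed over the selected loci; the p-value
#' is one-sided (proportion of random reassignments of individuals to the two
#' groups with theta at least as large as observed).
#'
#' @param ds a `genotype_dataset`
#' @param stage_a,stage_b the two stage labels
#' @param loci optional locus subset (e.g. the panel with HWE-conformant loci)
#' @param n_perms number of permutations
#' @param rng_seed optional integer seed
#' @return list with `theta`, `p`, `loci`, `n` (group sizes)
#' @export
pairwise_fst_amova <- function(ds, stage_a, stage_b, loci = NULL,
                               n_perms = 10000, rng_seed = NULL) {
  sub <- subset_individuals(ds, stage = c(stage_a, stage_b))
  if (is.null(loci)) loci <- locus_names(sub)
  grp <- sub$info$stage == stage_a
  if (sum(grp) < 2 || sum(!grp) < 2) stop("both stages need >= 2 individuals")
  obs <- .wc_theta(sub, grp, loci)
  if (is.na(obs)) stop("zero total variance; theta undefined")
  perms <- numeric(n_perms)
  with_rng_seed(rng_seed, {
    for (r in seq_len(n_perms)) perms[r] <- .wc_theta(sub, sample(grp), loci)
  })
  perms <- perms[!is.na(perms)]
  list(theta = obs, p = perm_p_geq(obs, perms), loci = loci,
       n = c(sum(grp), sum(!grp)))
}

#' All pairwise F_ST values between stages
#'
#' @inheritParams pairwise_fst_amova
#' @param stages stages to compare (default: all present)
#' @return list of class `fst_matrix` with matrices `theta` and `p`
#' @export
pairwise_fst_matrix <- function(ds, stages = NULL, loci = NULL,
                                n_perms = 10000, rng_seed = NULL) {
  stages <- stages %||% intersect(STAGES, unique(ds$info$stage))
  k <- length(stages)
  th <- matrix(NA_real_, k, k, dimnames = list(stages, stages))
  pv <- th
  seeds <- if (is.null(rng_seed)) rep(list(NULL), k * k) else
    as.list(rng_seed + seq_len(k * k))
  s <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    s <- s + 1
    r <- pairwise_fst_amova(ds, stages[i], stages[j], loci, n_perms, seeds[[s]])
    th[i, j] <- th[j, i] <- r$theta
    pv[i, j] <- pv[j, i] <- r$p
  }
  structure(list(theta = th, p = pv, n_perms = n_perms), class = "fst_matrix")
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' The test statistic is the conditional probability of the genotype array
#' given the allele counts (Levene's formula); the null distribution is built
#' by shuffling the observed gene copies into random diploid pairings, and
#' `p` is the proportion of arrays with conditional probability at most the
#' observed one (rank-based, +1-corrected).
#'
#' @param ds a `genotype_dataset`
#' @param stage optional stage filter
#' @param locus locus name
#' @param n_reps Monte-Carlo replicates
#' @param rng_seed optional integer seed
#' @return list with `p`, `n` (typed individuals), `log_prob_obs`
#' @export
hwe_mc_exact_test <- function(ds, stage = NULL, locus, n_reps = 2000,
                              rng_seed = NULL) {
  ds <- .stage_subset(ds, stage)
  typed <- !is.na(ds$a1[, locus])
  n <- sum(typed)
  if (n < 5) stop("locus ", locus, " typed in < 5 individuals")
  x1 <- ds$a1[typed, locus]; x2 <- ds$a2[typed, locus]
  if (length(unique(c(x1, x2))) < 2)
    return(list(p = 1, n = n, log_prob_obs = 0))
  log_cond_prob <- function(g1, g2) {
    h <- sum(g1 != g2)
    geno <- paste(pmin(g1, g2), pmax(g1, g2))
    copies <- c(g1, g2)
    lfactorial(n) + sum(lfactorial(table(copies))) + h * log(2) -
      lfactorial(2 * n) - sum(lfactorial(table(geno)))
  }
  obs <- log_cond_prob(x1, x2)
  cnt <- 0L
  with_rng_seed(rng_seed, {
    pool <- c(x1, x2)
    for (r in seq_len(n_reps)) {
      s <- sample(pool)
      if (log_cond_prob(s[seq_len(n)], s[n + seq_len(n)]) <= obs + 1e-12)
        cnt <- cnt + 1L
    }
  })
  list(p = (1 + cnt) / (n_reps + 1), n = n, log_prob_obs = obs)
}

#' Genotypic linkage-disequilibrium permutation test for a locus pair
#'
#' The statistic is the log-likelihood-ratio (G) of association between the
#' two loci's genotype classes; the null is built by permuting one locus's
#' genotypes among individuals.
#'
#' @inheritParams hwe_mc_exact_test
#' @param locus_a,locus_b the two locus names
#' @return list with `p`, `G_obs`, `n` (individuals typed at both loci)
#' @export
ld_permutation_test <- function(ds, stage = NULL, locus_a, locus_b,
                                n_reps = 2000, rng_seed = NULL) {
  ds <- .stage_subset(ds, stage)
  typed <- !is.na(ds$a1[, locus_a]) & !is.na(ds$a1[, locus_b])
  if (sum(typed) < 5) stop("fewer than 5 individuals typed at both loci")
  ga <- paste(pmin(ds$a1[typed, locus_a], ds$a2[typed, locus_a]),
              pmax(ds$a1[typed, locus_a], ds$a2[typed, locus_a]))
  gb <- paste(pmin(ds$a1[typed, locus_b], ds$a2[typed, locus_b]),
              pmax(ds$a1[typed, locus_b], ds$a2[typed, locus_b]))
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2)
    stop("both loci must be polymorphic (>= 2 genotype classes)")
  gstat <- function(a, b) {
    tab <- table(a, b)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    idx <- tab > 0
    2 * sum(tab[idx] * log(tab[idx] / e[idx]))
  }
  obs <- gstat(ga, gb)
  perms <- numeric(n_reps)
  with_rng_seed(rng_seed, {
    for (r in seq_len(n_reps)) perms[r] <- gstat(ga, sample(gb))
  })
  list(p = perm_p_geq(obs, perms), G_obs = obs, n = sum(typed))
}

#' Stage-wise diversity summary table
#'
#' One row per stage with observed heterozygosity, gene diversity,
#' Weir-Cockerham F_IS, rarefied allelic richness and the joint-ML
#' null-corrected inbreeding coefficient.
#'
#' @param ds a `genotype_dataset`
#' @param stages stages to summarise (default: all present)
#' @param g standard gene count for rarefaction; default = smallest number of
#'   typed gene copies over loci and stages
#' @param fis_null also compute the null-aware inbreeding coefficient via
#'   [fis_null_joint_ml()] (slower)
#' @return data.frame of class `diversity_summary` with columns `stage`, `n`,
#'   `H_O`, `H_S`, `F_IS`, `R_S`, `F_IS_null`
#' @export
diversity_summary <- function(ds, stages = NULL, g = NULL, fis_null = TRUE) {
  stages <- stages %||% intersect(STAGES, unique(ds$info$stage))
  if (is.null(g)) {
    g <- min(vapply(stages, function(st) {
      sub <- subset_individuals(ds, stage = st)
      min(colSums(!is.na(sub$a1)) * 2)
    }, 1))
  }
  rows <- lapply(stages, function(st) {
    sub <- subset_individuals(ds, stage = st)
    fn <- if (fis_null) fis_null_joint_ml(ds, stage = st)$f else NA_real_
    data.frame(stage = st, n = n_individuals(sub),
               H_O = observed_heterozygosity(sub)$mean,
               H_S = gene_diversity(sub)$mean,
               F_IS = multilocus_fis(sub)$f,
               R_S = allelic_richness(sub, g = g)$mean,
               F_IS_null = fn)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_summary", "data.frame")
  attr(out, "g") <- g
  out
}
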