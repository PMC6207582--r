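# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately use naive loops, not the package's vectorised
# code paths.

# A small hand-specified dataset.  geno: list per individual of
# list(locusname = c(a, b) or NA).
make_ds <- function(geno, stage = "mature", x = NULL, y = NULL,
                    dbh = NULL, cwd_id = NULL, loci = NULL) {
  n <- length(geno)
  loci <- loci %||% unique(unlist(lapply(geno, names)))
  a1 <- a2 <- matrix(NA_integer_, n, length(loci),
                     dimnames = list(NULL, loci))
  for (i in seq_len(n)) for (l in names(geno[[i]])) {
    g <- geno[[i]][[l]]
    if (length(g) == 2 && !anyNA(g)) { a1[i, l] <- g[1]; a2[i, l] <- g[2] }
  }
  stage <- rep_len(stage, n)
  info <- data.frame(id = sprintf("I%02d", seq_len(n)), stage = stage,
                     x = x %||% seq_len(n), y = y %||% rep(0, n),
                     cwd_id = cwd_id %||%
                       ifelse(stage %in% c("seedling", "sapling"), "L1", NA),
                     dbh = dbh %||% ifelse(stage == "mature", 30,
                                    ifelse(stage == "juvenile", 10, NA)),
                     age = NA, stringsAsFactors = FALSE)
  genotype_dataset(info, a1, a2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random HWE dataset drawn from given per-locus frequencies.
random_hwe_ds <- function(n, freqs, stage = "mature", extent = c(100, 100)) {
  loci <- names(freqs)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci),
                     dimnames = list(NULL, loci))
  for (l in loci) {
    p <- freqs[[l]]
    a1[, l] <- as.integer(sample(names(p), n, TRUE, prob = p))
    a2[, l] <- as.integer(sample(names(p), n, TRUE, prob = p))
  }
  stage <- rep_len(stage, n)
  info <- data.frame(id = sprintf("R%04d", seq_len(n)), stage = stage,
                     x = runif(n, 0, extent[1]), y = runif(n, 0, extent[2]),
                     cwd_id = ifelse(stage %in% c("seedling", "sapling"),
                                     "L1", NA),
                     dbh = ifelse(stage == "mature", 30,
                                  ifelse(stage == "juvenile", 10, NA)),
                     age = NA, stringsAsFactors = FALSE)
  genotype_dataset(info, a1, a2)
}

equifreqs <- function(n_loci, k) {
  f <- lapply(seq_len(n_loci), function(i)
    stats::setNames(rep(1 / k, k), 100 + 2 * (seq_len(k) - 1)))
  names(f) <- sprintf("Loc%02d", seq_len(n_loci))
  f
}

# ---- oracles ----------------------------------------------------------------

# Loiselle kinship by direct summation over reference alleles.
bf_loiselle <- function(ds, i, j, ref, bias_correction = TRUE) {
  num <- 0; den <- 0
  for (l in locus_names(ds)) {
    if (!l %in% names(ref$freqs)) next
    p <- ref$freqs[[l]]
    if (length(p) < 2) next
    if (is.na(ds$a1[i, l]) || is.na(ds$a1[j, l])) next
    w <- 0; s <- 0
    for (a in names(p)) {
      dose_i <- (sum(as.character(c(ds$a1[i, l], ds$a2[i, l])) == a)) / 2
      dose_j <- (sum(as.character(c(ds$a1[j, l], ds$a2[j, l])) == a)) / 2
      s <- s + (dose_i - p[[a]]) * (dose_j - p[[a]])
      w <- w + p[[a]] * (1 - p[[a]])
    }
    if (bias_correction && is.finite(ref$n[[l]]))
      s <- s + w / (ref$n[[l]] - 1)
    num <- num + s; den <- den + w
  }
  num / den
}

# Weir-Cockerham single-sample f by explicit per-allele loops.
bf_wc_fis <- function(ds) {
  sb <- 0; sc <- 0
  for (l in locus_names(ds)) {
    typed <- !is.na(ds$a1[, l])
    n <- sum(typed)
    if (n < 2) next
    g1 <- ds$a1[typed, l]; g2 <- ds$a2[typed, l]
    for (a in unique(c(g1, g2))) {
      p <- (sum(g1 == a) + sum(g2 == a)) / (2 * n)
      if (p == 0 || p == 1) next
      hbar <- mean((g1 == a) != (g2 == a))
      sb <- sb + n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
      sc <- sc + hbar / 2
    }
  }
  1 - sc / (sb + sc)
}

# Weir-Cockerham two-sample theta by explicit loops.
bf_theta <- function(ds, grp) {
  sa <- sb <- sc <- 0
  for (l in locus_names(ds)) {
    t1 <- grp & !is.na(ds$a1[, l]); t2 <- !grp & !is.na(ds$a1[, l])
    n1 <- sum(t1); n2 <- sum(t2)
    if (n1 < 1 || n2 < 1) next
    g <- list(list(ds$a1[t1, l], ds$a2[t1, l]),
              list(ds$a1[t2, l], ds$a2[t2, l]))
    alleles <- unique(unlist(g))
    if (length(alleles) < 2) next
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2))
    for (a in alleles) {
      p1 <- (sum(g[[1]][[1]] == a) + sum(g[[1]][[2]] == a)) / (2 * n1)
      p2 <- (sum(g[[2]][[1]] == a) + sum(g[[2]][[2]] == a)) / (2 * n2)
      h1 <- mean((g[[1]][[1]] == a) != (g[[1]][[2]] == a))
      h2 <- mean((g[[2]][[1]] == a) != (g[[2]][[2]] == a))
      pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
      hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
      sa <- sa + nbar / nc * (s2 - 1 / (nbar - 1) *
              (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
      sb <- sb + nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 -
              (2 * nbar - 1) / (4 * nbar) * hbar)
      sc <- sc + hbar / 2
    }
  }
  sa / (sa + sb + sc)
}

# Rarefied richness by exhaustive enumeration of all g-subsets of the gene
# copies at one locus.
bf_richness_enum <- function(gene_copies, g) {
  combs <- utils::combn(length(gene_copies), g)
  mean(apply(combs, 2, function(idx) length(unique(gene_copies[idx]))))
}
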