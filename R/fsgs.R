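# Fine-scale spatial genetic structure: correlograms, the kinship-distance
# regression slope b_F, the Sp statistic, the mean-F_is permutation test,
# cluster kinship summaries and the Evanno delta-K table.

#' Distance-class scheme for correlograms
#'
#' Half-open classes `[lo, hi)` defined by strictly increasing breakpoints in
#' metres.  The default is the 20-class, 10-m scheme from 0 to 200 m.
#'
#' @param breaks numeric breakpoints (metres)
#' @return an object of class `distance_class_scheme`
#' @export
distance_class_scheme <- function(breaks = seq(0, 200, by = 10)) {
  if (length(breaks) < 2 || any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing with >= 2 values")
  structure(list(breaks = as.numeric(breaks)), class = "distance_class_scheme")
}

# Shared engine: observed + permuted class means and regression slopes from a
# fixed kinship matrix.  Permutations shuffle individual locations jointly
# (one permutation of ids applied to the coordinate set), which preserves the
# geometry of the distance matrix under the null that genotypes are
# independent of location.
.fsgs_engine <- function(K, D, breaks, n_perms, rng_seed) {
  n <- nrow(K)
  ut <- upper_pairs(n)
  kv <- K[ut]
  ok <- !is.na(kv)
  kv <- kv[ok]
  nb <- length(breaks) - 1
  class_stats <- function(dv) {
    bin <- findInterval(dv, breaks, rightmost.closed = FALSE)
    bin[bin < 1 | bin > nb | dv >= breaks[nb + 1]] <- NA
    f <- factor(bin, levels = seq_len(nb))
    cnt <- tabulate(f, nbins = nb)
    sums <- vapply(split(kv, f), sum, 1)
    means <- ifelse(cnt > 0, sums / cnt, NA_real_)
    list(means = means, counts = cnt)
  }
  slope <- function(dv) {
    pos <- dv > 0
    if (sum(pos) < 3) return(NA_real_)
    ld <- log(dv[pos])
    if (stats::var(ld) == 0) return(NA_real_)
    stats::cov(kv[pos], ld) / stats::var(ld)
  }
  dv_obs <- D[ut][ok]
  obs_cls <- class_stats(dv_obs)
  obs_b <- slope(dv_obs)
  perm_means <- matrix(NA_real_, n_perms, nb)
  perm_b <- numeric(n_perms)
  with_rng_seed(rng_seed, {
    for (r in seq_len(n_perms)) {
      pm <- sample.int(n)
      dv <- D[pm, pm][ut][ok]
      perm_means[r, ] <- class_stats(dv)$means
      perm_b[r] <- slope(dv)
    }
  })
  list(kv = kv, dv = dv_obs, obs_means = obs_cls$means, counts = obs_cls$counts,
       obs_b = obs_b, perm_means = perm_means, perm_b = perm_b)
}

#' Kinship correlogram with permutation envelope
#'
#' Mean pairwise kinship per distance class, with a permutation null in which
#' individual locations are shuffled jointly among individuals and the class
#' means recomputed.  The envelope is the 2.5/97.5 percentile band of the
#' permuted class means; p-values are two-sided rank-based.
#'
#' @param ds a `genotype_dataset`
#' @param stage optional stage filter (>= 3 individuals required)
#' @param ref reference [allele_freq_table()]; `NULL` = dataset's own
#'   frequencies
#' @param scheme a [distance_class_scheme()]
#' @param n_perms number of location permutations
#' @param bias_correction see [kinship_matrix()]
#' @param rng_seed optional integer for reproducible permutations
#' @return a data.frame of class `fsgs_correlogram` with columns `lo`, `hi`,
#'   `n_pairs`, `mean_fij`, `env_lo`, `env_hi`, `p`; empty classes carry
#'   count 0 and `NA` statistics.
#' @export
fsgs_correlogram <- function(ds, stage = NULL, ref = NULL,
                             scheme = distance_class_scheme(),
                             n_perms = 1000, bias_correction = TRUE,
                             rng_seed = NULL) {
  if (!is.null(stage)) ds <- subset_individuals(ds, stage = stage)
  if (n_individuals(ds) < 3) stop("need >= 3 individuals")
  K <- kinship_matrix(ds, ref, bias_correction)
  D <- pairwise_distances(ds)
  eng <- .fsgs_engine(K, D, scheme$breaks, n_perms, rng_seed)
  nb <- length(scheme$breaks) - 1
  env <- apply(eng$perm_means, 2, stats::quantile,
               probs = c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  p <- vapply(seq_len(nb), function(b) {
    pm <- eng$perm_means[, b]; pm <- pm[!is.na(pm)]
    if (eng$counts[b] == 0 || length(pm) == 0) return(NA_real_)
    perm_p_two(eng$obs_means[b], pm)
  }, 1)
  out <- data.frame(lo = scheme$breaks[-(nb + 1)], hi = scheme$breaks[-1],
                    n_pairs = eng$counts, mean_fij = eng$obs_means,
                    env_lo = env[1, ], env_hi = env[2, ], p = p)
  class(out) <- c("fsgs_correlogram", "data.frame")
  attr(out, "n_perms") <- n_perms
  out
}

#' Regression of pairwise kinship on log distance
#'
#' Ordinary least squares of `F_ij` on `ln(d)` over all pairs with `d > 0`
#' (coincident pairs are excluded: `ln 0` is undefined).  The standard error
#' is a delete-one-locus jackknife of the slope; the p-value is one-sided
#' (observed slope more negative than the location-permutation null).
#'
#' @inheritParams fsgs_correlogram
#' @return list with `b_F`, `se` (jackknife, needs >= 2 loci), `p`,
#'   `n_pairs` (pairs entering the regression)
#' @export
kinship_distance_regression <- function(ds, stage = NULL, ref = NULL,
                                        n_perms = 1000,
                                        bias_correction = TRUE,
                                        rng_seed = NULL) {
  if (!is.null(stage)) ds <- subset_individuals(ds, stage = stage)
  if (is.null(ref)) ref <- allele_frequencies(ds)
  kt <- kinship_matrix(ds, ref, bias_correction, keep_locus_terms = TRUE)
  D <- pairwise_distances(ds)
  n <- nrow(kt$K)
  ut <- upper_pairs(n)
  dv <- D[ut]
  wsum <- kt$wsum[ut]
  pos <- dv > 0 & wsum > 0
  if (sum(pos) < 3) stop("need >= 3 pairs at distance > 0")
  ld <- log(dv[pos])
  if (stats::var(ld) == 0) stop("all pairs at identical distance; slope undefined")
  kfull <- (Reduce(`+`, kt$num)[ut] / wsum)[pos]
  b_obs <- stats::cov(kfull, ld) / stats::var(ld)

  # jackknife over loci
  L <- length(kt$loci)
  if (L < 2) stop("jackknife SE needs >= 2 polymorphic loci")
  tot_num <- Reduce(`+`, kt$num)[ut]
  bj <- vapply(kt$loci, function(l) {
    numl <- kt$num[[l]][ut]          # already zero for pairs untyped at l
    typed <- !is.na(ds$a1[, l])      # a pair contributes w_l iff both typed
    tp <- tcrossprod(typed + 0)[ut]
    wj <- wsum - kt$w[[l]] * tp
    keep <- pos & wj > 0
    kj <- (tot_num - numl)[keep] / wj[keep]
    ldj <- log(dv[keep])
    stats::cov(kj, ldj) / stats::var(ldj)
  }, 1)
  se <- sqrt((L - 1) / L * sum((bj - mean(bj))^2))

  perm_b <- numeric(n_perms)
  kv <- kfull
  with_rng_seed(rng_seed, {
    for (r in seq_len(n_perms)) {
      pm <- sample.int(n)
      dvp <- D[pm, pm][ut]
      keep <- dvp > 0 & wsum > 0
      ldp <- log(dvp[keep])
      kp <- (tot_num[keep] / wsum[keep])
      perm_b[r] <- stats::cov(kp, ldp) / stats::var(ldp)
    }
  })
  list(b_F = b_obs, se = unname(se), p = perm_p_leq(b_obs, perm_b),
       n_pairs = sum(pos))
}

#' Sp statistic of FSGS intensity
#'
#' `Sp = b_F / (F_1 - 1)`, with `b_F` the slope of kinship on log distance
#' and `F_1` the mean kinship in the first distance class.
#'
#' @param b_F regression slope (per ln metre)
#' @param F_1 mean kinship in the first distance class
#' @return Sp (dimensionless)
#' @export
sp_statistic <- function(b_F, F_1) {
  if (any(F_1 == 1)) stop("Sp undefined at F_1 = 1")
  b_F / (F_1 - 1)
}

#' Stage-level FSGS summary: F_1, b_F, jackknife SE, permutation p, Sp
#'
#' Combines the correlogram's first-class mean, the log-distance regression
#' and the Sp statistic, sharing one kinship matrix and one permutation
#' stream.
#'
#' @inheritParams fsgs_correlogram
#' @return list of class `fsgs_summary` with fields `F_1`, `b_F`, `se_bF`,
#'   `p_bF` (one-sided, more negative), `p_F1` (two-sided class test), `Sp`,
#'   `n`, `correlogram`
#' @export
fsgs_summary <- function(ds, stage = NULL, ref = NULL,
                         scheme = distance_class_scheme(),
                         n_perms = 1000, bias_correction = TRUE,
                         rng_seed = NULL) {
  if (!is.null(stage)) ds <- subset_individuals(ds, stage = stage)
  cor <- fsgs_correlogram(ds, NULL, ref, scheme, n_perms, bias_correction,
                          rng_seed)
  reg <- kinship_distance_regression(ds, NULL, ref, n_perms, bias_correction,
                                     rng_seed)
  F_1 <- cor$mean_fij[1]
  out <- list(F_1 = F_1, b_F = reg$b_F, se_bF = reg$se, p_bF = reg$p,
              p_F1 = cor$p[1], Sp = sp_statistic(reg$b_F, F_1),
              n = n_individuals(ds), correlogram = cor)
  class(out) <- "fsgs_summary"
  out
}

#' @export
print.fsgs_summary <- function(x, ...) {
  cat(sprintf("FSGS summary (n = %d):\n", x$n))
  cat(sprintf("  F_1 = %.4f (p = %.4g)\n", x$F_1, x$p_F1))
  cat(sprintf("  b_F = %.4f (SE %.4f, p = %.4g)\n", x$b_F, x$se_bF, x$p_bF))
  cat(sprintf("  Sp  = %.4f\n", x$Sp))
  invisible(x)
}

#' Permutation test of the mean individual inbreeding coefficient
#'
#' The observed statistic is the mean of [individual_fis()] over the stage.
#' The null re-pairs gene copies at random among the stage's individuals,
#' locus by locus (preserving allele counts and missing-data pattern), and
#' recomputes the mean; p is one-sided (observed higher).  Bonferroni
#' adjustment multiplies p by the number of stages tested.
#'
#' @inheritParams fsgs_correlogram
#' @param n_stages_for_bonferroni number of parallel stage tests
#' @return list of class `fis_test` with `mean_fis`, `p`, `p_adj`,
#'   `significant` (at 0.05 after adjustment), `n`
#' @export
mean_fis_test <- function(ds, stage = NULL, ref = NULL, n_perms = 1000,
                          n_stages_for_bonferroni = 1,
                          bias_correction = TRUE, rng_seed = NULL) {
  if (!is.null(stage)) ds <- subset_individuals(ds, stage = stage)
  if (n_individuals(ds) < 2) stop("need >= 2 individuals")
  if (is.null(ref)) ref <- allele_frequencies(ds)
  n <- n_individuals(ds)
  # per-locus prepared pieces
  prep <- list()
  for (l in locus_names(ds)) {
    lk <- .kin_locus(ds, ref, l, bias_correction)
    if (is.null(lk)) next
    prep[[l]] <- lk
  }
  if (length(prep) == 0) stop("no usable loci")
  w_tot <- numeric(n)
  for (lk in prep) w_tot <- w_tot + lk$w * lk$typed
  if (any(w_tot == 0))
    stop("individual F_is undefined for some individuals")

  fis_from <- function(copies1, copies2) {
    # copies*: per locus, integer allele index (into ref alleles) or NA
    num_tot <- numeric(n)
    for (li in seq_along(prep)) {
      lk <- prep[[li]]
      p <- lk$p; sump2 <- sum(p^2)
      x1 <- copies1[[li]]; x2 <- copies2[[li]]
      p1 <- ifelse(is.na(x1), 0, p[x1])
      p2 <- ifelse(is.na(x2), 0, p[x2])
      eq <- as.numeric(!is.na(x1) & !is.na(x2) & x1 == x2)
      num <- (eq - p1 - p2 + sump2 + lk$cc) * lk$typed
      num_tot <- num_tot + num
    }
    mean(num_tot / w_tot)
  }
  obs1 <- lapply(prep, function(lk) lk$x1)
  obs2 <- lapply(prep, function(lk) lk$x2)
  obs <- fis_from(obs1, obs2)

  perms <- numeric(n_perms)
  with_rng_seed(rng_seed, {
    for (r in seq_len(n_perms)) {
      c1 <- obs1; c2 <- obs2
      for (li in seq_along(prep)) {
        typed <- prep[[li]]$typed
        pool <- c(obs1[[li]][typed], obs2[[li]][typed])
        pool <- sample(pool)
        t2 <- sum(typed)
        c1[[li]][typed] <- pool[seq_len(t2)]
        c2[[li]][typed] <- pool[t2 + seq_len(t2)]
      }
      perms[r] <- fis_from(c1, c2)
    }
  })
  p <- perm_p_geq(obs, perms)
  p_adj <- min(1, p * n_stages_for_bonferroni)
  structure(list(mean_fis = obs, p = p, p_adj = p_adj,
                 significant = p_adj < 0.05, n = n),
            class = "fis_test")
}

#' Mean kinship among members of an inferred genetic cluster
#'
#' Selects individuals whose membership probability for one cluster exceeds a
#' threshold (strict inequality) and summarises the pairwise kinship among
#' them.
#'
#' @param ds a `genotype_dataset`
#' @param ref reference [allele_freq_table()]
#' @param q_matrix numeric matrix (individuals x clusters) of membership
#'   probabilities, rownames = ids covering the dataset
#' @param cluster cluster column (index or name)
#' @param threshold membership cut-off; members satisfy `Q > threshold`
#' @param stage optional stage filter applied before thresholding
#' @param bias_correction see [kinship_matrix()]
#' @return list with `members` (ids), `n_members`, `n_pairs`, `mean_fij`
#' @export
cluster_kinship_summary <- function(ds, ref, q_matrix, cluster,
                                    threshold = 0.9, stage = NULL,
                                    bias_correction = TRUE) {
  if (!is.null(stage)) ds <- subset_individuals(ds, stage = stage)
  if (is.null(rownames(q_matrix))) stop("q_matrix needs id rownames")
  bad <- abs(rowSums(q_matrix) - 1) > 1e-6
  if (any(bad)) stop("q_matrix rows must sum to 1")
  m <- match(ds$info$id, rownames(q_matrix))
  if (anyNA(m)) stop("q_matrix does not cover all individuals")
  q <- q_matrix[m, cluster]
  members <- which(q > threshold)
  if (length(members) < 2)
    stop("fewer than 2 individuals exceed the membership threshold")
  sub <- subset_individuals(ds, members)
  K <- kinship_matrix(sub, ref, bias_correction)
  kv <- K[upper_pairs(nrow(K))]
  list(members = sub$info$id, n_members = length(members),
       n_pairs = choose(length(members), 2),
       mean_fij = mean(kv, na.rm = TRUE))
}

#' Read a cluster membership (Q) matrix
#'
#' Whitespace-delimited per-individual membership table in the de-facto
#' layout of Bayesian clustering output: either plain `id q1 ... qk` columns,
#' or the indented form `row id (miss) pop : q1 ... qk` where everything
#' before a colon is metadata.
#'
#' @param path file path
#' @return numeric matrix with id rownames; rows sum to 1 (checked to 1e-6)
#' @export
read_structure_q <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[trimws(lines) != ""])
  parse1 <- function(ln) {
    if (grepl(":", ln, fixed = TRUE)) {
      halves <- strsplit(ln, ":", fixed = TRUE)[[1]]
      meta <- strsplit(trimws(halves[1]), "\\s+")[[1]]
      id <- meta[2] %||% meta[1]
      q <- as.numeric(strsplit(trimws(halves[2]), "\\s+")[[1]])
    } else {
      parts <- strsplit(ln, "\\s+")[[1]]
      id <- parts[1]
      q <- as.numeric(parts[-1])
    }
    list(id = id, q = q)
  }
  rows <- lapply(lines, parse1)
  k <- unique(vapply(rows, function(r) length(r$q), 1L))
  if (length(k) != 1) stop("inconsistent number of clusters across rows")
  q <- do.call(rbind, lapply(rows, `[[`, "q"))
  rownames(q) <- vapply(rows, `[[`, "", "id")
  if (any(abs(rowSums(q) - 1) > 1e-6)) stop("Q rows must sum to 1 (tol 1e-6)")
  q
}

#' Evanno delta-K from cluster-run log-probabilities
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))` with the
#' sample standard deviation over runs; undefined at the endpoints and where
#' `sd = 0` (flagged `NA`).
#'
#' @param runs data.frame with columns `K`, `run`, `lnP`
#' @return data.frame with `K`, `n_runs`, `mean_lnP`, `sd_lnP`, `delta_K`
#' @export
evanno_delta_k <- function(runs) {
  if (!all(c("K", "lnP") %in% names(runs))) stop("runs needs columns K, lnP")
  ks <- sort(unique(runs$K))
  if (length(ks) < 3) stop("need >= 3 distinct K for delta-K")
  if (any(diff(ks) != 1)) stop("K values must be contiguous")
  agg <- do.call(rbind, lapply(ks, function(k) {
    v <- runs$lnP[runs$K == k]
    if (length(v) < 2) stop("need >= 2 runs per K (K = ", k, ")")
    data.frame(K = k, n_runs = length(v), mean_lnP = mean(v),
               sd_lnP = stats::sd(v))
  }))
  dk <- rep(NA_real_, nrow(agg))
  for (i in seq(2, nrow(agg) - 1)) {
    s <- agg$sd_lnP[i]
    if (s > 0)
      dk[i] <- abs(agg$mean_lnP[i + 1] - 2 * agg$mean_lnP[i] +
                     agg$mean_lnP[i - 1]) / s
  }
  agg$delta_K <- dk
  agg
}
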