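# Null-allele frequency estimation (EM) and the joint maximum-likelihood
# inbreeding coefficient with per-locus null alleles.
#
# Model per locus: visible alleles a with frequencies p_a, a null allele with
# frequency rho (sum p_a + rho = 1), inbreeding coefficient f, and a
# whole-locus amplification-failure rate beta.  Observed classes:
#   het a/b        (1-beta) * 2 p_a p_b (1-f)
#   hom a/a        (1-beta) * [p_a^2 (1-f) + f p_a + 2 p_a rho (1-f)]
#   missing        beta + (1-beta) * [rho^2 (1-f) + f rho]
# An a/null heterozygote reads as an a/a homozygote; a null homozygote reads
# as missing, indistinguishable from amplification failure except through the
# homozygote-excess signal that identifies rho.

# Genotype class counts for one locus in one subset.
.locus_counts <- function(ds, locus) {
  x1 <- ds$a1[, locus]; x2 <- ds$a2[, locus]
  typed <- !is.na(x1)
  list(het = table(paste(pmin(x1[typed], x2[typed]),
                         pmax(x1[typed], x2[typed]))[x1[typed] != x2[typed]]),
       hom = table(x1[typed][x1[typed] == x2[typed]]),
       n_miss = sum(!typed), n = length(x1))
}

# EM for (p, rho, beta) at fixed f.  Gene counting: an identical-by-descent
# homozygote contributes one independent gene copy, an outbred genotype two;
# failures contribute nothing.  Returns the converged parameters and the
# observed-data log-likelihood.
.null_em <- function(counts, f = 0, tol = 1e-8, max_iter = 10000,
                     est_beta = TRUE) {
  het <- counts$het; hom <- counts$hom
  hom_al <- as.character(names(hom))
  het_al <- strsplit(as.character(names(het)), " ")
  alleles <- sort(unique(c(hom_al, unlist(het_al))))
  A <- length(alleles)
  if (A < 1) stop("locus has no typed genotypes")
  n <- counts$n
  # init: raw visible frequencies, small rho and beta
  cnt0 <- stats::setNames(numeric(A), alleles)
  for (i in seq_along(het)) {
    al <- het_al[[i]]
    cnt0[al[1]] <- cnt0[al[1]] + het[i]; cnt0[al[2]] <- cnt0[al[2]] + het[i]
  }
  cnt0[hom_al] <- cnt0[hom_al] + 2 * hom
  p <- as.numeric(cnt0) / sum(cnt0) * 0.95
  rho <- 0.05; beta <- if (est_beta) 0.02 else 0
  names(p) <- alleles
  loglik <- function(p, rho, beta) {
    ll <- 0
    for (i in seq_along(het)) {
      al <- het_al[[i]]
      ll <- ll + het[i] * log((1 - beta) * 2 * p[al[1]] * p[al[2]] * (1 - f))
    }
    for (a in hom_al) {
      pa <- p[a]
      ll <- ll + hom[a] * log((1 - beta) *
        (pa^2 * (1 - f) + f * pa + 2 * pa * rho * (1 - f)))
    }
    if (counts$n_miss > 0)
      ll <- ll + counts$n_miss * log(beta + (1 - beta) *
        (rho^2 * (1 - f) + f * rho))
    unname(ll)
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    gene <- stats::setNames(numeric(A), alleles); gnull <- 0; nfail <- 0
    # hets: always outbred a/b
    for (i in seq_along(het)) {
      al <- het_al[[i]]
      gene[al[1]] <- gene[al[1]] + het[i]
      gene[al[2]] <- gene[al[2]] + het[i]
    }
    # observed homozygotes: outbred aa / ibd aa / a-null
    for (a in hom_al) {
      pa <- p[a]
      w <- c(pa^2 * (1 - f), f * pa, 2 * pa * rho * (1 - f))
      if (sum(w) <= 0) next
      w <- w / sum(w)
      gene[a] <- gene[a] + hom[a] * (2 * w[1] + 1 * w[2] + 1 * w[3])
      gnull <- gnull + hom[a] * w[3]
    }
    # missing: failure / outbred null-null / ibd null
    if (counts$n_miss > 0) {
      w <- c(beta, (1 - beta) * rho^2 * (1 - f), (1 - beta) * f * rho)
      w <- w / sum(w)
      nfail <- counts$n_miss * w[1]
      gnull <- gnull + counts$n_miss * (2 * w[2] + 1 * w[3])
    }
    tot <- sum(gene) + gnull
    p_new <- gene / tot
    rho_new <- gnull / tot
    beta_new <- if (est_beta) nfail / n else 0
    delta <- max(abs(c(p_new - p, rho_new - rho, beta_new - beta)))
    p <- p_new; rho <- unname(rho_new); beta <- unname(beta_new)
    if (delta < tol) break
    if (it == max_iter)
      stop("null-allele EM failed to converge in ", max_iter, " iterations")
  }
  list(p = p, rho = rho, beta = beta, loglik = loglik(p, rho, beta),
       n_iter = it)
}

#' EM estimate of the null-allele frequency at one locus
#'
#' Expectation-maximisation over visible-allele frequencies, the null-allele
#' frequency and a whole-locus failure rate, under Hardy-Weinberg
#' proportions.  Observed homozygotes are modelled as a mixture of true
#' homozygotes and visible/null heterozygotes; observed missing genotypes mix
#' null homozygotes and amplification failures.
#'
#' @param ds a `genotype_dataset`
#' @param stage optional stage filter
#' @param locus locus name (must be polymorphic)
#' @param tol convergence tolerance on parameter change
#' @param max_iter iteration cap (error on non-convergence)
#' @return list with `null_freq`, `failure_rate`, `freqs` (visible alleles),
#'   `loglik`, `n_iter`
#' @export
null_allele_em <- function(ds, stage = NULL, locus, tol = 1e-8,
                           max_iter = 10000) {
  ds <- .stage_subset(ds, stage)
  counts <- .locus_counts(ds, locus)
  if (length(counts$het) + length(counts$hom) == 0)
    stop("locus ", locus, " has no typed genotypes")
  if (length(unique(c(as.character(names(counts$hom)),
                      unlist(strsplit(as.character(names(counts$het)),
                                      " "))))) < 2)
    stop("locus ", locus, " is monomorphic")
  fit <- .null_em(counts, f = 0, tol = tol, max_iter = max_iter)
  list(null_freq = fit$rho, failure_rate = fit$beta, freqs = fit$p,
       loglik = fit$loglik, n_iter = fit$n_iter)
}

#' Joint ML estimate of inbreeding with per-locus null alleles
#'
#' Profile likelihood: for a shared inbreeding coefficient `f` across loci,
#' each locus's visible-allele frequencies and null frequency are maximised
#' by EM; the total log-likelihood is then maximised over `f` by a coarse
#' grid followed by golden-section refinement.  Unlike [null_allele_em()],
#' the joint model sets the amplification-failure rate to zero — a free
#' per-locus failure rate would make `f` and the null frequencies jointly
#' unidentifiable, because nulls and inbreeding inflate homozygote classes
#' in the same allele-frequency-proportional way and only the missing class
#' separates them.  This is a point-estimate approximation of Bayesian
#' null-aware inbreeding estimators.
#'
#' @param ds a `genotype_dataset`
#' @param stage optional stage filter
#' @param f_grid coarse grid for the profile search
#' @param tol EM tolerance
#' @return list with `f`, `null_freqs` (per locus), `loglik`, `boundary`
#'   (TRUE if the estimate sits on the edge of the searched interval)
#' @export
fis_null_joint_ml <- function(ds, stage = NULL,
                              f_grid = seq(0, 0.9, by = 0.05), tol = 1e-8) {
  ds <- .stage_subset(ds, stage)
  if (ncol(ds$a1) < 2) stop("need >= 2 loci")
  counts <- lapply(locus_names(ds), function(l) .locus_counts(ds, l))
  names(counts) <- locus_names(ds)
  poly <- vapply(counts, function(ct)
    length(unique(c(names(ct$hom), unlist(strsplit(names(ct$het), " "))))) >= 2,
    TRUE)
  counts <- counts[poly]
  if (length(counts) == 0) stop("no polymorphic loci")
  prof <- function(f) sum(vapply(counts, function(ct)
    .null_em(ct, f = f, tol = tol, est_beta = FALSE)$loglik, 1))
  ll <- vapply(f_grid, prof, 1)
  i <- which.max(ll)
  lo <- f_grid[max(1, i - 1)]; hi <- f_grid[min(length(f_grid), i + 1)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-4)
  f_hat <- opt$maximum
  fits <- lapply(counts, function(ct)
    .null_em(ct, f = f_hat, tol = tol, est_beta = FALSE))
  nulls <- vapply(fits, `[[`, 1, "rho")
  boundary <- f_hat <= min(f_grid) + 1e-3 || f_hat >= max(f_grid) - 1e-3
  list(f = f_hat, null_freqs = nulls, loglik = opt$objective,
       boundary = boundary)
}
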