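# Loiselle kinship coefficient, individual inbreeding, and the augmented
# reference population.
#
# F_ij = (Q_ij - Q_m) / (1 - Q_m): identity-in-state between genes of i and j,
# relative to the mean identity of the reference gene pool.  The estimator per
# locus is
#   F_ij(l) = [ sum_a (p_ia - p_a)(p_ja - p_a) + c_l ] / sum_a p_a (1 - p_a)
# with p_ia in {0, 1/2, 1} the dose of allele a in i, p_a the reference
# frequency, and c_l = sum_a p_a (1 - p_a) / (n_l - 1) a finite-reference bias
# correction (n_l reference gene copies).  Multilocus values average locus
# values weighted by w_l = sum_a p_a (1 - p_a).

#' Reference allele frequencies from mature trees, augmented by cohort-unique alleles
#'
#' Builds the reference gene pool for kinship estimation: allele counts from
#' the mature stage, plus one gene copy of every allele observed only in the
#' younger (adolescent) cohort, so that rare immigrant alleles carry a small
#' positive reference frequency instead of breaking the estimator.
#'
#' @param mature `genotype_dataset` of the reference (mature) individuals
#' @param adolescents `genotype_dataset` of the younger cohorts whose unique
#'   alleles are to be folded in (may be `NULL` for no augmentation)
#' @return an [allele_freq_table()]; gene counts grow by one per unique allele
#' @export
build_reference_frequencies <- function(mature, adolescents = NULL) {
  if (n_individuals(mature) == 0) stop("mature dataset is empty")
  freqs <- list(); n <- numeric(0)
  for (l in locus_names(mature)) {
    g <- c(mature$a1[, l], mature$a2[, l]); g <- g[!is.na(g)]
    if (length(g) == 0) { warning("locus ", l, " untyped in mature; excluded"); next }
    cnt <- table(g)
    counts <- stats::setNames(as.numeric(cnt), names(cnt))
    if (!is.null(adolescents) && l %in% locus_names(adolescents)) {
      ga <- c(adolescents$a1[, l], adolescents$a2[, l]); ga <- ga[!is.na(ga)]
      uniq <- setdiff(unique(as.character(ga)), names(counts))
      for (u in uniq) counts[u] <- 1
    }
    freqs[[l]] <- counts / sum(counts)
    n[[l]] <- sum(counts)
  }
  allele_freq_table(freqs, n)
}

# Per-locus building blocks shared by the pairwise and the within-individual
# estimator.  Returns NULL for loci monomorphic in (or absent from) the ref.
.kin_locus <- function(ds, ref, l, bias_correction) {
  if (!l %in% names(ref$freqs)) return(NULL)
  p <- ref$freqs[[l]]
  if (length(p) < 2) return(NULL)
  w <- sum(p * (1 - p))
  nl <- ref$n[[l]]
  cc <- if (bias_correction && is.finite(nl)) w / (nl - 1) else 0
  alleles <- names(p)
  x1 <- match(as.character(ds$a1[, l]), alleles)   # NA if missing or not in ref
  x2 <- match(as.character(ds$a2[, l]), alleles)
  typed <- !is.na(ds$a1[, l])
  list(p = p, w = w, cc = cc, x1 = x1, x2 = x2, typed = typed)
}

# Dose matrix (n x A) for a prepared locus; rows of untyped individuals are 0.
.kin_dose <- function(lk) {
  n <- length(lk$typed); A <- length(lk$p)
  X <- matrix(0, n, A)
  idx1 <- which(lk$typed & !is.na(lk$x1))
  idx2 <- which(lk$typed & !is.na(lk$x2))
  X[cbind(idx1, lk$x1[idx1])] <- X[cbind(idx1, lk$x1[idx1])] + 0.5
  X[cbind(idx2, lk$x2[idx2])] <- X[cbind(idx2, lk$x2[idx2])] + 0.5
  X
}

#' Pairwise Loiselle kinship matrix
#'
#' Multilocus kinship between every pair of individuals, relative to a
#' reference allele-frequency table.  Loci missing in either member of a pair
#' are dropped from that pair (pairwise deletion); loci monomorphic in the
#' reference are excluded throughout.
#'
#' @param ds a `genotype_dataset`
#' @param ref an [allele_freq_table()]; `NULL` uses the dataset's own
#'   frequencies (the "no external reference" mode of the thinning analysis)
#' @param bias_correction add the finite-reference term
#'   `sum p(1-p)/(n_l - 1)` per locus (on by default, matching standard
#'   kinship software); it vanishes for an infinite (known) reference.
#' @param keep_locus_terms also return per-locus numerator matrices and
#'   weights (needed for the delete-one-locus jackknife of the regression
#'   slope).
#' @return an n x n symmetric matrix (diagonal `NA`); pairs with no shared
#'   typed locus are `NA`.  With `keep_locus_terms`, a list
#'   `(K, num, wsum, loci, w)` where `num` is n x n x L and `wsum` the n x n
#'   matrix of summed weights.
#' @export
kinship_matrix <- function(ds, ref = NULL, bias_correction = TRUE,
                           keep_locus_terms = FALSE) {
  if (is.null(ref)) ref <- allele_frequencies(ds)
  n <- n_individuals(ds)
  loci <- locus_names(ds)
  num_tot <- matrix(0, n, n); w_tot <- matrix(0, n, n)
  num_l <- if (keep_locus_terms) list() else NULL
  used <- character(0)
  for (l in loci) {
    lk <- .kin_locus(ds, ref, l, bias_correction)
    if (is.null(lk)) next
    X <- .kin_dose(lk)
    C <- X - rep(lk$p, each = n)
    C[!lk$typed, ] <- 0
    num <- tcrossprod(C)
    tp <- tcrossprod(lk$typed + 0)        # 1 where both typed
    num <- (num + lk$cc) * tp
    num_tot <- num_tot + num
    w_tot <- w_tot + lk$w * tp
    if (keep_locus_terms) num_l[[l]] <- num
    used <- c(used, l)
  }
  if (length(used) == 0) stop("no polymorphic reference loci shared with dataset")
  K <- num_tot / w_tot
  K[w_tot == 0] <- NA
  diag(K) <- NA
  dimnames(K) <- list(ds$info$id, ds$info$id)
  if (!keep_locus_terms) return(K)
  w <- vapply(used, function(l) sum(ref$freqs[[l]] * (1 - ref$freqs[[l]])), 1)
  list(K = K, num = num_l, wsum = w_tot, loci = used, w = w)
}

#' Loiselle kinship between two individuals
#'
#' @param ds a `genotype_dataset`
#' @param i,j ids or row indices of the two individuals (`i == j` gives the
#'   self-comparison of dose vectors, not the inbreeding coefficient — see
#'   [individual_fis()])
#' @inheritParams kinship_matrix
#' @return multilocus `F_ij`
#' @export
loiselle_kinship <- function(ds, i, j, ref = NULL, bias_correction = TRUE) {
  if (is.character(i)) i <- match(i, ds$info$id)
  if (is.character(j)) j <- match(j, ds$info$id)
  if (is.null(ref)) ref <- allele_frequencies(ds)
  num <- 0; wsum <- 0
  for (l in locus_names(ds)) {
    lk <- .kin_locus(ds, ref, l, bias_correction)
    if (is.null(lk) || !lk$typed[i] || !lk$typed[j]) next
    X <- .kin_dose(lk)
    num <- num + sum((X[i, ] - lk$p) * (X[j, ] - lk$p)) + lk$cc
    wsum <- wsum + lk$w
  }
  if (wsum == 0) stop("individuals share no typed polymorphic locus")
  num / wsum
}

#' Individual inbreeding coefficients (kinship between genes within individuals)
#'
#' The same estimator as [loiselle_kinship()] with the individual's two gene
#' copies as the two gene samples: per locus the numerator is
#' `1{a1 == a2} - p_{a1} - p_{a2} + sum_a p_a^2 + c_l` (alleles absent from
#' the reference contribute frequency 0), weighted across loci by
#' `w_l = sum_a p_a (1 - p_a)`.
#'
#' @inheritParams kinship_matrix
#' @return named numeric vector of `F_is`, one per individual
#' @export
individual_fis <- function(ds, ref = NULL, bias_correction = TRUE) {
  if (is.null(ref)) ref <- allele_frequencies(ds)
  n <- n_individuals(ds)
  num_tot <- numeric(n); w_tot <- numeric(n)
  for (l in locus_names(ds)) {
    lk <- .kin_locus(ds, ref, l, bias_correction)
    if (is.null(lk)) next
    p <- lk$p; sump2 <- sum(p^2)
    p1 <- ifelse(is.na(lk$x1), 0, p[lk$x1])
    p2 <- ifelse(is.na(lk$x2), 0, p[lk$x2])
    eq <- as.numeric(!is.na(lk$x1) & !is.na(lk$x2) & lk$x1 == lk$x2)
    num <- eq - p1 - p2 + sump2 + lk$cc
    num[!lk$typed] <- 0
    num_tot <- num_tot + num * lk$typed
    w_tot <- w_tot + lk$w * lk$typed
  }
  if (any(w_tot == 0))
    stop("individual F_is undefined (no typed polymorphic locus) for: ",
         paste(utils::head(ds$info$id[w_tot == 0], 5), collapse = ", "))
  stats::setNames(num_tot / w_tot, ds$info$id)
}
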