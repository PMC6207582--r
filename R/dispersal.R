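# Exponential-power dispersal kernels and the neighborhood (parentage
# mixture) model: maximum-likelihood estimation of seed and pollen kernels,
# immigration rates and a dbh fecundity effect from offspring genotypes.

#' Exponential-power dispersal kernel
#'
#' 2-D density `P(r) = b / (2 pi a^2 Gamma(2/b)) * exp(-(r/a)^b)`; `b = 2` is
#' the Gaussian form, `b < 1` fat-tailed.
#'
#' @param a scale parameter (metres), > 0
#' @param b shape parameter, > 0
#' @return object of class `dispersal_kernel`
#' @export
dispersal_kernel <- function(a, b) {
  if (a <= 0 || b <= 0) stop("kernel parameters must satisfy a > 0, b > 0")
  structure(list(a = a, b = b), class = "dispersal_kernel")
}

#' Exponential-power kernel density
#'
#' Computed in log space via `lgamma` for numerical stability.
#'
#' @param r distance(s) in metres, >= 0
#' @param a scale (metres) or a [dispersal_kernel()]
#' @param b shape (ignored when `a` is a kernel)
#' @return density per square metre
#' @export
exp_power_pdf <- function(r, a, b = NULL) {
  if (inherits(a, "dispersal_kernel")) { b <- a$b; a <- a$a }
  if (a <= 0 || b <= 0) stop("kernel parameters must satisfy a > 0, b > 0")
  if (any(r < 0)) stop("r must be >= 0")
  exp(log(b) - log(2 * pi) - 2 * log(a) - lgamma(2 / b) - (r / a)^b)
}

#' Mean dispersal distance of an exponential-power kernel
#'
#' Closed form `d = a * Gamma(3/b) / Gamma(2/b)`, evaluated with log-gamma so
#' extreme shapes stay finite.
#'
#' @inheritParams exp_power_pdf
#' @return mean distance in metres
#' @export
mean_dispersal_distance <- function(a, b = NULL) {
  if (inherits(a, "dispersal_kernel")) { b <- a$b; a <- a$a }
  if (a <= 0 || b <= 0) stop("kernel parameters must satisfy a > 0, b > 0")
  a * exp(lgamma(3 / b) - lgamma(2 / b))
}

# ---- genotype transition machinery ------------------------------------------

# Gamete distribution matrix (n_parents x (A+1)) for one locus; the last
# column is the null allele.  Observed heterozygotes transmit each visible
# allele with prob 1/2.  An observed a/a homozygote is a mixture of true a/a
# (posterior pi = p_a / (p_a + 2 rho)) and a/null; an untyped parent
# transmits a population gamete.
.gamete_matrix <- function(a1, a2, p_vis, rho) {
  alleles <- names(p_vis)
  A <- length(alleles)
  n <- length(a1)
  G <- matrix(0, n, A + 1, dimnames = list(NULL, c(alleles, ".null")))
  x1 <- match(as.character(a1), alleles)
  x2 <- match(as.character(a2), alleles)
  typed <- !is.na(a1)
  pop <- c(p_vis, rho); pop <- pop / sum(pop)
  for (i in seq_len(n)) {
    if (!typed[i]) { G[i, ] <- pop; next }
    if (is.na(x1[i]) || is.na(x2[i])) { G[i, ] <- pop; next }  # allele not in table
    if (x1[i] != x2[i]) {
      G[i, x1[i]] <- 0.5; G[i, x2[i]] <- 0.5
    } else {
      pa <- p_vis[x1[i]]
      pi_true <- if (pa + 2 * rho > 0) pa / (pa + 2 * rho) else 1
      G[i, x1[i]] <- pi_true + (1 - pi_true) / 2
      G[i, A + 1] <- (1 - pi_true) / 2
    }
  }
  G
}

# Probability of an OBSERVED offspring genotype class at one locus given two
# gamete probability vectors (mother, father), marginalising over null
# masking: an observed a/a may be true a/a or a/null.
# u, v: indices into the gamete vector's visible alleles (v = NA for hom).
.obs_class_prob <- function(gm, gf, u, v, null_col) {
  if (!is.na(v) && u != v)
    gm[u] * gf[v] + gm[v] * gf[u]
  else
    gm[u] * gf[u] + gm[u] * gf[null_col] + gm[null_col] * gf[u]
}

#' Precompute genotype transition tables for the neighborhood model
#'
#' Heavy, parameter-independent part of the likelihood: per offspring, the
#' Mendelian probability of its observed multilocus genotype for every
#' (mother, father) pair of mature trees, for every mother with an immigrant
#' father, and under a fully immigrant origin.  Null-allele masking is
#' marginalised per locus using `null_freqs`.
#'
#' @param offspring,mature `genotype_dataset`s (same loci)
#' @param background [allele_freq_table()] for immigrant gametes; default =
#'   mature frequencies augmented by offspring-unique alleles
#' @param null_freqs named per-locus null-allele frequencies (default: the
#'   dataset's `null_freq`, with `NA` treated as 0)
#' @return an opaque list consumed by [nm_offspring_loglik()] and
#'   [fit_neighborhood_model()]
#' @export
nm_precompute <- function(offspring, mature, background = NULL,
                          null_freqs = NULL) {
  loci <- intersect(locus_names(offspring), locus_names(mature))
  if (length(loci) == 0) stop("no shared loci")
  if (is.null(background))
    background <- build_reference_frequencies(mature, offspring)
  if (is.null(null_freqs)) {
    null_freqs <- mature$null_freq
    null_freqs[is.na(null_freqs)] <- 0
  }
  J <- n_individuals(mature); O <- n_individuals(offspring)
  Tjk <- array(1, dim = c(J, J, O))
  Tbg <- matrix(1, J, O)    # local mother j, immigrant father
  Bg <- rep(1, O)           # fully immigrant
  for (l in loci) {
    if (!l %in% names(background$freqs)) next
    pb <- background$freqs[[l]]
    rho <- unname(null_freqs[l] %||% 0); if (is.na(rho)) rho <- 0
    p_vis <- pb * (1 - rho)
    G <- .gamete_matrix(mature$a1[, l], mature$a2[, l], p_vis, rho)
    nullc <- ncol(G)
    bg <- c(p_vis, rho); bg <- bg / sum(bg)
    alleles <- names(p_vis)
    o1 <- match(as.character(offspring$a1[, l]), alleles)
    o2 <- match(as.character(offspring$a2[, l]), alleles)
    typed <- !is.na(offspring$a1[, l])
    for (o in seq_len(O)) {
      if (!typed[o]) next                       # missing locus skipped
      u <- o1[o]; v <- o2[o]
      if (is.na(u) || is.na(v)) next            # allele outside table: skip
      if (u != v) {
        Tl <- outer(G[, u], G[, v]) + outer(G[, v], G[, u])
        tb <- G[, u] * bg[v] + G[, v] * bg[u]
        bb <- 2 * bg[u] * bg[v]
      } else {
        Tl <- outer(G[, u], G[, u] + G[, nullc]) + outer(G[, nullc], G[, u])
        tb <- G[, u] * (bg[u] + bg[nullc]) + G[, nullc] * bg[u]
        bb <- bg[u]^2 + 2 * bg[u] * bg[nullc]
      }
      Tjk[, , o] <- Tjk[, , o] * Tl
      Tbg[, o] <- Tbg[, o] * tb
      Bg[o] <- Bg[o] * bb
    }
  }
  d_om <- outer(seq_len(O), seq_len(J), function(o, j) {
    sqrt((offspring$info$x[o] - mature$info$x[j])^2 +
           (offspring$info$y[o] - mature$info$y[j])^2)
  })
  d_mm <- pairwise_distances(mature)
  dbh <- mature$info$dbh
  if (all(is.na(dbh))) stop("mature trees need dbh for the fecundity term")
  z <- as.numeric(scale(dbh))
  z[is.na(z)] <- 0
  # flat (J*J) x O layout (row j + (k-1)J) for the vectorised father sum
  Tmat <- matrix(Tjk, J * J, O)
  list(Tmat = Tmat, Tbg = Tbg, Bg = Bg, d_om = d_om, d_mm = d_mm, z = z,
       group = rep(seq_len(J), times = J), J = J, O = O, loci = loci)
}

#' Neighborhood-model log-likelihood of offspring genotypes
#'
#' Per offspring `o`:
#' `L_o = m_s B(g_o) + (1 - m_s) sum_j psi_j [ m_p T(g_o | g_j, bg) +
#' (1 - m_p) sum_{k != j} phi_jk T(g_o | g_j, g_k) ]`
#' with mother weights `psi_j` proportional to `exp(gamma z_j) P_s(d_oj)`
#' over all mature trees and father weights `phi_jk` proportional to
#' `exp(gamma z_k) P_p(d_jk)` over `k != j` (the zero-selfing constraint).
#' `z` is standardised dbh.
#'
#' @inheritParams nm_precompute
#' @param params list with `m_s`, `m_p`, `a_s`, `b_s`, `a_p`, `b_p`, `gamma`
#' @param precomp optional result of [nm_precompute()] (computed if missing)
#' @return total log-likelihood; attribute `zero_lik` lists offspring with
#'   zero likelihood (contributing `-Inf`)
#' @export
nm_offspring_loglik <- function(offspring, mature, params, background = NULL,
                                null_freqs = NULL, precomp = NULL) {
  pc <- precomp %||% nm_precompute(offspring, mature, background, null_freqs)
  .nm_loglik(pc, params)
}

.nm_loglik <- function(pc, params) {
  m_s <- params$m_s; m_p <- params$m_p; gam <- params$gamma
  fec <- exp(gam * pc$z)
  Ps <- exp_power_pdf(pc$d_om, params$a_s, params$b_s)  # O x J
  psi <- sweep(Ps, 2, fec, `*`)
  psi <- psi / rowSums(psi)
  Pp <- exp_power_pdf(pc$d_mm, params$a_p, params$b_p)  # J x J
  W <- sweep(Pp, 2, fec, `*`)
  diag(W) <- 0
  W <- W / rowSums(W)                                   # phi, row = mother j
  # father-integrated transition: FT[j, o] = sum_k phi_jk T[j, k, o];
  # the column-recycled product exploits the (j + (k-1)J, o) flat layout
  FT <- rowsum(pc$Tmat * as.vector(W), pc$group)
  inner <- m_p * pc$Tbg + (1 - m_p) * FT                # J x O
  Lo <- m_s * pc$Bg + (1 - m_s) * rowSums(psi * t(inner))
  zero <- which(Lo <= 0)
  ll <- sum(log(Lo[Lo > 0])) + if (length(zero)) -Inf else 0
  attr(ll, "zero_lik") <- zero
  ll
}

# parameter transforms: unconstrained theta <-> natural scale
.nm_b_range <- c(0.05, 20)
.nm_theta_to_params <- function(theta) {
  br <- .nm_b_range
  list(m_s = stats::plogis(theta[1]), m_p = stats::plogis(theta[2]),
       a_s = exp(theta[3]),
       b_s = br[1] + diff(br) * stats::plogis(theta[4]),
       a_p = exp(theta[5]),
       b_p = br[1] + diff(br) * stats::plogis(theta[6]),
       gamma = theta[7])
}
.nm_params_to_theta <- function(p) {
  br <- .nm_b_range
  c(stats::qlogis(p$m_s), stats::qlogis(p$m_p), log(p$a_s),
    stats::qlogis((p$b_s - br[1]) / diff(br)), log(p$a_p),
    stats::qlogis((p$b_p - br[1]) / diff(br)), p$gamma)
}
.nm_par_names <- c("m_s", "m_p", "a_s", "b_s", "a_p", "b_p", "gamma")

#' Fit the neighborhood dispersal model by maximum likelihood
#'
#' Maximises [nm_offspring_loglik()] over immigration rates (logit scale),
#' kernel scales (log scale), kernel shapes (logistic scale, bounded in
#' `[0.05, 20]`) and the dbh fecundity exponent, with multiple jittered
#' starts.  Standard errors come from the inverse observed information
#' (finite-difference Hessian on the transformed scale, delta method back);
#' mean dispersal distances `d_s`, `d_p` and their SEs are derived from the
#' fitted kernels.  Selfing is structurally zero (fathers exclude the
#' mother).
#'
#' @inheritParams nm_precompute
#' @param init optional named list of starting values (as in `params`)
#' @param n_starts number of jittered starts around `init`
#' @param rng_seed integer seed for the jitter
#' @param control passed to [stats::optim()] (Nelder-Mead)
#' @return object of class `nm_params`: estimates, SEs, mean distances,
#'   log-likelihood, convergence and boundary flags
#' @export
fit_neighborhood_model <- function(offspring, mature, background = NULL,
                                   null_freqs = NULL, init = NULL,
                                   n_starts = 3, rng_seed = NULL,
                                   control = list(maxit = 600,
                                                  reltol = 1e-9)) {
  if (n_individuals(offspring) < 20)
    warning("fewer than 20 offspring; estimates will be weakly identified")
  pc <- nm_precompute(offspring, mature, background, null_freqs)
  init <- utils::modifyList(
    list(m_s = 0.5, m_p = 0.5, a_s = 15, b_s = 1, a_p = 40, b_p = 1,
         gamma = 0.5), init %||% list())
  th0 <- .nm_params_to_theta(init)
  nll <- function(theta) {
    ll <- .nm_loglik(pc, .nm_theta_to_params(theta))
    if (!is.finite(ll)) return(1e10)
    -as.numeric(ll)
  }
  starts <- with_rng_seed(rng_seed, {
    lapply(seq_len(n_starts), function(s) {
      if (s == 1) th0 else th0 + stats::rnorm(7, 0, 0.7)
    })
  })
  fits <- lapply(starts, function(th)
    tryCatch(stats::optim(th, nll, method = "Nelder-Mead", control = control),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all optimisation starts failed")
  best <- fits[[which.min(vapply(fits, `[[`, 1, "value"))]]
  theta <- best$par
  est <- .nm_theta_to_params(theta)

  H <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
  vc <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  se_theta <- if (!is.null(vc) && all(diag(vc) > 0)) sqrt(diag(vc))
              else rep(NA_real_, 7)
  # delta method to the natural scale
  br <- .nm_b_range
  jac <- c(est$m_s * (1 - est$m_s), est$m_p * (1 - est$m_p), est$a_s,
           diff(br) * stats::plogis(theta[4]) * (1 - stats::plogis(theta[4])),
           est$a_p,
           diff(br) * stats::plogis(theta[6]) * (1 - stats::plogis(theta[6])),
           1)
  se <- stats::setNames(se_theta * abs(jac), .nm_par_names)

  d_se <- function(i_a, i_b, a, b) {
    # gradient of d = a Gamma(3/b)/Gamma(2/b) wrt (theta_a, theta_b)
    if (is.null(vc)) return(NA_real_)
    eps <- 1e-5
    f <- function(th) {
      p <- .nm_theta_to_params(th)
      aa <- if (i_a == 3) p$a_s else p$a_p
      bb <- if (i_a == 3) p$b_s else p$b_p
      mean_dispersal_distance(aa, bb)
    }
    g <- numeric(7)
    for (i in c(i_a, i_b)) {
      tp <- theta; tm <- theta
      tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
      g[i] <- (f(tp) - f(tm)) / (2 * eps)
    }
    v <- t(g) %*% vc %*% g
    if (v > 0) sqrt(v) else NA_real_
  }
  d_s <- mean_dispersal_distance(est$a_s, est$b_s)
  d_p <- mean_dispersal_distance(est$a_p, est$b_p)
  boundary <- abs(theta[1:2]) > stats::qlogis(0.999)
  out <- list(estimates = est, se = se, s = 0,
              d_s = d_s, se_d_s = d_se(3, 4),
              d_p = d_p, se_d_p = d_se(5, 6),
              loglik = -best$value, convergence = best$convergence,
              boundary = stats::setNames(boundary, c("m_s", "m_p")),
              theta = theta, vcov_theta = vc, n_offspring = pc$O)
  class(out) <- "nm_params"
  out
}

#' @export
print.nm_params <- function(x, ...) {
  cat("Neighborhood dispersal model fit (n offspring =", x$n_offspring, ")\n")
  print(as.data.frame(x))
  cat(sprintf("logLik = %.2f, convergence = %d\n", x$loglik, x$convergence))
  invisible(x)
}

#' Table-shaped view of a neighborhood-model fit
#'
#' Rows `a`, `b`, `s`, `d`, `m`, `Sigma (dbh)`; columns for the pollen and
#' seed components with their SEs.
#'
#' @param x an `nm_params` object
#' @param ... unused
#' @export
as.data.frame.nm_params <- function(x, ...) {
  e <- x$estimates
  data.frame(
    parameter = c("a", "b", "s", "d", "m", "Sigma (dbh)"),
    pollen = c(e$a_p, e$b_p, 0, x$d_p, e$m_p, e$gamma),
    pollen_se = c(x$se["a_p"], x$se["b_p"], NA, x$se_d_p, x$se["m_p"],
                  x$se["gamma"]),
    seed = c(e$a_s, e$b_s, 0, x$d_s, e$m_s, e$gamma),
    seed_se = c(x$se["a_s"], x$se["b_s"], NA, x$se_d_s, x$se["m_s"],
                x$se["gamma"]))
}
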