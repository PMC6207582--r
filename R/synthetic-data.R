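# Spatially explicit synthetic SSR data: a log-strewn plot, a mature stand,
# offspring generated under the same seed/pollen dispersal mixture the
# neighborhood model fits, and labelled sib families for kinship
# calibration.  True genotypes and pedigrees are carried as attributes so
# that every estimator can be validated against known truth.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the package is designed around: a
#' 200 x 250 m plot, 112 fallen logs, 123 mature trees, 11 SSR loci with
#' 3-46 alleles, null alleles, offspring cohorts of 179 seedlings and 190
#' saplings established only on logs, and seed/pollen exponential-power
#' kernels with immigration.
#'
#' @param ... overrides of any default field, among: `plot_extent`,
#'   `n_mature`, `n_logs`, `n_loci`, `alleles_per_locus` (range),
#'   `null_freq_range`, `missing_rate`, `seed_kernel` (`c(a, b)`),
#'   `pollen_kernel`, `m_s`, `m_p` (immigration probabilities), `gamma`
#'   (fecundity exponent on standardised dbh), `selfing` (fixed 0),
#'   `n_offspring` (named `seedling`/`sapling` counts), `log_length_range`,
#'   `log_diameter_range`, `dbh_shape`, `dbh_scale` (mature dbh = 20 +
#'   gamma-distributed excess, cm), `mature_placement` (`"uniform"` or
#'   `"thomas"`), `background_divergence` (Dirichlet divergence of the
#'   immigrant gene pool), `soil_establishment`, `rng_seed`.
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(...) {
  cfg <- utils::modifyList(list(
    plot_extent = c(200, 250),
    n_mature = 123,
    n_logs = 112,
    n_loci = 11,
    alleles_per_locus = c(3, 46),
    null_freq_range = c(0, 0.18),
    missing_rate = 0.01,
    seed_kernel = c(a = 3.823, b = 0.571),
    pollen_kernel = c(a = 81.816, b = 3.097),
    m_s = 0.744,
    m_p = 0.866,
    gamma = 1.2,
    selfing = 0,
    n_offspring = c(seedling = 179, sapling = 190),
    log_length_range = c(5, 30),
    log_diameter_range = c(20, 80),
    dbh_shape = 2, dbh_scale = 15,
    mature_placement = "uniform",
    thomas_parents = 15, thomas_sd = 15,
    background_divergence = 0.02,
    soil_establishment = FALSE,
    rng_seed = NULL
  ), list(...))
  # config files round-trip vectors as lists; flatten them back
  for (f in c("plot_extent", "alleles_per_locus", "null_freq_range",
              "seed_kernel", "pollen_kernel", "n_offspring",
              "log_length_range", "log_diameter_range"))
    cfg[[f]] <- unlist(cfg[[f]])
  # restore positional names that plain-sequence YAML drops
  for (f in c("seed_kernel", "pollen_kernel"))
    if (is.null(names(cfg[[f]]))) names(cfg[[f]]) <- c("a", "b")
  if (is.null(names(cfg$n_offspring))) {
    if (length(cfg$n_offspring) > 2)
      stop("n_offspring needs stage names when more than 2 cohorts are given")
    names(cfg$n_offspring) <- c("seedling", "sapling")[seq_along(cfg$n_offspring)]
  }
  stopifnot(cfg$n_mature >= 1, cfg$n_logs >= 1, cfg$n_loci >= 1,
            cfg$m_s >= 0, cfg$m_s <= 1, cfg$m_p >= 0, cfg$m_p <= 1,
            cfg$selfing == 0,
            all(cfg$seed_kernel > 0), all(cfg$pollen_kernel > 0),
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            all(cfg$null_freq_range >= 0), all(cfg$null_freq_range <= 1))
  structure(cfg, class = "sim_config")
}

#' Generate a plot landscape of fallen logs
#'
#' Log midpoints uniform in the plot, orientations uniform, lengths uniform
#' in the configured range; segments are clipped to the plot boundary.
#' Basal diameters are uniform in the configured range (>= 20 cm).
#'
#' @param config a [sim_config()]
#' @return data.frame of class `landscape` with columns `id`, `x0`, `y0`,
#'   `x1`, `y1`, `diameter`; attribute `plot_extent`
#' @export
generate_landscape <- function(config = sim_config()) {
  with_rng_seed(config$rng_seed, {
    W <- config$plot_extent[1]; H <- config$plot_extent[2]
    n <- config$n_logs
    mx <- stats::runif(n, 0, W); my <- stats::runif(n, 0, H)
    th <- stats::runif(n, 0, pi)
    len <- stats::runif(n, config$log_length_range[1], config$log_length_range[2])
    # clip the segment parameter range to the plot
    x0 <- mx - len / 2 * cos(th); x1 <- mx + len / 2 * cos(th)
    y0 <- my - len / 2 * sin(th); y1 <- my + len / 2 * sin(th)
    clip <- function(p0, p1, lim) {
      # returns t-range [0,1] of the segment inside [0, lim]
      d <- p1 - p0
      t0 <- ifelse(d == 0, 0, pmax(0, pmin((0 - p0) / d, (lim - p0) / d)))
      t1 <- ifelse(d == 0, 1, pmin(1, pmax((0 - p0) / d, (lim - p0) / d)))
      cbind(t0, t1)
    }
    tx <- clip(x0, x1, W); ty <- clip(y0, y1, H)
    t0 <- pmax(tx[, 1], ty[, 1]); t1 <- pmin(tx[, 2], ty[, 2])
    t0 <- pmin(t0, t1)
    out <- data.frame(
      id = sprintf("L%03d", seq_len(n)),
      x0 = x0 + t0 * (x1 - x0), y0 = y0 + t0 * (y1 - y0),
      x1 = x0 + t1 * (x1 - x0), y1 = y0 + t1 * (y1 - y0),
      diameter = stats::runif(n, config$log_diameter_range[1],
                              config$log_diameter_range[2]))
    class(out) <- c("landscape", "data.frame")
    attr(out, "plot_extent") <- config$plot_extent
    out
  })
}

# Dirichlet draw via normalised gammas.
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

# Draws a true per-locus allele table: visible SSR codes plus a null allele
# (code 0) with frequency from null_freq_range.
.draw_locus_tables <- function(config) {
  kr <- config$alleles_per_locus
  loci <- sprintf("Loc%02d", seq_len(config$n_loci))
  tabs <- lapply(loci, function(l) {
    k <- sample(seq(kr[1], kr[2]), 1)
    p <- .rdirichlet(rep(1, k))
    p <- pmax(p, 1e-4); p <- p / sum(p)
    rho <- stats::runif(1, config$null_freq_range[1], config$null_freq_range[2])
    list(codes = 100L + 2L * (seq_len(k) - 1L),
         p_vis = p * (1 - rho), rho = rho)
  })
  names(tabs) <- loci
  tabs
}

# Sample 2n gene copies per locus from a truth table (code 0 = null).
.draw_genotypes <- function(tabs, n) {
  a1 <- a2 <- matrix(NA_integer_, n, length(tabs),
                     dimnames = list(NULL, names(tabs)))
  for (l in names(tabs)) {
    tb <- tabs[[l]]
    codes <- c(tb$codes, 0L)
    pr <- c(tb$p_vis, tb$rho)
    a1[, l] <- sample(codes, n, replace = TRUE, prob = pr)
    a2[, l] <- sample(codes, n, replace = TRUE, prob = pr)
  }
  list(a1 = a1, a2 = a2)
}

# Observation layer: a visible/null heterozygote reads as a visible
# homozygote, a null homozygote reads as missing; then random missingness.
.observe <- function(a1, a2, missing_rate) {
  o1 <- a1; o2 <- a2
  nn <- a1 == 0L & a2 == 0L
  o1[a1 == 0L] <- a2[a1 == 0L]
  o2[a2 == 0L] <- o1[a2 == 0L]
  o1[nn] <- NA; o2[nn] <- NA
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(o1)) < missing_rate, nrow(o1))
    o1[drop] <- NA; o2[drop] <- NA
  }
  list(a1 = o1, a2 = o2)
}

#' Generate the mature stand
#'
#' Mature trees placed uniformly (or Thomas-clustered), genotypes drawn at
#' Hardy-Weinberg from Dirichlet-sampled allele frequencies (with per-locus
#' null alleles), dbh `>= 20` cm.  The returned dataset holds the OBSERVED
#' genotypes; true genotypes and the truth frequency tables are in
#' `attr(, "truth")`.
#'
#' @param config a [sim_config()]
#' @return a `genotype_dataset` with attribute `truth` = list(`a1`, `a2`
#'   true allele matrices with 0 = null, `tables` per-locus truth tables,
#'   `null_freq`)
#' @export
generate_mature_population <- function(config = sim_config()) {
  with_rng_seed(config$rng_seed, {
    n <- config$n_mature
    W <- config$plot_extent[1]; H <- config$plot_extent[2]
    if (config$mature_placement == "thomas") {
      np <- config$thomas_parents
      px <- stats::runif(np, 0, W); py <- stats::runif(np, 0, H)
      pick <- sample(np, n, replace = TRUE)
      x <- pmin(pmax(px[pick] + stats::rnorm(n, 0, config$thomas_sd), 0), W)
      y <- pmin(pmax(py[pick] + stats::rnorm(n, 0, config$thomas_sd), 0), H)
    } else {
      x <- stats::runif(n, 0, W); y <- stats::runif(n, 0, H)
    }
    tabs <- .draw_locus_tables(config)
    true <- .draw_genotypes(tabs, n)
    obs <- .observe(true$a1, true$a2, config$missing_rate)
    info <- data.frame(id = sprintf("M%03d", seq_len(n)), stage = "mature",
                       x = x, y = y, cwd_id = NA, dbh = 20 +
                         stats::rgamma(n, config$dbh_shape,
                                       scale = config$dbh_scale),
                       age = NA, stringsAsFactors = FALSE)
    nf <- vapply(tabs, `[[`, 1, "rho")
    ds <- genotype_dataset(info, obs$a1, obs$a2, null_freq = nf,
                           plot_extent = config$plot_extent)
    attr(ds, "truth") <- list(a1 = true$a1, a2 = true$a2, tables = tabs,
                              null_freq = nf)
    ds
  })
}

# Background (immigrant) truth tables: Dirichlet perturbation of the local
# visible frequencies with divergence parameter d (concentration (1-d)/d).
.background_tables <- function(tabs, divergence) {
  conc <- (1 - divergence) / max(divergence, 1e-6)
  lapply(tabs, function(tb) {
    pv <- tb$p_vis / sum(tb$p_vis)
    pb <- .rdirichlet(pv * conc)
    pb <- pmax(pb, 1e-5); pb <- pb / sum(pb)
    list(codes = tb$codes, p_vis = pb * (1 - tb$rho), rho = tb$rho)
  })
}

#' Simulate offspring under the neighborhood dispersal model
#'
#' For each offspring: an establishment point drawn on a random log; with
#' probability `m_s` the seed is an immigrant (genotype from a diverged
#' background gene pool), otherwise a local mother is sampled with
#' probability proportional to `exp(gamma z_j) P_s(d)`; given a local
#' mother, the pollen is immigrant with probability `m_p`, otherwise a local
#' father (never the mother: selfing = 0) sampled proportional to
#' `exp(gamma z_k) P_p(d)`.  Gametes are Mendelian draws from TRUE parental
#' genotypes; the observation layer then applies null-allele masking and
#' random missingness.  The mother/father sampling weights are exactly the
#' weights the likelihood in [nm_offspring_loglik()] uses, so fitting the
#' model to these data is a self-consistent parameter-recovery experiment.
#'
#' @param config a [sim_config()]
#' @param mature dataset from [generate_mature_population()] (its `truth`
#'   attribute supplies true genotypes; observed genotypes are used with a
#'   warning if it is absent)
#' @param landscape a [generate_landscape()] result
#' @param n_offspring named stage counts (default from `config`)
#' @return a `genotype_dataset` with attributes `pedigree` (data.frame
#'   `offspring_id`, `mother_id`, `father_id`, immigrants as `"IMM"`),
#'   `truth` (true allele matrices), and `background` (immigrant truth
#'   tables)
#' @export
simulate_offspring_nm <- function(config, mature, landscape,
                                  n_offspring = NULL) {
  if (n_individuals(mature) == 0) stop("mature dataset is empty")
  n_offspring <- n_offspring %||% config$n_offspring
  truth <- attr(mature, "truth")
  if (is.null(truth)) {
    warning("mature dataset lacks a truth attribute; using observed genotypes")
    truth <- list(a1 = mature$a1, a2 = mature$a2,
                  tables = NULL, null_freq = mature$null_freq)
  }
  tabs <- truth$tables
  if (is.null(tabs)) stop("simulation needs truth frequency tables")
  with_rng_seed(config$rng_seed, {
    bg <- .background_tables(tabs, config$background_divergence)
    J <- n_individuals(mature)
    z <- as.numeric(scale(mature$info$dbh))
    fec <- exp(config$gamma * z)
    n_tot <- sum(n_offspring)
    stages <- rep(names(n_offspring), n_offspring)
    # establishment points on logs
    li <- sample(nrow(landscape), n_tot, replace = TRUE)
    tt <- stats::runif(n_tot)
    ox <- landscape$x0[li] + tt * (landscape$x1[li] - landscape$x0[li])
    oy <- landscape$y0[li] + tt * (landscape$y1[li] - landscape$y0[li])
    cwd <- landscape$id[li]
    # parent sampling
    d_om <- outer(ox, mature$info$x, `-`)^2 + outer(oy, mature$info$y, `-`)^2
    d_om <- sqrt(d_om)
    Ps <- exp_power_pdf(d_om, config$seed_kernel["a"], config$seed_kernel["b"])
    psi <- sweep(Ps, 2, fec, `*`)
    d_mm <- pairwise_distances(mature)
    Pp <- exp_power_pdf(d_mm, config$pollen_kernel["a"], config$pollen_kernel["b"])
    W <- sweep(Pp, 2, fec, `*`); diag(W) <- 0

    bg_gamete <- function(l) {
      tb <- bg[[l]]
      sample(c(tb$codes, 0L), 1, prob = c(tb$p_vis, tb$rho))
    }
    loci <- names(tabs)
    a1 <- a2 <- matrix(NA_integer_, n_tot, length(loci),
                       dimnames = list(NULL, loci))
    mother <- father <- character(n_tot)
    for (o in seq_len(n_tot)) {
      if (stats::runif(1) < config$m_s) {
        mother[o] <- "IMM"; father[o] <- "IMM"
        for (li2 in seq_along(loci)) {
          a1[o, li2] <- bg_gamete(loci[li2])
          a2[o, li2] <- bg_gamete(loci[li2])
        }
      } else {
        j <- sample.int(J, 1, prob = psi[o, ])
        mother[o] <- mature$info$id[j]
        imm_f <- stats::runif(1) < config$m_p
        k <- if (imm_f) NA_integer_ else sample.int(J, 1, prob = W[j, ])
        father[o] <- if (imm_f) "IMM" else mature$info$id[k]
        for (li2 in seq_along(loci)) {
          mg <- if (stats::runif(1) < 0.5) truth$a1[j, li2] else truth$a2[j, li2]
          fg <- if (imm_f) bg_gamete(loci[li2]) else
            if (stats::runif(1) < 0.5) truth$a1[k, li2] else truth$a2[k, li2]
          a1[o, li2] <- mg; a2[o, li2] <- fg
        }
      }
    }
    obs <- .observe(a1, a2, config$missing_rate)
    info <- data.frame(id = sprintf("O%04d", seq_len(n_tot)), stage = stages,
                       x = ox, y = oy, cwd_id = cwd, dbh = NA, age = NA,
                       stringsAsFactors = FALSE)
    nf <- vapply(tabs, `[[`, 1, "rho")
    ds <- genotype_dataset(info, obs$a1, obs$a2, null_freq = nf,
                           plot_extent = config$plot_extent)
    attr(ds, "pedigree") <- data.frame(offspring_id = info$id,
                                       mother_id = mother, father_id = father,
                                       stringsAsFactors = FALSE)
    attr(ds, "truth") <- list(a1 = a1, a2 = a2, tables = tabs, null_freq = nf)
    attr(ds, "background") <- bg
    ds
  })
}

#' Generate labelled half-sib or full-sib families
#'
#' Parents drawn at Hardy-Weinberg from a known reference table (default:
#' equifrequent alleles); offspring are Mendelian draws with no genotyping
#' error.  Half-sib families share the mother and have independent fathers;
#' full-sib families share both parents.
#'
#' @param n_families number of families
#' @param offspring_per_family sibs per family (>= 2)
#' @param type `"half"` or `"full"`
#' @param n_loci,alleles_per_locus reference design (equifrequent)
#' @param ref optional [allele_freq_table()] to draw parents from instead
#' @param rng_seed optional integer seed
#' @return list with `dataset` (offspring `genotype_dataset`), `pedigree`,
#'   and `ref` (the true reference table, gene count `Inf` so that kinship
#'   against it uses no finite-sample correction)
#' @export
generate_sib_families <- function(n_families, offspring_per_family = 2,
                                  type = c("half", "full"), n_loci = 10,
                                  alleles_per_locus = 10, ref = NULL,
                                  rng_seed = NULL) {
  type <- match.arg(type)
  if (offspring_per_family < 2) stop("family sizes must be >= 2")
  if (is.null(ref)) {
    freqs <- lapply(seq_len(n_loci), function(i)
      stats::setNames(rep(1 / alleles_per_locus, alleles_per_locus),
                      100L + 2L * (seq_len(alleles_per_locus) - 1L)))
    names(freqs) <- sprintf("Loc%02d", seq_len(n_loci))
    ref <- allele_freq_table(freqs, stats::setNames(rep(Inf, n_loci),
                                                    names(freqs)))
  }
  loci <- names(ref$freqs)
  with_rng_seed(rng_seed, {
    draw_parent <- function() {
      g <- lapply(loci, function(l) {
        p <- ref$freqs[[l]]
        as.integer(sample(names(p), 2, replace = TRUE, prob = p))
      })
      do.call(rbind, g)   # L x 2
    }
    n_off <- n_families * offspring_per_family
    a1 <- a2 <- matrix(NA_integer_, n_off, length(loci),
                       dimnames = list(NULL, loci))
    fam <- integer(n_off); moms <- dads <- character(n_off)
    o <- 0
    for (f in seq_len(n_families)) {
      mom <- draw_parent()
      dad <- if (type == "full") draw_parent() else NULL
      for (s in seq_len(offspring_per_family)) {
        o <- o + 1
        sire <- if (type == "full") dad else draw_parent()
        pick <- stats::runif(length(loci)) < 0.5
        a1[o, ] <- ifelse(pick, mom[, 1], mom[, 2])
        pick <- stats::runif(length(loci)) < 0.5
        a2[o, ] <- ifelse(pick, sire[, 1], sire[, 2])
        fam[o] <- f
        moms[o] <- sprintf("F%04d_M", f)
        dads[o] <- if (type == "full") sprintf("F%04d_D", f)
                   else sprintf("F%04d_D%d", f, s)
      }
    }
    info <- data.frame(id = sprintf("S%05d", seq_len(n_off)),
                       stage = "seedling",
                       x = stats::runif(n_off, 0, 100),
                       y = stats::runif(n_off, 0, 100),
                       cwd_id = sprintf("FAM%04d", fam), dbh = NA, age = NA,
                       stringsAsFactors = FALSE)
    ds <- genotype_dataset(info, a1, a2)
    ped <- data.frame(offspring_id = info$id, family = fam,
                      mother_id = moms, father_id = dads,
                      stringsAsFactors = FALSE)
    list(dataset = ds, pedigree = ped, ref = ref)
  })
}

#' Write a simulated dataset and its pedigree to plain-text files
#'
#' @param ds a `genotype_dataset` carrying a `pedigree` attribute
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the written paths
#' @export
write_simulated_dataset <- function(ds, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, paste0(prefix, "_genotypes.csv"))
  write_genotype_table(ds, gp)
  paths <- gp
  ped <- attr(ds, "pedigree")
  if (!is.null(ped)) {
    pp <- file.path(dir, paste0(prefix, "_pedigree.tsv"))
    utils::write.table(ped, pp, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, pp)
  }
  invisible(paths)
}
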