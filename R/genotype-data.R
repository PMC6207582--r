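# Core data model: spatially referenced, stage-structured codominant genotypes.

#' Recognised growth-stage labels, ordered youngest to oldest
#' @export
STAGES <- c("seedling", "sapling", "juvenile", "mature")

#' Construct a genotype dataset
#'
#' The central container of the package: a set of individuals with growth
#' stage, map coordinates (metres, plot-local, origin at a plot corner),
#' optional coarse-woody-debris (log) id, dbh and age, plus a multilocus
#' codominant genotype stored as two allele matrices.
#'
#' @param info data.frame with columns `id`, `stage`, `x`, `y` and optionally
#'   `cwd_id`, `dbh`, `age`.  `stage` must be one of
#'   `r paste(STAGES, collapse = ", ")`.
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   codes per locus; a locus is missing for an individual iff both entries
#'   are `NA`.  Column names are the locus names.
#' @param null_freq optional named numeric of per-locus null-allele
#'   frequencies in `[0, 1]`.
#' @param plot_extent numeric `(width, height)` of the mapped plot in metres,
#'   or `NULL`.
#' @param validate check invariants (stage labels, dbh/stage consistency,
#'   unique ids, allele/missing conventions).
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(info, a1, a2, null_freq = NULL,
                             plot_extent = NULL, validate = TRUE) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (is.null(colnames(a1))) stop("allele matrices must have locus column names")
  if (!identical(dim(a1), dim(a2)) || !identical(colnames(a1), colnames(a2)))
    stop("a1 and a2 must have identical dimensions and locus names")
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  for (col in c("cwd_id", "dbh", "age"))
    if (is.null(info[[col]])) info[[col]] <- NA
  info$id <- as.character(info$id)
  info$cwd_id <- as.character(info$cwd_id)
  info$stage <- as.character(info$stage)
  info$dbh <- as.numeric(info$dbh)
  rownames(a1) <- rownames(a2) <- info$id
  nf <- rep(NA_real_, ncol(a1)); names(nf) <- colnames(a1)
  if (!is.null(null_freq)) nf[names(null_freq)] <- null_freq
  ds <- structure(list(info = info, a1 = a1, a2 = a2, null_freq = nf,
                       plot_extent = plot_extent),
                  class = "genotype_dataset")
  if (validate) validate_genotype_dataset(ds)
  ds
}

#' Validate a genotype dataset's invariants
#'
#' @param ds a `genotype_dataset`
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_genotype_dataset <- function(ds) {
  info <- ds$info
  if (nrow(info) != nrow(ds$a1)) stop("info and allele matrices disagree on n")
  if (anyDuplicated(info$id)) stop("individual ids must be unique")
  bad <- !info$stage %in% STAGES
  if (any(bad))
    stop("unknown stage label(s): ", paste(unique(info$stage[bad]), collapse = ", "))
  if (any(!is.finite(info$x)) || any(!is.finite(info$y)))
    stop("all coordinates must be finite")
  # one-sided missing is not allowed: a locus is typed (2 alleles) or absent
  if (any(is.na(ds$a1) != is.na(ds$a2)))
    stop("half-missing genotypes found; a locus must have 2 alleles or be missing")
  dbh <- info$dbh
  viol <- (info$stage == "mature" & !is.na(dbh) & dbh < 20) |
          (info$stage == "juvenile" & !is.na(dbh) & (dbh < 5 | dbh >= 20))
  if (any(viol))
    stop("dbh/stage inconsistency for id(s): ",
         paste(utils::head(info$id[viol], 5), collapse = ", "))
  young <- info$stage %in% c("seedling", "sapling")
  if (any(young & (is.na(info$cwd_id) | info$cwd_id == "")))
    stop("seedlings and saplings must carry a cwd_id (log of establishment)")
  if (any(!is.na(ds$null_freq) & (ds$null_freq < 0 | ds$null_freq > 1)))
    stop("null_freq must lie in [0, 1]")
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  tab <- table(factor(x$info$stage, levels = STAGES))
  cat("genotype_dataset:", nrow(x$info), "individuals,",
      ncol(x$a1), "loci\n")
  cat("  stages:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$plot_extent))
    cat("  plot:", x$plot_extent[1], "x", x$plot_extent[2], "m\n")
  invisible(x)
}

#' Number of individuals in a dataset
#' @param ds a `genotype_dataset`
#' @export
n_individuals <- function(ds) nrow(ds$info)

#' Locus names of a dataset
#' @param ds a `genotype_dataset`
#' @export
locus_names <- function(ds) colnames(ds$a1)

#' Subset a dataset by individual index, id or stage
#'
#' @param ds a `genotype_dataset`
#' @param idx integer/logical index or character ids
#' @param stage optional stage label(s); applied after `idx`
#' @return a `genotype_dataset`
#' @export
subset_individuals <- function(ds, idx = NULL, stage = NULL) {
  keep <- seq_len(nrow(ds$info))
  if (!is.null(idx)) {
    if (is.character(idx)) idx <- match(idx, ds$info$id)
    keep <- keep[idx]
  }
  if (!is.null(stage)) keep <- keep[ds$info$stage[keep] %in% stage]
  genotype_dataset(ds$info[keep, , drop = FALSE],
                   ds$a1[keep, , drop = FALSE], ds$a2[keep, , drop = FALSE],
                   null_freq = ds$null_freq, plot_extent = ds$plot_extent,
                   validate = FALSE)
}

#' Subset a dataset by locus
#'
#' @param ds a `genotype_dataset`
#' @param keep,drop locus names to keep or to drop (exactly one given)
#' @return a `genotype_dataset`
#' @export
subset_loci <- function(ds, keep = NULL, drop = NULL) {
  if (is.null(keep) == is.null(drop)) stop("give exactly one of keep/drop")
  loci <- locus_names(ds)
  if (!is.null(drop)) keep <- setdiff(loci, drop)
  miss <- setdiff(keep, loci)
  if (length(miss)) stop("unknown loci: ", paste(miss, collapse = ", "))
  genotype_dataset(ds$info, ds$a1[, keep, drop = FALSE],
                   ds$a2[, keep, drop = FALSE],
                   null_freq = ds$null_freq[keep],
                   plot_extent = ds$plot_extent, validate = FALSE)
}

# ---- allele frequency tables -------------------------------------------------

#' Construct a per-locus allele frequency table
#'
#' Houses the reference population used by the kinship estimator: per locus, a
#' named frequency vector and the number of sampled gene copies behind it.
#'
#' @param freqs named list; per locus a named numeric vector of allele
#'   frequencies (names = allele codes) summing to 1.
#' @param n named numeric of gene counts per locus (>= 2; may be `Inf` for a
#'   "known" theoretical reference, which switches off finite-sample bias
#'   corrections downstream).
#' @return An object of class `allele_freq_table`.
#' @export
allele_freq_table <- function(freqs, n) {
  if (is.null(names(freqs))) stop("freqs must be a named list (locus names)")
  n <- n[names(freqs)]
  for (l in names(freqs)) {
    f <- freqs[[l]]
    if (any(f <= 0)) stop("frequencies must be > 0 (locus ", l, ")")
    if (abs(sum(f) - 1) > 1e-9) stop("frequencies must sum to 1 (locus ", l, ")")
    if (is.na(n[[l]]) || n[[l]] < 2) stop("gene count must be >= 2 (locus ", l, ")")
  }
  structure(list(freqs = freqs, n = n), class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  k <- vapply(x$freqs, length, 1L)
  cat("allele_freq_table:", length(x$freqs), "loci;",
      "alleles/locus", min(k), "-", max(k), "\n")
  invisible(x)
}

#' Per-locus allele frequencies of (a subset of) a dataset
#'
#' Counts non-missing gene copies; loci with zero typed individuals in the
#' subset are dropped with a warning.
#'
#' @param ds a `genotype_dataset`
#' @param stages optional stage filter
#' @param loci optional locus filter
#' @return an `allele_freq_table` with gene counts `n = 2 x` typed individuals
#' @export
allele_frequencies <- function(ds, stages = NULL, loci = NULL) {
  if (!is.null(stages)) ds <- subset_individuals(ds, stage = stages)
  if (n_individuals(ds) == 0) stop("no individuals in requested subset")
  if (!is.null(loci)) ds <- subset_loci(ds, keep = loci)
  freqs <- list(); n <- numeric(0)
  for (l in locus_names(ds)) {
    g <- c(ds$a1[, l], ds$a2[, l])
    g <- g[!is.na(g)]
    if (length(g) == 0) {
      warning("locus ", l, " has no typed individuals in subset; excluded")
      next
    }
    tab <- table(g)
    freqs[[l]] <- stats::setNames(as.numeric(tab) / length(g), names(tab))
    n[[l]] <- length(g)
  }
  allele_freq_table(freqs, n)
}

#' Euclidean distance matrix between individuals (metres)
#'
#' @param ds a `genotype_dataset`
#' @return symmetric matrix with zero diagonal, dimnames = ids
#' @export
pairwise_distances <- function(ds) {
  d <- as.matrix(stats::dist(cbind(ds$info$x, ds$info$y)))
  dimnames(d) <- list(ds$info$id, ds$info$id)
  d
}
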