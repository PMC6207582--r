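# Demographic-thinning simulations: removal of inbred offspring, random
# removal, and eradication of the most densely colonised logs, followed by
# FSGS recomputation without an external reference population.

#' Pool two offspring cohorts into one dataset
#'
#' @param seedlings,saplings `genotype_dataset`s with identical loci and
#'   disjoint id sets
#' @return a `genotype_dataset` with stage labels retained
#' @export
pool_offspring <- function(seedlings, saplings) {
  if (n_individuals(saplings) == 0) return(seedlings)
  if (!identical(locus_names(seedlings), locus_names(saplings)))
    stop("datasets must share an identical locus set")
  dup <- intersect(seedlings$info$id, saplings$info$id)
  if (length(dup)) stop("id collision: ", paste(utils::head(dup, 5), collapse = ", "))
  genotype_dataset(rbind(seedlings$info, saplings$info),
                   rbind(seedlings$a1, saplings$a1),
                   rbind(seedlings$a2, saplings$a2),
                   null_freq = seedlings$null_freq,
                   plot_extent = seedlings$plot_extent %||% saplings$plot_extent,
                   validate = FALSE)
}

#' Thin by inbreeding: keep the least-inbred offspring
#'
#' Ranks individuals by [individual_fis()] (against the supplied reference,
#' normally the augmented mature reference) and keeps the `n_keep` lowest;
#' ties at the cut are broken by id order (stable sort).
#'
#' @param pooled pooled offspring `genotype_dataset`
#' @param ref_for_fis [allele_freq_table()] used to rank inbreeding
#' @param n_keep survivors (default 123)
#' @param bias_correction see [kinship_matrix()]
#' @return the surviving `genotype_dataset`; attribute `fis` holds the
#'   ranking values
#' @export
thin_by_inbreeding <- function(pooled, ref_for_fis, n_keep = 123,
                               bias_correction = TRUE) {
  if (n_individuals(pooled) < n_keep) stop("pooled dataset smaller than n_keep")
  fis <- individual_fis(pooled, ref_for_fis, bias_correction)
  keep <- order(fis)[seq_len(n_keep)]   # stable: ties keep id (row) order
  out <- subset_individuals(pooled, sort(keep))
  attr(out, "fis") <- fis[sort(keep)]
  out
}

#' Thin at random: repeated uniform subsets without replacement
#'
#' @param pooled pooled offspring `genotype_dataset`
#' @param n_keep survivors per replicate (default 123)
#' @param n_reps number of independent replicates (default 10)
#' @param rng_seed optional integer seed
#' @return named list of `genotype_dataset`s (`random1`, `random2`, ...)
#' @export
thin_random <- function(pooled, n_keep = 123, n_reps = 10, rng_seed = NULL) {
  n <- n_individuals(pooled)
  if (n < n_keep) stop("pooled dataset smaller than n_keep")
  with_rng_seed(rng_seed, {
    out <- lapply(seq_len(n_reps), function(r)
      subset_individuals(pooled, sort(sample.int(n, n_keep))))
    names(out) <- paste0("random", seq_len(n_reps))
    out
  })
}

#' Thin by log eradication: remove all offspring on the fullest logs
#'
#' Logs are ranked by offspring count, descending, ties broken by log id;
#' all offspring on the top `top_k` logs (or on every log carrying more than
#' `more_than` offspring) are removed.
#'
#' @param pooled pooled offspring `genotype_dataset`; every individual must
#'   carry a `cwd_id`
#' @param top_k remove the k most heavily colonised logs
#' @param more_than alternatively, remove every log with count `> more_than`
#' @return surviving `genotype_dataset`; attribute `removed_logs`
#' @export
thin_by_cwd <- function(pooled, top_k = NULL, more_than = NULL) {
  if (is.null(top_k) == is.null(more_than))
    stop("give exactly one of top_k / more_than")
  cwd <- pooled$info$cwd_id
  if (any(is.na(cwd) | cwd == ""))
    stop("all offspring need a cwd_id for log-eradication thinning")
  cnt <- table(cwd)
  ord <- order(-as.numeric(cnt), names(cnt))   # count desc, id asc
  logs <- names(cnt)[ord]
  doomed <- if (!is.null(top_k)) logs[seq_len(min(top_k, length(logs)))]
            else names(cnt)[cnt > more_than]
  keep <- which(!cwd %in% doomed)
  out <- subset_individuals(pooled, keep)
  attr(out, "removed_logs") <- doomed
  out
}

#' The six log-eradication scenario datasets
#'
#' Top-1 through top-5 removals plus the "more than `more_than` offspring"
#' rule.
#'
#' @inheritParams thin_by_cwd
#' @param ks the top-k values (default 1:5)
#' @return named list of `genotype_dataset`s
#' @export
cwd_scenario_datasets <- function(pooled, ks = 1:5, more_than = 8) {
  out <- lapply(ks, function(k) thin_by_cwd(pooled, top_k = k))
  names(out) <- paste0("cwd_top", ks)
  out[[paste0("cwd_gt", more_than)]] <- thin_by_cwd(pooled, more_than = more_than)
  out
}

#' FSGS report over thinning-scenario datasets
#'
#' For each dataset the reference population is the dataset's OWN allele
#' frequencies (no external reference, no augmentation); reports mean
#' individual F_is with its permutation p, the first-class mean kinship F_1,
#' the log-distance slope b_F with its permutation p, and Sp.
#'
#' @param datasets named list of `genotype_dataset`s (>= 3 individuals each)
#' @param scheme a [distance_class_scheme()]
#' @param n_perms permutations per test
#' @param bias_correction see [kinship_matrix()]
#' @param rng_seed optional integer seed (one sub-seed per dataset)
#' @return data.frame of class `thinning_report`: `dataset`, `n`,
#'   `mean_fis`, `p_fis`, `F_1`, `b_F`, `se_bF`, `p_bF`, `Sp`
#' @export
thinning_fsgs_report <- function(datasets, scheme = distance_class_scheme(),
                                 n_perms = 1000, bias_correction = TRUE,
                                 rng_seed = NULL) {
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  rows <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    seed_i <- if (is.null(rng_seed)) NULL else rng_seed + i
    ref <- allele_frequencies(ds)
    fs <- fsgs_summary(ds, ref = ref, scheme = scheme, n_perms = n_perms,
                       bias_correction = bias_correction, rng_seed = seed_i)
    ft <- mean_fis_test(ds, ref = ref, n_perms = n_perms,
                        bias_correction = bias_correction,
                        rng_seed = if (is.null(seed_i)) NULL else seed_i + 10000L)
    data.frame(dataset = names(datasets)[i], n = n_individuals(ds),
               mean_fis = ft$mean_fis, p_fis = ft$p,
               F_1 = fs$F_1, b_F = fs$b_F, se_bF = fs$se_bF, p_bF = fs$p_bF,
               Sp = fs$Sp)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("thinning_report", "data.frame")
  out
}
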