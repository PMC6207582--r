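# End-to-end orchestration: a config-driven pipeline that simulates or loads
# a dataset and writes diversity, FSGS, dispersal, thinning and delta-K
# reports as TSV/JSON, with a manifest recording parameters and seeds.

#' Run the analysis pipeline
#'
#' Stages (selected via `config$stages`, default all applicable):
#' `simulate` (or load `config$input$genotypes`), `diversity`, `fsgs`,
#' `dispersal`, `thinning`, `deltak`.  Every run writes the resolved config
#' and a manifest next to the outputs; reruns with the same config and seed
#' are numerically identical.
#'
#' @param config a list, or path to a YAML file, with fields: `out_dir`;
#'   `rng_seed`; `stages` (character vector); `simulate` (overrides for
#'   [sim_config()]) or `input` (`genotypes` CSV path, optional
#'   `format_spec`); `n_perms` (default 1000); `distance_breaks`;
#'   `exclude_loci` (dropped from all kinship/F_is computations);
#'   `richness_g`; `dispersal` (list: `stage`, `n_starts`, `init`);
#'   `thinning` (list: `n_keep`, `n_reps`, `more_than`); `deltak`
#'   (`runs_file` TSV with columns K, run, lnP).
#' @return invisibly, a list with the outputs of each executed stage and
#'   `errors`; the function stops (after writing the manifest) if any stage
#'   failed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$rng_seed %||% 1L
  n_perms <- config$n_perms %||% 1000L
  config$exclude_loci <- unlist(config$exclude_loci)
  scheme <- distance_class_scheme(
    unlist(config$distance_breaks) %||% seq(0, 200, 10))
  results <- list(); errors <- list(); manifest <- list(config = config)
  log_msg <- function(...) message("[spatkin] ", ...)

  run_stage <- function(name, fun) {
    tryCatch({
      log_msg("stage ", name, " ...")
      results[[name]] <<- fun()
      manifest$stages[[name]] <<- "ok"
    }, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      manifest$stages[[name]] <<- paste("ERROR:", conditionMessage(e))
      log_msg("stage ", name, " FAILED: ", conditionMessage(e))
    })
  }
  wtsv <- function(df, f) {
    utils::write.table(df, file.path(out_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    f
  }
  wjson <- function(x, f) {
    jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    f
  }

  stages <- config$stages %||%
    c(if (is.null(config$input)) "simulate",
      "diversity", "fsgs",
      if (!is.null(config$dispersal)) "dispersal",
      if (!is.null(config$thinning)) "thinning",
      if (!is.null(config$deltak)) "deltak")

  # --- data -------------------------------------------------------------
  ds <- NULL; mature <- NULL; offspring <- NULL; landscape <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      cfg <- do.call(sim_config, utils::modifyList(
        config$simulate %||% list(), list(rng_seed = seed)))
      landscape <<- generate_landscape(cfg)
      cfg2 <- cfg; cfg2$rng_seed <- seed + 1L
      mature <<- generate_mature_population(cfg2)
      cfg3 <- cfg; cfg3$rng_seed <- seed + 2L
      offspring <<- simulate_offspring_nm(cfg3, mature, landscape)
      ds <<- pool_offspring(offspring, mature)
      attr(ds, "pedigree") <- attr(offspring, "pedigree")
      write_simulated_dataset(ds, out_dir, "dataset")
      utils::write.table(landscape, file.path(out_dir, "landscape.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(config = unclass(cfg), n = n_individuals(ds))
    })
  } else if (!is.null(config$input$genotypes)) {
    run_stage("load", function() {
      ds <<- read_genotype_table(config$input$genotypes,
                                 config$input$format_spec %||% list())
      list(n = n_individuals(ds))
    })
  }
  if (is.null(ds)) {
    manifest$error <- "no dataset available"
    wjson(manifest, "manifest.json")
    stop("pipeline has no dataset (simulate failed or no input given)")
  }
  ds_fsgs <- if (length(config$exclude_loci))
    subset_loci(ds, drop = config$exclude_loci) else ds

  # --- diversity --------------------------------------------------------
  if ("diversity" %in% stages) run_stage("diversity", function() {
    div <- diversity_summary(ds, g = config$richness_g,
                             fis_null = isTRUE(config$fis_null %||% TRUE))
    wtsv(div, "diversity.tsv")
    fst <- pairwise_fst_matrix(ds, n_perms = n_perms, rng_seed = seed + 100L)
    stars <- ifelse(is.na(fst$p), "", ifelse(fst$p < 0.01, "**",
                    ifelse(fst$p < 0.05, "*", "n.s.")))
    fst_df <- data.frame(stage = rownames(fst$theta),
                         round(fst$theta, 4), stars,
                         check.names = FALSE)
    wtsv(fst_df, "fst.tsv")
    list(diversity = div, fst = fst)
  })

  # --- fsgs -------------------------------------------------------------
  if ("fsgs" %in% stages) run_stage("fsgs", function() {
    present <- intersect(STAGES, unique(ds_fsgs$info$stage))
    adolescent <- setdiff(present, "mature")
    mt <- subset_individuals(ds_fsgs, stage = "mature")
    ado <- if (length(adolescent))
      subset_individuals(ds_fsgs, stage = adolescent) else NULL
    ref <- build_reference_frequencies(mt, ado)
    summaries <- list()
    for (st in present) {
      fs <- fsgs_summary(ds_fsgs, stage = st, ref = ref, scheme = scheme,
                         n_perms = n_perms, rng_seed = seed + 200L)
      ft <- mean_fis_test(ds_fsgs, stage = st, ref = ref, n_perms = n_perms,
                          n_stages_for_bonferroni = length(present),
                          rng_seed = seed + 300L)
      wtsv(fs$correlogram, paste0("fsgs_correlogram_", st, ".tsv"))
      summaries[[st]] <- data.frame(stage = st, n = fs$n,
                                    F_is = ft$mean_fis, p_Fis = ft$p_adj,
                                    F_1 = fs$F_1, b_F = fs$b_F,
                                    se_bF = fs$se_bF, p_bF = fs$p_bF,
                                    Sp = fs$Sp)
    }
    tab <- do.call(rbind, summaries)
    wtsv(tab, "fsgs_summary.tsv")
    wjson(tab, "fsgs_summary.json")
    tab
  })

  # --- dispersal --------------------------------------------------------
  if ("dispersal" %in% stages) run_stage("dispersal", function() {
    dcfg <- config$dispersal %||% list()
    st <- dcfg$stage %||% "seedling"
    mt <- subset_individuals(ds, stage = "mature")
    off <- subset_individuals(ds, stage = st)
    fit <- fit_neighborhood_model(off, mt,
                                  init = dcfg$init,
                                  n_starts = dcfg$n_starts %||% 3,
                                  rng_seed = seed + 400L)
    tab <- as.data.frame(fit)
    wtsv(tab, paste0("dispersal_", st, ".tsv"))
    wjson(tab, paste0("dispersal_", st, ".json"))
    fit
  })

  # --- thinning ---------------------------------------------------------
  if ("thinning" %in% stages) run_stage("thinning", function() {
    tcfg <- config$thinning %||% list()
    pooled <- subset_individuals(ds_fsgs, stage = c("seedling", "sapling"))
    mt <- subset_individuals(ds_fsgs, stage = "mature")
    ref <- build_reference_frequencies(mt, pooled)
    n_keep <- tcfg$n_keep %||% 123L
    sets <- c(list(pooled = pooled,
                   inbred = thin_by_inbreeding(pooled, ref, n_keep)),
              thin_random(pooled, n_keep, tcfg$n_reps %||% 10L,
                          rng_seed = seed + 500L),
              cwd_scenario_datasets(pooled, more_than = tcfg$more_than %||% 8))
    rep <- thinning_fsgs_report(sets, scheme, n_perms, rng_seed = seed + 600L)
    wtsv(rep, "thinning.tsv")
    rep
  })

  # --- delta-K ----------------------------------------------------------
  if ("deltak" %in% stages) run_stage("deltak", function() {
    runs <- utils::read.table(config$deltak$runs_file, header = TRUE,
                              sep = "\t")
    dk <- evanno_delta_k(runs)
    wtsv(dk, "deltak.tsv")
    dk
  })

  manifest$rng_seed <- seed
  manifest$n_perms <- n_perms
  wjson(manifest, "manifest.json")
  wjson(config, "config_resolved.json")
  if (length(errors))
    stop("pipeline stage(s) failed: ", paste(names(errors), collapse = ", "))
  invisible(list(results = results, errors = errors, out_dir = out_dir))
}
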