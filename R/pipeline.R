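#' Build a pipeline configuration
#'
#' All knobs of the end-to-end synthetic study in one list; every
#' stochastic stage derives its own stream from the single `seed`.  The
#' configuration is serialized (YAML) into the output directory and its
#' MD5 hash is recorded in every summary, so any output can be traced to
#' the exact configuration that produced it.
#'
#' @param seed master integer seed.
#' @param ... overrides of the defaults listed below.
#' @return a named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # bulk simulation
    n_genes = 800L, n_stages = 8L, maturity_stage = 6L,
    reps_per_sex_stage = 2L, n_spiked = 80L, lfc_values = c(1, 2, 3),
    # calling
    alpha = 0.05, spline_df = 3L, poly_degree = 3L, window_n_perm = 500L,
    callers = c("spline", "factor", "poly", "window"),
    organ2_callers = c("poly", "window"),
    # onset
    onset_K = 0L, effect_threshold = 0.5,   # 0 = scan 2..8 by FPC elbow
    # conservation
    overlap_n_perm = 2000L, conserved_fraction = 0.5,
    ortholog_families = 4000L, ortholog_bias = 100L,
    # cells
    cell_n_genes = 1200L, cells_per_type_sex = 150L, cell_lfc = 2,
    cell_n_bias = 40L, module_n_bins = 24L, module_n_ctrl = 100L,
    # regulation
    region_window_bp = 3000L, region_target_fraction = 0.6,
    region_bg_fraction = 0.2)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("PipelineConfig", "list"))
}

#' Load a pipeline configuration from YAML
#'
#' @param file YAML path of overrides (field names as in
#'   [pipeline_config()]).
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(file) {
  over <- yaml::read_yaml(file)
  do.call(pipeline_config, over)
}

run_caller <- function(name, ts, cfg) {
  switch(name,
         spline = caller_spline_lrt(ts, df = cfg$spline_df,
                                    alpha = cfg$alpha),
         factor = caller_factor_lrt(ts, alpha = cfg$alpha),
         poly = caller_poly2step(ts, degree = cfg$poly_degree,
                                 alpha = cfg$alpha),
         window = caller_window_perm(ts, n_perm = cfg$window_n_perm,
                                     seed = derive_seed(cfg$seed, 61L),
                                     alpha = cfg$alpha),
         stop("unknown caller: ", name))
}

#' Run the full synthetic study end to end
#'
#' One seeded call reproduces the whole pipeline: bulk two-organ
#' simulation, the four-caller consensus with evaluation against truth,
#' onset classification, specificity and multi-organ summaries, adult
#' stage-wise calls and the extended set, ortholog conservation with a
#' permutation test, single-cell attribution, and regulatory-target
#' enrichment.  All tables are written as TSV, the truth as JSON, and a
#' `summary.json` collects the headline metrics; the output is
#' byte-stable given the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg <- config
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  summary <- list(config_hash = cfg_hash, seed = cfg$seed)

  ## organ 1: simulate, call, evaluate -----------------------------------
  sim1 <- stage("simulate_organ1", {
    design <- timeseries_design(n_genes = cfg$n_genes,
                                n_stages = cfg$n_stages,
                                maturity_stage = cfg$maturity_stage,
                                reps_per_sex_stage = cfg$reps_per_sex_stage,
                                seed = derive_seed(cfg$seed, 21L))
    spikes <- random_spikes(design, cfg$n_spiked, cfg$lfc_values,
                            seed = derive_seed(cfg$seed, 22L))
    simulate_timeseries(design, spikes)
  })
  ts1 <- normalize_counts(sim1$ts)
  write_counts(ts1, file.path(out_dir, "counts_organ1.tsv"),
               file.path(out_dir, "samples_organ1.tsv"))
  write_truth(sim1$truth, file.path(out_dir, "truth_organ1.json"))

  results1 <- stage("call_organ1",
    lapply(cfg$callers, run_caller, ts = ts1, cfg = cfg))
  calls1 <- suppressMessages(consensus(results1, alpha = cfg$alpha))
  write_calls(calls1, file.path(out_dir, "calls_organ1.tsv"))
  ev <- evaluate_calls(calls1, sim1$truth)
  summary$consensus <- list(
    n_called = sum(calls1$table$status != "unbiased"),
    sensitivity = ev$sensitivity, specificity = ev$specificity,
    fdp = ev$fdp, per_lfc_sensitivity = as.list(ev$per_lfc))

  ## adult stage-wise calls and extended set -----------------------------
  adult <- stage("adult_calls",
    stagewise_de(ts1, stages = cfg$n_stages, alpha = cfg$alpha))
  ext <- suppressMessages(extended_set(calls1, adult))
  write_calls(ext, file.path(out_dir, "calls_extended_organ1.tsv"))
  summary$extended <- list(
    n_called = sum(ext$table$status != "unbiased"),
    n_adult_only = sum(ext$table$provenance == "adult_only"))

  ## onset ----------------------------------------------------------------
  onset <- stage("onset", {
    genes <- calls1$table$gene[calls1$table$status != "unbiased"]
    if (length(genes) >= max(8, cfg$onset_K)) {
      tr <- difference_trajectories(ts1, genes)
      K <- if (cfg$onset_K > 0) cfg$onset_K
           else choose_k(tr$z, seed = derive_seed(cfg$seed, 23L))
      cl <- soft_cluster(tr$z, K,
                         seed = derive_seed(cfg$seed, 23L))
      classify_onset(cl, tr$stages, cfg$maturity_stage,
                     effect_threshold = cfg$effect_threshold)
    } else NULL
  })
  if (!is.null(onset)) {
    write.table(onset, file.path(out_dir, "onset_organ1.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth_cls <- c(always = "always_SB", pre_SM = "pre_SM",
                   post_SM = "post_SM")[sim1$truth$spikes$onset_class]
    names(truth_cls) <- sim1$truth$spikes$gene
    shared <- intersect(onset$gene, names(truth_cls))
    acc <- if (length(shared))
      mean(onset$class[match(shared, onset$gene)] == truth_cls[shared])
      else NA_real_
    summary$onset <- list(
      n_classified = sum(onset$class != "unassigned"),
      unassigned_fraction = mean(onset$class == "unassigned"),
      class_counts = as.list(table(onset$class)),
      accuracy_vs_truth = acc)
  }

  ## organ 2 (cheaper caller pair) + specificity --------------------------
  sim2 <- stage("simulate_organ2", {
    design2 <- timeseries_design(n_genes = cfg$n_genes,
                                 n_stages = cfg$n_stages,
                                 maturity_stage = cfg$maturity_stage,
                                 reps_per_sex_stage = cfg$reps_per_sex_stage,
                                 seed = derive_seed(cfg$seed, 24L))
    spikes2 <- random_spikes(design2, cfg$n_spiked %/% 2, cfg$lfc_values,
                             seed = derive_seed(cfg$seed, 25L))
    simulate_timeseries(design2, spikes2)
  })
  ts2 <- normalize_counts(sim2$ts)
  results2 <- stage("call_organ2",
    lapply(cfg$organ2_callers, run_caller, ts = ts2, cfg = cfg))
  calls2 <- suppressMessages(consensus(results2, alpha = cfg$alpha))

  specres <- stage("specificity", {
    om <- cbind(organ1 = rowMeans(norm_counts(ts1)),
                organ2 = rowMeans(norm_counts(ts2)))
    prof <- specificity_profile(om)
    ms <- multiorgan_summary(list(organ1 = calls1, organ2 = calls2))
    biased1 <- calls1$table$gene[calls1$table$status != "unbiased"]
    enr <- if (length(biased1))
      chromosome_enrichment(biased1, calls1$table$gene,
                            sim1$truth$chromosomes) else NULL
    list(prof = prof, ms = ms, enr = enr)
  })
  write.table(specres$prof, file.path(out_dir, "specificity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$specificity <- list(
    mean_tau = mean(specres$prof$tau, na.rm = TRUE),
    n_organ_specific = sum(specres$prof$organ_specific),
    n_multi_organ = sum(specres$ms$n_organs_biased >= 2),
    direction_consistent_fraction =
      if (any(specres$ms$n_organs_biased >= 2))
        mean(specres$ms$consistent[specres$ms$n_organs_biased >= 2])
      else NA_real_,
    sexchrom_p = specres$enr$p.value %||% NA_real_)

  ## conservation ---------------------------------------------------------
  cons <- stage("conservation", {
    orth <- simulate_orthologs(
      n_species = 2, n_families = cfg$ortholog_families,
      conserved_fraction = cfg$conserved_fraction,
      n_bias = cfg$ortholog_bias, seed = derive_seed(cfg$seed, 26L))
    fam1 <- match(orth$bias_sets$sp1, orth$map$sp1_gene)
    fam2 <- match(orth$bias_sets$sp2, orth$map$sp2_gene)
    univ_fam <- which(orth$map$relation == "1:1")
    ov <- permutation_overlap(
      intersect(fam1, univ_fam), intersect(fam2, univ_fam), univ_fam,
      n_perm = cfg$overlap_n_perm, seed = derive_seed(cfg$seed, 27L))
    # effect sizes: time-series vs adult-only calls in organ 1
    lfc_ts <- abs(ext$table$lfc[ext$table$provenance %in%
                                  c("time_series", "both")])
    lfc_ad <- abs(ext$table$lfc[ext$table$provenance == "adult_only"])
    esc <- if (length(lfc_ts) >= 2 && length(lfc_ad) >= 2)
      effect_size_compare(lfc_ts, lfc_ad) else NULL
    list(ov = ov, esc = esc)
  })
  summary$conservation <- list(
    observed_overlap = cons$ov$observed,
    expected_overlap = cons$ov$expected,
    permutation_p = cons$ov$p.value,
    effect_size_p = cons$esc$p.value %||% NA_real_)

  ## cells ----------------------------------------------------------------
  cellres <- stage("cells", {
    spec <- cell_sim_spec(n_genes = cfg$cell_n_genes,
                          n_cells_per_type_sex = cfg$cells_per_type_sex,
                          n_bias = cfg$cell_n_bias, lfc = cfg$cell_lfc,
                          seed = derive_seed(cfg$seed, 28L))
    sim <- simulate_cells(spec)
    sc_m <- module_score(sim$cells, sim$truth$male_set,
                         n_bins = cfg$module_n_bins,
                         n_ctrl = cfg$module_n_ctrl,
                         seed = derive_seed(cfg$seed, 29L))
    cmp <- suppressMessages(compare_by_sex(sc_m, sim$cells$meta))
    sw <- setwise_specificity(sc_m, sim$cells$meta)
    list(sim = sim, scores = sc_m, cmp = cmp, sw = sw)
  })
  write.table(cellres$cmp, file.path(out_dir, "cell_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig_types <- cellres$cmp$type[cellres$cmp$padj <= cfg$alpha]
  summary$cells <- list(
    significant_types = as.list(sig_types),
    dimorphic_detected =
      cellres$sim$truth$dimorphic_type %in% sig_types &&
      length(sig_types) == 1,
    top_type = cellres$sw$type[1],
    top_specific = cellres$sw$top_specific[1])

  ## regulation -----------------------------------------------------------
  regres <- stage("regulation", {
    genes <- rownames(ts1$counts)
    ann <- make_gene_annotation(length(genes),
                                seed = derive_seed(cfg$seed, 30L))
    ann$gene <- genes
    biased <- calls1$table$gene[calls1$table$status != "unbiased"]
    rest <- setdiff(genes, biased)
    set.seed(derive_seed(cfg$seed, 31L))
    targets <- c(sample(biased, round(cfg$region_target_fraction *
                                        length(biased))),
                 sample(rest, round(cfg$region_bg_fraction * length(rest))))
    regsim <- simulate_regions(ann, targets, n_decoys = 100,
                               window_bp = cfg$region_window_bp,
                               seed = derive_seed(cfg$seed, 32L))
    tm <- assign_targets(regsim$regions, ann,
                         window_bp = cfg$region_window_bp)
    enr <- target_enrichment(biased, list(tf = tm), genes)
    list(tm = tm, enr = enr)
  })
  summary$regulation <- list(
    bias_targeted_fraction = regres$enr$coverage$bias_fraction,
    universe_targeted_fraction = regres$enr$coverage$universe_fraction,
    odds_ratio = regres$enr$coverage$odds_ratio,
    p.value = regres$enr$coverage$p.value)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}
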