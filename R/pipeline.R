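# Full-analysis orchestration: simulate/load -> age -> PCA -> model ->
# permutation threshold -> classification -> enrichment -> introgression ->
# phenotype & survival, with TSV outputs, a run log, and (for synthetic
# input) a truth-comparison appendix.

#' Principal-component scores of the samples
#'
#' PCA of the sample x gene matrix of mean-centred log2 ratios. Component
#' signs are fixed by making each component's largest-magnitude gene
#' loading positive, so scores are deterministic.
#'
#' @param dataset a ratio-scale [expression_dataset()] (apply
#'   [mean_ratio_transform()] first)
#' @param n_components components to report (default 2)
#' @return object of class `PcaScores`: `scores` (data.frame sample_id,
#'   PC1, PC2, ...), `variance_fraction` (all components)
#' @export
pca_scores <- function(dataset, n_components = 2) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  stop_if(dataset$scale != "ratio",
          "PCA expects mean-ratio data; apply mean_ratio_transform() first")
  stop_if(ncol(dataset$matrix) < 3, "need at least 3 samples for PCA")
  X <- t(dataset$matrix)
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  k <- min(n_components, ncol(pr$x))
  scores <- data.frame(sample_id = rownames(X), pr$x[, seq_len(k),
                                                    drop = FALSE],
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(scores = scores, variance_fraction = vf),
            class = "PcaScores")
}

#' Configuration for a full pipeline run
#'
#' Exactly one of `sim_config` (synthetic run with recorded truth) or
#' `input` (list of file paths: `expression`, `sample_sheet`, `gene_map`,
#' `go_genes`, `go_terms`, `age_calibration`, optional `phenotypes`,
#' `survival`, `marker_genes`) must be supplied.
#'
#' @param sim_config a [simulation_config()], or NULL
#' @param input named list of input paths, or NULL
#' @param out_dir output directory (created if missing)
#' @param seed seed propagated to every stochastic stage
#' @param n_permutations permutations for the FDR stage
#' @param target_ratio FP/TP target
#' @param threshold_mode `"per_term"` or `"global"`
#' @param enrich_threshold -log10(p) cutoff defining enrichment groups
#' @param min_run minimum marker run for introgression intervals
#' @export
pipeline_config <- function(sim_config = NULL, input = NULL,
                            out_dir = tempfile("iltx_run_"), seed = 1,
                            n_permutations = 100, target_ratio = 0.05,
                            threshold_mode = "per_term",
                            enrich_threshold = 2, min_run = 3) {
  stop_if(is.null(sim_config) == is.null(input),
          "supply exactly one of sim_config or input")
  structure(list(sim_config = sim_config, input = input, out_dir = out_dir,
                 seed = seed, n_permutations = n_permutations,
                 target_ratio = target_ratio,
                 threshold_mode = threshold_mode,
                 enrich_threshold = enrich_threshold, min_run = min_run),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the arguments of [pipeline_config()] and
#' [simulation_config()] (simulation keys nested under `simulation:`).
#' @param path YAML file
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation))
    do.call(simulation_config, y$simulation)
  args <- y[setdiff(names(y), "simulation")]
  args$sim_config <- sim
  do.call(pipeline_config, args)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order, writes each stage's TSV
#' output plus a run log under `config$out_dir`, and returns the report
#' bundle. On synthetic input a truth-comparison appendix (false-discovery
#' proportions, age-recovery error, introgression boundary error) is
#' included. Identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()]
#' @return list of stage results (invisible components documented in the
#'   vignette)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste("iltx", as.character(utils::packageVersion("iltx"))),
                 R.version.string, paste("seed:", config$seed),
                 paste("started:", format(Sys.time())))

  truth <- NULL
  sim <- NULL
  if (!is.null(config$sim_config)) {
    sim_cfg <- config$sim_config
    sim_cfg$seed <- config$seed
    sim <- run_stage("simulate", {
      ex <- simulate_expression_experiment(sim_cfg)
      ex$go <- simulate_go_annotation(ex$truth, seed = config$seed + 3L)
      ex$phenotypes <- simulate_phenotypes(sim_cfg)
      ex$survival <- simulate_survival(sim_cfg)
      ex
    })
    dataset <- sim$dataset
    gmap <- sim$gene_map
    go <- sim$go
    calibration <- sim$calibration
    truth <- sim$truth
    phen <- sim$phenotypes$table
    surv <- sim$survival$table
    marker_genes <- truth$gene_id[truth$is_marker]
  } else {
    inp <- config$input
    loaded <- run_stage("load", load_dataset(
      inp$expression, inp$sample_sheet, inp$gene_map, inp$go_genes,
      inp$go_terms, quiet = TRUE))
    dataset <- loaded$dataset
    gmap <- loaded$gene_map
    go <- loaded$go
    calibration <- run_stage("load", read_age_calibration(inp$age_calibration))
    phen <- if (!is.null(inp$phenotypes)) read_phenotype_table(inp$phenotypes)
    surv <- if (!is.null(inp$survival)) read_survival_table(inp$survival)
    marker_genes <- if (!is.null(inp$marker_genes))
      utils::read.delim(inp$marker_genes, stringsAsFactors = FALSE)$gene_id
  }

  ages <- run_stage("age", estimate_sample_ages(dataset, calibration))
  write_results(ages, file.path(config$out_dir, "estimated_ages.tsv"))

  ratio_ds <- run_stage("transform", mean_ratio_transform(dataset))
  pca <- run_stage("pca", pca_scores(ratio_ds))
  write_results(pca$scores, file.path(config$out_dir, "pca_scores.tsv"))

  design <- run_stage("design", build_design_matrix(
    dataset$samples, ages$estimated_age_h))
  results <- run_stage("fit", fit_gene_models(ratio_ds, design))
  write_results(results, file.path(config$out_dir, "model_results.tsv"))

  plan <- permutation_plan(ncol(dataset$matrix),
                           n_permutations = config$n_permutations,
                           seed = config$seed + 10L)
  curve <- run_stage("permute", fdr_threshold_curve(results, plan, ratio_ds,
                                                    design))
  for (t in TERMS) {
    write_results(cbind(term = t, curve$terms[[t]]$table),
                  file.path(config$out_dir,
                            paste0("threshold_curve_", term_suffix[[t]],
                                   ".tsv")))
  }
  selection <- run_stage("select", select_threshold(
    curve, target_ratio = config$target_ratio, mode = config$threshold_mode))
  write_results(selection$selection,
                file.path(config$out_dir, "threshold_selection.tsv"))

  classes <- run_stage("classify", classify_genes(results, selection))
  write_results(classes$venn, file.path(config$out_dir, "venn_regions.tsv"))
  set_sizes <- data.frame(set = c(names(classes$sets), "aS_specific"),
                          n_genes = c(lengths(classes$sets),
                                      length(classes$aS_specific)))
  write_results(set_sizes, file.path(config$out_dir, "set_sizes.tsv"))

  enrich <- NULL
  if (!is.null(go)) {
    group <- run_stage("enrich", suppressWarnings(select_significant_genes(
      results, "aS", threshold = config$enrich_threshold)))
    enrich <- if (length(group) > 0)
      run_stage("enrich", hypergeometric_enrichment(
        group, go, universe_genes = results$gene_id))
    if (!is.null(enrich))
      write_results(enrich, file.path(config$out_dir, "enrichment_aS.tsv"))
  }

  intervals <- NULL
  if (!is.null(marker_genes) && length(marker_genes) > 0 &&
      !is.null(gmap)) {
    calls <- run_stage("introgress", call_marker_presence(
      dataset, marker_genes,
      reference_genotype = design$reference$genotype))
    intervals <- run_stage("introgress", detect_introgression_intervals(
      calls, gmap, min_run = config$min_run))
    if (nrow(intervals) > 0)
      write_results(intervals,
                    file.path(config$out_dir, "introgression_intervals.tsv"))
  }

  age_anova <- run_stage("age", age_contrast_summary(ages, dataset$samples))
  write_results(age_anova$table,
                file.path(config$out_dir, "age_anova.tsv"))

  phen_stats <- NULL
  if (!is.null(phen)) {
    phen_stats <- run_stage("phenotype", lapply(
      unique(phen$phenotype_name), function(ph) {
        list(phenotype = ph, anova = two_way_anova(phen, ph),
             tukey = tukey_within_genotype(phen, ph))
      }))
    names(phen_stats) <- unique(phen$phenotype_name)
    for (ph in names(phen_stats)) {
      write_results(phen_stats[[ph]]$anova$table,
                    file.path(config$out_dir, paste0("anova_", ph, ".tsv")))
      write_results(phen_stats[[ph]]$tukey,
                    file.path(config$out_dir, paste0("tukey_", ph, ".tsv")))
    }
  }

  surv_stats <- NULL
  if (!is.null(surv)) {
    surv_stats <- run_stage("survival", {
      genos <- unique(surv$genotype)
      per_geno <- lapply(genos, function(g) {
        lines <- unique(surv$line[surv$genotype == g])
        wt <- unique(surv$line[surv$genotype == g & surv$aS == 0])[1]
        as_ <- unique(surv$line[surv$genotype == g & surv$aS == 1])[1]
        list(genotype = g,
             km_wt = kaplan_meier(surv, wt),
             km_as = kaplan_meier(surv, as_),
             logrank = logrank(surv, wt, as_),
             bagging = bagging_rate_test(surv, g))
      })
      names(per_geno) <- genos
      per_geno
    })
    summ <- do.call(rbind, lapply(surv_stats, function(s) data.frame(
      genotype = s$genotype,
      mean_lifespan_wt = s$km_wt$mean_lifespan_days,
      mean_lifespan_as = s$km_as$mean_lifespan_days,
      logrank_p = s$logrank$p,
      bagging_diff_pct = s$bagging$difference_pct_points,
      bagging_p = s$bagging$p)))
    write_results(summ, file.path(config$out_dir, "survival_summary.tsv"))
  }

  appendix <- NULL
  if (!is.null(truth)) {
    appendix <- run_stage("truth_appendix", {
      fdp <- vapply(TERMS, function(t) {
        found <- classes$sets[[t]]
        if (length(found) == 0) return(NA_real_)
        truth_flag <- switch(t,
          age = truth$is_age, aS = truth$is_aS | truth$is_interaction,
          genotype = truth$is_genotype | truth$is_interaction,
          "aS:genotype" = truth$is_interaction)
        true_ids <- truth$gene_id[truth_flag]
        mean(!found %in% true_ids)
      }, 1.0)
      age_err <- mean(abs(ages$estimated_age_h - sim$samples$true_age_h))
      int_err <- NA_real_
      if (!is.null(intervals) && nrow(intervals) > 0) {
        blocks <- sim_block_table(config$sim_config %||% sim_cfg)
        errs <- interval_boundary_errors(intervals, blocks)
        int_err <- if (length(errs) > 0) mean(errs) else NA_real_
      }
      list(fdp = fdp, age_mae_h = age_err,
           interval_boundary_mae_mb = int_err)
    })
  }

  log_lines <- c(log_lines, paste("finished:", format(Sys.time())),
                 paste("genes:", nrow(dataset$matrix)),
                 paste("samples:", ncol(dataset$matrix)),
                 paste("permutations:", config$n_permutations))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(dataset = dataset, ages = ages, pca = pca,
                 design = design, results = results, curve = curve,
                 selection = selection, classes = classes,
                 enrichment = enrich, intervals = intervals,
                 age_anova = age_anova, phenotype_stats = phen_stats,
                 survival_stats = surv_stats, truth = truth,
                 appendix = appendix, out_dir = config$out_dir))
}

sim_block_table <- function(sim_cfg) sim_cfg$introgression_blocks

# mean absolute boundary error (Mb) of detected vs true blocks, matching
# each true block to the closest detected interval of the same line and
# chromosome
interval_boundary_errors <- function(intervals, blocks) {
  errs <- numeric(0)
  for (b in seq_len(nrow(blocks))) {
    hit <- intervals[intervals$line == blocks$genotype[b] &
                       intervals$chromosome == blocks$chromosome[b], ]
    if (nrow(hit) == 0) next
    mid <- (blocks$start_mb[b] + blocks$end_mb[b]) / 2
    i <- which.min(abs((hit$start_mb + hit$end_mb) / 2 - mid))
    errs <- c(errs, abs(hit$start_mb[i] - blocks$start_mb[b]),
              abs(hit$end_mb[i] - blocks$end_mb[b]))
  }
  errs
}
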