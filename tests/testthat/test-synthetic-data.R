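test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(n_genes = 300, n_age_genes = 30,
                           n_calibration_markers = 15, n_genotype_genes = 20,
                           n_as_genes = 20, n_interaction_genes = 10,
                           marker_chromosomes = "IV", seed = 11)
  a <- simulate_expression_experiment(cfg)
  b <- simulate_expression_experiment(cfg)
  expect_identical(a$dataset$matrix, b$dataset$matrix)
  expect_identical(a$gene_map, b$gene_map)
  expect_identical(simulate_phenotypes(cfg)$table,
                   simulate_phenotypes(cfg)$table)
  expect_identical(simulate_survival(cfg)$table,
                   simulate_survival(cfg)$table)
})

test_that("structural effects are exact when noise vanishes", {
  cfg <- simulation_config(n_genes = 100, n_age_genes = 10,
                           n_calibration_markers = 10, n_genotype_genes = 10,
                           n_as_genes = 10, n_interaction_genes = 0,
                           marker_chromosomes = character(0),
                           as_effect_size = 2, noise_sd = 1e-12, seed = 5)
  sim <- simulate_expression_experiment(cfg)
  tr <- sim$truth
  sm <- sim$dataset$samples
  for (gid in tr$gene_id[tr$is_aS]) {
    for (g in unique(as.character(sm$genotype))) {
      d <- mean(sim$dataset$matrix[gid, sm$genotype == g & sm$aS == 1]) -
        mean(sim$dataset$matrix[gid, sm$genotype == g & sm$aS == 0])
      expect_equal(d, tr$beta_aS[tr$gene_id == gid], tolerance = 1e-9)
    }
  }
})

test_that("truth-table bookkeeping matches the configured effect counts", {
  cfg <- simulation_config(n_genes = 2000, n_as_genes = 100, seed = 2)
  sim <- simulate_expression_experiment(cfg)
  expect_equal(sum(sim$truth$is_aS), 100)
  expect_equal(sum(sim$truth$is_age), cfg$n_age_genes)
  expect_equal(sum(sim$truth$is_age_marker), cfg$n_calibration_markers)
  expect_equal(sum(sim$truth$is_marker), nrow(cfg$marker_layout))
  expect_equal(nrow(sim$truth), 2000)
  expect_false(anyDuplicated(sim$truth$gene_id) > 0)
  # infeasible config
  expect_error(simulation_config(n_genes = 50), "exceed")
})

test_that("count phenotypes are non-negative integers; bad means error", {
  cfg <- simulation_config(n_genes = 100, n_age_genes = 0,
                           n_calibration_markers = 0, n_genotype_genes = 0,
                           n_as_genes = 0, n_interaction_genes = 0,
                           marker_chromosomes = character(0), seed = 3)
  ph <- simulate_phenotypes(cfg, n_per_group = 10)
  counts <- ph$table[ph$table$phenotype_name != "development_h", ]
  expect_true(all(counts$value >= 0))
  expect_true(all(counts$value == round(counts$value)))
  bad <- list(pumping_72h = list(base = rep(10, 5),
                                 as_shift = rep(-20, 5), sd = NA,
                                 duration_s = 60))
  expect_error(simulate_phenotypes(cfg, effects = bad), "negative structural")
})

test_that("aS-null phenotype simulations give uniform aS p-values", {
  cfg0 <- simulation_config(n_genes = 100, n_age_genes = 0,
                            n_calibration_markers = 0, n_genotype_genes = 0,
                            n_as_genes = 0, n_interaction_genes = 0,
                            marker_chromosomes = character(0))
  null_eff <- list(development_h = list(base = rep(60, 5),
                                        as_shift = rep(0, 5), sd = 2,
                                        duration_s = NA_real_))
  pvals <- vapply(1:100, function(s) {
    cfg0$seed <- s
    ph <- simulate_phenotypes(cfg0, n_per_group = 12, effects = null_eff)
    a <- two_way_anova(ph$table, "development_h")
    a$table$p[a$table$term == "aS"]
  }, 1.0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("survival generator honours censoring settings and effect sizes", {
  cfg <- simulation_config(n_genes = 100, n_age_genes = 0,
                           n_calibration_markers = 0, n_genotype_genes = 0,
                           n_as_genes = 0, n_interaction_genes = 0,
                           marker_chromosomes = character(0), seed = 9)
  sv <- simulate_survival(cfg, n_worms = 50, p_bag = 0, p_bag_wt = 0,
                          p_crawl = 0)
  expect_true(all(sv$table$event == "death"))
  expect_error(simulate_survival(cfg, p_bag = 1.5), "probabilities")
  # a scale ratio < 1 must shift the KM median down at large n
  sv2 <- simulate_survival(cfg, n_worms = 4000, p_bag = 0, p_bag_wt = 0,
                           p_crawl = 0,
                           as_scale_ratio = rep(0.8, 5))
  med <- function(line) stats::median(sv2$table$time_days[
    sv2$table$line == line])
  expect_lt(med("NL5901"), med("N2"))
})
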