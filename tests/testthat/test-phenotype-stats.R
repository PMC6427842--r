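test_that("the balanced fixture reproduces the hand-computed ANOVA table", {
  tab <- anova_fixture_table()
  a <- two_way_anova(tab, "devtime")
  at <- a$table
  # frozen textbook decomposition: SS 12/27/3, residual 8 on 8 df, MSE 1
  expect_equal(at$SS[at$term == "aS"], 12, tolerance = 1e-9)
  expect_equal(at$SS[at$term == "genotype"], 27, tolerance = 1e-9)
  expect_equal(at$SS[at$term == "aS:genotype"], 3, tolerance = 1e-9)
  expect_equal(at$SS[at$term == "residual"], 8, tolerance = 1e-9)
  expect_equal(at$F[at$term == "aS"], 12, tolerance = 1e-9)
  expect_equal(at$F[at$term == "genotype"], 27, tolerance = 1e-9)
  expect_equal(at$F[at$term == "aS:genotype"], 3, tolerance = 1e-9)
  # independent means-formula oracle
  oracle <- textbook_anova_2x2(tab$value, factor(tab$aS),
                               factor(tab$genotype))
  expect_equal(at$F[1:3], unname(oracle$F), tolerance = 1e-12)
  # SS decomposition identity on balanced data
  expect_equal(sum(at$SS), sum((tab$value - mean(tab$value))^2),
               tolerance = 1e-9)
})

test_that("Type II F values agree with car::Anova on unbalanced data", {
  set.seed(6)
  tab <- anova_fixture_table()
  tab <- tab[-c(1, 5), ]  # unbalance two cells
  tab$value <- tab$value + rnorm(nrow(tab), 0, 0.5)
  a <- two_way_anova(tab, "devtime")
  fit <- stats::lm(value ~ factor(aS) * factor(genotype), data = tab)
  ca <- car::Anova(fit, type = 2)
  expect_equal(a$table$F[a$table$term == "aS"], ca$`F value`[1],
               tolerance = 1e-9)
  expect_equal(a$table$F[a$table$term == "genotype"], ca$`F value`[2],
               tolerance = 1e-9)
  expect_equal(a$table$F[a$table$term == "aS:genotype"], ca$`F value`[3],
               tolerance = 1e-9)
})

test_that("degenerate phenotype tables are guarded", {
  tab <- anova_fixture_table()
  add <- tab$value * 0
  tab_additive <- tab
  # purely additive cell means: interaction SS must vanish
  cm <- c(A.0 = 10, A.1 = 12, B.0 = 8, B.1 = 10)
  tab_additive$value <- cm[paste(tab$genotype, tab$aS, sep = ".")] +
    rep(c(-1, 0, 1), 4)
  a <- two_way_anova(tab_additive, "devtime")
  expect_equal(a$table$SS[a$table$term == "aS:genotype"], 0,
               tolerance = 1e-9)
  flat <- tab
  flat$value <- 5
  expect_warning(af <- two_way_anova(flat, "devtime"), "identical")
  expect_true(all(af$table$p[1:3] == 1))
  gone <- tab[!(tab$genotype == "B" & tab$aS == 1), ]
  expect_error(two_way_anova(gone, "devtime"), "B/aS=1")
})

test_that("Tukey contrasts extract within-genotype transgene pairs", {
  set.seed(11)
  cfg <- simulation_config(n_genes = 100, n_age_genes = 0,
                           n_calibration_markers = 0, n_genotype_genes = 0,
                           n_as_genes = 0, n_interaction_genes = 0,
                           marker_chromosomes = character(0), seed = 11)
  eff <- list(devtime = list(base = rep(60, 5),
                             as_shift = c(0, 0, 0, 0, 2), sd = 1,
                             duration_s = NA_real_))
  ph <- simulate_phenotypes(cfg, n_per_group = 20, effects = eff)
  tk <- tukey_within_genotype(ph$table, "devtime")
  expect_equal(nrow(tk), 5)
  expect_lt(tk$adjusted_p[tk$genotype == "JU1941"], 0.01)
  expect_true(all(tk$adjusted_p[tk$genotype != "JU1941"] > 0.05))
  # family-wise adjusted p dominates the unadjusted p from the same
  # pooled-variance fit
  tab <- ph$table
  tab$group <- interaction(tab$genotype, tab$aS, drop = TRUE)
  fit <- stats::aov(value ~ group, data = tab)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  ns <- table(tab$group)
  se <- sqrt(mse * (1 / ns[["JU1941.0"]] + 1 / ns[["JU1941.1"]]))
  tstat <- abs(tk$difference[tk$genotype == "JU1941"]) / se
  unadj <- 2 * stats::pt(tstat, fit$df.residual, lower.tail = FALSE)
  expect_gte(tk$adjusted_p[tk$genotype == "JU1941"], unadj * (1 - 1e-9))
  # identical groups: adjusted p near 1
  eq <- anova_fixture_table()
  eq$value <- rep(c(1, 2, 3), 4)
  tk_eq <- tukey_within_genotype(eq, "devtime")
  expect_true(all(tk_eq$adjusted_p > 0.95))
  single <- anova_fixture_table()[c(1, 4, 7, 10, 2), ]
  expect_error(tukey_within_genotype(single, "devtime"), "single")
})

test_that("Kaplan-Meier estimates match hand product-limit computations", {
  mk <- function(times, events) {
    iltx:::validate_survival_table(data.frame(
      line = "L", genotype = "N2", aS = 0,
      worm_id = paste0("w", seq_along(times)), time_days = times,
      event = events))
  }
  km <- kaplan_meier(mk(c(5, 10), c("death", "death")), "L")
  expect_equal(km$surv, c(0.5, 0))
  expect_equal(km$mean_lifespan_days, 7.5)

  km2 <- kaplan_meier(mk(c(5, 7, 10), c("death", "bagging", "death")), "L")
  expect_equal(km2$surv[km2$time == 5], 2 / 3, tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 10], 0)
  expect_equal(km2$mean_lifespan_days, 7.5)  # deaths only

  # censoring-only tail leaves the curve flat
  km3 <- kaplan_meier(mk(c(5, 8, 9), c("death", "crawloff", "crawloff")),
                      "L")
  expect_equal(min(km3$surv), 2 / 3, tolerance = 1e-12)
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_warning(kaplan_meier(mk(c(3, 4), c("bagging", "crawloff")), "L"),
                 "no death")
})

test_that("log-rank matches the hand-computed O-E fixture and symmetries", {
  fx <- data.frame(line = rep(c("A", "B"), each = 5), genotype = "N2",
                   aS = rep(0:1, each = 5), worm_id = paste0("w", 1:10),
                   time_days = c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10),
                   event = "death")
  fx <- iltx:::validate_survival_table(fx)
  lr <- logrank(fx, "A", "B")
  expect_equal(lr$chisq, 3.4925156019, tolerance = 1e-9)
  expect_equal(lr$chisq, manual_logrank_chisq(c(1, 2, 3, 4, 5),
                                              c(2, 4, 6, 8, 10)),
               tolerance = 1e-12)
  # symmetry under group swap
  lr_swap <- logrank(fx, "B", "A")
  expect_equal(lr_swap$chisq, lr$chisq, tolerance = 1e-12)
  expect_equal(lr_swap$p, lr$p, tolerance = 1e-12)
  # identical event-time vectors: statistic 0, p 1
  fx_eq <- fx
  fx_eq$time_days <- rep(c(2, 4, 6, 8, 10), 2)
  lr_eq <- logrank(fx_eq, "A", "B")
  expect_equal(lr_eq$chisq, 0, tolerance = 1e-12)
  expect_equal(lr_eq$p, 1, tolerance = 1e-12)
  # time restriction administratively censors, it does not subset
  lr_r <- logrank(fx, "A", "B", restrict_days = 5)
  expect_true(is.finite(lr_r$chisq))
  expect_error(logrank(fx, "A", "B", restrict_days = 0.5), "no death")
})

test_that("bagging rates use the exact 2x2 test", {
  mk <- function(bag_a, n_a, bag_b, n_b) {
    iltx:::validate_survival_table(data.frame(
      line = rep(c("WT", "AS"), c(n_a, n_b)), genotype = "JU1511",
      aS = rep(c(0, 1), c(n_a, n_b)),
      worm_id = paste0("w", 1:(n_a + n_b)), time_days = 10,
      event = c(rep("bagging", bag_a), rep("death", n_a - bag_a),
                rep("bagging", bag_b), rep("death", n_b - bag_b))))
  }
  b0 <- bagging_rate_test(mk(0, 100, 0, 100), "JU1511")
  expect_equal(b0$difference_pct_points, 0)
  expect_equal(b0$p, 1)
  b1 <- bagging_rate_test(mk(10, 100, 30, 100), "JU1511")
  expect_equal(b1$difference_pct_points, 20)
  expect_equal(b1$p, enum_fisher_two_sided(30, 70, 10, 90),
               tolerance = 1e-9)
  # swapping lines negates the difference, p unchanged
  b2 <- bagging_rate_test(mk(30, 100, 10, 100), "JU1511")
  expect_equal(b2$difference_pct_points, -20)
  expect_equal(b2$p, b1$p, tolerance = 1e-12)
})
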