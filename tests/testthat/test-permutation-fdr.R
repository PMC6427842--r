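# helper: fabricate a ThresholdCurve with prescribed tau/TP/FP values
fake_curve <- function(tau, TP, FP, n_perm = 10) {
  obs <- rep(tau, TP - c(TP[-1], 0))  # observed nlp values realizing TP(tau)
  null_vals <- rep(tau, (FP - c(FP[-1], 0)) * n_perm)
  tab <- data.frame(tau = tau, TP = TP, FP = FP, ratio = FP / TP)
  structure(list(terms = list(aS = list(table = tab, obs_sorted = sort(obs),
                                        null_sorted = sort(null_vals))),
                 n_permutations = n_perm, n_genes = max(TP)),
            class = "ThresholdCurve")
}

test_that("permutations preserve value multisets and respect batches", {
  td <- toy_dataset(n_genes = 6, noise_sd = 1)
  plan <- permutation_plan(12, n_permutations = 20, seed = 4)
  plan_b <- permutation_plan(12, n_permutations = 20, seed = 4)
  expect_identical(plan$perms, plan_b$perms)  # seed determinism
  for (k in seq_len(20)) {
    perm_ds <- permute_sample_labels(plan, td$dataset, i = k)
    for (g in rownames(td$dataset$matrix))
      expect_identical(unname(sort(perm_ds$matrix[g, ])),
                       unname(sort(td$dataset$matrix[g, ])))
    expect_identical(perm_ds$samples, td$dataset$samples)
  }
  batch <- rep(c("x", "y"), each = 6)
  wb <- permutation_plan(12, n_permutations = 50, scheme = "within_batch",
                         seed = 1, batch = batch)
  for (k in seq_len(50))
    expect_identical(batch[wb$perms[k, ]], batch)
  expect_warning(permutation_plan(3, 5, scheme = "within_batch",
                                  batch = c("a", "b", "c")), "identity")
})

test_that("threshold curves behave correctly under the complete null", {
  td <- toy_dataset(n_genes = 800, noise_sd = 1, seed = 31)
  age <- rep(c(47, 48, 49), 4)
  des <- build_design_matrix(td$samples, age)
  res <- fit_gene_models(td$dataset, des)
  plan <- permutation_plan(12, n_permutations = 50, seed = 8)
  cur <- fdr_threshold_curve(res, plan, td$dataset, des)
  tab <- cur$terms$aS$table
  # FP at threshold zero counts every gene
  expect_equal(iltx:::eval_curve_at(cur, "aS", 0)[["FP"]], 800)
  expect_equal(iltx:::eval_curve_at(cur, "aS", 0)[["TP"]], 800)
  # monotone non-increasing in tau
  expect_true(all(diff(tab$TP) <= 0))
  expect_true(all(diff(tab$FP) <= 1e-9))
  # with no signal the FP/TP ratio is ~1 where counts are well estimated
  mid <- tab[tab$TP >= 100, ]
  expect_true(all(abs(mid$ratio - 1) < 0.3))
  expect_warning(
    fdr_threshold_curve(res, permutation_plan(12, 5, seed = 2), td$dataset,
                        des),
    "unstable")
})

test_that("an injected strong signal yields a clean threshold and ratio 0", {
  td <- toy_dataset(n_genes = 500, noise_sd = 1, seed = 77)
  ds <- td$dataset
  sig <- rownames(ds$matrix)[1:50]
  ds$matrix[sig, ] <- ds$matrix[sig, ] + 4 * rep(td$samples$aS,
                                                 each = length(sig))
  age <- rep(c(47, 48, 49), 4)
  des <- build_design_matrix(td$samples, age)
  res <- fit_gene_models(ds, des)
  plan <- permutation_plan(12, n_permutations = 40, seed = 5)
  cur <- fdr_threshold_curve(res, plan, ds, des)
  sel <- select_threshold(cur, target_ratio = 0.05)
  row <- sel$selection[sel$selection$term == "aS", ]
  expect_true(row$qualifies)
  expect_lte(row$ratio, 0.05)
  found <- suppressWarnings(classify_genes(res, sel))$sets$aS
  expect_gt(mean(sig %in% found), 0.9)
})

test_that("threshold selection picks the first qualifying tau", {
  cur <- fake_curve(tau = c(2, 3, 4), TP = c(100, 50, 10), FP = c(50, 2, 0.1))
  sel <- select_threshold(cur, target_ratio = 0.05, terms = "aS")
  expect_equal(sel$selection$tau, 3)
  expect_equal(sel$selection$ratio, 0.04)
  cur2 <- fake_curve(tau = c(2, 3), TP = c(100, 10), FP = c(90, 8))
  sel2 <- select_threshold(cur2, target_ratio = 0.05, terms = "aS")
  expect_false(sel2$selection$qualifies)
  expect_true(is.na(sel2$selection$tau))
})

test_that("classification implements the aS-specific definition and Venn sums", {
  genes <- paste0("g", 1:6)
  res <- data.frame(gene_id = genes,
                    nlp_age = c(5, 0, 0, 5, 0, 0),
                    nlp_aS = c(5, 5, 0, 0, 5, 0),
                    nlp_genotype = c(0, 0, 5, 0, 5, 0),
                    nlp_interaction = c(0, 0, 0, 0, 5, 0))
  class(res) <- c("TermTestResult", "data.frame")
  sel <- structure(list(selection = data.frame(
    term = iltx:::TERMS, tau = 3, ratio = 0.01, n_pass = 1,
    qualifies = TRUE), target_ratio = 0.05, mode = "per_term"),
    class = "ThresholdSelection")
  cl <- classify_genes(res, sel)
  expect_true("g2" %in% cl$aS_specific)        # aS only
  expect_false("g1" %in% cl$aS_specific)       # aS + age
  expect_false("g5" %in% cl$aS_specific)       # aS + genotype
  expect_true("g5" %in% cl$sets$aS)
  # Venn partition sums to the number of genes significant for >= 1 term
  n_any <- sum(apply(cl$membership, 1, any))
  venn_sum <- sum(cl$venn$Freq[cl$venn$region != "none"])
  expect_equal(venn_sum, n_any)
  # interaction-exclusion flag removes g5-like genes from specific set
  res2 <- res
  res2$nlp_age[2] <- 0
  res2$nlp_interaction[2] <- 5
  class(res2) <- c("TermTestResult", "data.frame")
  cl_keep <- classify_genes(res2, sel)
  cl_drop <- classify_genes(res2, sel,
                            exclude_interaction_from_specific = TRUE)
  expect_true("g2" %in% cl_keep$aS_specific)
  expect_false("g2" %in% cl_drop$aS_specific)
})
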