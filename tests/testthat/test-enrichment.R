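test_that("hypergeometric upper tail matches enumeration and phyper", {
  # the classical fully-overlapping case: P = 1 / C(10,5)
  expect_equal(hyper_upper_tail(5, 10, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(combn_hyper_upper(5, 10, 5, 5), 1 / 252, tolerance = 1e-12)
  # k = 0 is the certain event under P(X >= k)
  expect_equal(hyper_upper_tail(0, 10, 5, 5), 1)
  # brute-force draw enumeration on a handful of configurations
  for (case in list(c(2, 8, 3, 4), c(1, 12, 6, 2), c(4, 9, 5, 6))) {
    expect_equal(hyper_upper_tail(case[1], case[2], case[3], case[4]),
                 combn_hyper_upper(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  # exact-integer counting agreement over every configuration with N <= 12
  # (full N <= 20 sweep lives in the acceptance suite)
  for (N in 1:12) for (K in 0:N) for (n in 0:N) {
    for (k in 0:min(K, n)) {
      expect_equal(hyper_upper_tail(k, N, K, n), enum_hyper_upper(k, N, K, n),
                   tolerance = 1e-12)
    }
  }
  # independent library implementation as cross-check
  expect_equal(hyper_upper_tail(17, 2000, 60, 100),
               stats::phyper(16, 60, 1940, 100, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("group selection applies the strict -log10(p) cutoff", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    nlp_aS = -log10(c(0.005, 0.05, 0.011)))
  class(res) <- c("TermTestResult", "data.frame")
  expect_identical(select_significant_genes(res, "aS", 2), "a")
  expect_warning(select_significant_genes(res, "aS", 10), "no gene")
})

test_that("enrichment results have consistent counts and BH adjustment", {
  set.seed(14)
  universe <- sprintf("g%03d", 1:200)
  terms <- data.frame(go_id = c("GO:1", "GO:2", "GO:3"),
                      description = c("muscle contraction", "lipid transport",
                                      "innate immune response"),
                      type = c("BP", "BP", "BP"))
  gene2go <- rbind(
    data.frame(gene_id = universe[1:30], go_id = "GO:1"),
    data.frame(gene_id = universe[21:50], go_id = "GO:2"),
    data.frame(gene_id = universe[190:199], go_id = "GO:3"))
  go <- go_annotation(gene2go, terms)
  group <- universe[1:25]  # heavily overlaps GO:1
  res <- hypergeometric_enrichment(group, go, universe, universe = "all",
                                   min_overlap = 5)
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_true(all(res$adjusted_p >= res$p_value))
  expect_true(all(diff(res$p_value) >= 0))  # sorted by p
  expect_equal(res$N[1], 200)
  top <- res[1, ]
  expect_equal(top$go_id, "GO:1")
  expect_equal(top$p_value, hyper_upper_tail(top$k, 200, 30, 25),
               tolerance = 1e-12)
  # min_overlap gates reporting, not retention
  expect_true(all(c("GO:1", "GO:2", "GO:3") %in% res$go_id))
  expect_false(res$reported[res$go_id == "GO:3"])
  # annotated-gene universe shrinks N to annotated array genes
  res_ann <- hypergeometric_enrichment(group, go, universe,
                                       universe = "annotated")
  expect_equal(res_ann$N[1], length(unique(gene2go$gene_id)))
})

test_that("term p-values depend only on membership counts", {
  universe <- sprintf("g%03d", 1:60)
  terms <- data.frame(go_id = "GO:9", description = "d", type = "MF")
  p_for <- function(members, group) {
    go <- go_annotation(data.frame(gene_id = members, go_id = "GO:9"), terms)
    hypergeometric_enrichment(group, go, universe, universe = "all",
                              min_overlap = 1)$p_value
  }
  set.seed(3)
  group <- sample(universe, 15)
  members <- c(group[1:4], setdiff(universe, group)[1:8])
  relabelled <- c(group[5:8], setdiff(universe, group)[10:17])
  expect_equal(p_for(members, group), p_for(relabelled, group))
})

test_that("random groups give approximately uniform enrichment p-values", {
  universe <- sprintf("g%03d", 1:80)
  terms <- data.frame(go_id = "GO:7", description = "d", type = "CC")
  go <- go_annotation(data.frame(gene_id = universe[1:20], go_id = "GO:7"),
                      terms)
  set.seed(8)
  pvals <- vapply(1:500, function(i) {
    hypergeometric_enrichment(sample(universe, 25), go, universe,
                              universe = "all", min_overlap = 1)$p_value
  }, 1.0)
  # discrete p-values are super-uniform: P(p <= x) <= x must hold
  for (x in c(0.05, 0.1, 0.25, 0.5))
    expect_lt(mean(pvals <= x), x + 3 * sqrt(x * (1 - x) / 500))
})

test_that("BH adjustment follows the step-up rule and stays monotone", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(1, 4)), rep(1, 4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  set.seed(2)
  p <- runif(50)
  adj <- adjust_pvalues(p)
  expect_true(all(adj >= p - 1e-15))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))  # monotone in order statistics
})
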