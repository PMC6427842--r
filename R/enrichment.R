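# Hypergeometric GO-term enrichment on significance-defined gene groups.
#
# The upper-tail probability is computed directly from the distribution's
# definition: with N universe genes, K of them annotated to the term, and
# a group of n genes of which k are annotated,
#   P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n),
# evaluated with log-binomial coefficients for numerical stability.

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' @param k observed overlap
#' @param N universe size
#' @param K annotated genes in the universe
#' @param n group size
#' @export
hyper_upper_tail <- function(k, N, K, n) {
  stop_if(K > N || n > N || k < 0, "inconsistent hypergeometric parameters")
  if (k <= max(0, n + K - N)) return(1)
  i <- seq(k, min(K, n))
  if (length(i) == 0) return(0)
  min(1, sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))))
}

#' Select the significance-defined gene group for enrichment
#'
#' @param results `TermTestResult` from [fit_gene_models()]
#' @param term model term (`"aS"`, `"age"`, `"genotype"`,
#'   `"aS:genotype"`)
#' @param threshold cutoff on -log10(p); genes strictly above it join the
#'   group (default 2, i.e. p < 0.01)
#' @export
select_significant_genes <- function(results, term, threshold = 2) {
  stop_if(threshold <= 0, "threshold must be positive")
  stop_if(!term %in% TERMS, "unknown term: ", term)
  group <- results$gene_id[results[[nlp_col(term)]] > threshold]
  if (length(group) == 0)
    warning("no gene exceeds -log10(p) > ", threshold, " for term ", term)
  group
}

#' Hypergeometric GO-term enrichment of a gene group
#'
#' @param group gene ids to test (genes outside the universe are dropped
#'   with a message)
#' @param go a `GOAnnotation` (see [go_annotation()])
#' @param universe_genes all gene ids on the array
#' @param universe `"annotated"` restricts the universe to array genes
#'   with at least one GO annotation (default); `"all"` uses every array
#'   gene
#' @param min_overlap smallest group overlap for a term to enter the
#'   ranked report (smaller terms are retained with `reported = FALSE`)
#' @param adjust multiple-testing adjustment method for [adjust_pvalues()]
#' @return `EnrichmentResult` data.frame sorted by p-value: `go_id`,
#'   `description`, `type`, `K` (annotated in universe), `k` (annotated in
#'   group), `n` (group size), `N` (universe size), `p_value`,
#'   `adjusted_p`, `reported`
#' @export
hypergeometric_enrichment <- function(group, go, universe_genes,
                                      universe = c("annotated", "all"),
                                      min_overlap = 5, adjust = "BH") {
  stopifnot(inherits(go, "GOAnnotation"))
  universe <- match.arg(universe)
  stop_if(min_overlap < 1, "min_overlap must be >= 1")
  annotated <- unique(unlist(go$genes))
  uni <- if (universe == "annotated") intersect(universe_genes, annotated)
         else unique(universe_genes)
  dropped_ann <- length(setdiff(annotated, uni))
  if (dropped_ann > 0 && universe == "all")
    message(dropped_ann, " annotated gene(s) absent from the universe: ",
            "dropped from term counts")
  out_group <- setdiff(group, uni)
  if (length(out_group) > 0)
    message(length(out_group), " group gene(s) outside the universe: dropped")
  group <- intersect(group, uni)
  N <- length(uni)
  n <- length(group)
  res <- lapply(names(go$genes), function(id) {
    ann <- intersect(go$genes[[id]], uni)
    K <- length(ann)
    k <- length(intersect(ann, group))
    data.frame(go_id = id, K = K, k = k, n = n, N = N,
               p_value = hyper_upper_tail(k, N, K, n),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- merge(go$terms, res, by = "go_id", sort = FALSE)
  res$adjusted_p <- adjust_pvalues(res$p_value, method = adjust)
  res$reported <- res$k >= min_overlap
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Adjust p-values for multiple testing
#'
#' Default is the Benjamini-Hochberg step-up procedure.
#'
#' @param p vector of p-values in [0, 1]
#' @param method any method of [stats::p.adjust()]
#' @export
adjust_pvalues <- function(p, method = "BH") {
  stop_if(any(!is.finite(p)) || any(p < 0 | p > 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}
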