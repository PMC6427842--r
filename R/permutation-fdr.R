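# Permutation null, FP/TP-ratio threshold curve, threshold selection and
# significance-set (Venn) classification.
#
# The null is built by permuting whole sample columns of the expression
# matrix (one shared permutation per iteration, preserving gene-gene
# correlation) and refitting the identical factorial model; at a candidate
# threshold tau on the -log10(p) scale, FP(tau) is the mean permuted
# exceedance count and TP(tau) the observed one, so FP/TP estimates the
# false discovery rate realized at tau.

#' Plan a set of sample-label permutations
#'
#' @param n_samples number of samples (columns) to permute
#' @param n_permutations permutations to draw
#' @param scheme `"unrestricted"` permutes freely; `"within_batch"` only
#'   permutes samples within their batch
#' @param seed RNG seed
#' @param batch per-sample batch labels (required for `within_batch`)
#' @return object of class `PermutationPlan` with element `perms`, an
#'   n_permutations x n_samples matrix of sample-index orderings
#' @export
permutation_plan <- function(n_samples, n_permutations = 100,
                             scheme = c("unrestricted", "within_batch"),
                             seed = 1, batch = NULL) {
  scheme <- match.arg(scheme)
  stop_if(n_permutations < 1, "need at least one permutation")
  if (scheme == "within_batch") {
    stop_if(is.null(batch), "within_batch scheme needs batch labels")
    stop_if(length(batch) != n_samples, "one batch label per sample")
    if (all(table(batch) == 1))
      warning("all batches are singletons: every permutation is identity")
  }
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_permutations), function(i) {
      if (scheme == "unrestricted") {
        sample.int(n_samples)
      } else {
        out <- seq_len(n_samples)
        for (b in unique(batch)) {
          idx <- which(batch == b)
          if (length(idx) > 1) out[idx] <- idx[sample.int(length(idx))]
        }
        out
      }
    }, integer(n_samples)))
  })
  structure(list(perms = perms, scheme = scheme, seed = seed,
                 n_permutations = n_permutations, batch = batch),
            class = "PermutationPlan")
}

#' Apply the planned permutations to a dataset
#'
#' Each permutation reassigns whole expression columns to the (fixed)
#' sample metadata, breaking the sample-to-metadata link while preserving
#' every gene's value multiset and the gene-gene correlation structure.
#'
#' @param plan a [permutation_plan()]
#' @param dataset an [expression_dataset()]
#' @param i permutation index; if `NULL`, a list of all permuted datasets
#'   is returned (intended for small studies and tests --
#'   [fdr_threshold_curve()] streams internally instead)
#' @export
permute_sample_labels <- function(plan, dataset, i = NULL) {
  stopifnot(inherits(plan, "PermutationPlan"),
            inherits(dataset, "ExpressionDataset"))
  stop_if(ncol(plan$perms) != ncol(dataset$matrix),
          "plan and dataset sample counts differ")
  one <- function(k) {
    out <- dataset
    out$matrix <- dataset$matrix[, plan$perms[k, ], drop = FALSE]
    colnames(out$matrix) <- colnames(dataset$matrix)
    out
  }
  if (!is.null(i)) return(one(i))
  lapply(seq_len(nrow(plan$perms)), one)
}

#' Permutation FP/TP threshold curve
#'
#' Refits the factorial model once per permutation and tabulates, for each
#' model term and each candidate threshold tau (the sorted unique observed
#' -log10 p values), the observed exceedance count TP(tau), the mean
#' permuted exceedance count FP(tau), and their ratio.
#'
#' @param observed `TermTestResult` from [fit_gene_models()] on the
#'   unpermuted data
#' @param plan a [permutation_plan()]
#' @param dataset the dataset the observed results were computed on
#' @param design the same [build_design_matrix()]
#' @return object of class `ThresholdCurve`: per-term data.frames with
#'   columns `tau`, `TP`, `FP`, `ratio`, plus the sorted permuted null
#'   values used to evaluate FP at arbitrary thresholds
#' @export
fdr_threshold_curve <- function(observed, plan, dataset, design) {
  stopifnot(inherits(observed, "TermTestResult"),
            inherits(plan, "PermutationPlan"))
  if (plan$n_permutations < 10)
    warning("fewer than 10 permutations: FP/TP ratios will be unstable")
  Y <- t(dataset$matrix)
  n_perm <- plan$n_permutations
  perm_nlp <- stats::setNames(vector("list", length(TERMS)), TERMS)
  for (k in seq_len(n_perm)) {
    ft <- term_f_tests(Y[plan$perms[k, ], , drop = FALSE], design)
    for (t in TERMS) perm_nlp[[t]][[k]] <- -ft$log10p[, t]
  }
  curve <- list()
  for (t in TERMS) {
    obs <- sort(observed[[nlp_col(t)]])
    null_sorted <- sort(unlist(perm_nlp[[t]]))
    tau <- unique(obs)
    TP <- length(obs) - findInterval(tau, obs, left.open = TRUE)
    FP <- (length(null_sorted) -
             findInterval(tau, null_sorted, left.open = TRUE)) / n_perm
    curve[[t]] <- list(
      table = data.frame(tau = tau, TP = TP, FP = FP, ratio = FP / TP),
      obs_sorted = obs, null_sorted = null_sorted)
  }
  structure(list(terms = curve, n_permutations = n_perm,
                 n_genes = nrow(observed)),
            class = "ThresholdCurve")
}

# TP, FP and ratio for one term at an arbitrary threshold
eval_curve_at <- function(curve, term, tau) {
  tc <- curve$terms[[term]]
  TP <- length(tc$obs_sorted) -
    findInterval(tau, tc$obs_sorted, left.open = TRUE)
  FP <- (length(tc$null_sorted) -
           findInterval(tau, tc$null_sorted, left.open = TRUE)) /
    curve$n_permutations
  c(TP = TP, FP = FP, ratio = if (TP > 0) FP / TP else NA_real_)
}

#' Select the significance threshold from an FP/TP curve
#'
#' `per_term` mode picks, independently for each term, the smallest tau on
#' the candidate grid whose FP/TP ratio is at or below the target;
#' `global` mode picks the smallest tau that satisfies the target
#' simultaneously for all designated terms, mirroring a single
#' "for convenience" threshold shared across terms. The realized per-term
#' ratios at the chosen tau are the empirical FDRs. Thresholds where
#' TP = 0 are skipped (the ratio is undefined there).
#'
#' @param curve a [fdr_threshold_curve()]
#' @param target_ratio FP/TP target (default 0.05)
#' @param mode `"per_term"` or `"global"`
#' @param terms terms to consider (default all four)
#' @return object of class `ThresholdSelection`: data.frame with one row
#'   per term (`term`, `tau`, `ratio`, `n_pass`, `qualifies`); a term (or,
#'   in global mode, the study) with no qualifying tau gets
#'   `qualifies = FALSE` and `tau = NA` rather than an error.
#' @export
select_threshold <- function(curve, target_ratio = 0.05,
                             mode = c("per_term", "global"), terms = TERMS) {
  stopifnot(inherits(curve, "ThresholdCurve"))
  mode <- match.arg(mode)
  rows <- list()
  if (mode == "per_term") {
    for (t in terms) {
      tab <- curve$terms[[t]]$table
      ok <- which(tab$TP > 0 & tab$ratio <= target_ratio)
      if (length(ok) > 0) {
        i <- ok[1]  # grid is ascending in tau
        rows[[t]] <- data.frame(term = t, tau = tab$tau[i],
                                ratio = tab$ratio[i], n_pass = tab$TP[i],
                                qualifies = TRUE)
      } else {
        rows[[t]] <- data.frame(term = t, tau = NA_real_, ratio = NA_real_,
                                n_pass = 0L, qualifies = FALSE)
      }
    }
  } else {
    grid <- sort(unique(unlist(lapply(curve$terms[terms],
                                      function(tc) tc$table$tau))))
    chosen <- NA_real_
    for (tau in grid) {
      vals <- vapply(terms, function(t) eval_curve_at(curve, t, tau)["ratio"],
                     1.0)
      defined <- !is.na(vals)
      if (any(defined) && all(vals[defined] <= target_ratio)) {
        chosen <- tau
        break
      }
    }
    for (t in terms) {
      if (is.na(chosen)) {
        rows[[t]] <- data.frame(term = t, tau = NA_real_, ratio = NA_real_,
                                n_pass = 0L, qualifies = FALSE)
      } else {
        v <- eval_curve_at(curve, t, chosen)
        rows[[t]] <- data.frame(term = t, tau = chosen,
                                ratio = unname(v["ratio"]),
                                n_pass = as.integer(v["TP"]),
                                qualifies = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(selection = out, target_ratio = target_ratio, mode = mode),
            class = "ThresholdSelection")
}

#' @export
print.ThresholdSelection <- function(x, ...) {
  cat("ThresholdSelection (mode ", x$mode, ", target FP/TP ",
      x$target_ratio, "):\n", sep = "")
  print(x$selection)
  invisible(x)
}

#' Classify genes into significance sets
#'
#' A gene joins a term's set iff its -log10(p) for that term is at or
#' above the selected threshold (ties move together). The `aS_specific`
#' set is the aS set minus the Age and Genotype sets; by default genes
#' that are also interaction-significant remain in it, controlled by
#' `exclude_interaction_from_specific`.
#'
#' @param results `TermTestResult`
#' @param selection a [select_threshold()] result
#' @param exclude_interaction_from_specific also remove
#'   interaction-significant genes from the aS-specific set
#' @return list with `sets` (named list of gene-id vectors, one per term),
#'   `aS_specific`, `venn` (counts of all 16 membership regions), and
#'   `thresholds`
#' @export
classify_genes <- function(results, selection,
                           exclude_interaction_from_specific = FALSE) {
  stopifnot(inherits(results, "TermTestResult"),
            inherits(selection, "ThresholdSelection"))
  sel <- selection$selection
  stop_if(!any(sel$qualifies), "no term has a usable threshold")
  member <- matrix(FALSE, nrow(results), length(TERMS),
                   dimnames = list(results$gene_id, TERMS))
  for (t in TERMS) {
    row <- sel[sel$term == t, ]
    if (nrow(row) == 0 || !row$qualifies) {
      warning("no usable threshold for term '", t, "': empty set")
      next
    }
    member[, t] <- results[[nlp_col(t)]] >= row$tau
  }
  sets <- lapply(TERMS, function(t) results$gene_id[member[, t]])
  names(sets) <- TERMS
  spec <- setdiff(sets[["aS"]], union(sets[["age"]], sets[["genotype"]]))
  if (exclude_interaction_from_specific)
    spec <- setdiff(spec, sets[["aS:genotype"]])
  labs <- c("Age", "aS", "GB", "aSxGB")  # in TERMS order
  region <- apply(member, 1, function(m)
    if (any(m)) paste(labs[m], collapse = "+") else "none")
  venn <- as.data.frame(table(region = region), stringsAsFactors = FALSE)
  list(sets = sets, aS_specific = spec, venn = venn,
       thresholds = sel, membership = member)
}
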