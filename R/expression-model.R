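# Per-gene factorial linear model: expression ~ age + aS * genotype,
# fitted by OLS for every gene with per-term Type II F tests.

TERMS <- c("age", "aS", "genotype", "aS:genotype")

# results-table column suffix for each model term
term_suffix <- c(age = "age", aS = "aS", genotype = "genotype",
                 "aS:genotype" = "interaction")

nlp_col <- function(term) paste0("nlp_", term_suffix[[term]])
p_col <- function(term) paste0("p_", term_suffix[[term]])
f_col <- function(term) paste0("F_", term_suffix[[term]])

#' Build the factorial design matrix
#'
#' Treatment coding with a declared reference level (default N2, aS = 0):
#' intercept, a centred continuous age covariate, the transgene flag, G-1
#' genotype dummies and G-1 aS:genotype interaction dummies.
#'
#' @param samples sample metadata (`samples` element of an
#'   [expression_dataset()], or any data.frame with `sample_id`,
#'   `genotype`, `aS`)
#' @param age per-sample developmental age (h); typically the estimates
#'   from [estimate_sample_ages()]
#' @param reference_genotype reference level; defaults to `"N2"` when
#'   present, otherwise the first level
#' @return object of class `DesignMatrix`: list with the model matrix `X`,
#'   `terms` (term -> column indices), `sample_ids`, `reference`
#' @export
build_design_matrix <- function(samples, age, reference_genotype = NULL) {
  samples <- as.data.frame(samples)
  stop_if(length(age) != nrow(samples),
          "`age` must have one value per sample")
  stop_if(any(!is.finite(age)), "ages must be finite")
  geno <- factor(as.character(samples$genotype))
  stop_if(nlevels(geno) < 2, "need at least 2 genotype levels")
  if (is.null(reference_genotype))
    reference_genotype <- if ("N2" %in% levels(geno)) "N2" else levels(geno)[1]
  geno <- stats::relevel(geno, ref = reference_genotype)
  aS <- as.integer(samples$aS)
  stop_if(length(unique(aS)) < 2,
          "design is rank deficient: aS has a single level")
  cells <- table(geno, aS)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_if(TRUE, "empty design cell(s): ",
            paste(rownames(cells)[empty[, 1]], "/aS=",
                  colnames(cells)[empty[, 2]], sep = "", collapse = ", "))
  }
  stop_if(stats::var(age) == 0,
          "age covariate has no variation across samples")

  age_c <- age - mean(age)
  G <- nlevels(geno)
  geno_dummies <- stats::model.matrix(~geno)[, -1, drop = FALSE]
  colnames(geno_dummies) <- paste0("genotype", levels(geno)[-1])
  int_dummies <- geno_dummies * aS
  colnames(int_dummies) <- paste0("aS:genotype", levels(geno)[-1])
  X <- cbind(`(Intercept)` = 1, age = age_c, aS = aS, geno_dummies,
             int_dummies)
  rownames(X) <- as.character(samples$sample_id)
  terms <- list(age = 2L, aS = 3L, genotype = 3L + seq_len(G - 1),
                "aS:genotype" = 3L + (G - 1) + seq_len(G - 1))
  stop_if(qr(X)$rank < ncol(X),
          "design matrix is rank deficient (collinear covariates)")
  structure(list(X = X, terms = terms,
                 sample_ids = as.character(samples$sample_id),
                 reference = list(genotype = reference_genotype, aS = 0L),
                 age = age),
            class = "DesignMatrix")
}

# Per-term Type II F tests for every response column of Y (samples x genes),
# against the full-model residual. Main effects are tested with the
# interaction excluded from both nested models; the interaction is tested
# as full vs main-effects model. Returns F, log10(p) and coefficients.
term_f_tests <- function(Y, design) {
  X <- design$X
  n <- nrow(X)
  qr_full <- qr(X)
  df_res <- n - qr_full$rank
  stop_if(df_res <= 0, "no residual degrees of freedom")
  rss_full <- qr_rss(qr_full, Y)
  idx_main <- c(1L, design$terms$age, design$terms$aS, design$terms$genotype)
  rss_main <- qr_rss(qr(X[, idx_main, drop = FALSE]), Y)

  df_term <- vapply(design$terms, length, 1L)
  delta <- matrix(NA_real_, ncol(Y), length(TERMS),
                  dimnames = list(NULL, TERMS))
  for (t in c("age", "aS", "genotype")) {
    idx <- setdiff(idx_main, design$terms[[t]])
    delta[, t] <- pmax(qr_rss(qr(X[, idx, drop = FALSE]), Y) - rss_main, 0)
  }
  delta[, "aS:genotype"] <- pmax(rss_main - rss_full, 0)

  mse <- rss_full / df_res
  tot_ss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  const <- tot_ss < 1e-12 * pmax(1, colSums(Y^2) / n)

  Fm <- matrix(NA_real_, ncol(Y), length(TERMS),
               dimnames = list(NULL, TERMS))
  log10p <- Fm
  for (t in TERMS) {
    f <- (delta[, t] / df_term[[t]]) / mse
    # 0/0 (e.g. noiseless gene with no effect on this term) -> no evidence
    f[!is.finite(f) & delta[, t] <= .Machine$double.eps * tot_ss] <- 0
    f[is.nan(f)] <- 0
    lp <- stats::pf(f, df_term[[t]], df_res, lower.tail = FALSE,
                    log.p = TRUE) / log(10)
    lp[is.infinite(f)] <- -Inf
    f[const] <- 0
    lp[const] <- 0
    Fm[, t] <- f
    log10p[, t] <- lp
  }
  if (any(const))
    warning(sum(const), " constant gene(s): p set to 1 for all terms")
  beta <- qr.coef(qr_full, Y)
  list(F = Fm, log10p = log10p, beta = beta, df_term = df_term,
       df_res = df_res, rss_full = rss_full)
}

#' Fit the factorial model gene by gene
#'
#' Ordinary least squares per gene with Type II sum-of-squares F tests:
#' each main effect (age, aS, genotype) is tested by comparing the
#' main-effects model with and without that term; the aS x genotype
#' interaction is tested against the full model. All F tests use the full
#' model's residual mean square.
#'
#' @param dataset an [expression_dataset()]
#' @param design a [build_design_matrix()] whose rows align with the
#'   dataset samples
#' @return a `TermTestResult` data.frame: `gene_id`, then per term
#'   `F_<term>`, `p_<term>`, `nlp_<term>` (-log10 p) for age, aS, genotype
#'   and interaction, then the full-model coefficient estimates (log2
#'   units) as `b_<coefficient>` columns.
#' @export
fit_gene_models <- function(dataset, design) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(design, "DesignMatrix"))
  stop_if(!identical(design$sample_ids, colnames(dataset$matrix)),
          "design rows do not align with dataset samples")
  Y <- t(dataset$matrix)
  ft <- term_f_tests(Y, design)
  out <- data.frame(gene_id = rownames(dataset$matrix),
                    stringsAsFactors = FALSE)
  for (t in TERMS) {
    out[[f_col(t)]] <- ft$F[, t]
    out[[p_col(t)]] <- 10^ft$log10p[, t]
    out[[nlp_col(t)]] <- -ft$log10p[, t]
  }
  bt <- t(ft$beta)
  colnames(bt) <- paste0("b_", gsub("[^A-Za-z0-9_.]", "_", colnames(bt)))
  out <- cbind(out, as.data.frame(bt, optional = TRUE))
  rownames(out) <- NULL
  attr(out, "df_term") <- ft$df_term
  attr(out, "df_res") <- ft$df_res
  class(out) <- c("TermTestResult", "data.frame")
  out
}

#' Centre each gene on its across-sample mean
#'
#' Converts log2 intensities to "log2 ratios with the mean": every gene
#' row has its mean subtracted, so all output row means are zero. Guarded
#' against double application.
#'
#' @param dataset an intensity-scale [expression_dataset()]
#' @return the dataset on the ratio scale
#' @export
mean_ratio_transform <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  stop_if(dataset$scale == "ratio",
          "dataset is already on the mean-ratio scale")
  dataset$matrix <- dataset$matrix - rowMeans(dataset$matrix)
  dataset$scale <- "ratio"
  dataset
}
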