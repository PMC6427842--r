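# Independent oracles and small fixture builders shared across tests.
# Each oracle recomputes a quantity from first principles (enumeration,
# textbook formulas) so it stays independent of the package code paths
# it checks.

# Exhaustive-counting hypergeometric upper tail: exact integer arithmetic,
# valid for N <= 20 (all counts < 2^53).
enum_hyper_upper <- function(k, N, K, n) {
  if (k <= max(0, n + K - N)) return(1)
  i <- seq(k, min(K, n))
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force enumeration over every possible draw of n from N, counting
# draws whose overlap with the K annotated genes is >= k.
combn_hyper_upper <- function(k, N, K, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)  # genes 1..K are the annotated ones
}

# Textbook log-rank O-E chi-square for two samples of death times
# (no censoring), summing over distinct event times.
manual_logrank_chisq <- function(times_a, times_b) {
  times <- sort(unique(c(times_a, times_b)))
  U <- 0
  V <- 0
  for (t in times) {
    n1 <- sum(times_a >= t)
    n2 <- sum(times_b >= t)
    nj <- n1 + n2
    d1 <- sum(times_a == t)
    d <- d1 + sum(times_b == t)
    U <- U + d1 - d * n1 / nj
    if (nj > 1) V <- V + d * (n1 / nj) * (n2 / nj) * (nj - d) / (nj - 1)
  }
  U^2 / V
}

# Two-sided Fisher exact p by enumeration of the 2x2 tables with the
# observed margins: sum P(X = k) over k with probability <= observed.
enum_fisher_two_sided <- function(a, b, c, d) {
  # table: rbind(c(a, b), c(c, d)); margins fixed
  m <- a + c
  n_ <- b + d
  kk <- a + b
  support <- max(0, kk - n_):min(kk, m)
  probs <- stats::dhyper(support, m, n_, kk)
  p_obs <- stats::dhyper(a, m, n_, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Balanced 2x2x r factorial ANOVA by the classical means formulas.
textbook_anova_2x2 <- function(values, fA, fB) {
  gm <- mean(values)
  mA <- tapply(values, fA, mean)
  mB <- tapply(values, fB, mean)
  mAB <- tapply(values, interaction(fA, fB), mean)
  nA <- length(values) / 2
  r <- length(values) / 4
  ss_A <- nA * sum((mA - gm)^2)
  ss_B <- nA * sum((mB - gm)^2)
  cell <- expand.grid(A = names(mA), B = names(mB))
  dev <- mAB[paste(cell$A, cell$B, sep = ".")] - mA[cell$A] - mB[cell$B] + gm
  ss_AB <- r * sum(dev^2)
  ss_res <- sum((values - mAB[interaction(fA, fB)])^2)
  list(ss = c(A = ss_A, B = ss_B, AB = unname(ss_AB), res = ss_res),
       F = c(A = ss_A / (ss_res / (length(values) - 4)),
             B = ss_B / (ss_res / (length(values) - 4)),
             AB = unname(ss_AB) / (ss_res / (length(values) - 4))))
}

# Frozen balanced 2x2x3 phenotype fixture. Cell means 10/13/8/9,
# within-cell SS 2 each, so SS(aS) = 12, SS(genotype) = 27,
# SS(interaction) = 3, SS(residual) = 8 (df 8, MSE 1) and F = 12/27/3.
anova_fixture_table <- function() {
  vals <- c(10, 11, 9,    # A, WT
            12, 13, 14,   # A, aS
            8, 9, 7,      # B, WT
            9, 8, 10)     # B, aS
  data.frame(line = rep(c("A", "A_as", "B", "B_as"), each = 3),
             genotype = rep(c("A", "A", "B", "B"), each = 3),
             aS = rep(c(0L, 1L, 0L, 1L), each = 3),
             replicate = rep(paste0("rep", 1:3), 4),
             phenotype_name = "devtime",
             value = vals, duration_s = NA_real_,
             stringsAsFactors = FALSE)
}

# Expression dataset carrying the same fixture values in one gene, with an
# age covariate orthogonal to all factorial columns (within-cell pattern
# (1, -2, 1) is orthogonal to the centred ages (-1, 0, 1)).
anova_fixture_dataset <- function() {
  tab <- anova_fixture_table()
  samples <- data.frame(sample_id = paste0("s", 1:12),
                        genotype = tab$genotype, aS = tab$aS,
                        batch = tab$replicate, stringsAsFactors = FALSE)
  m <- matrix(tab$value, nrow = 1,
              dimnames = list("gene_fix", samples$sample_id))
  list(dataset = expression_dataset(m, samples),
       age = rep(c(47, 48, 49), 4))
}

# Small dataset with explicit per-gene structure for design/fit tests.
toy_dataset <- function(n_genes = 5, genotypes = c("N2", "JU1511"),
                        reps = 3, seed = 42, noise_sd = 0) {
  cells <- expand.grid(rep = seq_len(reps), aS = 0:1, genotype = genotypes,
                       stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0(cells$genotype, "_", cells$aS, "_", cells$rep),
    genotype = cells$genotype, aS = cells$aS,
    batch = paste0("b", cells$rep), stringsAsFactors = FALSE)
  set.seed(seed)
  m <- matrix(rnorm(n_genes * nrow(samples), sd = max(noise_sd, 1e-12)),
              nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              samples$sample_id))
  list(dataset = expression_dataset(m + 6, samples), samples = samples)
}
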