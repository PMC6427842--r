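# Synthetic experiment generator with recorded ground truth.
#
# The generator realizes the structural model the analysis stages assume:
#   x_gj = baseline_g + beta_age_g (age_j - 46) + beta_GB_g[genotype_j]
#          + beta_aS_g aS_j + beta_int_g[genotype_j] aS_j + N(0, noise_sd),
# on the log2-intensity scale, for a factorial design of genetic
# backgrounds x transgene state x replicates. Wild-isolate marker genes
# additionally carry background-specific offsets that are reset to the
# reference (N2) level inside each introgression line's introgressed block,
# which is what the marker-based interval mapping detects.

# approximate C. elegans chromosome lengths (Mb)
CHROM_LENGTH_MB <- c(I = 15.1, II = 15.3, III = 13.8, IV = 17.5, V = 20.9,
                     X = 17.7)

#' Configuration for the synthetic experiment generator
#'
#' Defaults emulate the study design the package targets: 5 genetic
#' backgrounds (N2 plus four wild isolates) x wild-type/transgenic x 3
#' replicates sampled at 48 h chronological age, with transgenic lines
#' developmentally delayed by up to 2.5 h inside the 46-54 h calibration
#' window, i.i.d. Gaussian noise (sd 0.25 log2 units), and an introgressed
#' reference-genome block spanning 4.2-13.2 Mb of chromosome IV in every
#' introgression line (plus an extra block on V in the JU1931 background).
#'
#' @param n_genes total genes simulated
#' @param genotypes genetic background labels; the first is the reference
#' @param n_replicates replicates per (genotype, aS) cell
#' @param age_window_h calibration window (h) for age-responsive markers
#' @param chronological_age_h sampling time (h since egg isolation)
#' @param age_offsets_h data.frame(genotype, aS, offset_h): developmental
#'   age offset of each design cell relative to `chronological_age_h`.
#'   Default: wild-type cells 0, transgenic cells between -0.3 and
#'   -1.75 h (delayed development, up to 2 h including replicate jitter);
#'   every resulting developmental age must stay
#'   inside `age_window_h`, where marker linearity holds. Larger delays
#'   (up to the 2.5 h scale of the emulated study) are available by also
#'   raising `chronological_age_h`.
#' @param age_replicate_jitter_h half-width (h) of the deterministic
#'   replicate-to-replicate developmental spread: replicate r of every
#'   cell is shifted by an evenly spaced offset in
#'   `[-jitter, +jitter]`. Mirrors batch-wise growth differences and
#'   makes the age covariate identifiable within cells.
#' @param n_age_genes genes with a linear age response
#' @param n_calibration_markers class-I age markers (subset of the age
#'   genes) with strictly positive slopes, used for age estimation
#' @param n_genotype_genes genes with background-specific expression
#' @param n_as_genes genes with a transgene (aS) main effect
#' @param n_interaction_genes genes with background-specific aS effects
#' @param age_slope_range magnitude range of age slopes (log2 units / h)
#' @param genotype_effect_sd sd of per-background offsets (log2 units)
#' @param as_effect_size |aS| main effect (log2 units); sign randomised
#' @param interaction_effect_sd sd of per-background aS effects
#' @param marker_chromosomes chromosomes carrying wild-isolate marker genes
#' @param marker_spacing_mb spacing of marker genes along each chromosome
#' @param marker_separation log2 offset between reference and wild-isolate
#'   marker expression (the signal introgression mapping relies on)
#' @param introgression_blocks data.frame(genotype, chromosome, start_mb,
#'   end_mb); defaults to IV:4.2-13.2 for every non-reference background
#'   plus V:2-6 for JU1931 if present
#' @param noise_sd residual sd on the log2 scale
#' @param baseline_mean,baseline_sd distribution of per-gene baselines
#' @param seed RNG seed; identical seeds give identical output
#' @return object of class `SimulationConfig`
#' @export
simulation_config <- function(n_genes = 2000,
                              genotypes = c("N2", "JU1511", "JU1926",
                                            "JU1931", "JU1941"),
                              n_replicates = 3,
                              age_window_h = c(46, 54),
                              chronological_age_h = 48,
                              age_offsets_h = NULL,
                              age_replicate_jitter_h = 0.25,
                              n_age_genes = 300,
                              n_calibration_markers = 50,
                              n_genotype_genes = 200,
                              n_as_genes = 100,
                              n_interaction_genes = 60,
                              age_slope_range = c(0.1, 0.5),
                              genotype_effect_sd = 1,
                              as_effect_size = 1,
                              interaction_effect_sd = 1,
                              marker_chromosomes = c("IV", "V"),
                              marker_spacing_mb = 0.5,
                              marker_separation = 2,
                              introgression_blocks = NULL,
                              noise_sd = 0.25,
                              baseline_mean = 7,
                              baseline_sd = 1,
                              seed = 1) {
  stop_if(noise_sd <= 0, "noise_sd must be > 0")
  stop_if(n_calibration_markers > n_age_genes,
          "calibration markers are a subset of the age-responsive genes")
  stop_if(length(genotypes) < 2, "need at least 2 genotypes")
  genotypes <- as.character(genotypes)

  if (is.null(age_offsets_h)) {
    defaults <- c(N2 = -0.5, JU1511 = -1, JU1926 = -1.5, JU1931 = -0.3,
                  JU1941 = -1.75, CB4856 = -1.25)
    off <- defaults[genotypes]
    off[is.na(off)] <- -1
    age_offsets_h <- rbind(
      data.frame(genotype = genotypes, aS = 0L, offset_h = 0),
      data.frame(genotype = genotypes, aS = 1L, offset_h = unname(off)))
  }
  dev_age <- chronological_age_h + age_offsets_h$offset_h
  stop_if(any(dev_age - age_replicate_jitter_h < age_window_h[1] |
                dev_age + age_replicate_jitter_h > age_window_h[2]),
          "age offsets place samples outside the calibration window")

  markers <- marker_layout(marker_chromosomes, marker_spacing_mb)
  n_special <- n_age_genes + n_genotype_genes + n_as_genes +
    n_interaction_genes + nrow(markers)
  stop_if(n_special > n_genes,
          "effect-set counts (", n_special, ") exceed n_genes (", n_genes, ")")

  if (is.null(introgression_blocks)) {
    wild <- setdiff(genotypes, genotypes[1])
    introgression_blocks <- data.frame(
      genotype = wild, chromosome = "IV", start_mb = 4.2, end_mb = 13.2,
      stringsAsFactors = FALSE)
    if ("JU1931" %in% wild) {
      introgression_blocks <- rbind(
        introgression_blocks,
        data.frame(genotype = "JU1931", chromosome = "V",
                   start_mb = 2, end_mb = 6))
    }
  }
  stop_if(any(introgression_blocks$start_mb > introgression_blocks$end_mb),
          "introgression block start after end")

  structure(list(
    n_genes = n_genes, genotypes = genotypes, n_replicates = n_replicates,
    age_window_h = age_window_h, chronological_age_h = chronological_age_h,
    age_offsets_h = age_offsets_h,
    age_replicate_jitter_h = age_replicate_jitter_h,
    n_age_genes = n_age_genes,
    n_calibration_markers = n_calibration_markers,
    n_genotype_genes = n_genotype_genes, n_as_genes = n_as_genes,
    n_interaction_genes = n_interaction_genes,
    age_slope_range = age_slope_range,
    genotype_effect_sd = genotype_effect_sd,
    as_effect_size = as_effect_size,
    interaction_effect_sd = interaction_effect_sd,
    marker_layout = markers, marker_separation = marker_separation,
    introgression_blocks = introgression_blocks, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd, seed = seed),
    class = "SimulationConfig")
}

# evenly spaced marker-gene positions along the chosen chromosomes
marker_layout <- function(chromosomes, spacing_mb) {
  if (length(chromosomes) == 0)
    return(data.frame(chromosome = character(), position_mb = numeric(),
                      stringsAsFactors = FALSE))
  out <- lapply(chromosomes, function(chr) {
    len <- CHROM_LENGTH_MB[[chr]]
    pos <- seq(spacing_mb / 2, len - spacing_mb / 2, by = spacing_mb)
    data.frame(chromosome = chr, position_mb = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# canonical strain names for (genotype, aS) cells
line_name <- function(genotype, aS) {
  special_wt <- c(N2 = "N2")
  special_as <- c(N2 = "NL5901")
  ifelse(aS == 1,
         ifelse(genotype %in% names(special_as), special_as[genotype],
                sub("^(JU|CB)", "SCH", genotype)),
         genotype)
}

sim_sample_sheet <- function(config) {
  cells <- expand.grid(replicate = seq_len(config$n_replicates),
                       aS = c(0L, 1L), genotype = config$genotypes,
                       stringsAsFactors = FALSE)
  cells <- cells[, c("genotype", "aS", "replicate")]
  off <- merge(cells, config$age_offsets_h, by = c("genotype", "aS"),
               sort = FALSE)
  stop_if(nrow(off) != nrow(cells), "age_offsets_h must cover every cell")
  off <- off[order(match(off$genotype, config$genotypes), off$aS,
                   off$replicate), ]
  jit <- if (config$n_replicates > 1)
    seq(-config$age_replicate_jitter_h, config$age_replicate_jitter_h,
        length.out = config$n_replicates)
  else 0
  data.frame(
    sample_id = paste0(line_name(off$genotype, off$aS), "_r", off$replicate),
    genotype = off$genotype, aS = off$aS,
    batch = paste0("batch", off$replicate),
    chronological_time_h = config$chronological_age_h,
    true_age_h = config$chronological_age_h + off$offset_h +
      jit[off$replicate],
    stringsAsFactors = FALSE)
}

#' Simulate a complete expression experiment with known truth
#'
#' Generates an [expression_dataset()] (log2 intensities), a gene map, a
#' truth table flagging each gene's simulated effects, and the age
#' calibration (true marker slopes and intercepts) used by
#' [estimate_sample_ages()].
#'
#' @param config a [simulation_config()]
#' @return list with `dataset`, `gene_map`, `truth`, `calibration`,
#'   `samples` (sheet including the hidden `true_age_h` column)
#' @export
simulate_expression_experiment <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, {
    samples <- sim_sample_sheet(config)
    n <- nrow(samples)
    g <- config$n_genes
    gene_ids <- sprintf("gene_%04d", seq_len(g))
    genos <- config$genotypes
    wild <- setdiff(genos, genos[1])

    # role assignment: disjoint blocks, remainder null genes
    idx <- 0L
    take <- function(k) {
      out <- idx + seq_len(k)
      idx <<- idx + k
      out
    }
    i_age <- take(config$n_age_genes)
    i_cal <- i_age[seq_len(config$n_calibration_markers)]
    i_gb <- take(config$n_genotype_genes)
    i_as <- take(config$n_as_genes)
    i_int <- take(config$n_interaction_genes)
    i_mark <- take(nrow(config$marker_layout))

    baseline <- rnorm(g, config$baseline_mean, config$baseline_sd)

    beta_age <- numeric(g)
    slo <- config$age_slope_range
    beta_age[i_cal] <- runif(length(i_cal), slo[1], slo[2])
    i_age_rest <- setdiff(i_age, i_cal)
    beta_age[i_age_rest] <- runif(length(i_age_rest), slo[1], slo[2]) *
      sample(c(-1, 1), length(i_age_rest), replace = TRUE)

    beta_gb <- matrix(0, g, length(wild), dimnames = list(NULL, wild))
    beta_gb[i_gb, ] <- rnorm(length(i_gb) * length(wild),
                             sd = config$genotype_effect_sd)

    beta_as <- numeric(g)
    beta_as[i_as] <- config$as_effect_size *
      sample(c(-1, 1), length(i_as), replace = TRUE)

    beta_int <- matrix(0, g, length(wild), dimnames = list(NULL, wild))
    beta_int[i_int, ] <- rnorm(length(i_int) * length(wild),
                               sd = config$interaction_effect_sd)

    # marker genes: expressed at baseline in the reference, offset by
    # -marker_separation in wild backgrounds, reset to reference level
    # inside the introgressed block of each transgenic line
    marker_offset <- matrix(0, g, length(wild), dimnames = list(NULL, wild))
    marker_offset[i_mark, ] <- -config$marker_separation
    marker_pos <- config$marker_layout

    # gene map: markers at their designated positions, others uniform
    chrom <- character(g)
    pos <- numeric(g)
    chrom[i_mark] <- marker_pos$chromosome
    pos[i_mark] <- marker_pos$position_mb
    others <- setdiff(seq_len(g), i_mark)
    chrom[others] <- sample(names(CHROM_LENGTH_MB), length(others),
                            replace = TRUE,
                            prob = CHROM_LENGTH_MB / sum(CHROM_LENGTH_MB))
    pos[others] <- runif(length(others)) * CHROM_LENGTH_MB[chrom[others]]
    map <- gene_map(gene_ids, chrom, pos)

    in_block <- function(geno) {
      blocks <- config$introgression_blocks
      blocks <- blocks[blocks$genotype == geno, , drop = FALSE]
      hit <- rep(FALSE, g)
      for (b in seq_len(nrow(blocks))) {
        hit <- hit | (chrom == blocks$chromosome[b] &
                        pos >= blocks$start_mb[b] &
                        pos <= blocks$end_mb[b])
      }
      hit
    }

    M <- matrix(0, g, n, dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(n)) {
      geno <- samples$genotype[j]
      as_j <- samples$aS[j]
      mu <- baseline + beta_age * (samples$true_age_h[j] -
                                     config$age_window_h[1])
      if (geno %in% wild) {
        moff <- marker_offset[, geno]
        if (as_j == 1) moff[in_block(geno)] <- 0
        mu <- mu + beta_gb[, geno] + moff + as_j * beta_int[, geno]
      }
      mu <- mu + as_j * beta_as
      M[, j] <- mu
    }
    M <- M + rnorm(g * n, sd = config$noise_sd)

    samples_pub <- samples[, c("sample_id", "genotype", "aS", "batch",
                               "chronological_time_h")]
    ds <- expression_dataset(M, samples_pub, scale = "intensity")

    is_marker <- seq_len(g) %in% i_mark
    truth <- data.frame(
      gene_id = gene_ids,
      is_age = seq_len(g) %in% i_age,
      is_genotype = seq_len(g) %in% i_gb | is_marker,
      is_aS = seq_len(g) %in% i_as,
      is_interaction = seq_len(g) %in% i_int | is_marker,
      is_marker = is_marker,
      is_age_marker = seq_len(g) %in% i_cal,
      beta_age = beta_age,
      beta_aS = beta_as,
      max_abs_genotype = apply(abs(beta_gb) + abs(marker_offset), 1, max),
      max_abs_interaction = apply(abs(beta_int), 1, max),
      stringsAsFactors = FALSE)

    calibration <- age_calibration(data.frame(
      gene_id = gene_ids[i_cal], slope = beta_age[i_cal],
      intercept = baseline[i_cal], stringsAsFactors = FALSE),
      window_h = config$age_window_h)

    list(dataset = ds, gene_map = map, truth = truth,
         calibration = calibration, samples = samples)
  })
}

#' Simulate life-history phenotype measurements
#'
#' Produces a long-format phenotype table for development time (h),
#' pharyngeal pumping counts (30 s at 48 h, 60 s at 72 h), and thrashing
#' activity counts (30 min), each generated as genotype mean + aS shift +
#' genotype-specific aS shift; counts are Poisson around the structural
#' mean, development time Gaussian. Default effect patterns follow the
#' qualitative study outcome (largest delays/deficits in JU1941 and JU1926,
#' little effect in N2 and JU1931); variances are placeholders since no
#' empirical estimates are available.
#'
#' @param config a [simulation_config()]
#' @param n_per_group worms measured per (genotype, aS) cell and phenotype
#' @param effects optional list overriding the per-phenotype structural
#'   means; see the package vignette
#' @return list with `table` (a `PhenotypeTable`) and `truth` (per-cell
#'   structural means)
#' @export
simulate_phenotypes <- function(config, n_per_group = 19, effects = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  genos <- config$genotypes
  pick <- function(x, default) {
    out <- x[genos]
    out[is.na(out)] <- default
    unname(out)
  }
  if (is.null(effects)) {
    effects <- list(
      development_h = list(
        base = pick(c(N2 = 62, JU1511 = 64, JU1926 = 63, JU1931 = 61,
                      JU1941 = 65, CB4856 = 63), 63),
        as_shift = pick(c(N2 = 0.1, JU1511 = 0.4, JU1926 = 1.2,
                          JU1931 = 0.1, JU1941 = 2.2, CB4856 = 1.5), 1),
        sd = 1.2, duration_s = NA_real_),
      pumping_48h = list(
        base = pick(c(N2 = 120, JU1511 = 115, JU1926 = 118, JU1931 = 122,
                      JU1941 = 117, CB4856 = 119), 118),
        as_shift = rep(0, length(genos)), sd = NA, duration_s = 30),
      pumping_72h = list(
        base = pick(c(N2 = 230, JU1511 = 225, JU1926 = 235, JU1931 = 240,
                      JU1941 = 228, CB4856 = 232), 230),
        as_shift = -pick(c(N2 = 1, JU1511 = 20, JU1926 = 30, JU1931 = 3,
                           JU1941 = 45, CB4856 = 35), 20),
        sd = NA, duration_s = 60),
      thrashing = list(
        base = pick(c(N2 = 900, JU1511 = 950, JU1926 = 880, JU1931 = 920,
                      JU1941 = 860, CB4856 = 910), 900),
        as_shift = -pick(c(N2 = 5, JU1511 = 120, JU1926 = 80, JU1931 = 70,
                           JU1941 = 30, CB4856 = 90), 60),
        sd = NA, duration_s = 1800))
  }
  with_seed(config$seed + 1L, {
    rows <- list()
    truth <- list()
    for (ph in names(effects)) {
      e <- effects[[ph]]
      for (gi in seq_along(genos)) {
        for (as_j in c(0L, 1L)) {
          mu <- e$base[gi] + as_j * e$as_shift[gi]
          stop_if(mu < 0, "negative structural mean for ", ph, " in ",
                  genos[gi])
          vals <- if (is.na(e$sd)) rpois(n_per_group, mu)
                  else rnorm(n_per_group, mu, e$sd)
          rows[[length(rows) + 1L]] <- data.frame(
            line = line_name(genos[gi], as_j), genotype = genos[gi],
            aS = as_j,
            replicate = paste0("rep", rep_len(1:3, n_per_group)),
            phenotype_name = ph, value = vals, duration_s = e$duration_s,
            stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            phenotype_name = ph, genotype = genos[gi], aS = as_j,
            structural_mean = mu, stringsAsFactors = FALSE)
        }
      }
    }
    list(table = validate_phenotype_table(do.call(rbind, rows)),
         truth = do.call(rbind, truth))
  })
}

#' Simulate a lifespan assay with bagging and crawl-off censoring
#'
#' Lifespans are Weibull per (genotype, aS) cell; each worm independently
#' bags with probability `p_bag` (bagging times drawn uniformly from the
#' reproductive window) or crawls off with probability `p_crawl`.
#'
#' @param config a [simulation_config()]
#' @param n_worms worms per line
#' @param shape Weibull shape (shared)
#' @param scale_days named per-genotype wild-type Weibull scale (days)
#' @param as_scale_ratio per-genotype multiplicative effect of the
#'   transgene on the scale (values < 1 shorten lifespan)
#' @param p_bag per-genotype bagging probability of the transgenic lines
#'   (single number recycled); default 5% in the reference background, 20%
#'   in wild isolates
#' @param p_bag_wt per-genotype bagging probability of the wild-type lines
#'   (default 5%)
#' @param p_crawl per-genotype crawl-off probability (default 5%)
#' @param bag_window_days reproductive window bagging times are drawn from
#' @return list with `table` (a `SurvivalTable`) and `truth` (per-cell
#'   Weibull parameters and censoring probabilities)
#' @export
simulate_survival <- function(config, n_worms = 100, shape = 4,
                              scale_days = NULL, as_scale_ratio = NULL,
                              p_bag = NULL, p_bag_wt = 0.05, p_crawl = 0.05,
                              bag_window_days = c(3, 9)) {
  stopifnot(inherits(config, "SimulationConfig"))
  genos <- config$genotypes
  pick <- function(x, default) {
    out <- x[genos]
    out[is.na(out)] <- default
    unname(out)
  }
  if (is.null(scale_days))
    scale_days <- pick(c(N2 = 19, JU1511 = 17, JU1926 = 18, JU1931 = 16,
                         JU1941 = 18, CB4856 = 17), 18)
  if (is.null(as_scale_ratio))
    as_scale_ratio <- pick(c(N2 = 0.97, JU1511 = 0.85, JU1926 = 0.75,
                             JU1931 = 0.95, JU1941 = 0.8, CB4856 = 0.8), 0.85)
  if (is.null(p_bag)) {
    p_bag <- ifelse(genos == genos[1], 0.05, 0.2)  # transgenic cells
  }
  if (length(p_bag) == 1) p_bag <- rep(p_bag, length(genos))
  if (length(p_bag_wt) == 1) p_bag_wt <- rep(p_bag_wt, length(genos))
  if (length(p_crawl) == 1) p_crawl <- rep(p_crawl, length(genos))
  stop_if(any(c(p_bag, p_bag_wt, p_crawl) < 0 |
                c(p_bag, p_bag_wt, p_crawl) > 1),
          "censoring probabilities must lie in [0, 1]")

  with_seed(config$seed + 2L, {
    rows <- list()
    truth <- list()
    for (gi in seq_along(genos)) {
      for (as_j in c(0L, 1L)) {
        sc <- scale_days[gi] * if (as_j == 1) as_scale_ratio[gi] else 1
        pb <- if (as_j == 1) p_bag[gi] else p_bag_wt[gi]
        life <- rweibull(n_worms, shape = shape, scale = sc)
        u <- runif(n_worms)
        event <- ifelse(u < pb, "bagging",
                        ifelse(u < pb + p_crawl[gi], "crawloff", "death"))
        time <- life
        bag <- event == "bagging"
        time[bag] <- runif(sum(bag), bag_window_days[1], bag_window_days[2])
        cra <- event == "crawloff"
        time[cra] <- runif(sum(cra), 0.5, pmax(life[cra], 1))
        rows[[length(rows) + 1L]] <- data.frame(
          line = line_name(genos[gi], as_j), genotype = genos[gi],
          aS = as_j, worm_id = sprintf("w%03d", seq_len(n_worms)),
          time_days = pmax(time, 0.25), event = event,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          genotype = genos[gi], aS = as_j, shape = shape, scale_days = sc,
          p_bag = pb, p_crawl = p_crawl[gi], stringsAsFactors = FALSE)
      }
    }
    list(table = validate_survival_table(do.call(rbind, rows)),
         truth = do.call(rbind, truth))
  })
}

#' Simulate a GO annotation over the simulated genes
#'
#' Random term memberships, with a few terms deliberately enriched for the
#' transgene-affected genes so that a full synthetic pipeline run exercises
#' the enrichment stage end to end.
#'
#' @param truth truth table from [simulate_expression_experiment()]
#' @param n_terms number of GO terms
#' @param seed RNG seed
#' @export
simulate_go_annotation <- function(truth, n_terms = 50, seed = 1) {
  with_seed(seed, {
    genes <- truth$gene_id
    as_genes <- truth$gene_id[truth$is_aS | truth$is_interaction]
    pairs <- list()
    terms <- data.frame(
      go_id = sprintf("GO:%07d", seq_len(n_terms)),
      description = paste("synthetic term", seq_len(n_terms)),
      type = sample(c("BP", "MF", "CC"), n_terms, replace = TRUE),
      stringsAsFactors = FALSE)
    for (t in seq_len(n_terms)) {
      size <- sample(5:50, 1)
      if (t <= 3 && length(as_genes) >= 5) {
        k <- min(length(as_genes), ceiling(size * 0.6))
        members <- c(sample(as_genes, k),
                     sample(setdiff(genes, as_genes), size - k))
      } else {
        members <- sample(genes, size)
      }
      pairs[[t]] <- data.frame(gene_id = members, go_id = terms$go_id[t],
                               stringsAsFactors = FALSE)
    }
    go_annotation(do.call(rbind, pairs), terms)
  })
}
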