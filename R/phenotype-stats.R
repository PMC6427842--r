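# Phenotype and survival statistics: two-way factorial ANOVA (Type II)
# with Tukey HSD contrasts, Kaplan-Meier curves with bagging/crawl-off
# censoring, log-rank tests (optionally time-restricted), and the
# bagging-rate comparison.

#' Two-way ANOVA of a phenotype on transgene and genotype
#'
#' Least-squares fit of value ~ aS * genotype with Type II sums of
#' squares (each main effect adjusted for the other, the interaction
#' against the full model), which coincides with the classical balanced
#' decomposition when cell sizes are equal and remains well defined for
#' the unbalanced tables censoring produces.
#'
#' @param table a `PhenotypeTable` (long format)
#' @param phenotype_name which phenotype to test
#' @return object of class `AnovaResult`: `table` (per-term SS, df, F, p
#'   plus residual row), `cell_means`, `n`
#' @export
two_way_anova <- function(table, phenotype_name) {
  d <- table[table$phenotype_name == phenotype_name, , drop = FALSE]
  stop_if(nrow(d) == 0, "no rows for phenotype ", phenotype_name)
  geno <- factor(as.character(d$genotype))
  aS <- factor(as.integer(d$aS), levels = c(0, 1))
  stop_if(nlevels(geno) < 2 || length(unique(d$aS)) < 2,
          "need at least 2 levels of genotype and both aS states")
  cells <- table(geno, aS)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop_if(TRUE, "empty design cell(s): ",
            paste0(rownames(cells)[empty[, 1]], "/aS=",
                   colnames(cells)[empty[, 2]], collapse = ", "))
  }
  y <- d$value
  n <- length(y)
  X_as <- stats::model.matrix(~aS)[, -1, drop = FALSE]
  X_gb <- stats::model.matrix(~geno)[, -1, drop = FALSE]
  X_int <- X_gb * as.vector(X_as)
  one <- matrix(1, n, 1)
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  rss_full <- rss(cbind(one, X_as, X_gb, X_int))
  rss_main <- rss(cbind(one, X_as, X_gb))
  df_res <- n - (1 + ncol(X_as) + ncol(X_gb) + ncol(X_int))
  stop_if(df_res <= 0, "no residual degrees of freedom")

  ss <- c(aS = max(rss(cbind(one, X_gb)) - rss_main, 0),
          genotype = max(rss(cbind(one, X_as)) - rss_main, 0),
          `aS:genotype` = max(rss_main - rss_full, 0))
  df <- c(aS = ncol(X_as), genotype = ncol(X_gb),
          `aS:genotype` = ncol(X_int))
  mse <- rss_full / df_res
  tot_ss <- sum((y - mean(y))^2)
  if (mse < 1e-12 * max(tot_ss, 1) || tot_ss == 0) {
    # degenerate: (near-)zero residual variance
    Fv <- ifelse(ss > 1e-12 * max(tot_ss, 1), Inf, 0)
    p <- ifelse(is.infinite(Fv), 0, 1)
    if (tot_ss == 0) {
      Fv[] <- 0
      p[] <- 1
      warning("all phenotype values identical: p set to 1")
    }
  } else {
    Fv <- (ss / df) / mse
    p <- stats::pf(Fv, df, df_res, lower.tail = FALSE)
  }
  tab <- data.frame(term = c(names(ss), "residual"),
                    SS = c(ss, rss_full), df = c(df, df_res),
                    F = c(Fv, NA), p = c(p, NA), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  cm <- stats::aggregate(value ~ genotype + aS, data = d, FUN = mean)
  structure(list(table = tab, cell_means = cm, n = n,
                 phenotype = phenotype_name),
            class = "AnovaResult")
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat("Two-way ANOVA (Type II): ", x$phenotype, " ~ aS * genotype, n = ",
      x$n, "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Tukey HSD within-genotype transgene contrasts
#'
#' Runs Tukey's honestly-significant-difference test over all
#' (genotype x aS) groups (studentized-range family) and extracts the
#' within-genotype wild-type vs transgenic contrasts.
#'
#' @param table a `PhenotypeTable`
#' @param phenotype_name which phenotype to test
#' @return `TukeyContrast` data.frame: `genotype`, `wt_mean`, `as_mean`,
#'   `difference` (aS - WT), `adjusted_p`
#' @export
tukey_within_genotype <- function(table, phenotype_name) {
  d <- table[table$phenotype_name == phenotype_name, , drop = FALSE]
  stop_if(nrow(d) == 0, "no rows for phenotype ", phenotype_name)
  d$group <- interaction(d$genotype, d$aS, sep = "|", drop = TRUE)
  sizes <- table(d$group)
  stop_if(length(sizes) < 2, "need at least 2 groups")
  stop_if(any(sizes < 2),
          "group(s) with a single observation: ",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  fit <- stats::aov(value ~ group, data = d)
  hsd <- stats::TukeyHSD(fit)$group
  genos <- unique(as.character(d$genotype))
  out <- lapply(genos, function(g) {
    g0 <- paste0(g, "|0")
    g1 <- paste0(g, "|1")
    key <- c(paste0(g1, "-", g0), paste0(g0, "-", g1))
    hit <- intersect(key, rownames(hsd))
    if (length(hit) == 0) return(NULL)
    diff <- hsd[hit[1], "diff"]
    if (hit[1] == key[2]) diff <- -diff  # orient as aS - WT
    data.frame(genotype = g,
               wt_mean = mean(d$value[d$group == g0]),
               as_mean = mean(d$value[d$group == g1]),
               difference = unname(diff),
               adjusted_p = unname(hsd[hit[1], "p adj"]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("TukeyContrast", "data.frame")
  res
}

survival_object <- function(d, restrict_days = NULL) {
  time <- d$time_days
  status <- as.integer(d$event == "death")  # bagging/crawloff censor
  if (!is.null(restrict_days)) {
    # administrative censoring at the bound preserves risk sets
    status[time > restrict_days] <- 0L
    time <- pmin(time, restrict_days)
  }
  survival::Surv(time, status)
}

#' Kaplan-Meier curve for one line
#'
#' Product-limit estimate with bagging and crawl-off treated as
#' right-censoring. The mean lifespan is computed over death events only
#' (censored worms are excluded, as in the assay's bookkeeping) and is NA
#' when no deaths occurred.
#'
#' @param table a `SurvivalTable`
#' @param group value of the `line` column selecting the worms
#' @return object of class `KMCurve`: `time`, `surv`, `n_risk`,
#'   `n_event`, `n_censor`, `mean_lifespan_days`, `n`
#' @export
kaplan_meier <- function(table, group) {
  d <- table[table$line == group, , drop = FALSE]
  stop_if(nrow(d) == 0, "no worms for line ", group)
  fit <- survival::survfit(survival_object(d) ~ 1)
  deaths <- d$time_days[d$event == "death"]
  if (length(deaths) == 0)
    warning("no death events for line ", group,
            ": mean lifespan unavailable")
  structure(list(group = group, time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor,
                 mean_lifespan_days = if (length(deaths) > 0) mean(deaths)
                                      else NA_real_,
                 n = nrow(d)),
            class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat("Kaplan-Meier curve for ", x$group, ": n = ", x$n, ", ",
      sum(x$n_event), " deaths, mean lifespan ",
      format(x$mean_lifespan_days, digits = 4), " days\n", sep = "")
  invisible(x)
}

#' Log-rank test between two lines
#'
#' Standard O-E chi-square over the shared event times. An optional time
#' restriction administratively censors every observation at the bound
#' first, reproducing "first k days" analyses while preserving risk sets.
#'
#' @param table a `SurvivalTable`
#' @param group_a,group_b `line` values of the two groups
#' @param restrict_days optional restriction bound (days)
#' @return `LogrankResult`: list with `chisq`, `df` (1), `p`, group
#'   labels, `restrict_days`
#' @export
logrank <- function(table, group_a, group_b, restrict_days = NULL) {
  d <- table[table$line %in% c(group_a, group_b), , drop = FALSE]
  stop_if(length(unique(d$line)) < 2, "both groups need observations")
  srv <- survival_object(d, restrict_days)
  stop_if(sum(srv[, "status"]) == 0, "no death events within restriction")
  grp <- factor(d$line, levels = c(group_a, group_b))
  sd <- survival::survdiff(srv ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(group_a = group_a, group_b = group_b,
                 chisq = unname(sd$chisq), df = 1L, p = p,
                 restrict_days = restrict_days),
            class = "LogrankResult")
}

#' @export
print.LogrankResult <- function(x, ...) {
  cat("Log-rank ", x$group_a, " vs ", x$group_b,
      if (!is.null(x$restrict_days))
        paste0(" (first ", x$restrict_days, " days)"),
      ": chisq = ", format(x$chisq, digits = 4), ", p = ",
      format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Compare bagging rates between the WT and transgenic line of a genotype
#'
#' Bagging proportion per line (bagging events / worms assayed), their
#' difference in percentage points (aS - WT), and a two-sided Fisher
#' exact test on the 2x2 table.
#'
#' @param table a `SurvivalTable`
#' @param genotype genetic background to compare within
#' @return list: `genotype`, `wt_rate`, `as_rate`,
#'   `difference_pct_points`, `p`, the underlying 2x2 counts
#' @export
bagging_rate_test <- function(table, genotype) {
  d <- table[table$genotype == genotype, , drop = FALSE]
  wt <- d[d$aS == 0, ]
  as_ <- d[d$aS == 1, ]
  stop_if(nrow(wt) == 0 || nrow(as_) == 0,
          "need both WT and aS worms for genotype ", genotype)
  counts <- matrix(c(sum(as_$event == "bagging"),
                     sum(as_$event != "bagging"),
                     sum(wt$event == "bagging"),
                     sum(wt$event != "bagging")),
                   nrow = 2, dimnames = list(c("bagging", "other"),
                                             c("aS", "WT")))
  ft <- stats::fisher.test(counts)
  wt_rate <- counts["bagging", "WT"] / nrow(wt)
  as_rate <- counts["bagging", "aS"] / nrow(as_)
  list(genotype = genotype, wt_rate = wt_rate, as_rate = as_rate,
       difference_pct_points = 100 * (as_rate - wt_rate), p = ft$p.value,
       counts = counts)
}
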