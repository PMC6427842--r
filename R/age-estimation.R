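# Developmental age estimation from class-I age-responsive marker genes.
#
# Each marker m increases linearly in log2 expression during development
# within the 46-54 h window: x_m(a) = intercept_m + slope_m * (a - 46).
# A sample's age is the least-squares inversion across its markers:
#   a_hat = 46 + sum_m s_m (x_m - b_m) / sum_m s_m^2,
# the closed-form minimiser of sum_m (x_m - b_m - s_m (a - 46))^2.

#' Construct an age calibration
#'
#' @param markers data.frame with columns `gene_id`, `slope` (log2 units
#'   per hour, strictly positive), `intercept` (log2 expression at the
#'   lower window edge)
#' @param window_h validity window in hours; linearity is only asserted
#'   inside it
#' @export
age_calibration <- function(markers, window_h = c(46, 54)) {
  stop_if(!all(c("gene_id", "slope", "intercept") %in% names(markers)),
          "calibration needs columns gene_id, slope, intercept")
  stop_if(any(markers$slope <= 0),
          "class-I marker slopes must be strictly positive")
  if (nrow(markers) < 10)
    warning("fewer than 10 calibration markers: estimates may be unstable")
  structure(list(markers = markers, window_h = window_h),
            class = "AgeCalibration")
}

#' Read an age calibration file (TSV: gene_id, slope, intercept)
#' @param path file path
#' @param window_h validity window in hours
#' @export
read_age_calibration <- function(path, window_h = c(46, 54)) {
  age_calibration(utils::read.delim(path, stringsAsFactors = FALSE),
                  window_h = window_h)
}

#' Estimate developmental age per sample from marker expression
#'
#' @param dataset an intensity-scale [expression_dataset()]
#' @param calibration an [age_calibration()]
#' @return `AgeEstimate` data.frame: `sample_id`, `estimated_age_h`, `se`
#'   (residual-based standard error), `n_markers`, `in_window` (flag;
#'   linearity is only asserted inside the calibration window)
#' @export
estimate_sample_ages <- function(dataset, calibration) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(calibration, "AgeCalibration"))
  mk <- calibration$markers
  present <- mk$gene_id %in% rownames(dataset$matrix)
  stop_if(!any(present), "no calibration marker is present in the dataset")
  if (sum(present) < nrow(mk))
    warning(sum(!present), " calibration marker(s) absent from the dataset")
  if (sum(present) < 10)
    warning("fewer than 10 markers available: estimates may be unstable")
  mk <- mk[present, , drop = FALSE]
  X <- dataset$matrix[mk$gene_id, , drop = FALSE]
  s <- mk$slope
  b <- mk$intercept
  w0 <- calibration$window_h[1]
  ss2 <- sum(s^2)
  est <- w0 + colSums(s * (X - b)) / ss2
  M <- length(s)
  se <- vapply(seq_len(ncol(X)), function(j) {
    r <- X[, j] - (b + s * (est[j] - w0))
    if (M > 1) sqrt(sum(r^2) / (M - 1)) / sqrt(ss2) else NA_real_
  }, 1.0)
  out <- data.frame(sample_id = colnames(X), estimated_age_h = unname(est),
                    se = se, n_markers = M,
                    in_window = est > calibration$window_h[1] &
                      est < calibration$window_h[2],
                    stringsAsFactors = FALSE)
  class(out) <- c("AgeEstimate", "data.frame")
  out
}

#' Two-way ANOVA of estimated age on transgene and genotype
#'
#' Fits estimated_age ~ aS * genotype, the decomposition used to ask
#' whether the transgene's developmental delay is genotype independent.
#'
#' @param estimates an [estimate_sample_ages()] result
#' @param samples sample metadata with `sample_id`, `genotype`, `aS`
#' @return an `AnovaResult` (see [two_way_anova()])
#' @export
age_contrast_summary <- function(estimates, samples) {
  samples <- as.data.frame(samples)
  merged <- merge(samples, estimates, by = "sample_id")
  stop_if(nrow(merged) != nrow(samples),
          "estimates missing for some samples")
  tab <- data.frame(line = merged$sample_id, genotype = merged$genotype,
                    aS = merged$aS, replicate = "r1",
                    phenotype_name = "estimated_age_h",
                    value = merged$estimated_age_h, duration_s = NA_real_,
                    stringsAsFactors = FALSE)
  two_way_anova(validate_phenotype_table(tab), "estimated_age_h")
}
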