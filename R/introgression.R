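# Introgression mapping: locate introgressed reference-genome (N2) regions
# in each IL from wild-isolate marker-gene absence in the expression data,
# and from PCR marker panels.

#' Call marker presence per introgression line
#'
#' For each wild-isolate marker gene and each IL (a non-reference genotype
#' with the transgene), the IL's mean expression is compared to the
#' wild-isolate centroid (that genotype's wild-type samples) and to the
#' reference centroid (N2 wild-type samples). The nearest centroid wins;
#' calls within the ambiguity margin of the midpoint are `ambiguous`.
#' A marker whose wild-isolate signal is "missing" (reference-like) in an
#' IL indicates introgressed reference genome at that position.
#'
#' @param dataset an [expression_dataset()]
#' @param marker_genes gene ids of the wild-isolate marker panel
#' @param reference_genotype label of the reference background (default N2)
#' @param margin_factor ambiguity margin as a fraction of the centroid
#'   separation; the call is ambiguous iff |score| < margin_factor *
#'   |separation|, where score = dist(bg) - dist(N2)
#' @return `MarkerCall` data.frame: `gene_id`, `line` (genotype of the
#'   IL), `call` in {background_like, n2_like, ambiguous}, `score`,
#'   centroids
#' @export
call_marker_presence <- function(dataset, marker_genes,
                                 reference_genotype = "N2",
                                 margin_factor = 0.5) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  sm <- dataset$samples
  absent <- setdiff(marker_genes, rownames(dataset$matrix))
  if (length(absent) > 0)
    warning(length(absent), " marker gene(s) absent from dataset: skipped")
  marker_genes <- setdiff(marker_genes, absent)
  stop_if(length(marker_genes) == 0, "no marker genes present")
  ref_wt <- sm$sample_id[sm$genotype == reference_genotype & sm$aS == 0]
  stop_if(length(ref_wt) == 0,
          "no wild-type samples for reference genotype ", reference_genotype)
  ils <- setdiff(unique(as.character(sm$genotype[sm$aS == 1])),
                 reference_genotype)
  out <- list()
  M <- dataset$matrix[marker_genes, , drop = FALSE]
  c_ref <- rowMeans(M[, ref_wt, drop = FALSE])
  for (g in ils) {
    bg_wt <- sm$sample_id[sm$genotype == g & sm$aS == 0]
    il <- sm$sample_id[sm$genotype == g & sm$aS == 1]
    stop_if(length(bg_wt) == 0, "no wild-type samples for background ", g)
    c_bg <- rowMeans(M[, bg_wt, drop = FALSE])
    m_il <- rowMeans(M[, il, drop = FALSE])
    score <- abs(m_il - c_bg) - abs(m_il - c_ref)  # >0: closer to reference
    delta <- margin_factor * abs(c_ref - c_bg)
    call <- ifelse(abs(score) < delta, "ambiguous",
                   ifelse(score > 0, "n2_like", "background_like"))
    out[[g]] <- data.frame(gene_id = marker_genes, line = g, call = call,
                           score = unname(score),
                           n2_centroid = unname(c_ref),
                           background_centroid = unname(c_bg),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("MarkerCall", "data.frame")
  res
}

#' Detect introgression intervals from positioned marker calls
#'
#' Per line and chromosome, maximal runs of at least `min_run` consecutive
#' reference-like (`n2_like`) markers become intervals; ambiguous calls
#' neither break a run nor count toward `min_run`, while background-like
#' calls terminate it. Interval bounds are the positions of the outermost
#' reference-like markers; the flanking columns give the distance to the
#' nearest background-like marker on each side (the uncertainty zone).
#'
#' @param calls a [call_marker_presence()] result
#' @param gene_map a [gene_map()] positioning the marker genes
#' @param min_run minimum number of reference-like markers per interval
#' @return `IntrogressionInterval` data.frame (possibly 0 rows): `line`,
#'   `chromosome`, `start_mb`, `end_mb`, `n_markers`, `flank_left_mb`,
#'   `flank_right_mb`
#' @export
detect_introgression_intervals <- function(calls, gene_map, min_run = 3) {
  merged <- merge(calls, gene_map, by = "gene_id")
  empty <- data.frame(line = character(), chromosome = character(),
                      start_mb = numeric(), end_mb = numeric(),
                      n_markers = integer(), flank_left_mb = numeric(),
                      flank_right_mb = numeric(), stringsAsFactors = FALSE)
  out <- list()
  for (ln in unique(merged$line)) {
    for (chr in unique(merged$chromosome[merged$line == ln])) {
      d <- merged[merged$line == ln & merged$chromosome == chr, ]
      d <- d[order(d$position_mb), ]
      run_first <- NA_real_
      run_last <- NA_real_
      run_n <- 0L
      flush <- function(next_bg_pos) {
        if (run_n >= min_run) {
          prev_bg <- d$position_mb[d$call == "background_like" &
                                     d$position_mb < run_first]
          left <- if (length(prev_bg) > 0) run_first - max(prev_bg)
                  else NA_real_
          right <- if (!is.na(next_bg_pos)) next_bg_pos - run_last
                   else NA_real_
          out[[length(out) + 1L]] <<- data.frame(
            line = ln, chromosome = chr, start_mb = run_first,
            end_mb = run_last, n_markers = run_n, flank_left_mb = left,
            flank_right_mb = right, stringsAsFactors = FALSE)
        }
        run_first <<- NA_real_
        run_last <<- NA_real_
        run_n <<- 0L
      }
      for (i in seq_len(nrow(d))) {
        cl <- d$call[i]
        if (cl == "n2_like") {
          if (run_n == 0L) run_first <- d$position_mb[i]
          run_last <- d$position_mb[i]
          run_n <- run_n + 1L
        } else if (cl == "background_like") {
          flush(d$position_mb[i])
        }  # ambiguous: neither breaks nor counts
      }
      flush(NA_real_)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else empty
  rownames(res) <- NULL
  class(res) <- c("IntrogressionInterval", "data.frame")
  res
}

#' Introgression interval from a PCR marker panel
#'
#' The interval spans the first to the last reference (N2) call on the
#' target chromosome; the uncertainty zone extends outward to the nearest
#' flanking background calls, making the panel's inability to pin precise
#' introgression boundaries explicit.
#'
#' @param panel long-format data.frame with columns `name`, `chromosome`,
#'   `position_mb`, `line`, `call` (one of N2, background, fail)
#' @param line line to genotype
#' @param chromosome target chromosome (default IV, the transgene's locus)
#' @return one-row data.frame (`line`, `chromosome`, `start_mb`, `end_mb`,
#'   `uncertain_start_mb`, `uncertain_end_mb`, call counts), or a 0-row
#'   data.frame when the panel carries no reference calls
#' @export
interval_from_pcr_markers <- function(panel, line, chromosome = "IV") {
  d <- panel[panel$line == line & panel$chromosome == chromosome, ]
  stop_if(nrow(d) < 2, "need at least 2 panel markers on chromosome ",
          chromosome)
  stop_if(all(d$call == "fail"), "all panel markers failed for line ", line)
  d <- d[order(d$position_mb), ]
  n2 <- d$position_mb[d$call == "N2"]
  bg <- d$position_mb[d$call == "background"]
  if (length(n2) == 0) {
    return(data.frame(line = character(), chromosome = character(),
                      start_mb = numeric(), end_mb = numeric(),
                      uncertain_start_mb = numeric(),
                      uncertain_end_mb = numeric(), n_n2 = integer(),
                      n_background = integer(), n_fail = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- min(n2)
  end <- max(n2)
  lo <- bg[bg < start]
  hi <- bg[bg > end]
  data.frame(line = line, chromosome = chromosome, start_mb = start,
             end_mb = end,
             uncertain_start_mb = if (length(lo) > 0) max(lo) else NA_real_,
             uncertain_end_mb = if (length(hi) > 0) min(hi) else NA_real_,
             n_n2 = length(n2), n_background = length(bg),
             n_fail = sum(d$call == "fail"), stringsAsFactors = FALSE)
}
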