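# Shared data containers and readers/writers for the standard file formats
# consumed by every analysis stage.

#' Chromosome labels of the C. elegans nuclear genome
#' @export
CHROMOSOMES <- c("I", "II", "III", "IV", "V", "X")

#' Construct and validate an expression dataset
#'
#' The central container of the package: a genes x samples matrix of log2
#' values together with per-sample metadata. The matrix either holds log2
#' intensities (`scale = "intensity"`) or mean-centred log2 ratios
#' (`scale = "ratio"`); the flag controls whether [mean_ratio_transform()]
#' may still be applied.
#'
#' @param matrix numeric genes x samples matrix, log2 scale, rownames are
#'   gene ids, colnames are sample ids. No missing values are allowed.
#' @param samples data.frame with one row per sample and at least the
#'   columns `sample_id`, `genotype`, `aS` (0/1 transgene flag) and `batch`.
#'   An optional `chronological_time_h` column carries hours since egg
#'   isolation. Row order defines the sample order of the dataset.
#' @param scale `"intensity"` or `"ratio"`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `samples`, `scale`.
#' @export
expression_dataset <- function(matrix, samples, scale = c("intensity", "ratio")) {
  scale <- match.arg(scale)
  stop_if(!is.matrix(matrix) || !is.numeric(matrix),
          "`matrix` must be a numeric matrix")
  stop_if(is.null(rownames(matrix)), "`matrix` must carry gene ids as rownames")
  stop_if(is.null(colnames(matrix)), "`matrix` must carry sample ids as colnames")
  dup <- rownames(matrix)[duplicated(rownames(matrix))]
  stop_if(length(dup) > 0,
          "duplicated gene ids: ", paste(unique(dup), collapse = ", "))
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    bad <- which(is.na(matrix) | !is.finite(matrix), arr.ind = TRUE)
    coords <- apply(utils::head(bad, 5), 1L, function(ij)
      paste0(rownames(matrix)[ij[1]], "/", colnames(matrix)[ij[2]]))
    stop_if(TRUE, "missing or non-finite expression values at (gene/sample): ",
            paste(coords, collapse = ", "))
  }

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "aS", "batch")
  miss <- setdiff(need, names(samples))
  stop_if(length(miss) > 0,
          "sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  stop_if(length(dup) > 0,
          "duplicated sample ids: ", paste(unique(dup), collapse = ", "))
  stop_if(nrow(samples) != ncol(matrix),
          "sample sheet has ", nrow(samples), " rows but matrix has ",
          ncol(matrix), " columns")

  only_sheet <- setdiff(samples$sample_id, colnames(matrix))
  only_matrix <- setdiff(colnames(matrix), samples$sample_id)
  stop_if(length(only_sheet) > 0 || length(only_matrix) > 0,
          "sample ids do not match; only in sheet: [",
          paste(only_sheet, collapse = ", "), "]; only in matrix: [",
          paste(only_matrix, collapse = ", "), "]")
  # canonical order = sample-sheet row order
  matrix <- matrix[, samples$sample_id, drop = FALSE]

  samples$genotype <- as.factor(samples$genotype)
  if (is.logical(samples$aS)) samples$aS <- as.integer(samples$aS)
  stop_if(!all(samples$aS %in% c(0L, 1L)),
          "`aS` must be a 0/1 transgene flag")
  samples$aS <- as.integer(samples$aS)
  samples$batch <- as.factor(samples$batch)

  structure(list(matrix = matrix, samples = samples, scale = scale),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  tab <- table(genotype = x$samples$genotype, aS = x$samples$aS)
  cat("ExpressionDataset: ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples (log2 ", x$scale, ")\n", sep = "")
  cat("design cells (genotype x aS):\n")
  print(tab)
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$matrix)

#' Read a tab-separated expression matrix
#'
#' First column holds gene ids, remaining columns one sample each.
#' @param path file path
#' @return numeric matrix with gene rownames and sample colnames
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(ncol(tab) < 2, "expression matrix needs a gene id column plus samples")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Read a sample sheet (CSV)
#'
#' Expected columns: `sample_id`, `genotype`, `aS` (0/1), `batch`, and
#' optionally `chronological_time_h`.
#' @param path file path
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a gene map from a BED file
#'
#' BED convention: 0-based, half-open, coordinates in bp, columns
#' chrom / start / end / gene_id. Internally positions become 1-based
#' midpoints in Mb, the unit used for introgression intervals.
#'
#' @param path BED file path
#' @return data.frame with columns `gene_id`, `chromosome`, `position_mb`
#' @export
read_gene_map <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stop_if(ncol(bed) < 4, "gene map BED needs chrom, start, end, gene_id")
  names(bed)[1:4] <- c("chromosome", "start", "end", "gene_id")
  bed$chromosome <- sub("^chr", "", as.character(bed$chromosome))
  gene_map(bed$gene_id, bed$chromosome, ((bed$start + 1) + bed$end) / 2 / 1e6)
}

#' Construct a validated gene map
#'
#' @param gene_id,chromosome,position_mb parallel vectors
#' @export
gene_map <- function(gene_id, chromosome, position_mb) {
  chromosome <- as.character(chromosome)
  bad <- setdiff(unique(chromosome), CHROMOSOMES)
  stop_if(length(bad) > 0,
          "unknown chromosome label(s): ", paste(bad, collapse = ", "))
  stop_if(any(position_mb < 0), "gene positions must be non-negative")
  structure(data.frame(gene_id = as.character(gene_id),
                       chromosome = chromosome,
                       position_mb = as.numeric(position_mb),
                       stringsAsFactors = FALSE),
            class = c("GeneMap", "data.frame"))
}

#' Write a gene map as BED (0-based half-open, bp)
#'
#' Midpoints are written as 1-bp features so that reading the file back
#' reproduces `position_mb`.
#' @param map a `GeneMap`
#' @param path output path
#' @export
write_gene_map_bed <- function(map, path) {
  start <- round(map$position_mb * 1e6) - 1L
  utils::write.table(
    data.frame(map$chromosome, start, start + 1L, map$gene_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read GO annotation from two flat files
#'
#' @param gene2go_path TSV with columns `gene_id`, `go_id` (one pair/row)
#' @param terms_path TSV with columns `go_id`, `description`, `type`
#'   (type one of BP, MF, CC)
#' @return object of class `GOAnnotation`: list with `terms` (data.frame)
#'   and `genes` (named list go_id -> character vector of gene ids)
#' @export
read_go_annotation <- function(gene2go_path, terms_path) {
  g2g <- utils::read.delim(gene2go_path, stringsAsFactors = FALSE)
  terms <- utils::read.delim(terms_path, stringsAsFactors = FALSE)
  go_annotation(g2g, terms)
}

#' Construct a validated GO annotation object
#' @param gene2go data.frame with columns `gene_id`, `go_id`
#' @param terms data.frame with columns `go_id`, `description`, `type`
#' @export
go_annotation <- function(gene2go, terms) {
  stop_if(!all(c("gene_id", "go_id") %in% names(gene2go)),
          "gene2go needs columns gene_id, go_id")
  stop_if(!all(c("go_id", "description", "type") %in% names(terms)),
          "terms table needs columns go_id, description, type")
  bad <- setdiff(unique(terms$type), c("BP", "MF", "CC"))
  stop_if(length(bad) > 0,
          "GO type must be BP, MF or CC; found: ", paste(bad, collapse = ", "))
  genes <- split(as.character(gene2go$gene_id), as.character(gene2go$go_id))
  empty <- vapply(genes, length, 1L) == 0L
  stop_if(any(empty), "GO terms with empty gene sets")
  terms <- terms[match(names(genes), terms$go_id), , drop = FALSE]
  stop_if(anyNA(terms$go_id),
          "gene2go references go_ids absent from the terms table")
  rownames(terms) <- NULL
  structure(list(terms = terms, genes = genes), class = "GOAnnotation")
}

#' @export
print.GOAnnotation <- function(x, ...) {
  cat("GOAnnotation:", length(x$genes), "terms,",
      length(unique(unlist(x$genes))), "annotated genes\n")
  invisible(x)
}

#' Read a long-format phenotype table (CSV)
#'
#' Columns: `line`, `genotype`, `aS`, `replicate`, `phenotype_name`,
#' `value`, and `duration_s` (may be empty for non-count phenotypes).
#' @param path file path
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotype_table(tab)
}

validate_phenotype_table <- function(tab) {
  need <- c("line", "genotype", "aS", "replicate", "phenotype_name", "value")
  miss <- setdiff(need, names(tab))
  stop_if(length(miss) > 0,
          "phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  stop_if(any(!is.finite(tab$value)), "phenotype values must be finite")
  if (is.null(tab$duration_s)) tab$duration_s <- NA_real_
  count_phen <- grepl("pumping|thrash", tab$phenotype_name, ignore.case = TRUE)
  stop_if(any(count_phen & !is.finite(tab$duration_s)),
          "count phenotypes (pumping, thrashing) need a duration_s")
  structure(tab, class = c("PhenotypeTable", "data.frame"))
}

#' Read a per-worm survival table (CSV)
#'
#' Columns: `line`, `genotype`, `aS`, `worm_id`, `time_days`, `event`.
#' `event` is one of `death`, `bagging`, `crawloff`; bagging and crawl-off
#' are right-censoring events for lifespan, but bagging worms count toward
#' the matricidal-hatching analysis.
#' @param path file path
#' @export
read_survival_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survival_table(tab)
}

validate_survival_table <- function(tab) {
  need <- c("line", "genotype", "aS", "worm_id", "time_days", "event")
  miss <- setdiff(need, names(tab))
  stop_if(length(miss) > 0,
          "survival table lacks column(s): ", paste(miss, collapse = ", "))
  stop_if(any(tab$time_days <= 0), "survival times must be positive")
  bad <- setdiff(unique(tab$event), c("death", "bagging", "crawloff"))
  stop_if(length(bad) > 0,
          "unknown event type(s): ", paste(bad, collapse = ", "))
  structure(tab, class = c("SurvivalTable", "data.frame"))
}

#' Load a complete dataset from standard files
#'
#' Reads the expression matrix, sample sheet and (optionally) gene map and
#' GO annotation, validates that ids match, and reorders matrix columns to
#' sample-sheet row order.
#'
#' @param expression_path TSV expression matrix (see
#'   [read_expression_matrix()])
#' @param sample_sheet_path CSV sample sheet
#' @param gene_map_path optional BED gene map
#' @param go_genes_path,go_terms_path optional GO annotation files
#' @param scale `"intensity"` (default) or `"ratio"`
#' @param quiet suppress the loading report
#' @return list with elements `dataset`, `gene_map` (or NULL), `go` (or NULL)
#' @export
load_dataset <- function(expression_path, sample_sheet_path,
                         gene_map_path = NULL, go_genes_path = NULL,
                         go_terms_path = NULL, scale = "intensity",
                         quiet = FALSE) {
  m <- read_expression_matrix(expression_path)
  samples <- read_sample_sheet(sample_sheet_path)
  ds <- expression_dataset(m, samples, scale = scale)
  gm <- if (!is.null(gene_map_path)) read_gene_map(gene_map_path)
  go <- if (!is.null(go_genes_path))
    read_go_annotation(go_genes_path, go_terms_path)
  if (!quiet) {
    message("loaded ", nrow(ds$matrix), " genes x ", ncol(ds$matrix),
            " samples; ", nlevels(ds$samples$genotype), " genotypes x ",
            length(unique(ds$samples$aS)), " transgene states")
  }
  list(dataset = ds, gene_map = gm, go = go)
}

#' Write a result table as TSV
#'
#' Numeric columns are serialised with 17 significant digits so that
#' reading the file back reproduces the values exactly.
#'
#' @param table non-empty data.frame
#' @param path output path
#' @export
write_results <- function(table, path) {
  table <- as.data.frame(table)
  stop_if(nrow(table) == 0, "refusing to write an empty result table")
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a TSV written by [write_results()]
#' @param path file path
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    encoding = "UTF-8")
}
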