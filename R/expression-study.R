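#' Construct an ExpressionStudy
#'
#' Bundles a gene x sample matrix of linear-scale expression estimates with
#' the blocked factorial design metadata (donor = block, condition =
#' treatment, replicate). Intensities below `floor` are clamped to `floor` so
#' that fold-change ratios are always defined.
#'
#' @param intensities numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param design data.frame with columns `sample_id`, `donor`, `condition`,
#'   `replicate`; one row per sample, `sample_id` matching the matrix columns.
#' @param floor intensity floor applied before any ratio is formed
#'   (default 1.0). Set to `-Inf` to disable.
#' @param synonyms condition synonym map; see [condition_synonyms()].
#' @return An object of class `expression_study`: a list with elements
#'   `intensities` (floored matrix) and `design` (canonicalized data.frame).
#' @export
expression_study <- function(intensities, design, floor = 1.0,
                             synonyms = condition_synonyms()) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities)) {
    stop("intensities must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("intensities must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(intensities))) {
    stop("duplicate gene identifiers in intensity matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(intensities))) {
    stop("duplicate sample identifiers in intensity matrix", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("non-finite intensity values present", call. = FALSE)
  }
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("sample_id", "donor", "condition", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  design$sample_id <- as.character(design$sample_id)
  design$donor <- as.character(design$donor)
  design$condition <- canonical_condition(design$condition, synonyms)
  design$replicate <- as.integer(design$replicate)
  if (any(is.na(design$replicate)) || any(design$replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample identifiers in sample sheet", call. = FALSE)
  }
  only_matrix <- setdiff(colnames(intensities), design$sample_id)
  only_sheet <- setdiff(design$sample_id, colnames(intensities))
  if (length(only_matrix) || length(only_sheet)) {
    stop("sample ids do not match between matrix and sheet.",
         if (length(only_matrix)) paste0(" Matrix only: ",
                                         paste(only_matrix, collapse = ", "), "."),
         if (length(only_sheet)) paste0(" Sheet only: ",
                                        paste(only_sheet, collapse = ", "), "."),
         call. = FALSE)
  }
  design <- design[match(colnames(intensities), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  if (is.finite(floor)) {
    intensities[intensities < floor] <- floor
  }
  structure(list(intensities = intensities, design = design, floor = floor),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  d <- x$design
  cat("ExpressionStudy: ", nrow(x$intensities), " genes x ",
      ncol(x$intensities), " samples\n", sep = "")
  cat("  donors: ", length(unique(d$donor)),
      " | conditions: ", paste(sort(unique(d$condition)), collapse = ", "),
      " | max replicate: ", max(d$replicate), "\n", sep = "")
  invisible(x)
}

#' Gene identifiers of a study
#' @param study an `expression_study`.
#' @return Character vector of gene ids.
#' @export
study_genes <- function(study) rownames(study$intensities)

# error unless every donor has all four conditions
check_complete_design <- function(study, conditions = nk_conditions()) {
  d <- study$design
  donors <- unique(d$donor)
  cells <- expand.grid(donor = donors, condition = conditions,
                       stringsAsFactors = FALSE)
  have <- paste(d$donor, d$condition)
  missing <- cells[!(paste(cells$donor, cells$condition) %in% have), , drop = FALSE]
  if (nrow(missing)) {
    stop("incomplete design; missing cell(s): ",
         paste(paste0(missing$donor, ":", missing$condition), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read an expression study from TSV files
#'
#' @param matrix_path TSV with a header row of sample ids and first column of
#'   gene ids.
#' @param sample_sheet_path TSV with columns `sample_id`, `donor`,
#'   `condition`, `replicate`.
#' @param floor,synonyms passed to [expression_study()].
#' @return An `expression_study`.
#' @export
read_expression_study <- function(matrix_path, sample_sheet_path,
                                  floor = 1.0, synonyms = condition_synonyms()) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression matrix needs gene id column plus >=1 sample",
                           call. = FALSE)
  genes <- as.character(raw[[1L]])
  mat <- raw[, -1L, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn) & !anyNA(v)) {
        bad <- which(is.na(vn))[1L]
        stop(sprintf("non-numeric expression value at row %d, column '%s': '%s'",
                     bad, colnames(mat)[j], v[bad]), call. = FALSE)
      }
      mat[[j]] <- vn
    }
  }
  m <- as.matrix(mat)
  rownames(m) <- genes
  sheet <- utils::read.delim(sample_sheet_path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
  expression_study(m, sheet, floor = floor, synonyms = synonyms)
}

#' Write an expression study to TSV files
#'
#' Inverse of [read_expression_study()]; round-trips intensities to full
#' double precision (17 significant digits).
#'
#' @param study an `expression_study`.
#' @param matrix_path,sample_sheet_path output paths.
#' @return Invisibly, the study.
#' @export
write_expression_study <- function(study, matrix_path, sample_sheet_path) {
  m <- study$intensities
  df <- data.frame(gene = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(m))
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$design, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(study)
}

#' Collapse replicate arrays to one profile per donor and condition
#'
#' Duplicate hybridizations are averaged arithmetically in linear intensity
#' scale, giving one expression profile per (donor, condition) cell, as the
#' block ANOVA expects. Cells with a single replicate pass through unchanged.
#'
#' @param study an `expression_study`.
#' @param method collapse rule; only `"mean"` is implemented.
#' @return An `expression_study` with one sample per (donor, condition),
#'   sample ids `"<donor>.<condition>"`, replicate set to 1.
#' @export
collapse_replicates <- function(study, method = c("mean")) {
  method <- match.arg(method)
  d <- study$design
  cell <- paste(d$donor, d$condition, sep = ".")
  ucell <- unique(cell)
  # group-by mean via indicator matrix: X[i, j] = 1/n_j if sample i in cell j
  ind <- outer(cell, ucell, "==") * 1
  ind <- sweep(ind, 2L, colSums(ind), "/")
  m <- study$intensities %*% ind
  colnames(m) <- ucell
  first <- match(ucell, cell)
  design <- data.frame(sample_id = ucell,
                       donor = d$donor[first],
                       condition = d$condition[first],
                       replicate = 1L,
                       stringsAsFactors = FALSE)
  expression_study(m, design, floor = study$floor)
}

#' Replicate concordance (squared Pearson correlation)
#'
#' For every (donor, condition) cell with exactly two replicate arrays,
#' computes the squared Pearson correlation of the two replicate intensity
#' vectors across genes. Quality check mirroring the duplicate-array
#' reproducibility summary customary for blocked microarray designs.
#'
#' @param study an `expression_study` with duplicate arrays.
#' @return data.frame with columns `donor`, `condition`, `r_squared`; the
#'   mean r-squared over rows is attached as attribute `"mean_r_squared"`.
#'   Cells without exactly two replicates are skipped with a warning;
#'   zero-variance replicate vectors yield `NA`.
#' @export
replicate_concordance <- function(study) {
  if (nrow(study$intensities) < 3L) {
    stop("need at least 3 genes for a meaningful correlation", call. = FALSE)
  }
  d <- study$design
  cell <- paste(d$donor, d$condition, sep = "\r")
  out <- list()
  for (uc in unique(cell)) {
    idx <- which(cell == uc)
    donor <- d$donor[idx[1L]]
    cond <- d$condition[idx[1L]]
    if (length(idx) != 2L) {
      warning(sprintf("cell %s:%s has %d replicates (expected 2); skipped",
                      donor, cond, length(idx)), call. = FALSE)
      next
    }
    x <- study$intensities[, idx[1L]]
    y <- study$intensities[, idx[2L]]
    r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)^2
    out[[length(out) + 1L]] <- data.frame(donor = donor, condition = cond,
                                          r_squared = r2,
                                          stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(donor = character(), condition = character(),
               r_squared = numeric(), stringsAsFactors = FALSE)
  attr(res, "mean_r_squared") <- if (nrow(res)) mean(res$r_squared, na.rm = TRUE)
    else NA_real_
  res
}
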