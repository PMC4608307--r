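#' Venn partition of three gene sets
#'
#' Partitions the union of three comparison gene sets (by convention
#' A = IgG vs medium, B = IL12 vs medium, C = IgG_IL12 vs medium) into the
#' seven exclusive intersection regions.
#'
#' @param set_a,set_b,set_c character vectors of gene ids (duplicates
#'   ignored).
#' @param labels length-3 character vector naming the sets.
#' @param direction optional `"up"` or `"down"` annotation carried on the
#'   result.
#' @return object of class `venn_partition`: list with `regions` (named list
#'   of gene vectors, keys `A`,`B`,`C`,`AB`,`AC`,`BC`,`ABC` — `A` means
#'   A-only, etc.), `counts`, `labels`, `direction`.
#' @export
venn_partition <- function(set_a, set_b, set_c,
                           labels = c("IgG", "IL12", "IgG_IL12"),
                           direction = NULL) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  cc <- unique(as.character(set_c))
  all_genes <- sort(unique(c(a, b, cc)))
  code <- paste0(ifelse(all_genes %in% a, "A", ""),
                 ifelse(all_genes %in% b, "B", ""),
                 ifelse(all_genes %in% cc, "C", ""))
  keys <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  regions <- lapply(keys, function(k) all_genes[code == k])
  names(regions) <- keys
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1L)),
                 labels = labels, direction = direction),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("VennPartition (", paste(x$labels, collapse = ", "), ")",
      if (!is.null(x$direction)) paste0(" [", x$direction, "]"), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Region membership as a data.frame
#' @param x a `venn_partition`.
#' @return data.frame with columns `gene`, `region`.
#' @export
venn_membership <- function(x) {
  stopifnot(inherits(x, "venn_partition"))
  data.frame(
    gene = unlist(x$regions, use.names = FALSE),
    region = rep(names(x$regions), lengths(x$regions)),
    stringsAsFactors = FALSE
  )
}

#' Select the variable genes of the primary comparisons
#'
#' Union of genes passing the full triple filter, in either direction, in
#' any of the three vs-medium comparisons; the gene set underlying the
#' hierarchical-clustering display and the enrichment seed.
#'
#' @param table a `contrast_table`.
#' @return Character vector of gene ids (sorted, unique).
#' @export
select_variable_genes <- function(table) {
  sort(unique(table$gene[table$primary & table$significant]))
}

#' Hierarchical clustering of genes and samples
#'
#' Mean-centers each gene's profile across samples (on log2 scale by
#' default, matching heat-map display semantics), then clusters genes and
#' samples agglomeratively. Correlation distance is 1 - Pearson; a
#' zero-variance gene gets the maximal distance 2.0 to every other profile,
#' with a warning.
#'
#' @param study an `expression_study`.
#' @param genes gene ids to cluster (>= 2).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @param log2_transform transform intensities before centering (default
#'   TRUE).
#' @return object of class `cluster_result`: list with `gene_hclust`,
#'   `sample_hclust` (stats::hclust trees), `gene_order`, `sample_order`
#'   (leaf orders), and `matrix` (the centered gene x sample display matrix).
#' @export
hierarchical_cluster <- function(study, genes,
                                 distance = c("correlation", "euclidean"),
                                 linkage = c("average", "complete"),
                                 log2_transform = TRUE) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  genes <- as.character(genes)
  miss <- setdiff(genes, rownames(study$intensities))
  if (length(miss)) stop("gene(s) not in study: ",
                         paste(utils::head(miss, 5L), collapse = ", "),
                         call. = FALSE)
  if (length(genes) < 2L) stop("need at least 2 genes to cluster", call. = FALSE)
  if (ncol(study$intensities) < 2L) stop("need at least 2 samples", call. = FALSE)
  m <- study$intensities[genes, , drop = FALSE]
  if (log2_transform) m <- log2(m)
  m <- m - rowMeans(m)

  dist_of <- function(mat) {
    if (distance == "euclidean") return(stats::dist(mat))
    v <- apply(mat, 1L, stats::sd)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance profile(s); correlation distance ",
              "set to the maximum (2.0)", call. = FALSE)
    }
    cm <- suppressWarnings(stats::cor(t(mat)))
    d <- 1 - cm
    d[!is.finite(d)] <- 2.0
    diag(d) <- 0
    stats::as.dist(d)
  }
  gene_h <- stats::hclust(dist_of(m), method = linkage)
  sample_h <- stats::hclust(dist_of(t(m)), method = linkage)
  structure(list(gene_hclust = gene_h, sample_hclust = sample_h,
                 gene_order = rownames(m)[gene_h$order],
                 sample_order = colnames(m)[sample_h$order],
                 matrix = m, distance = distance, linkage = linkage),
            class = "cluster_result")
}
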