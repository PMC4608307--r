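#' Hypergeometric overrepresentation of functional categories
#'
#' For a query gene list (restricted to the annotation universe first), each
#' category with at least one query member is tested with the one-sided
#' hypergeometric upper tail: the probability of observing at least
#' k = |query ∩ category| category members when drawing n = |query| genes
#' without replacement from a universe of N genes containing K category
#' members. Benjamini-Hochberg adjustment is applied across the tested
#' categories.
#'
#' @param query character vector of gene ids.
#' @param catalog an `annotation_catalog`.
#' @param universe optional override of the catalog universe (e.g. its
#'   intersection with the genes on the analyzed array).
#' @return data.frame of class `enrichment_table`, one row per tested
#'   category: `category`, `name`, `k`, `K`, `n`, `N`, `ratio`
#'   ((k/n)/(K/N)), `p`, `q`. Rows are in catalog order. An empty
#'   query-after-restriction yields an empty table with a warning.
#' @export
hypergeometric_enrichment <- function(query, catalog, universe = NULL) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  universe <- if (is.null(universe)) catalog$universe else
    intersect(catalog$universe, as.character(universe))
  N <- length(universe)
  if (N == 0L) stop("empty universe", call. = FALSE)
  q_genes <- intersect(unique(as.character(query)), universe)
  n <- length(q_genes)
  empty <- data.frame(category = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), ratio = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_table", "data.frame")
  if (n == 0L) {
    warning("query is empty after restriction to the universe", call. = FALSE)
    return(empty)
  }
  rows <- lapply(names(catalog$categories), function(id) {
    members <- intersect(catalog$categories[[id]], universe)
    K <- length(members)
    k <- length(intersect(q_genes, members))
    if (k < 1L) return(NULL)
    data.frame(category = id, name = unname(catalog$category_names[id]),
               k = k, K = K, n = n, N = N,
               ratio = (k / n) / (K / N),
               p = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Top enriched categories
#'
#' Categories with q < `q_max` and k >= `min_k`, ordered by ascending q,
#' then descending k, then category id.
#'
#' @param table an `enrichment_table`.
#' @param q_max BH-adjusted significance cutoff (default 0.05).
#' @param min_k minimum query overlap (default 2).
#' @return Character vector of category ids, best first.
#' @export
top_categories <- function(table, q_max = 0.05, min_k = 2L) {
  keep <- table$q < q_max & table$k >= min_k
  t2 <- table[keep, , drop = FALSE]
  t2$category[order(t2$q, -t2$k, t2$category)]
}

#' Augment a seed gene set with members of enriched categories
#'
#' Implements enrichment-driven aggregation: genes sharing the most common
#' biomolecular functions of the differentially expressed seed are pulled in
#' before network construction, so that functionally linked but
#' individually sub-threshold genes can be recovered by centrality ranking.
#' Added genes beyond `cap` are truncated in (category order, gene id)
#' order.
#'
#' @param seed_genes character vector (the differentially expressed seed).
#' @param categories ordered category ids, e.g. from [top_categories()].
#' @param catalog an `annotation_catalog` containing those categories.
#' @param cap maximum number of genes added beyond the seed (default Inf).
#' @return Character vector (sorted, unique) of the augmented set, with a
#'   `provenance` attribute: data.frame `gene`, `source` (`"seed"` or
#'   `"added"`), `category` (the first listing category for added genes,
#'   `NA` for seed genes).
#' @export
augment_gene_set <- function(seed_genes, categories, catalog, cap = Inf) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  seed_genes <- unique(as.character(seed_genes))
  miss <- setdiff(categories, names(catalog$categories))
  if (length(miss)) stop("category not in catalog: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  added <- character(0); via <- character(0)
  for (cat_id in categories) {
    new <- sort(setdiff(catalog$categories[[cat_id]], c(seed_genes, added)))
    added <- c(added, new)
    via <- c(via, rep(cat_id, length(new)))
  }
  if (length(added) > cap) {
    keep <- seq_len(cap)
    added <- added[keep]; via <- via[keep]
  }
  out <- sort(unique(c(seed_genes, added)))
  prov <- data.frame(
    gene = c(seed_genes, added),
    source = c(rep("seed", length(seed_genes)), rep("added", length(added))),
    category = c(rep(NA_character_, length(seed_genes)), via),
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- prov[order(prov$gene), , drop = FALSE]
  out
}
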