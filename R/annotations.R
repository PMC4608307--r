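#' Construct an AnnotationCatalog
#'
#' A catalog maps functional-category identifiers (e.g. GO terms) to gene
#' sets, plus the universe of annotatable genes used as the enrichment
#' background.
#'
#' @param categories named list of character vectors (category id -> genes).
#' @param universe optional character vector; defaults to the union of all
#'   category members.
#' @param category_names optional named character vector of human-readable
#'   names, same names as `categories`.
#' @return An object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(categories, universe = NULL,
                               category_names = NULL) {
  if (!is.list(categories) || is.null(names(categories)) ||
      any(!nzchar(names(categories)))) {
    stop("categories must be a named list of gene vectors", call. = FALSE)
  }
  categories <- lapply(categories, function(g) sort(unique(as.character(g))))
  empty <- names(categories)[lengths(categories) == 0L]
  if (length(empty)) {
    stop("empty categories after load: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(categories, use.names = FALSE)))
  } else {
    universe <- sort(unique(as.character(universe)))
    outside <- setdiff(unlist(categories, use.names = FALSE), universe)
    if (length(outside)) {
      stop("category members outside the supplied universe: ",
           paste(utils::head(outside, 5L), collapse = ", "),
           if (length(outside) > 5L) ", ...", call. = FALSE)
    }
  }
  if (is.null(category_names)) {
    category_names <- stats::setNames(names(categories), names(categories))
  }
  structure(list(categories = categories, universe = universe,
                 category_names = category_names),
            class = "annotation_catalog")
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat("AnnotationCatalog: ", length(x$categories), " categories, ",
      length(x$universe), " genes in universe\n", sep = "")
  invisible(x)
}

#' Read a gene-annotation catalog
#'
#' Supports the Broad GMT dialect (one line per category:
#' `name TAB description TAB gene1 TAB gene2 ...`) and a two-column TSV of
#' `(gene, category)` pairs with a header.
#'
#' @param path file path.
#' @param format `"gmt"` or `"tsv2col"`.
#' @param universe optional explicit universe (character vector or path to a
#'   one-column file of gene ids).
#' @return An `annotation_catalog`. Duplicate category names are merged with
#'   a warning.
#' @export
read_annotations <- function(path, format = c("gmt", "tsv2col"),
                             universe = NULL) {
  format <- match.arg(format)
  if (is.character(universe) && length(universe) == 1L && file.exists(universe)) {
    universe <- utils::read.delim(universe, header = FALSE,
                                  stringsAsFactors = FALSE)[[1L]]
  }
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty annotation file: ", path, call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad)) {
      stop("malformed GMT line(s) (need name, description, >=1 gene): line ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ids <- vapply(parts, `[[`, character(1L), 1L)
    descs <- vapply(parts, `[[`, character(1L), 2L)
    sets <- lapply(parts, function(p) p[-c(1L, 2L)])
  } else {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!nrow(df)) stop("empty annotation file: ", path, call. = FALSE)
    if (ncol(df) < 2L) stop("tsv2col annotations need (gene, category) columns",
                            call. = FALSE)
    sets <- split(as.character(df[[1L]]), as.character(df[[2L]]))
    ids <- names(sets)
    descs <- ids
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate category name(s) merged: ", paste(dup, collapse = ", "),
            call. = FALSE)
    sets <- lapply(split(sets, ids), function(s) unique(unlist(s)))
    descs <- descs[match(names(sets), ids)]
    ids <- names(sets)
  }
  names(sets) <- ids
  annotation_catalog(sets, universe = universe,
                     category_names = stats::setNames(descs, ids))
}

#' Write a catalog in GMT format
#'
#' @param catalog an `annotation_catalog`.
#' @param path output path.
#' @return Invisibly, the catalog.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$categories), function(id) {
    paste(c(id, unname(catalog$category_names[id]), catalog$categories[[id]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(catalog)
}
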