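#' Construct an EdgeTable
#'
#' Row-level container for functional-linkage edges between genes
#' (co-expression, pathway, physical interaction, ...). Self-loop rows are
#' dropped with a warning; weights must be non-negative.
#'
#' @param df data.frame with columns `source`, `target`, and optionally
#'   `weight` (default 1.0), `edge_type` (default `"link"`), `directed`
#'   (logical or 0/1; default `TRUE`).
#' @return data.frame of class `edge_table` with all five columns.
#' @export
edge_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("source", "target")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("edge table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  if (is.null(df$weight)) df$weight <- 1.0
  df$weight <- as.numeric(df$weight)
  if (any(!is.finite(df$weight)) || any(df$weight < 0)) {
    stop("edge weights must be finite and non-negative", call. = FALSE)
  }
  if (is.null(df$edge_type)) df$edge_type <- "link"
  df$edge_type <- as.character(df$edge_type)
  if (is.null(df$directed)) df$directed <- TRUE
  dr <- df$directed
  if (is.character(dr) || is.numeric(dr)) {
    ok <- as.character(dr) %in% c("0", "1", "TRUE", "FALSE")
    if (any(!ok)) {
      stop("malformed directed flag (expect 0/1): '",
           as.character(dr)[which(!ok)[1L]], "'", call. = FALSE)
    }
    dr <- as.character(dr) %in% c("1", "TRUE")
  }
  df$directed <- as.logical(dr)
  loops <- df$source == df$target
  if (any(loops)) {
    warning(sum(loops), " self-loop edge row(s) dropped", call. = FALSE)
    df <- df[!loops, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("edge_table", "data.frame")
  df
}

#' Read a functional-linkage edge table from TSV
#'
#' Expected columns: `source`, `target`, and optionally `weight`,
#' `edge_type`, `directed` (0/1). Missing optional columns take their
#' defaults (weight 1.0, type "link", directed).
#'
#' @param path TSV file with header.
#' @return An `edge_table`.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  edge_table(df)
}

#' Write an edge table to TSV
#' @param edges an `edge_table`.
#' @param path output path.
#' @return Invisibly, the edges.
#' @export
write_edge_table <- function(edges, path) {
  df <- as.data.frame(edges)
  df$directed <- as.integer(df$directed)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}
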