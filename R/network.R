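#' Build the functional network over a gene set
#'
#' Induces the directed subgraph of an edge table on a gene set (optionally
#' extended by first neighbors). Undirected rows are expanded into two
#' opposing arcs; parallel arcs between the same ordered pair are aggregated
#' by weight sum with their contributing edge types concatenated. Requested
#' genes with no incident edges are retained as isolated nodes.
#'
#' @param gene_set character vector of gene ids.
#' @param edges an `edge_table`.
#' @param include_neighbors also keep edges with exactly one endpoint in
#'   `gene_set`, adding the outside endpoint as a node (default FALSE).
#' @param seed_genes optional subset of nodes flagged as the
#'   differential-expression seed (default `gene_set`).
#' @param de_direction optional named character vector gene -> "up"/"down".
#' @return object of class `functional_network`: list with `nodes` (sorted
#'   ids), `arcs` (data.frame `source`, `target`, `weight`, `types`),
#'   `in_seed` (named logical), `de_direction` (named character).
#' @export
build_network <- function(gene_set, edges, include_neighbors = FALSE,
                          seed_genes = NULL, de_direction = NULL) {
  gene_set <- unique(as.character(gene_set))
  e <- as.data.frame(edges)
  in_a <- e$source %in% gene_set
  in_b <- e$target %in% gene_set
  keep <- if (include_neighbors) in_a | in_b else in_a & in_b
  e <- e[keep, , drop = FALSE]
  nodes <- sort(unique(c(gene_set, e$source, e$target)))
  if (!length(nodes)) stop("resulting network has no nodes", call. = FALSE)
  if (nrow(e)) {
    undec <- !e$directed
    if (any(undec)) {
      rev <- e[undec, , drop = FALSE]
      tmp <- rev$source; rev$source <- rev$target; rev$target <- tmp
      e <- rbind(e, rev)
    }
    key <- paste(e$source, e$target, sep = "\r")
    w <- tapply(e$weight, key, sum)
    ty <- tapply(e$edge_type, key,
                 function(x) paste(sort(unique(x)), collapse = ","))
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    arcs <- data.frame(source = vapply(parts, `[[`, character(1L), 1L),
                       target = vapply(parts, `[[`, character(1L), 2L),
                       weight = as.numeric(w), types = as.character(ty),
                       stringsAsFactors = FALSE)
    arcs <- arcs[order(arcs$source, arcs$target), , drop = FALSE]
    rownames(arcs) <- NULL
  } else {
    arcs <- data.frame(source = character(), target = character(),
                       weight = numeric(), types = character(),
                       stringsAsFactors = FALSE)
  }
  seed_genes <- if (is.null(seed_genes)) gene_set else
    unique(as.character(seed_genes))
  in_seed <- stats::setNames(nodes %in% seed_genes, nodes)
  dedir <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  if (!is.null(de_direction)) {
    hit <- intersect(names(de_direction), nodes)
    dedir[hit] <- unname(de_direction[hit])
  }
  structure(list(nodes = nodes, arcs = arcs, in_seed = in_seed,
                 de_direction = dedir),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat("FunctionalNetwork: ", length(x$nodes), " nodes, ", nrow(x$arcs),
      " arcs (", sum(x$in_seed), " seed)\n", sep = "")
  invisible(x)
}

# out-adjacency list (indices) of a functional_network
adjacency_list <- function(net) {
  n <- length(net$nodes)
  adj <- rep(list(integer(0)), n)
  if (nrow(net$arcs)) {
    s <- match(net$arcs$source, net$nodes)
    t <- match(net$arcs$target, net$nodes)
    sp <- split(t, s)
    adj[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  adj
}

#' Normalized betweenness centrality (Brandes)
#'
#' Betweenness of a vertex v is the sum over ordered pairs (s, t), s != v,
#' t != v, with at least one s->t path, of the fraction of shortest s->t
#' paths passing through v. Shortest paths are by unweighted hop count on
#' the directed graph (Brandes' dependency-accumulation algorithm); scores
#' are normalized by (n-1)(n-2) so they lie in [0, 1]. Networks with fewer
#' than 3 nodes score all zeros.
#'
#' @param net a `functional_network`.
#' @return Named numeric vector of normalized BC scores, one per node.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  n <- length(net$nodes)
  bc <- stats::setNames(numeric(n), net$nodes)
  if (n < 3L || !nrow(net$arcs)) return(bc)
  adj <- adjacency_list(net)
  for (s in seq_len(n)) {
    # BFS from s recording predecessors on shortest paths and path counts
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- rep(list(integer(0)), n)
    stack <- integer(0)
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      stack <- c(stack, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(stack)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / ((n - 1) * (n - 2))
}

#' HITS hub and authority scores
#'
#' Power iteration of the mutually reinforcing hub/authority recursion on
#' the unweighted adjacency matrix A (weighted mode optional): from a
#' uniform positive start, authority <- t(A) %*% hub and hub <- A %*%
#' authority, each L2-normalized per iteration, until the maximum absolute
#' change falls below `tol` or `max_iter` is reached. These are the
#' principal eigenvectors of t(A) A and A t(A). Nodes incident to no arc
#' score 0 in both.
#'
#' @param net a `functional_network` with at least one arc.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @param weighted use aggregated arc weights instead of 0/1 adjacency
#'   (default FALSE).
#' @param start optional positive numeric start vector for the hub scores
#'   (length = number of nodes); defaults to uniform. The fixed point does
#'   not depend on the (positive) start, only the iteration path does.
#' @return list with named numeric vectors `hub` and `authority` (unit L2
#'   norm over nodes), plus `iterations` and `converged`.
#' @export
hits_scores <- function(net, tol = 1e-8, max_iter = 1000L, weighted = FALSE,
                        start = NULL) {
  stopifnot(inherits(net, "functional_network"))
  if (!nrow(net$arcs)) stop("HITS undefined on an arc-free network",
                            call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  si <- match(net$arcs$source, net$nodes)
  ti <- match(net$arcs$target, net$nodes)
  A[cbind(si, ti)] <- if (weighted) net$arcs$weight else 1
  if (is.null(start)) {
    h <- rep(1 / sqrt(n), n)
  } else {
    if (length(start) != n || any(start <= 0)) {
      stop("start must be a positive vector of length n_nodes", call. = FALSE)
    }
    h <- start / sqrt(sum(start^2))
  }
  a <- rep(1 / sqrt(n), n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    a_new <- as.vector(crossprod(A, h))
    na <- sqrt(sum(a_new^2))
    if (na > 0) a_new <- a_new / na
    h_new <- as.vector(A %*% a_new)
    nh <- sqrt(sum(h_new^2))
    if (nh > 0) h_new <- h_new / nh
    delta <- max(abs(a_new - a), abs(h_new - h))
    a <- a_new; h <- h_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(hub = stats::setNames(h, net$nodes),
       authority = stats::setNames(a, net$nodes),
       iterations = iter, converged = converged)
}

#' Rank genes by centrality scores
#'
#' Produces the per-node table behind the prioritization report: normalized
#' betweenness, hub and authority scores with three independent 1-based rank
#' orders (descending score, ties broken by ascending gene id), annotated
#' with seed membership and differential-expression direction so that genes
#' recovered exclusively through functional linkages can be flagged.
#'
#' @param net a `functional_network`.
#' @param bc named vector from [betweenness_centrality()].
#' @param hits list from [hits_scores()].
#' @return data.frame of class `centrality_table` with columns `gene`, `bc`,
#'   `bc_rank`, `hub`, `hub_rank`, `authority`, `authority_rank`, `in_seed`,
#'   `de_direction`, ordered by `bc_rank`.
#' @export
rank_genes <- function(net, bc, hits) {
  nodes <- net$nodes
  for (nm in list(bc, hits$hub, hits$authority)) {
    miss <- setdiff(nodes, names(nm))
    if (length(miss)) stop("score map missing node(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "),
                           call. = FALSE)
  }
  rank_of <- function(score) {
    ord <- order(-score[nodes], nodes)
    r <- integer(length(nodes)); r[ord] <- seq_along(nodes)
    r
  }
  res <- data.frame(gene = nodes,
                    bc = unname(bc[nodes]), bc_rank = rank_of(bc),
                    hub = unname(hits$hub[nodes]), hub_rank = rank_of(hits$hub),
                    authority = unname(hits$authority[nodes]),
                    authority_rank = rank_of(hits$authority),
                    in_seed = unname(net$in_seed[nodes]),
                    de_direction = unname(net$de_direction[nodes]),
                    stringsAsFactors = FALSE)
  res <- res[order(res$bc_rank), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("centrality_table", "data.frame")
  res
}

#' Export a network in Pajek .net format
#'
#' Writes the vertex list (`*Vertices n`, 1-based ids with quoted labels)
#' followed by the weighted `*Arcs` list, for interoperability with Pajek
#' and other network tools.
#'
#' @param net a `functional_network`.
#' @param path output path.
#' @return Invisibly, the network.
#' @export
write_pajek <- function(net, path) {
  n <- length(net$nodes)
  lines <- c(sprintf("*Vertices %d", n),
             sprintf("%d \"%s\"", seq_len(n), net$nodes),
             "*Arcs")
  if (nrow(net$arcs)) {
    lines <- c(lines, sprintf("%d %d %s",
                              match(net$arcs$source, net$nodes),
                              match(net$arcs$target, net$nodes),
                              vapply(net$arcs$weight, format,
                                     character(1L), trim = TRUE,
                                     scientific = FALSE)))
  }
  writeLines(lines, path)
  invisible(net)
}
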