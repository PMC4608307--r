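# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# --- graphs ---------------------------------------------------------------

# random directed graph as a functional_network with n nodes and arc
# probability p (no self loops)
random_digraph <- function(n, p, prefix = "v") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  edges <- edge_table(data.frame(
    source = e$source, target = e$target, weight = rep(1, nrow(e)),
    edge_type = rep("x", nrow(e)), directed = rep(TRUE, nrow(e)),
    stringsAsFactors = FALSE))
  build_network(nodes, edges)
}

# BFS distances and shortest-path counts from one source over an adjacency
# matrix (0/1)
bfs_sigma <- function(A, s) {
  n <- nrow(A)
  dist <- rep(Inf, n); dist[s] <- 0
  sigma <- numeric(n); sigma[s] <- 1
  frontier <- s
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(A[v, ] > 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- d
          nxt <- c(nxt, w)
        }
        if (dist[w] == d) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# betweenness by the pair-combination formula
# BC(v) = sum over (s,t) of sigma_sv * sigma_vt / sigma_st when
# d_sv + d_vt = d_st  (no dependency accumulation)
oracle_bc <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n)
  if (nrow(net$arcs)) {
    A[cbind(match(net$arcs$source, net$nodes),
            match(net$arcs$target, net$nodes))] <- 1
  }
  bf <- lapply(seq_len(n), function(s) bfs_sigma(A, s))
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    if (!is.finite(bf[[s]]$dist[t]) || bf[[s]]$sigma[t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(bf[[s]]$dist[v]) && is.finite(bf[[v]]$dist[t]) &&
          bf[[s]]$dist[v] + bf[[v]]$dist[t] == bf[[s]]$dist[t]) {
        bc[v] <- bc[v] + bf[[s]]$sigma[v] * bf[[v]]$sigma[t] / bf[[s]]$sigma[t]
      }
    }
  }
  stats::setNames(if (n >= 3) bc / ((n - 1) * (n - 2)) else bc * 0, net$nodes)
}

# HITS via dense eigendecomposition of A A^T and A^T A
oracle_hits <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n)
  A[cbind(match(net$arcs$source, net$nodes),
          match(net$arcs$target, net$nodes))] <- 1
  principal <- function(M) {
    v <- eigen(M, symmetric = TRUE)$vectors[, 1L]
    v <- v * sign(sum(v))       # Perron vector of a non-negative matrix
    abs(v) / sqrt(sum(v^2))
  }
  list(hub = stats::setNames(principal(A %*% t(A)), net$nodes),
       authority = stats::setNames(principal(t(A) %*% A), net$nodes))
}

# --- linear models --------------------------------------------------------

# per-gene block ANOVA + contrast through an explicit design-matrix lm fit
oracle_block_fit <- function(y, donor, condition) {
  df <- data.frame(y = y, donor = factor(donor), condition = factor(condition))
  stats::lm(y ~ donor + condition, data = df)
}

oracle_contrast <- function(fit, cond_a, cond_b) {
  cf <- names(stats::coef(fit))
  L <- stats::setNames(numeric(length(cf)), cf)
  pick <- function(cond, sgn) {
    term <- paste0("condition", cond)
    if (term %in% cf) L[term] <<- L[term] + sgn
    # baseline level contributes 0 to the difference
  }
  pick(cond_a, 1); pick(cond_b, -1)
  est <- sum(L * stats::coef(fit))
  se <- sqrt(drop(t(L) %*% stats::vcov(fit) %*% L))
  t <- est / se
  p <- 2 * stats::pt(-abs(t), df = fit$df.residual)
  list(estimate = est, t = t, p = p,
       mse = sum(stats::resid(fit)^2) / fit$df.residual)
}

# --- combinatorics --------------------------------------------------------

# hypergeometric upper tail via explicit log-gamma summation
oracle_hyper_lgamma <- function(k, K, N, n) {
  lo <- pmax(k, pmax(0L, n + K - N))
  hi <- pmin(n, K)
  mapply(function(k1, K1, n1, lo1, hi1) {
    if (lo1 > hi1) return(0)
    i <- lo1:hi1
    sum(exp(lchoose(K1, i) + lchoose(N - K1, n1 - i) - lchoose(N, n1)))
  }, k, K, n, lo, hi)
}

# exact integer-arithmetic oracle, valid while every binomial coefficient
# and partial sum stays below 2^53 (all N <= 25 qualify)
oracle_hyper_exact <- function(k, K, N, n) {
  lo <- max(k, max(0L, n + K - N))
  hi <- min(n, K)
  if (lo > hi) return(0)
  i <- lo:hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# --- misc -----------------------------------------------------------------

# classify genes into the 7 Venn regions one element at a time
oracle_venn_region <- function(gene, a, b, cc) {
  paste0(if (gene %in% a) "A" else "", if (gene %in% b) "B" else "",
         if (gene %in% cc) "C" else "")
}

# small complete-block study built by hand from a gene x (donor, condition)
# value array; values[gene, donor, condition]
study_from_array <- function(values, conditions = nk_conditions()) {
  ng <- dim(values)[1L]; nd <- dim(values)[2L]; nc <- dim(values)[3L]
  genes <- dimnames(values)[[1L]] %||% sprintf("g%d", seq_len(ng))
  donors <- dimnames(values)[[2L]] %||% sprintf("d%d", seq_len(nd))
  conds <- dimnames(values)[[3L]] %||% conditions[seq_len(nc)]
  design <- expand.grid(donor = donors, condition = conds,
                        stringsAsFactors = FALSE)
  design$sample_id <- paste(design$donor, design$condition, sep = ".")
  design$replicate <- 1L
  m <- matrix(NA_real_, ng, nrow(design),
              dimnames = list(genes, design$sample_id))
  for (i in seq_len(nrow(design))) {
    m[, i] <- values[, match(design$donor[i], donors),
                     match(design$condition[i], conds)]
  }
  expression_study(m, design[, c("sample_id", "donor", "condition",
                                 "replicate")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
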