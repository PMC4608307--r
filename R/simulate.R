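#' Default effect-class palette
#'
#' Archetypes mirroring the Venn-region structure of a 2x2 factorial NK-cell
#' stimulation study: genes uniquely regulated by the IgG + IL-12
#' combination, genes shared between a single stimulus and the combination,
#' genes regulated by all three stimuli, and null genes. Effects are
#' per-condition log2 shifts relative to medium (order: medium, IgG, IL12,
#' IgG_IL12). Class sizes follow the per-region counts reported for this
#' design (97 combination-unique up, 133 IgG-shared up, 16 IL12-shared up,
#' 4 up in all three, 164 combination-unique down, 51 IgG-shared down); all
#' remaining genes are null. Planted magnitude is 3-fold, comfortably beyond
#' the 2-fold calling threshold.
#'
#' @return data.frame with columns `class`, `n`, `e_medium`, `e_IgG`,
#'   `e_IL12`, `e_IgG_IL12`.
#' @export
default_effect_classes <- function() {
  l3 <- log2(3)
  data.frame(
    class = c("combo_unique_up", "IgG_shared_up", "IL12_shared_up",
              "all_three_up", "combo_unique_down", "IgG_shared_down"),
    n = c(97L, 133L, 16L, 4L, 164L, 51L),
    e_medium = 0,
    e_IgG = c(0, l3, 0, l3, 0, -l3),
    e_IL12 = c(0, 0, l3, l3, 0, 0),
    e_IgG_IL12 = c(l3, l3, l3, l3, -l3, -l3),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Describes the generative world for [simulate_expression()]: an 8-donor x
#' 4-condition complete block design with duplicate arrays, log2-additive
#' donor (block) and treatment effects, and planted effect classes.
#'
#' intensity(g, d, c, r) = 2^(mu_g + beta_d + tau_gc + eps), with
#' mu_g ~ N(baseline_log2_mean, baseline_log2_sd), beta_d ~ N(0, donor_sd),
#' tau_gc the planted class effect, and
#' eps ~ N(0, sqrt(noise_sd^2 + replicate_sd^2)) drawn independently per
#' measurement.
#'
#' @param n_genes number of simulated genes (default 14500, the array scale;
#'   scale down for tests).
#' @param n_donors number of blocks (default 8).
#' @param n_replicates arrays per donor x condition (default 2, duplicate
#'   hybridizations).
#' @param baseline_log2_mean,baseline_log2_sd log2-scale gene baseline
#'   distribution (defaults 9 and 1.5: median intensity ~512 units, so a
#'   3-fold change clears a 150-unit absolute-difference filter for typical
#'   genes).
#' @param donor_sd log2 sd of the per-donor block effect (default 0.3).
#' @param noise_sd log2 sd of biological/array residual noise (default 0.15).
#' @param replicate_sd additional log2 sd attributable to the duplicate
#'   hybridization (default 0.1).
#' @param effect_classes data.frame as [default_effect_classes()]; class
#'   sizes must sum to at most `n_genes` (remainder is null). When `NULL`
#'   (the default) the default palette is used with its class sizes scaled
#'   proportionally to `n_genes / 14500`, so scaled-down worlds keep the
#'   same planted-effect composition as the full array.
#' @param seed integer driving the single RNG used for all draws.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 14500L, n_donors = 8L,
                              n_replicates = 2L,
                              baseline_log2_mean = 9, baseline_log2_sd = 1.5,
                              donor_sd = 0.3, noise_sd = 0.15,
                              replicate_sd = 0.1,
                              effect_classes = NULL,
                              seed = 1L) {
  if (is.null(effect_classes)) {
    effect_classes <- default_effect_classes()
    effect_classes$n <- as.integer(round(effect_classes$n *
                                           as.integer(n_genes) / 14500))
    effect_classes <- effect_classes[effect_classes$n >= 1L, , drop = FALSE]
  }
  cfg <- list(n_genes = as.integer(n_genes), n_donors = as.integer(n_donors),
              n_replicates = as.integer(n_replicates),
              conditions = nk_conditions(),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              donor_sd = donor_sd, noise_sd = noise_sd,
              replicate_sd = replicate_sd,
              effect_classes = as.data.frame(effect_classes,
                                             stringsAsFactors = FALSE),
              seed = as.integer(seed))
  ec <- cfg$effect_classes
  need <- c("class", "n", "e_medium", "e_IgG", "e_IL12", "e_IgG_IL12")
  miss <- setdiff(need, names(ec))
  if (length(miss)) {
    stop("effect_classes missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ec) && any(ec$e_medium != 0)) {
    stop("effect vectors must have a zero medium entry", call. = FALSE)
  }
  if (sum(ec$n) > cfg$n_genes) {
    stop("effect-class gene counts (", sum(ec$n), ") exceed n_genes (",
         cfg$n_genes, ")", call. = FALSE)
  }
  sds <- c(cfg$baseline_log2_sd, cfg$donor_sd, cfg$noise_sd, cfg$replicate_sd)
  if (any(sds < 0)) stop("all sd parameters must be >= 0", call. = FALSE)
  if (cfg$n_donors < 2L || cfg$n_genes < 1L || cfg$n_replicates < 1L) {
    stop("need n_donors >= 2, n_genes >= 1, n_replicates >= 1", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a blocked factorial expression study with known truth
#'
#' Draws, in a fixed documented order (gene baselines, donor effects, then
#' the residual matrix), from a single Mersenne-Twister stream seeded by
#' `config$seed`, so outputs are bit-identical across runs and platforms.
#'
#' @param config a [simulation_config()].
#' @return list with `study` (an `expression_study`) and `truth` (data.frame
#'   with per-gene class, the four per-condition log2 effects, true fold
#'   change vs medium per stimulated condition, and the expected Venn region
#'   per direction: one of `A`,`B`,`C`,`AB`,`AC`,`BC`,`ABC`, or `""`, where
#'   A = IgG, B = IL12, C = IgG_IL12, membership meaning a planted |effect|
#'   of at least log2(2) in that comparison).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  conds <- cfg$conditions
  genes <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  donors <- sprintf("donor_%d", seq_len(cfg$n_donors))

  ec <- cfg$effect_classes
  class_lab <- rep("null", cfg$n_genes)
  if (nrow(ec)) {
    class_lab[seq_len(sum(ec$n))] <- rep(ec$class, ec$n)
  }
  eff <- matrix(0, nrow = cfg$n_genes, ncol = 4L,
                dimnames = list(genes, conds))
  if (nrow(ec)) {
    idx <- match(class_lab, ec$class)
    planted <- !is.na(idx)
    eff[planted, ] <- as.matrix(ec[idx[planted],
                                   c("e_medium", "e_IgG", "e_IL12",
                                     "e_IgG_IL12")])
  }

  design <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        condition = conds, donor = donors,
                        stringsAsFactors = FALSE)
  design <- design[, c("donor", "condition", "replicate")]
  design$sample_id <- paste(design$donor, design$condition, design$replicate,
                            sep = ".")
  design <- design[, c("sample_id", "donor", "condition", "replicate")]
  n_samp <- nrow(design)

  eps_sd <- sqrt(cfg$noise_sd^2 + cfg$replicate_sd^2)
  sim <- with_sim_rng(cfg$seed, {
    mu <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    beta <- stats::rnorm(cfg$n_donors, 0, cfg$donor_sd)
    eps <- matrix(stats::rnorm(cfg$n_genes * n_samp, 0, eps_sd),
                  nrow = cfg$n_genes, ncol = n_samp)
    list(mu = mu, beta = beta, eps = eps)
  })
  log2m <- sim$mu +
    eff[, match(design$condition, conds), drop = FALSE] +
    matrix(sim$beta[match(design$donor, donors)], nrow = cfg$n_genes,
           ncol = n_samp, byrow = TRUE) +
    sim$eps
  m <- 2^log2m
  dimnames(m) <- list(genes, design$sample_id)
  study <- expression_study(m, design)

  thr <- log2(2)
  region_of <- function(sign) {
    memb <- cbind(A = sign * eff[, "IgG"] >= thr,
                  B = sign * eff[, "IL12"] >= thr,
                  C = sign * eff[, "IgG_IL12"] >= thr)
    apply(memb, 1L, function(r) paste(c("A", "B", "C")[r], collapse = ""))
  }
  truth <- data.frame(
    gene = genes, class = class_lab,
    e_medium = eff[, "medium"], e_IgG = eff[, "IgG"],
    e_IL12 = eff[, "IL12"], e_IgG_IL12 = eff[, "IgG_IL12"],
    fc_IgG = 2^eff[, "IgG"], fc_IL12 = 2^eff[, "IL12"],
    fc_IgG_IL12 = 2^eff[, "IgG_IL12"],
    region_up = region_of(1), region_down = region_of(-1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(study = study, truth = truth)
}

#' Simulate an annotation catalog with planted enriched categories
#'
#' Background categories draw members uniformly at random from all genes;
#' each planted category draws a stated fraction of its members from a named
#' truth class, so a hypergeometric overrepresentation test on that class is
#' expected to flag it.
#'
#' @param truth truth data.frame from [simulate_expression()] (columns `gene`
#'   and `class`).
#' @param n_categories total number of categories (default 50).
#' @param planted list of lists with fields `category` (id), `class` (a truth
#'   class name), `fraction` (in `[0,1]`), and optionally `size`.
#' @param size_range background category sizes drawn uniformly from this
#'   integer range (default 10..40).
#' @param seed integer seed.
#' @return An `annotation_catalog` with universe = all simulated genes.
#' @export
simulate_annotations <- function(truth, n_categories = 50L, planted = list(),
                                 size_range = c(10L, 40L), seed = 1L) {
  genes <- truth$gene
  classes <- split(truth$gene, truth$class)
  for (p in planted) {
    if (!is.null(p$fraction) && (p$fraction < 0 || p$fraction > 1)) {
      stop("enrichment fraction must lie in [0, 1]", call. = FALSE)
    }
    if (is.null(classes[[p$class]])) {
      stop("unknown truth class in planted spec: ", p$class, call. = FALSE)
    }
  }
  n_background <- n_categories - length(planted)
  if (n_background < 0L) stop("more planted categories than n_categories",
                              call. = FALSE)
  with_sim_rng(seed, {
    cats <- list()
    for (p in planted) {
      cls <- classes[[p$class]]
      size <- as.integer(p$size %||% length(cls))
      n_in <- min(round(p$fraction * size), length(cls))
      n_out <- size - n_in
      pool_out <- setdiff(genes, cls)
      members <- c(sample(cls, n_in),
                   if (n_out > 0L) sample(pool_out, min(n_out, length(pool_out))))
      cats[[p$category]] <- members
    }
    for (i in seq_len(n_background)) {
      size <- sample(seq(size_range[1L], size_range[2L]), 1L)
      cats[[sprintf("BG%04d", i)]] <- sample(genes, min(size, length(genes)))
    }
    annotation_catalog(cats, universe = genes)
  })
}

#' Simulate a directed network with planted bridge / hub / authority motifs
#'
#' `bridge`: two dense random directed clusters whose only connection is a
#' designated bridge node with arcs both ways to every cluster node; every
#' inter-cluster pair then has a unique two-hop shortest path through the
#' bridge, so the bridge has the maximum betweenness centrality by
#' construction. `hub_authority`: planted hub nodes arc to every planted
#' authority node (a dense bipartite block) over a sparse random background,
#' so the planted nodes attain the top HITS scores. `both`: disjoint union
#' of the two motifs, except that the bridge attaches through two gateway
#' nodes per cluster instead of all of them — inter-cluster paths still all
#' pass the bridge, while the bridge's adjacency stays spectrally light so
#' the bipartite block dominates the HITS principal component.
#'
#' @param n_cluster_nodes nodes per cluster in the bridge motif (>= 3).
#' @param p_within probability of each directed within-cluster arc (0 < p <= 1).
#' @param motif `"bridge"`, `"hub_authority"`, or `"both"`.
#' @param n_hubs,n_authorities bipartite block dimensions (defaults 3 and 8).
#' @param n_background,p_background sparse background digraph added to the
#'   hub/authority motif (defaults 10 nodes, arc probability 0.05).
#' @param seed integer seed.
#' @return list with `edges` (an `edge_table`, all arcs directed, weight 1)
#'   and `truth` (data.frame `node`, `role` in cluster/bridge/hub/authority/
#'   background).
#' @export
simulate_network <- function(n_cluster_nodes = 6L, p_within = 0.5,
                             motif = c("bridge", "hub_authority", "both"),
                             n_hubs = 3L, n_authorities = 8L,
                             n_background = 10L, p_background = 0.05,
                             seed = 1L) {
  motif <- match.arg(motif)
  if (motif %in% c("bridge", "both")) {
    if (n_cluster_nodes < 3L) stop("n_cluster_nodes must be >= 3", call. = FALSE)
    if (p_within <= 0 || p_within > 1) {
      stop("p_within must lie in (0, 1]", call. = FALSE)
    }
  }
  with_sim_rng(seed, {
    src <- character(0); tgt <- character(0)
    roles <- list()
    add_arc <- function(a, b) {
      src <<- c(src, a); tgt <<- c(tgt, b)
    }
    random_cluster <- function(nodes, p) {
      for (a in nodes) for (b in nodes) {
        if (a != b && stats::runif(1L) < p) add_arc(a, b)
      }
    }
    if (motif %in% c("bridge", "both")) {
      c1 <- sprintf("cl1_%02d", seq_len(n_cluster_nodes))
      c2 <- sprintf("cl2_%02d", seq_len(n_cluster_nodes))
      bridge <- "bridge_1"
      random_cluster(c1, p_within)
      random_cluster(c2, p_within)
      # pure bridge motif: bridge <-> every cluster node, so every
      # inter-cluster pair has the unique 2-hop path through the bridge.
      # combined motif: bridge <-> two gateway nodes per cluster, keeping all
      # inter-cluster paths through the bridge while leaving its adjacency
      # spectrally light so the bipartite block dominates HITS.
      attach <- if (motif == "bridge") c(c1, c2) else
        c(c1[1:2], c2[1:2])
      for (v in attach) {
        add_arc(bridge, v); add_arc(v, bridge)
      }
      roles[[length(roles) + 1L]] <- data.frame(
        node = c(c1, c2, bridge),
        role = c(rep("cluster", 2L * n_cluster_nodes), "bridge"),
        stringsAsFactors = FALSE)
    }
    if (motif %in% c("hub_authority", "both")) {
      hubs <- sprintf("hub_%02d", seq_len(n_hubs))
      auths <- sprintf("auth_%02d", seq_len(n_authorities))
      for (h in hubs) for (a in auths) add_arc(h, a)
      bg <- character(0)
      if (n_background > 0L) {
        bg <- sprintf("bg_%02d", seq_len(n_background))
        random_cluster(bg, p_background)
      }
      roles[[length(roles) + 1L]] <- data.frame(
        node = c(hubs, auths, bg),
        role = c(rep("hub", n_hubs), rep("authority", n_authorities),
                 rep("background", length(bg))),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, roles)
    edges <- edge_table(data.frame(source = src, target = tgt, weight = 1.0,
                                   edge_type = "sim", directed = TRUE,
                                   stringsAsFactors = FALSE))
    list(edges = edges, truth = truth)
  })
}
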