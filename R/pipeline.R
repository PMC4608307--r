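#' Pipeline configuration
#'
#' Either point the pipeline at existing inputs (`matrix_path`,
#' `sample_sheet_path`, `gmt_path`, `edges_path`) or provide a `simulation`
#' block, in which case truth-known inputs are generated first. A JSON file
#' with the same field names can be loaded with [read_pipeline_config()].
#'
#' @param matrix_path,sample_sheet_path,gmt_path,edges_path input file paths
#'   (ignored when `simulation` is given).
#' @param simulation optional list: a [simulation_config()] plus optional
#'   `annotations` (passed to [simulate_annotations()]) and `network`
#'   (passed to [simulate_network()]) blocks.
#' @param thresholds a [de_thresholds()].
#' @param q_max,min_k enrichment selection thresholds (defaults 0.05, 2).
#' @param augment_cap cap on genes added by augmentation (default 500).
#' @param include_neighbors extend the network to first neighbors (default
#'   FALSE).
#' @param top_bc,top_hub,top_authority report list sizes (defaults 20, 9, 9,
#'   the conventional table shapes for this analysis).
#' @param seed integer seed for any simulation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, sample_sheet_path = NULL,
                            gmt_path = NULL, edges_path = NULL,
                            simulation = NULL,
                            thresholds = de_thresholds(),
                            q_max = 0.05, min_k = 2L, augment_cap = 500L,
                            include_neighbors = FALSE,
                            top_bc = 20L, top_hub = 9L, top_authority = 9L,
                            seed = 1L) {
  if (is.null(simulation)) {
    paths <- c(matrix_path, sample_sheet_path, gmt_path, edges_path)
    if (length(paths) < 4L) {
      stop("either a simulation block or all four input paths are required",
           call. = FALSE)
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("input path(s) do not exist: ",
                              paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(matrix_path = matrix_path,
                 sample_sheet_path = sample_sheet_path,
                 gmt_path = gmt_path, edges_path = edges_path,
                 simulation = simulation, thresholds = thresholds,
                 q_max = q_max, min_k = as.integer(min_k),
                 augment_cap = augment_cap,
                 include_neighbors = include_neighbors,
                 top_bc = as.integer(top_bc), top_hub = as.integer(top_hub),
                 top_authority = as.integer(top_authority),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields mirror the [pipeline_config()]
#'   arguments; `thresholds` and `simulation` are nested objects.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- do.call(de_thresholds, as.list(raw$thresholds %||% list()))
  sim <- NULL
  if (!is.null(raw$simulation)) {
    sim_args <- as.list(raw$simulation)
    ann <- sim_args$annotations; net <- sim_args$network
    sim_args$annotations <- NULL; sim_args$network <- NULL
    if (!is.null(sim_args$effect_classes)) {
      sim_args$effect_classes <- as.data.frame(sim_args$effect_classes)
    }
    sim <- list(expression = do.call(simulation_config, sim_args),
                annotations = as.list(ann %||% list()),
                network = as.list(net %||% list()))
  }
  keep <- intersect(names(raw),
                    c("matrix_path", "sample_sheet_path", "gmt_path",
                      "edges_path", "q_max", "min_k", "augment_cap",
                      "include_neighbors", "top_bc", "top_hub",
                      "top_authority", "seed"))
  do.call(pipeline_config,
          c(raw[keep], list(simulation = sim, thresholds = thr)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full prioritization pipeline
#'
#' Stages, each persisting its table into `out_dir`: (1) load or simulate
#' inputs; (2) collapse replicates and record replicate concordance; (3)
#' blocked-ANOVA differential expression with the triple filter; (4) Venn
#' partition of the up and down vs-medium sets; (5) hierarchical clustering
#' of the variable genes; (6) hypergeometric enrichment of the variable-gene
#' seed; (7) enrichment-driven augmentation; (8) network construction,
#' betweenness / HITS scoring and ranking; (9) report with manifest
#' checksums and summary counts. Fully deterministic given config + seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages (default FALSE).
#' @return The report, invisibly also written as `report.json`: list with
#'   `parameters`, `summary`, `top_bc`, `top_hub`, `top_authority`,
#'   `manifest` (file name -> md5).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[nkfcnet] ", ...)
  files <- character(0)
  keep <- function(path) { files <<- c(files, path); path }

  # stage 1: inputs
  if (!is.null(config$simulation)) {
    say("stage simulate: generating inputs")
    sim_cfg <- config$simulation$expression
    sim <- simulate_expression(sim_cfg)
    study <- sim$study
    ann_args <- config$simulation$annotations %||% list()
    ann_args$truth <- sim$truth
    ann_args$seed <- ann_args$seed %||% (config$seed + 1L)
    catalog <- do.call(simulate_annotations, ann_args)
    net_args <- config$simulation$network %||% list()
    net_args$seed <- net_args$seed %||% (config$seed + 2L)
    simnet <- do.call(simulate_network, net_args)
    edges <- simnet$edges
    keep(write_tsv(sim$truth, file.path(out_dir, "truth.tsv")))
    keep(write_tsv(simnet$truth, file.path(out_dir, "network_truth.tsv")))
    write_expression_study(study, file.path(out_dir, "expression.tsv"),
                           file.path(out_dir, "samples.tsv"))
    keep(file.path(out_dir, "expression.tsv"))
    keep(file.path(out_dir, "samples.tsv"))
    write_gmt(catalog, keep(file.path(out_dir, "annotations.gmt")))
    write_edge_table(edges, keep(file.path(out_dir, "edges.tsv")))
  } else {
    say("stage load: reading inputs")
    study <- read_expression_study(config$matrix_path,
                                   config$sample_sheet_path)
    catalog <- read_annotations(config$gmt_path, format = "gmt")
    edges <- read_edge_table(config$edges_path)
    simnet <- NULL
  }

  # stage 2: replicate handling
  if (any(duplicated(paste(study$design$donor, study$design$condition)))) {
    conc <- replicate_concordance(study)
    keep(write_tsv(conc, file.path(out_dir, "replicate_concordance.tsv")))
    study <- collapse_replicates(study)
  }

  # stage 3: differential expression
  say("stage de: blocked ANOVA + triple filter")
  ct <- call_differential_genes(study, config$thresholds)
  keep(write_tsv(as.data.frame(ct), file.path(out_dir, "contrast_table.tsv")))
  prim <- unique(ct$contrast[ct$primary])
  de_counts <- list()
  for (cn in prim) {
    for (dir in c("up", "down")) {
      g <- significant_genes(ct, cn, dir)
      de_counts[[paste(cn, dir, sep = ".")]] <- length(g)
      keep(write_tsv(data.frame(gene = g),
                     file.path(out_dir, sprintf("genes_%s_%s.tsv", cn, dir))))
    }
  }

  # stage 4: Venn partitions
  say("stage venn")
  vlabels <- c("IgG", "IL12", "IgG_IL12")
  venns <- list()
  for (dir in c("up", "down")) {
    sets <- lapply(vlabels, function(cond)
      significant_genes(ct, paste0(cond, "_vs_medium"), dir))
    vp <- venn_partition(sets[[1L]], sets[[2L]], sets[[3L]],
                         labels = vlabels, direction = dir)
    venns[[dir]] <- vp
    keep(write_tsv(venn_membership(vp),
                   file.path(out_dir, sprintf("venn_%s.tsv", dir))))
  }

  # stage 5: clustering of variable genes
  variable <- select_variable_genes(ct)
  if (length(variable) >= 2L) {
    say("stage cluster: ", length(variable), " variable genes")
    cl <- hierarchical_cluster(study, variable)
    keep(write_tsv(data.frame(gene = cl$gene_order,
                              position = seq_along(cl$gene_order)),
                   file.path(out_dir, "cluster_gene_order.tsv")))
    keep(write_tsv(data.frame(sample = cl$sample_order,
                              position = seq_along(cl$sample_order)),
                   file.path(out_dir, "cluster_sample_order.tsv")))
  } else {
    say("stage cluster skipped: fewer than 2 variable genes")
  }

  # stage 6-7: enrichment and augmentation
  say("stage enrich")
  universe <- intersect(catalog$universe, study_genes(study))
  enr <- suppressWarnings(
    hypergeometric_enrichment(variable, catalog, universe = universe))
  keep(write_tsv(as.data.frame(enr), file.path(out_dir, "enrichment.tsv")))
  top_cats <- top_categories(enr, q_max = config$q_max, min_k = config$min_k)
  augmented <- augment_gene_set(variable, top_cats, catalog,
                                cap = config$augment_cap)
  keep(write_tsv(attr(augmented, "provenance"),
                 file.path(out_dir, "augmented_genes.tsv")))

  # stage 8: network + centrality
  net_nodes <- if (length(augmented)) augmented else character(0)
  # when simulating, the network motif nodes are the graph of interest;
  # include them so planted roles are scored even if not differential
  if (!is.null(simnet)) net_nodes <- union(net_nodes, simnet$truth$node)
  ranked <- NULL
  if (length(net_nodes)) {
    dedir <- ct$direction[ct$primary & ct$significant]
    names(dedir) <- ct$gene[ct$primary & ct$significant]
    dedir <- dedir[!duplicated(names(dedir))]
    net <- build_network(net_nodes, edges,
                         include_neighbors = config$include_neighbors,
                         seed_genes = variable, de_direction = dedir)
    if (nrow(net$arcs)) {
      say("stage network: ", length(net$nodes), " nodes, ", nrow(net$arcs),
          " arcs")
      bc <- betweenness_centrality(net)
      hits <- hits_scores(net)
      ranked <- rank_genes(net, bc, hits)
      keep(write_tsv(as.data.frame(ranked),
                     file.path(out_dir, "centrality.tsv")))
      write_pajek(net, keep(file.path(out_dir, "network.net")))
    } else {
      warning("network stage skipped: no arcs among the selected genes",
              call. = FALSE)
    }
  } else {
    warning("network stage skipped: empty gene set", call. = FALSE)
  }

  top_slice <- function(tbl, rank_col, n) {
    if (is.null(tbl)) return(list())
    t2 <- tbl[order(tbl[[rank_col]]), , drop = FALSE]
    t2 <- utils::head(t2, n)
    lapply(seq_len(nrow(t2)), function(i) as.list(t2[i, , drop = FALSE]))
  }
  report <- list(
    parameters = list(thresholds = unclass(config$thresholds),
                      q_max = config$q_max, min_k = config$min_k,
                      augment_cap = config$augment_cap,
                      include_neighbors = config$include_neighbors,
                      seed = config$seed,
                      simulated = !is.null(config$simulation)),
    summary = list(
      n_genes = length(study_genes(study)),
      n_significant = de_counts,
      venn_up = as.list(venns$up$counts),
      venn_down = as.list(venns$down$counts),
      n_variable = length(variable),
      n_enriched = length(top_cats),
      n_augmented = length(augmented),
      network_nodes = if (is.null(ranked)) 0L else nrow(ranked),
      network_arcs = if (is.null(ranked)) 0L else nrow(net$arcs)
    ),
    top_bc = top_slice(ranked, "bc_rank", config$top_bc),
    top_hub = top_slice(ranked, "hub_rank", config$top_hub),
    top_authority = top_slice(ranked, "authority_rank", config$top_authority)
  )
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- basename(files)
  report$manifest <- manifest
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", out_dir)
  invisible(report)
}

#' Summarize and verify a pipeline report directory
#'
#' Re-reads the persisted outputs, recomputes checksums and the headline
#' counts, and errors on any mismatch with the stored manifest.
#'
#' @param report_dir directory produced by [run_pipeline()].
#' @return The verified report list.
#' @export
summarize_report <- function(report_dir) {
  rp <- file.path(report_dir, "report.json")
  if (!file.exists(rp)) stop("missing report file: ", rp, call. = FALSE)
  report <- jsonlite::read_json(rp, simplifyVector = FALSE)
  for (fn in names(report$manifest)) {
    path <- file.path(report_dir, fn)
    if (!file.exists(path)) stop("integrity error: missing file ", fn,
                                 call. = FALSE)
    sum_now <- unname(tools::md5sum(path))
    if (!identical(sum_now, report$manifest[[fn]])) {
      stop("integrity error: checksum mismatch for ", fn, call. = FALSE)
    }
  }
  ct <- utils::read.delim(file.path(report_dir, "contrast_table.tsv"),
                          stringsAsFactors = FALSE)
  for (key in names(report$summary$n_significant)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    cn <- parts[1L]; dir <- parts[2L]
    n_now <- length(unique(ct$gene[ct$contrast == cn & ct$significant &
                                     ct$direction == dir]))
    if (n_now != report$summary$n_significant[[key]]) {
      stop("integrity error: significant-gene count mismatch for ", key,
           call. = FALSE)
    }
  }
  report
}
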