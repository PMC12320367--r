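#' Pipeline configuration
#'
#' Collects every threshold and flag of the pipeline in one list. The
#' defaults are the study conditions: prune at TPM > 10; keep cells with at
#' least 120 features and at most 25% mitochondrial reads; gate TAMs on at
#' least two of CD68/CD163/CD14 above 1; test genes detected in at least 1%
#' of cells in both groups, Bonferroni at 0.05; sweep w2 over 0.05..0.45 in
#' 0.05 steps with w1 = 0.5; build the core from the top 100 motifs; keep
#' FIT >= 0.3 and drugs covering at least 10 of 13 targets.
#'
#' @param ... overrides of any default (see the function definition for the
#'   full set).
#' @return A named list of class `tamnet_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # stage parameters
    tpm_threshold = 10,
    min_features = 120, max_mito_frac = 0.25,
    marker_genes = c("CD68", "CD163", "CD14"),
    min_markers = 2, marker_threshold = 1,
    min_pct = 0.01, alpha = 0.05, bonferroni_m = "tested",
    w2_values = seq(0.05, 0.45, by = 0.05), w1 = 0.5,
    normalize_features = TRUE,
    k = 100, edge_mode = "induced",
    directed_betweenness = TRUE, normalized_betweenness = TRUE,
    min_fit = 0.3, min_targets = 10, n_targets_total = 13,
    seed = 1L,
    # input paths (all optional; in-memory inputs may be given to
    # run_pipeline() instead)
    network = NULL, annotations = NULL,
    counts = NULL, labels = NULL, mito_genes = NULL,
    fit = NULL, dock = NULL,
    housekeeping = NULL, tfs = NULL, inflammation = NULL,
    # stages to skip: any of "prune", "de", "screen"
    skip = character()
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(override)] <- override
  structure(cfg, class = "tamnet_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unset fields fall back to the defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `tamnet_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full target-prioritization pipeline
#'
#' Stages, in order: expression pruning of the network; single-cell QC,
#' TAM gating and differential expression; motif enumeration; topology
#' features; score sweep and Pareto-layered top-K ranking; core-network
#' extraction; target filtering; screening-table ranking. Stages named in
#' `config$skip` are skipped ("de" falls back to node annotations already
#' on the network; "screen" requires no screening tables). Every output is
#' written as plain text under `out_dir`, together with a `manifest.json`
#' recording the resolved configuration and per-stage counts, so a rerun
#' with identical inputs and seed reproduces the directory bit for bit.
#'
#' @param config a `tamnet_config` (or the path to a YAML config).
#' @param inputs optional in-memory inputs overriding the config paths:
#'   a list with any of `network` (`tam_network`), `counts` (cells x genes
#'   matrix), `labels` (named vector), `mito_genes`, `fit`, `dock`
#'   (tibbles), `housekeeping`, `tfs`, `inflammation` (character vectors).
#' @param out_dir output directory; created if needed. `NULL` skips
#'   writing.
#' @return Invisibly, a list with the stage results: `network` (pruned),
#'   `de`, `motifs`, `topology`, `scores`, `top_motifs`, `core`,
#'   `targets`, `screening`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = list(),
                         out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  get_input <- function(name, reader) {
    if (!is.null(inputs[[name]])) return(inputs[[name]])
    if (!is.null(config[[name]])) return(reader(config[[name]]))
    NULL
  }
  net <- get_input("network", read_network)
  if (is.null(net)) abort("a network input is required")
  ann <- get_input("annotations", read_node_annotations)
  if (!is.null(ann)) net <- annotate_network(net, ann)

  manifest <- list(config = config_for_manifest(config), stages = list())
  manifest$stages$input_network <- as.list(glance(net)[c("n_nodes", "n_edges")])

  # --- prune ---------------------------------------------------------
  if (!"prune" %in% config$skip) {
    net <- prune_by_expression(net, config$tpm_threshold)
  }
  manifest$stages$pruned_network <-
    as.list(glance(net)[c("n_nodes", "n_edges", "n_components")])

  # --- differential expression --------------------------------------
  de <- NULL
  if (!"de" %in% config$skip) {
    counts <- get_input("counts", read_cell_counts)
    labels <- get_input("labels", read_cell_labels)
    if (!is.null(counts) && !is.null(labels)) {
      mito <- get_input("mito_genes", read_gene_list) %||% character()
      qc <- qc_filter_cells(counts, mito, config$min_features,
                            config$max_mito_frac)
      labels <- labels[rownames(qc)]
      tam_candidates <- rownames(qc)[labels == "TAM"]
      gated <- intersect(
        gate_tams(qc, config$marker_genes, config$min_markers,
                  config$marker_threshold),
        tam_candidates
      )
      keep <- c(gated, rownames(qc)[labels == "CTRL"])
      de <- differential_expression(
        qc[keep, , drop = FALSE], labels[keep],
        min_pct = config$min_pct, alpha = config$alpha,
        bonferroni_m = config$bonferroni_m
      )
      manifest$stages$de <- list(
        cells_after_qc = nrow(qc), tam_cells = length(gated),
        ctrl_cells = sum(labels[keep] == "CTRL"),
        genes_tested = nrow(de), genes_called = sum(de$called)
      )
    }
  }
  if (is.null(de)) {
    # fall back to DE records annotated on the network nodes
    de <- net$nodes |>
      filter(!is.na(.data$log2fc)) |>
      mutate(called = .data$p_adj < config$alpha) |>
      select("gene", "log2fc", "p_adj", "called")
    manifest$stages$de <- list(source = "node annotations",
                               genes_called = sum(de$called))
  }
  de_called <- filter(de, .data$called)

  # --- motifs, topology, scoring -------------------------------------
  motifs <- enumerate_motifs(net)
  manifest$stages$motifs <- as.list(setNames(
    count_by_template(motifs, default_templates())$n,
    count_by_template(motifs, default_templates())$template_id))
  manifest$stages$motifs$total <- nrow(motifs)

  topo <- topology_features(net, directed = config$directed_betweenness,
                            normalized = config$normalized_betweenness)
  feats <- motif_features(motifs, de_called, topo,
                          normalize = config$normalize_features)
  scores <- score_motifs(feats, weight_grid(config$w2_values, config$w1))
  top <- rank_top_motifs(scores, k = config$k)
  top_instances <- motifs |>
    filter(.data$motif_id %in% top$motif_id) |>
    left_join(top[c("motif_id", "pareto_layer", "rank", "aggregate")],
              by = "motif_id") |>
    arrange(.data$rank)

  # --- core & targets -------------------------------------------------
  core <- extract_core(net, top_instances, edge_mode = config$edge_mode)
  manifest$stages$core <- as.list(glance(core)[c("n_nodes", "n_edges")])

  hk <- get_input("housekeeping", read_gene_list) %||%
    net$nodes$gene[net$nodes$is_housekeeping]
  tfs <- get_input("tfs", read_gene_list) %||% net$nodes$gene[net$nodes$is_tf]
  infl <- get_input("inflammation", read_gene_list) %||%
    net$nodes$gene[net$nodes$is_inflammation]
  targets <- filter_targets(core, de, housekeeping = hk, tfs = tfs,
                            inflammation = infl, alpha = config$alpha)
  manifest$stages$targets <- list(shortlist = sum(targets$retained),
                                  excluded = sum(!targets$retained))

  # --- screening ------------------------------------------------------
  screening <- NULL
  if (!"screen" %in% config$skip) {
    fit <- get_input("fit", function(p) readr::read_csv(p, show_col_types = FALSE))
    dock <- get_input("dock", function(p) readr::read_csv(p, show_col_types = FALSE))
    if (!is.null(fit) && !is.null(dock)) {
      screening <- screen_rank(fit, dock,
                               n_targets_total = config$n_targets_total,
                               min_targets = config$min_targets,
                               min_fit = config$min_fit)
      manifest$stages$screening <- list(
        passing_drugs = nrow(screening$passing_drugs),
        ranked_pairs = nrow(screening$ranking)
      )
    }
  }

  res <- list(network = net, de = de, motifs = motifs, topology = topo,
              scores = scores, top_motifs = top_instances, core = core,
              targets = targets, screening = screening, manifest = manifest)
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  invisible(res)
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg[vapply(cfg, is.null, logical(1))] <- NULL
  cfg
}

write_run_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_network(res$network, file.path(out_dir, "pruned_network.sif"))
  readr::write_tsv(res$de, file.path(out_dir, "differential_expression.tsv"))
  readr::write_tsv(flatten_motifs(res$motifs), file.path(out_dir, "motifs.tsv"))
  readr::write_tsv(res$topology, file.path(out_dir, "topology.tsv"))
  readr::write_tsv(select(res$scores, -dplyr::any_of("nodes")),
                   file.path(out_dir, "motif_scores.tsv"))
  readr::write_tsv(flatten_motifs(res$top_motifs),
                   file.path(out_dir, "top_motifs.tsv"))
  write_network(res$core$network, file.path(out_dir, "core_network.graphml"),
                format = "graphml")
  readr::write_tsv(res$targets, file.path(out_dir, "target_shortlist.tsv"))
  if (!is.null(res$screening)) {
    readr::write_tsv(res$screening$passing_drugs,
                     file.path(out_dir, "passing_drugs.tsv"))
    readr::write_tsv(res$screening$ranking,
                     file.path(out_dir, "drug_target_ranking.tsv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

flatten_motifs <- function(motifs) {
  mutate(motifs,
         nodes = vapply(.data$nodes, paste, character(1), collapse = "|"))
}
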