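#' Extract the core network from top-ranked motifs
#'
#' The core is the union of the node sets of the selected motifs together
#' with either all parent-network edges among those nodes
#' (`edge_mode = "induced"`, default) or only the edges realizing the
#' motifs (`"motif_only"`). Motif membership is recorded per node.
#'
#' @param net the parent `tam_network` (the network the motifs were
#'   enumerated in).
#' @param top_motifs motif tibble (e.g. the output of [rank_top_motifs()],
#'   joined back to the instance table so the `nodes` and `edge_key`
#'   columns are present).
#' @param edge_mode `"induced"` or `"motif_only"`.
#' @return A `tam_core` object: list with the core `network`
#'   (a `tam_network`), a `membership` tibble (`gene`, `motif_ids`
#'   list-column, `n_motifs`) and the `edge_mode`.
#' @export
extract_core <- function(net, top_motifs, edge_mode = c("induced", "motif_only")) {
  edge_mode <- match.arg(edge_mode)
  if (nrow(top_motifs) == 0L) {
    warn("no motifs supplied; core network is empty")
    core_net <- regulatory_network()
    return(structure(list(network = core_net,
                          membership = tibble(gene = character(),
                                              motif_ids = list(),
                                              n_motifs = integer()),
                          edge_mode = edge_mode),
                     class = "tam_core"))
  }
  core_genes <- unique(unlist(top_motifs$nodes))
  missing <- setdiff(core_genes, net$nodes$gene)
  if (length(missing) > 0) {
    abort(sprintf("motif node(s) absent from the network: %s",
                  paste(missing, collapse = ", ")))
  }
  if (edge_mode == "induced") {
    edges <- filter(net$edges, .data$from %in% core_genes,
                    .data$to %in% core_genes)
  } else {
    realized <- unique(unlist(strsplit(top_motifs$edge_key, ";", fixed = TRUE)))
    pairs <- do.call(rbind, strsplit(realized, ">", fixed = TRUE))
    keys <- paste(pairs[, 1], pairs[, 2], sep = ">")
    edges <- filter(net$edges,
                    paste(.data$from, .data$to, sep = ">") %in% keys)
  }
  membership <- purrr::map_dfr(seq_len(nrow(top_motifs)), function(i) {
    tibble(gene = top_motifs$nodes[[i]], motif_id = top_motifs$motif_id[[i]])
  }) |>
    group_by(.data$gene) |>
    summarise(motif_ids = list(unique(.data$motif_id)),
              n_motifs = length(unique(.data$motif_id)), .groups = "drop")
  core_net <- structure(
    list(nodes = filter(net$nodes, .data$gene %in% core_genes),
         edges = edges),
    class = "tam_network"
  )
  structure(list(network = core_net, membership = membership,
                 edge_mode = edge_mode),
            class = "tam_core")
}

#' @export
print.tam_core <- function(x, ...) {
  cat(sprintf("<tam_core> %d nodes, %d edges (%s edges), from %d motifs\n",
              nrow(x$network$nodes), nrow(x$network$edges), x$edge_mode,
              length(unique(unlist(x$membership$motif_ids)))))
  invisible(x)
}

#' @method tidy tam_core
#' @export
tidy.tam_core <- function(x, ...) {
  left_join(x$membership, x$network$nodes, by = "gene") |>
    arrange(desc(.data$n_motifs), .data$gene)
}

#' @method glance tam_core
#' @export
glance.tam_core <- function(x, ...) {
  g <- glance(x$network)
  g$edge_mode <- x$edge_mode
  g
}

#' @method autoplot tam_core
#' @export
autoplot.tam_core <- function(object, ...) autoplot(object$network, ...)

#' Filter core-network genes into a target shortlist
#'
#' Drug-target candidates need specificity for the TAM state, so the core
#' genes are filtered by rule: a gene is retained only if it is
#' significantly upregulated (`log2fc > 0` and `p_adj < alpha`), is neither
#' a housekeeping gene nor a transcription factor, and appears in the
#' user-supplied inflammation gene set. Genes without a
#' differential-expression record cannot be assessed and are excluded.
#' Every excluded gene is reported with its exclusion flags.
#'
#' @param core a `tam_core` object (or a `tam_network`).
#' @param de data frame with `gene`, `log2fc`, `p_adj` columns.
#' @param housekeeping,tfs,inflammation character vectors of gene symbols;
#'   empty sets are allowed (with a warning — an empty inflammation set
#'   excludes everything).
#' @param alpha significance level on the adjusted p-value.
#' @return A tibble `gene`, `log2fc`, `p_adj`, `flags` (comma-joined
#'   exclusion reasons, `""` when retained) and `retained`; retained genes
#'   first, ordered by `log2fc` descending.
#' @export
filter_targets <- function(core, de, housekeeping = character(),
                           tfs = character(), inflammation = character(),
                           alpha = 0.05) {
  net <- if (inherits(core, "tam_core")) core$network else core
  housekeeping <- if (length(housekeeping)) normalize_symbols(housekeeping) else character()
  tfs <- if (length(tfs)) normalize_symbols(tfs) else character()
  inflammation <- if (length(inflammation)) normalize_symbols(inflammation) else character()
  if (length(inflammation) == 0) {
    warn("empty inflammation set: every gene will be excluded as not_inflammation")
  }
  if (length(housekeeping) == 0 && length(tfs) == 0) {
    warn("empty housekeeping and transcription-factor sets: those filters are vacuous")
  }
  de <- as_tibble(de)
  genes <- tibble(gene = net$nodes$gene) |>
    left_join(de[c("gene", "log2fc", "p_adj")], by = "gene")
  flags <- purrr::pmap_chr(genes, function(gene, log2fc, p_adj) {
    f <- character()
    if (is.na(log2fc) || is.na(p_adj)) f <- c(f, "no_de_record")
    else {
      if (log2fc <= 0) f <- c(f, "downregulated")
      if (p_adj >= alpha) f <- c(f, "not_significant")
    }
    if (gene %in% housekeeping) f <- c(f, "housekeeping")
    if (gene %in% tfs) f <- c(f, "transcription_factor")
    if (!gene %in% inflammation) f <- c(f, "not_inflammation")
    paste(f, collapse = ",")
  })
  genes |>
    mutate(flags = flags, retained = flags == "") |>
    arrange(desc(.data$retained), desc(.data$log2fc), .data$gene)
}
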