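#' Build a directed regulatory network
#'
#' The central container of the pipeline: a directed graph of genes/proteins
#' with per-node expression annotations. Edges carry an interaction kind
#' (`"activation"`, `"inhibition"` or `"unspecified"`); nodes carry the mean
#' TPM used for pruning, the projected differential expression (log2 fold
#' change and Bonferroni-adjusted p) used for motif scoring, and annotation
#' flags consumed by the target filter.
#'
#' Gene symbols are upper-cased on ingest and duplicate
#' (source, target, kind) triples are collapsed. Inputs must already use
#' human gene symbols; no orthology translation is performed.
#'
#' @param edges data frame with columns `from`, `to` and optionally `kind`
#'   (unknown or missing kinds become `"unspecified"`).
#' @param nodes optional data frame with column `gene` plus any of
#'   `mean_tpm`, `log2fc`, `p_adj`, `is_housekeeping`, `is_tf`,
#'   `is_inflammation`. Nodes appearing only in `edges` are added with
#'   default annotations.
#' @return An object of class `tam_network`: a list with tibbles `nodes`
#'   and `edges`.
#' @examples
#' net <- regulatory_network(data.frame(from = "A", to = "B", kind = "activation"))
#' net
#' @export
regulatory_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- tibble(from = character(), to = character(), kind = character())
  } else {
    edges <- as_tibble(edges)
    if (!all(c("from", "to") %in% names(edges))) {
      abort("`edges` needs columns `from` and `to`")
    }
    if (!"kind" %in% names(edges)) edges$kind <- "unspecified"
    edges <- tibble(
      from = normalize_symbols(edges$from),
      to   = normalize_symbols(edges$to),
      kind = canonical_kind(edges$kind)
    )
    edges <- distinct(edges)
  }

  node_genes <- unique(c(edges$from, edges$to))
  if (!is.null(nodes)) {
    nodes <- as_tibble(nodes)
    if (!"gene" %in% names(nodes)) abort("`nodes` needs a `gene` column")
    nodes$gene <- normalize_symbols(nodes$gene)
    if (anyDuplicated(nodes$gene)) abort("duplicate genes in `nodes`")
    node_genes <- union(nodes$gene, node_genes)
  }
  out_nodes <- tibble(gene = node_genes)
  defaults <- tibble(
    gene = node_genes,
    mean_tpm = NA_real_, log2fc = NA_real_, p_adj = NA_real_,
    is_housekeeping = FALSE, is_tf = FALSE, is_inflammation = FALSE
  )
  if (!is.null(nodes)) {
    keep <- intersect(names(defaults), names(nodes))
    defaults <- rows_patch_by_gene(defaults, nodes[keep])
  }
  net <- structure(list(nodes = defaults, edges = edges), class = "tam_network")
  validate_tam_network(net)
}

# Overwrite default annotation values with user-supplied ones, by gene.
rows_patch_by_gene <- function(base, patch) {
  idx <- match(patch$gene, base$gene)
  for (col in setdiff(names(patch), "gene")) {
    vals <- patch[[col]]
    ok <- !is.na(vals)
    base[[col]][idx[ok]] <- vals[ok]
  }
  base
}

canonical_kind <- function(kind) {
  kind <- tolower(trimws(as.character(kind)))
  kind[is.na(kind)] <- "unspecified"
  out <- rep("unspecified", length(kind))
  out[kind %in% c("activation", "activate", "activates", "positive", "->")] <- "activation"
  out[kind %in% c("inhibition", "inhibit", "inhibits", "negative", "-|")] <- "inhibition"
  out
}

validate_tam_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (!all(edges$from %in% nodes$gene) || !all(edges$to %in% nodes$gene)) {
    abort("edge endpoints must be members of the node set")
  }
  if (anyDuplicated(edges[c("from", "to", "kind")])) {
    abort("duplicate (from, to, kind) edges")
  }
  tpm <- nodes$mean_tpm
  if (any(!is.na(tpm) & tpm < 0)) abort("mean_tpm must be non-negative")
  pa <- nodes$p_adj
  if (any(!is.na(pa) & (pa < 0 | pa > 1))) abort("p_adj must lie in [0, 1]")
  if (any(is.na(nodes$log2fc) != is.na(pa))) {
    abort("log2fc and p_adj must be present or absent together")
  }
  net
}

#' @export
print.tam_network <- function(x, ...) {
  cat(sprintf("<tam_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  n_ann <- sum(!is.na(x$nodes$mean_tpm))
  if (n_ann > 0) cat(sprintf("  %d nodes with mean TPM annotation\n", n_ann))
  n_de <- sum(!is.na(x$nodes$log2fc))
  if (n_de > 0) cat(sprintf("  %d nodes with differential expression\n", n_de))
  invisible(x)
}

#' Convert a regulatory network to an igraph object
#'
#' Node annotations become vertex attributes and the interaction kind an
#' edge attribute, so the graph can be handed to any igraph routine.
#'
#' @param x a `tam_network`.
#' @param ... unused.
#' @return A directed `igraph` graph.
#' @importFrom igraph as.igraph
#' @method as.igraph tam_network
#' @export
as.igraph.tam_network <- function(x, ...) {
  igraph::graph_from_data_frame(x$edges, directed = TRUE, vertices = x$nodes)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Edge table of a regulatory network
#'
#' @param x a `tam_network`.
#' @param ... unused.
#' @return A tibble with one row per directed edge (`from`, `to`, `kind`).
#' @method tidy tam_network
#' @export
tidy.tam_network <- function(x, ...) x$edges

#' One-row summary of a regulatory network
#'
#' Reports node/edge counts and the number of weakly connected components —
#' the pipeline never forces a single component, so fragmentation after
#' pruning is surfaced here.
#'
#' @param x a `tam_network`.
#' @param ... unused.
#' @return A one-row tibble with `n_nodes`, `n_edges`, `n_components`,
#'   `n_annotated` (nodes with mean TPM) and `n_de` (nodes with DE records).
#' @method glance tam_network
#' @export
glance.tam_network <- function(x, ...) {
  n_comp <- if (nrow(x$nodes) == 0) 0L else {
    igraph::count_components(as.igraph.tam_network(x), mode = "weak")
  }
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_components = n_comp,
    n_annotated = sum(!is.na(x$nodes$mean_tpm)),
    n_de = sum(!is.na(x$nodes$log2fc))
  )
}

#' Read a regulatory network from SIF or GraphML
#'
#' SIF rows are `source<TAB>relation<TAB>target`; unknown relation labels
#' map to kind `"unspecified"` and duplicate rows are collapsed. GraphML
#' files written by [write_network()] round-trip node annotations.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sif"` or `"graphml"`.
#' @return A [regulatory_network()] object.
#' @export
read_network <- function(path, format = c("auto", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "sif"
  }
  if (!file.exists(path)) abort(sprintf("network file not found: %s", path))
  if (format == "sif") read_sif(path) else read_graphml(path)
}

read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("empty network file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed SIF row at line %d of %s (expected 3 tab-separated fields)",
                  bad[1], path))
  }
  m <- do.call(rbind, parts)
  regulatory_network(tibble(from = m[, 1], kind = m[, 2], to = m[, 3]))
}

read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0L) abort(sprintf("empty network file: %s", path))
  va <- igraph::vertex_attr(g)
  nodes <- tibble(gene = as.character(va$name %||% seq_len(igraph::vcount(g))))
  for (col in c("mean_tpm", "log2fc", "p_adj")) {
    if (!is.null(va[[col]])) nodes[[col]] <- clean_na(as.numeric(va[[col]]))
  }
  for (col in c("is_housekeeping", "is_tf", "is_inflammation")) {
    if (!is.null(va[[col]])) nodes[[col]] <- as.logical(va[[col]]) %in% TRUE
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  kind <- igraph::edge_attr(g, "kind") %||% rep("unspecified", nrow(el))
  regulatory_network(tibble(from = el[, 1], to = el[, 2], kind = kind),
                     nodes = nodes)
}

# igraph serializes NA numerics as NaN in GraphML
clean_na <- function(x) { x[is.nan(x)] <- NA_real_; x }

#' Write a regulatory network to SIF or GraphML
#'
#' SIF loses node annotations (three columns only); GraphML preserves them
#' as node attributes so that `read_network(write_network(net))` recovers
#' the network, annotations included.
#'
#' @param net a `tam_network`.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "sif"
  }
  validate_tam_network(net)
  if (format == "sif") {
    readr::write_tsv(net$edges[c("from", "kind", "to")], path, col_names = FALSE)
  } else {
    igraph::write_graph(as.igraph.tam_network(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read a node-annotation side-car table
#'
#' Tab-separated with a `gene` column and any of `mean_tpm`, `log2fc`,
#' `p_adj`, `is_housekeeping`, `is_tf`, `is_inflammation`.
#'
#' @param path TSV file path.
#' @return A tibble suitable for [annotate_network()].
#' @export
read_node_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene" %in% names(ann)) abort("annotation table needs a `gene` column")
  ann$gene <- normalize_symbols(ann$gene)
  as_tibble(ann)
}

#' Attach or overwrite node annotations
#'
#' @param net a `tam_network`.
#' @param annotations data frame with `gene` plus annotation columns
#'   (see [read_node_annotations()]). Genes absent from the network are
#'   ignored with a warning.
#' @return The annotated `tam_network`.
#' @export
annotate_network <- function(net, annotations) {
  annotations <- as_tibble(annotations)
  annotations$gene <- normalize_symbols(annotations$gene)
  missing <- setdiff(annotations$gene, net$nodes$gene)
  if (length(missing) > 0) {
    warn(sprintf("%d annotated genes are not in the network (e.g. %s)",
                 length(missing), missing[1]))
    annotations <- filter(annotations, .data$gene %in% net$nodes$gene)
  }
  keep <- intersect(names(net$nodes), names(annotations))
  net$nodes <- rows_patch_by_gene(net$nodes, annotations[keep])
  validate_tam_network(net)
}

#' Prune a network by average expression
#'
#' Retains nodes whose average TPM is strictly greater than the threshold
#' (default 10) and whose degree in the pruned graph is at least one.
#' Zero-degree removal is iterated to a fixed point, because the joint
#' TPM-and-degree condition is otherwise order dependent: removing a
#' low-expression node can orphan its neighbours, which are then removed in
#' turn. Nodes without a TPM annotation are treated as zero expression.
#'
#' @param net a `tam_network`.
#' @param tpm_threshold non-negative expression cut-off in TPM.
#' @return The pruned `tam_network` (a subgraph of the input, with the
#'   induced edges).
#' @export
prune_by_expression <- function(net, tpm_threshold = 10) {
  check_number(tpm_threshold, "tpm_threshold", min = 0)
  tpm <- ifelse(is.na(net$nodes$mean_tpm), 0, net$nodes$mean_tpm)
  keep <- net$nodes$gene[tpm > tpm_threshold]
  edges <- filter(net$edges, .data$from %in% keep, .data$to %in% keep)
  repeat {
    connected <- unique(c(edges$from, edges$to))
    keep2 <- intersect(keep, connected)
    if (length(keep2) == length(keep)) break
    keep <- keep2
    edges <- filter(edges, .data$from %in% keep, .data$to %in% keep)
  }
  structure(
    list(nodes = filter(net$nodes, .data$gene %in% keep), edges = edges),
    class = "tam_network"
  )
}

#' Plot a regulatory network
#'
#' Force-directed layout with edges coloured by interaction kind. Intended
#' for the (small) core network; large networks are better explored in a
#' dedicated viewer.
#'
#' @param object a `tam_network`.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_text
#'   theme_void arrow unit labs
#' @method autoplot tam_network
#' @export
autoplot.tam_network <- function(object, ...) {
  g <- as.igraph.tam_network(object)
  xy <- igraph::layout_with_fr(g)
  lay <- tibble(gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  ed <- object$edges |>
    left_join(setNames(lay, c("from", "x0", "y0")), by = "from") |>
    left_join(setNames(lay, c("to", "x1", "y1")), by = "to")
  ggplot() +
    geom_segment(data = ed,
                 aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                     colour = .data$kind),
                 arrow = arrow(length = unit(1.5, "mm")), alpha = 0.6) +
    geom_point(data = lay, aes(x = .data$x, y = .data$y), size = 2) +
    geom_text(data = lay, aes(x = .data$x, y = .data$y, label = .data$gene),
              vjust = -0.8, size = 2.8) +
    labs(colour = "interaction") +
    theme_void()
}

#' @export
ggplot2::autoplot
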