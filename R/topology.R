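#' Node degree
#'
#' Total degree (in + out) per node. Self-loops count twice and parallel
#' edges of different interaction kind each count once, so the degrees sum
#' to twice the number of edges.
#'
#' @param net a `tam_network`.
#' @return A tibble `gene`, `degree`, covering every node (isolates get 0).
#' @export
node_degree <- function(net) {
  ends <- c(net$edges$from, net$edges$to)
  deg <- table(factor(ends, levels = net$nodes$gene))
  tibble(gene = net$nodes$gene, degree = as.integer(deg))
}

#' Betweenness centrality
#'
#' Exact betweenness on unweighted shortest paths, endpoints excluded,
#' computed on the simple digraph (parallel edges collapsed, self-loops
#' dropped — neither can lie on a shortest path). Unreachable pairs
#' contribute zero. With `normalized = TRUE` values are divided by
#' `(n-1)(n-2)` for directed graphs and `(n-1)(n-2)/2` for undirected ones.
#'
#' @param net a `tam_network`.
#' @param directed treat edges as directed (default) or collapse direction.
#' @param normalized scale into `[0, 1]`.
#' @return A tibble `gene`, `betweenness`.
#' @export
betweenness_centrality <- function(net, directed = TRUE, normalized = TRUE) {
  n <- nrow(net$nodes)
  if (n == 0L) return(tibble(gene = character(), betweenness = double()))
  g <- as.igraph.tam_network(net)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  bc <- igraph::betweenness(g, directed = directed, normalized = FALSE)
  if (normalized && n > 2) {
    denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
    bc <- bc / denom
  } else if (normalized) {
    bc <- rep(0, n)
  }
  tibble(gene = igraph::V(g)$name, betweenness = as.numeric(bc))
}

#' Topological features used by the motif score
#'
#' @param net a `tam_network`.
#' @param directed,normalized passed to [betweenness_centrality()].
#' @return A tibble `gene`, `degree`, `betweenness`.
#' @export
topology_features <- function(net, directed = TRUE, normalized = TRUE) {
  left_join(node_degree(net),
            betweenness_centrality(net, directed, normalized),
            by = "gene")
}
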