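#' Weight grid for the motif score sweep
#'
#' The motif score is `Score_i = w1*FC_i + w2*BC_i + w3*D_i` with the
#' expression weight fixed at `w1 = 0.5` (equal relevance of expression and
#' topology) and the topology split swept: `w2` runs over
#' `0.05, 0.10, ..., 0.45` with `w3 = 0.5 - w2`, giving nine weight
#' settings that always sum to one.
#'
#' @param w2_values ordered vector of betweenness weights in `[0, 0.5]`.
#' @param w1 expression weight (fixed at 0.5 by default).
#' @return A tibble `w1`, `w2`, `w3`, one row per grid point.
#' @export
weight_grid <- function(w2_values = seq(0.05, 0.45, by = 0.05), w1 = 0.5) {
  check_number(w1, "w1", min = 0, max = 1)
  if (any(w2_values < 0 | w2_values > 1 - w1)) {
    abort("`w2_values` must lie in [0, 1 - w1] so all weights are non-negative")
  }
  tibble(w1 = w1, w2 = as.numeric(w2_values), w3 = 1 - w1 - w2_values)
}

#' Per-motif feature averages
#'
#' For each motif instance, the arithmetic mean over its node set of the
#' log2 fold change (`fc`), betweenness centrality (`bc`) and degree
#' (`deg`). Nodes without a differential-expression record contribute a
#' fold change of zero. With `normalize = TRUE` (default) each feature is
#' min-max scaled to `[0, 1]` across all motifs before any weighting — raw
#' degrees are orders of magnitude larger than fold changes and would
#' otherwise dominate the score; a feature constant across motifs maps
#' to zero.
#'
#' @param motifs instance tibble from [enumerate_motifs()].
#' @param de data frame with columns `gene` and `log2fc` (e.g. the called
#'   subset of a [differential_expression()] table), or `NULL` for all-zero
#'   fold changes.
#' @param topology tibble from [topology_features()] on the same network
#'   the motifs were enumerated in; every motif node must appear.
#' @param normalize min-max scale the three features across motifs.
#' @return A tibble `motif_id`, `template_id`, `node_key`, `fc`, `bc`,
#'   `deg`.
#' @export
motif_features <- function(motifs, de, topology, normalize = TRUE) {
  fc_map <- setNames(rep(0, nrow(topology)), topology$gene)
  if (!is.null(de) && nrow(as.data.frame(de)) > 0) {
    de <- as_tibble(de)
    known <- intersect(de$gene, names(fc_map))
    fc_map[known] <- de$log2fc[match(known, de$gene)]
  }
  bc_map <- setNames(topology$betweenness, topology$gene)
  deg_map <- setNames(as.numeric(topology$degree), topology$gene)
  feats <- purrr::map_dfr(seq_len(nrow(motifs)), function(i) {
    nodes <- motifs$nodes[[i]]
    missing <- setdiff(nodes, topology$gene)
    if (length(missing) > 0) {
      abort(sprintf("motif %s references node(s) absent from the network: %s",
                    motifs$motif_id[[i]], paste(missing, collapse = ", ")))
    }
    tibble(motif_id = motifs$motif_id[[i]],
           template_id = motifs$template_id[[i]],
           node_key = motifs$node_key[[i]],
           fc = mean(fc_map[nodes]),
           bc = mean(bc_map[nodes]),
           deg = mean(deg_map[nodes]))
  })
  if (normalize && nrow(feats) > 0) {
    feats <- mutate(feats, across(c("fc", "bc", "deg"), minmax_scale))
  }
  feats
}

minmax_scale <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Score motifs over the weight grid
#'
#' Applies `Score_i = w1*fc + w2*bc + w3*deg` at every grid point, and adds
#' the mean score across the grid (`aggregate`).
#'
#' @param features tibble from [motif_features()].
#' @param grid tibble from [weight_grid()].
#' @return The feature tibble with one score column per grid point
#'   (`score_w2_0.05`, ...) and an `aggregate` column.
#' @export
score_motifs <- function(features, grid = weight_grid()) {
  if (any(grid$w1 < 0 | grid$w2 < 0 | grid$w3 < 0) ||
      any(grid$w1 > 1 | grid$w2 > 1 | grid$w3 > 1)) {
    abort("weights must lie in [0, 1]")
  }
  sc <- outer(features$fc, grid$w1) + outer(features$bc, grid$w2) +
    outer(features$deg, grid$w3)
  colnames(sc) <- score_col_names(grid)
  bind_cols(features, as_tibble(sc), aggregate = rowMeans(sc))
}

score_col_names <- function(grid) sprintf("score_w2_%.2f", grid$w2)

score_cols <- function(scores) grep("^score_w2_", names(scores), value = TRUE)

#' Pareto frontier of motif score vectors
#'
#' Returns exactly the rows whose score vectors are not dominated under
#' component-wise maximization: `v` dominates `u` when `v >= u` in every
#' component and `v > u` in at least one. Duplicates of a frontier vector
#' are all retained (a copy never strictly beats its twin).
#'
#' @param scores tibble from [score_motifs()] (or any tibble with the
#'   score columns).
#' @return The non-dominated subset of `scores`, original order preserved.
#' @export
pareto_frontier <- function(scores) {
  cols <- score_cols(scores)
  if (length(cols) == 0) abort("no score columns found")
  m <- as.matrix(scores[cols])
  scores[non_dominated(m), , drop = FALSE]
}

# Skyline scan: only a vector with a strictly larger coordinate sum can
# dominate, so process in decreasing-sum order against the running frontier.
non_dominated <- function(m) {
  n <- nrow(m)
  if (n == 0) return(logical(0))
  ord <- order(rowSums(m), decreasing = TRUE)
  keep <- logical(n)
  front <- matrix(numeric(0), ncol = ncol(m))
  for (i in ord) {
    v <- m[i, ]
    if (nrow(front) > 0) {
      ge <- front >= matrix(v, nrow(front), ncol(m), byrow = TRUE)
      gt <- front > matrix(v, nrow(front), ncol(m), byrow = TRUE)
      if (any(rowSums(ge) == ncol(m) & rowSums(gt) > 0)) next
    }
    keep[i] <- TRUE
    front <- rbind(front, v)
  }
  keep
}

#' Rank motifs by Pareto layer and mean score
#'
#' Successive Pareto frontiers are peeled off until at least `k` motifs are
#' ranked; within a layer motifs are ordered by mean score over the weight
#' grid (descending), with ties broken deterministically by the sorted node
#' tuple. The top-`k` head of this ranking defines the core network.
#'
#' @param scores tibble from [score_motifs()].
#' @param k number of motifs to return (default 100, the core size used for
#'   target selection). When `k` exceeds the number of motifs, all are
#'   returned with a warning.
#' @return The ranked tibble with columns `pareto_layer` and `rank`,
#'   at most `k` rows.
#' @export
rank_top_motifs <- function(scores, k = 100) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be >= 1")
  if (k > nrow(scores)) {
    warn(sprintf("k = %d exceeds the %d motifs available; returning all",
                 k, nrow(scores)))
    k <- nrow(scores)
  }
  if (nrow(scores) == 0) return(mutate(scores, pareto_layer = integer(),
                                       rank = integer()))
  remaining <- mutate(scores, pareto_layer = NA_integer_)
  ranked <- remaining[0, ]
  layer <- 0L
  while (nrow(ranked) < k && nrow(remaining) > 0) {
    layer <- layer + 1L
    front <- pareto_frontier(remaining)
    front$pareto_layer <- layer
    ranked <- bind_rows(ranked, arrange(front, desc(.data$aggregate),
                                        .data$node_key))
    remaining <- filter(remaining, !.data$motif_id %in% front$motif_id)
  }
  ranked |>
    utils::head(k) |>
    mutate(rank = row_number())
}

#' Scatter of motif scores coloured by Pareto layer
#'
#' @param object ranked tibble from [rank_top_motifs()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_motif_ranking <- function(object, ...) {
  ggplot(object, aes(x = .data$rank, y = .data$aggregate,
                     colour = factor(.data$pareto_layer))) +
    geom_point() +
    labs(x = "rank", y = "mean score over weight grid",
         colour = "Pareto layer")
}
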