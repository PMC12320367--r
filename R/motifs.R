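#' Default feedback- and feed-forward-loop templates
#'
#' Seven directed patterns on at most four placeholder nodes: four feedback
#' loops (the self-loop `FBL1` and the directed cycles of length two, three
#' and four) and three feed-forward loops (`FFL3`: a regulator hitting a
#' target directly and through one intermediate; `FFL4_chain`: a three-step
#' cascade with a direct shortcut; `FFL4_diamond`: two parallel two-step
#' routes from regulator to target). Alternative patterns can be supplied
#' as a YAML file via [read_templates()].
#'
#' @return A tibble with columns `template_id`, `n_nodes` and a list-column
#'   `edges` of two-column integer matrices over placeholder indices.
#' @examples
#' default_templates()
#' @export
default_templates <- function() {
  tpl <- function(id, n, edges) {
    tibble(template_id = id, n_nodes = n,
           edges = list(matrix(edges, ncol = 2, byrow = TRUE)))
  }
  bind_rows(
    tpl("FBL1", 1L, c(1L, 1L)),
    tpl("FBL2", 2L, c(1L, 2L, 2L, 1L)),
    tpl("FBL3", 3L, c(1L, 2L, 2L, 3L, 3L, 1L)),
    tpl("FBL4", 4L, c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 1L)),
    tpl("FFL3", 3L, c(1L, 2L, 2L, 3L, 1L, 3L)),
    tpl("FFL4_chain", 4L, c(1L, 2L, 2L, 3L, 3L, 4L, 1L, 4L)),
    tpl("FFL4_diamond", 4L, c(1L, 2L, 2L, 4L, 1L, 3L, 3L, 4L))
  )
}

#' Read motif templates from a YAML file
#'
#' The file is a list of entries with fields `id`, `nodes` (placeholder
#' count, at most 4) and `edges` (list of two-element placeholder-index
#' pairs). Every pattern must be weakly connected.
#'
#' @param path YAML file path.
#' @return A template tibble as returned by [default_templates()].
#' @export
read_templates <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- purrr::map_dfr(raw, function(t) {
    edges <- matrix(as.integer(unlist(t$edges)), ncol = 2, byrow = TRUE)
    tibble(template_id = as.character(t$id), n_nodes = as.integer(t$nodes),
           edges = list(edges))
  })
  validate_templates(out)
}

validate_templates <- function(templates) {
  for (i in seq_len(nrow(templates))) {
    n <- templates$n_nodes[[i]]
    e <- templates$edges[[i]]
    if (n < 1L || n > 4L) abort("templates must have 1 to 4 nodes")
    if (any(e < 1L | e > n)) abort("template edges reference undefined placeholders")
    if (length(unique(as.vector(e))) < n || !template_connected(n, e)) {
      abort(sprintf("template %s is not weakly connected",
                    templates$template_id[[i]]))
    }
    if (anyDuplicated(paste(e[, 1], e[, 2]))) {
      abort("duplicate edges in template pattern")
    }
  }
  templates
}

template_connected <- function(n, edges) {
  if (n == 1L) return(TRUE)
  reach <- 1L
  repeat {
    nxt <- unique(c(reach,
                    edges[edges[, 1] %in% reach, 2],
                    edges[edges[, 2] %in% reach, 1]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  length(reach) == n
}

# Order placeholders so each one after the first touches an earlier one;
# the matcher then only ever extends along known adjacencies.
placeholder_order <- function(n, edges) {
  ord <- 1L
  while (length(ord) < n) {
    nxt <- setdiff(unique(c(edges[edges[, 1] %in% ord, 2],
                            edges[edges[, 2] %in% ord, 1])), ord)
    ord <- c(ord, nxt[1])
  }
  ord
}

#' Enumerate motif instances in a network
#'
#' Matches every template against the network by injective assignment of
#' placeholders to nodes: an instance exists whenever all pattern edges are
#' present (extra edges among the nodes are allowed — matching is not
#' induced). Matching ignores the interaction kind. Each distinct
#' (template, node set, edge set) realization is reported exactly once, so
#' a directed cycle is counted once per cyclic node set rather than once
#' per rotation, while feed-forward loops with different regulator/target
#' role assignments (hence different edge sets) stay distinct.
#'
#' @param net a `tam_network`.
#' @param templates template tibble ([default_templates()] by default).
#' @return A tibble with one row per instance: `motif_id`, `template_id`,
#'   `nodes` (list-column, placeholder order), `node_key` (sorted node
#'   string) and `edge_key` (sorted `from>to` string).
#' @export
enumerate_motifs <- function(net, templates = default_templates()) {
  validate_templates(templates)
  # adjacency on distinct ordered pairs; kind is ignored during matching
  ed <- distinct(net$edges[c("from", "to")])
  out_adj <- split(ed$to, factor(ed$from, levels = net$nodes$gene))
  in_adj <- split(ed$from, factor(ed$to, levels = net$nodes$gene))
  edge_set <- paste(ed$from, ed$to, sep = ">")

  res <- purrr::map_dfr(seq_len(nrow(templates)), function(ti) {
    match_template(templates$template_id[[ti]], templates$n_nodes[[ti]],
                   templates$edges[[ti]], out_adj, in_adj, edge_set,
                   net$nodes$gene)
  })
  if (nrow(res) == 0L) {
    return(tibble(motif_id = character(), template_id = character(),
                  nodes = list(), node_key = character(),
                  edge_key = character()))
  }
  res <- res |>
    distinct(.data$template_id, .data$node_key, .data$edge_key,
             .keep_all = TRUE) |>
    arrange(.data$template_id, .data$node_key, .data$edge_key) |>
    mutate(motif_id = sprintf("M%05d", row_number())) |>
    select("motif_id", "template_id", "nodes", "node_key", "edge_key")
  res
}

match_template <- function(id, n, tedges, out_adj, in_adj, edge_set, genes) {
  if (n == 1L) {
    loops <- genes[vapply(genes, function(g) g %in% out_adj[[g]], logical(1))]
    if (length(loops) == 0L) return(NULL)
    return(tibble(template_id = id, nodes = as.list(loops),
                  node_key = loops, edge_key = paste(loops, loops, sep = ">")))
  }
  ord <- placeholder_order(n, tedges)
  acc <- list()
  assign_next <- function(assigned, pos) {
    if (pos > n) {
      nodes <- character(n)
      nodes[ord] <- assigned
      realized <- paste(nodes[tedges[, 1]], nodes[tedges[, 2]], sep = ">")
      acc[[length(acc) + 1L]] <<- list(nodes = nodes, realized = realized)
      return(invisible())
    }
    p <- ord[pos]
    cands <- NULL
    for (k in seq_len(nrow(tedges))) {
      a <- tedges[k, 1]; b <- tedges[k, 2]
      prev <- ord[seq_len(pos - 1)]
      if (a == p && b %in% prev) {
        c_k <- in_adj[[assigned[match(b, ord)]]]
      } else if (b == p && a %in% prev) {
        c_k <- out_adj[[assigned[match(a, ord)]]]
      } else next
      cands <- if (is.null(cands)) c_k else intersect(cands, c_k)
      if (length(cands) == 0L) return(invisible())
    }
    cands <- setdiff(unique(cands), assigned)
    for (g in cands) assign_next(c(assigned, g), pos + 1L)
    invisible()
  }
  starts <- unique(c(names(out_adj)[lengths(out_adj) > 0],
                     names(in_adj)[lengths(in_adj) > 0]))
  for (g in starts) assign_next(g, 2L)
  if (length(acc) == 0L) return(NULL)
  nodes_list <- lapply(acc, `[[`, "nodes")
  edge_keys <- vapply(acc, function(a) paste(sort(a$realized), collapse = ";"),
                      character(1))
  ok <- vapply(acc, function(a) all(a$realized %in% edge_set), logical(1))
  if (!any(ok)) return(NULL)
  tibble(
    template_id = id,
    nodes = nodes_list[ok],
    node_key = vapply(nodes_list[ok],
                      function(x) paste(sort(x), collapse = "|"), character(1)),
    edge_key = edge_keys[ok]
  )
}

#' Count motif instances per template
#'
#' @param instances tibble from [enumerate_motifs()].
#' @param templates optional template tibble; when given, templates without
#'   instances appear with a zero count.
#' @return A tibble `template_id`, `n`; counts sum to `nrow(instances)`.
#' @export
count_by_template <- function(instances, templates = NULL) {
  out <- count(instances, .data$template_id)
  if (!is.null(templates)) {
    out <- tibble(template_id = templates$template_id) |>
      left_join(out, by = "template_id") |>
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  }
  out
}
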