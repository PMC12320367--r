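# Independent brute-force oracles used to validate the implementation.
# These deliberately take the dumbest correct route: exhaustive enumeration
# over subsets, permutations, assignments or paths.

# Random directed graph as a tam_network; self_loop_p adds self-loops.
rand_digraph <- function(n, p, seed, self_loop_p = 0) {
  set.seed(seed)
  genes <- sprintf("N%02d", seq_len(n))
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- stats::runif(n) < self_loop_p
  idx <- which(adj, arr.ind = TRUE)
  if (nrow(idx) == 0) return(regulatory_network(nodes = data.frame(gene = genes)))
  regulatory_network(data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]]),
                     nodes = data.frame(gene = genes))
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(k), function(i) {
    sub <- all_permutations(k - 1)
    cbind(i, matrix((seq_len(k)[-i])[sub], nrow(sub), k - 1))
  }))
}

# Exhaustive motif matcher: every node subset of template size, every
# injective placeholder assignment, checked against the adjacency matrix.
# Returns the set of distinct "template|sorted nodes|sorted edges" keys.
brute_force_motif_keys <- function(net, templates = default_templates()) {
  genes <- net$nodes$gene
  n <- length(genes)
  A <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  ed <- unique(net$edges[c("from", "to")])
  A[cbind(ed$from, ed$to)] <- TRUE
  keys <- character()
  for (ti in seq_len(nrow(templates))) {
    k <- templates$n_nodes[[ti]]
    tedges <- templates$edges[[ti]]
    id <- templates$template_id[[ti]]
    if (k > n) next
    subsets <- utils::combn(n, k)
    perms <- all_permutations(k)
    for (pi in seq_len(nrow(perms))) {
      assigned <- matrix(subsets[perms[pi, ], ], nrow = k)
      ok <- rep(TRUE, ncol(assigned))
      for (e in seq_len(nrow(tedges))) {
        ok <- ok & A[cbind(assigned[tedges[e, 1], ], assigned[tedges[e, 2], ])]
      }
      if (!any(ok)) next
      hit <- assigned[, ok, drop = FALSE]
      for (j in seq_len(ncol(hit))) {
        nodes <- genes[hit[, j]]
        realized <- paste(nodes[tedges[, 1]], nodes[tedges[, 2]], sep = ">")
        keys <- c(keys, paste(id, paste(sort(nodes), collapse = "|"),
                              paste(sort(realized), collapse = ";"),
                              sep = "||"))
      }
    }
  }
  sort(unique(keys))
}

motif_keys <- function(instances) {
  sort(paste(instances$template_id, instances$node_key, instances$edge_key,
             sep = "||"))
}

# All-pairs betweenness by explicit simple-path enumeration: list every
# simple path s -> t by DFS, keep the shortest, and credit interior nodes
# with the fraction of shortest paths through them.
brute_force_betweenness <- function(net, normalized = TRUE) {
  genes <- net$nodes$gene
  n <- length(genes)
  ed <- unique(net$edges[c("from", "to")])
  ed <- ed[ed$from != ed$to, ]
  out_adj <- split(ed$to, factor(ed$from, levels = genes))
  bc <- setNames(rep(0, n), genes)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) { paths[[length(paths) + 1L]] <<- path; return() }
      for (nb in setdiff(out_adj[[last]], path)) walk(c(path, nb))
    }
    walk(s)
    paths
  }
  for (s in genes) for (t in genes) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (pth in shortest) {
      interior <- pth[-c(1, length(pth))]
      bc[interior] <- bc[interior] + 1 / length(shortest)
    }
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2))
  tibble::tibble(gene = genes, betweenness = unname(bc))
}

# O(n^2) Pareto dominance check.
brute_force_frontier <- function(m) {
  n <- nrow(m)
  dominated <- vapply(seq_len(n), function(i) {
    ge <- m >= matrix(m[i, ], n, ncol(m), byrow = TRUE)
    gt <- m > matrix(m[i, ], n, ncol(m), byrow = TRUE)
    any(rowSums(ge) == ncol(m) & rowSums(gt) > 0)
  }, logical(1))
  !dominated
}

# Exact two-sided rank-sum p by enumerating every assignment of the pooled
# observations into a group of size n1.
brute_force_wilcox_p <- function(x, y) {
  n1 <- length(x)
  v <- c(x, y)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(v), n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
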