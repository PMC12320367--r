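toy_features <- function(fc, bc, deg, ids = NULL) {
  n <- length(fc)
  if (is.null(ids)) ids <- sprintf("M%03d", seq_len(n))
  tibble::tibble(
    motif_id = ids,
    template_id = "FBL3",
    node_key = ids,
    fc = fc, bc = bc, deg = deg
  )
}

test_that("the default weight grid has nine points summing to one", {
  grid <- weight_grid()
  expect_equal(nrow(grid), 9)
  expect_equal(grid$w2, seq(0.05, 0.45, by = 0.05))
  expect_equal(grid$w1 + grid$w2 + grid$w3, rep(1, 9))
  expect_true(all(grid$w3 >= 0))
  expect_error(weight_grid(w2_values = 0.6), "w2_values")
})

test_that("motif features average node values, defaulting absent DE to zero", {
  net <- regulatory_network(data.frame(from = c("A", "B"), to = c("B", "A")))
  inst <- enumerate_motifs(net)
  topo <- topology_features(net)
  de <- data.frame(gene = c("A", "B"), log2fc = c(1, 3))
  f <- motif_features(inst, de, topo, normalize = FALSE)
  expect_equal(f$fc, 2)
  expect_equal(f$deg, 2)
  # node without a DE record contributes zero
  f0 <- motif_features(inst, data.frame(gene = "A", log2fc = 1), topo,
                       normalize = FALSE)
  expect_equal(f0$fc, 0.5)
  # all motifs identical: min-max collapses every feature to zero
  fn <- motif_features(inst, de, topo, normalize = TRUE)
  expect_equal(unlist(fn[c("fc", "bc", "deg")]), c(fc = 0, bc = 0, deg = 0))
  # unknown node is an error
  bad <- inst
  bad$nodes[[1]] <- c("A", "ZZZ")
  expect_error(motif_features(bad, de, topo), "ZZZ")
})

test_that("scores follow the weighted sum exactly", {
  f <- toy_features(fc = c(1, 2), bc = c(1, 0), deg = c(1, 0))
  sc <- score_motifs(f)
  cols <- grep("^score_w2_", names(sc), value = TRUE)
  expect_equal(length(cols), 9)
  # fc=bc=deg=1: weights sum to 1 -> score 1 everywhere
  expect_equal(unlist(sc[1, cols]), rep(1, 9), ignore_attr = TRUE)
  # fc=2, bc=deg=0 -> w1*2 = 1 everywhere
  expect_equal(unlist(sc[2, cols]), rep(1, 9), ignore_attr = TRUE)
  expect_equal(sc$aggregate, c(1, 1))
  # affine in each feature: doubling fc doubles its contribution
  f2 <- toy_features(fc = c(2, 4), bc = c(1, 0), deg = c(1, 0))
  sc2 <- score_motifs(f2)
  expect_equal(as.matrix(sc2[cols]) - as.matrix(sc[cols]),
               matrix(0.5 * c(2, 4) - 0.5 * c(1, 2), 2, 9),
               ignore_attr = TRUE)
  expect_error(score_motifs(f, tibble::tibble(w1 = 1.2, w2 = -0.1, w3 = -0.1)),
               "weights")
})

test_that("the Pareto frontier is exactly the non-dominated set", {
  f <- toy_features(fc = c(1, 0.5, 1), bc = c(1, 0.5, 0.2), deg = 0)
  sc <- score_motifs(f, weight_grid(c(0.1, 0.4)))
  front <- pareto_frontier(sc)
  expect_equal(front$motif_id, "M001")

  # incomparable pair: both kept
  f2 <- toy_features(fc = c(0, 0), bc = c(1, 0), deg = c(0, 1))
  sc2 <- score_motifs(f2, weight_grid(c(0.05, 0.45)))
  expect_equal(nrow(pareto_frontier(sc2)), 2)

  # single vector is its own frontier; duplicates all retained
  expect_equal(nrow(pareto_frontier(sc2[1, ])), 1)
  dup <- dplyr::bind_rows(sc2[1, ], sc2[1, ])
  expect_equal(nrow(pareto_frontier(dup)), 2)
  expect_equal(nrow(pareto_frontier(sc2[0, ])), 0)
})

test_that("the frontier matches the O(n^2) dominance oracle on random sets", {
  withr::with_seed(55, {
    for (i in 1:20) {
      n <- sample(5:400, 1)
      m <- matrix(runif(n * 9), n, 9)
      if (i %% 3 == 0) m[, 5] <- round(m[, 5], 1)   # induce ties
      sc <- dplyr::bind_cols(
        toy_features(fc = 0, bc = 0, deg = rep(0, n)),
        tibble::as_tibble(`colnames<-`(m, tamnet:::score_col_names(weight_grid()))),
        aggregate = rowMeans(m))
      expect_equal(sc$motif_id[tamnet:::non_dominated(m)],
                   sc$motif_id[brute_force_frontier(m)])
      expect_equal(pareto_frontier(sc)$motif_id,
                   sc$motif_id[brute_force_frontier(m)])
    }
  })
})

test_that("frontier membership survives increasing transforms of one component", {
  withr::with_seed(66, {
    m <- matrix(runif(200 * 4), 200, 4)
    before <- brute_force_frontier(m)
    m2 <- m
    m2[, 2] <- exp(3 * m2[, 2])    # strictly increasing
    expect_equal(tamnet:::non_dominated(m2), before)
  })
})

test_that("top-motif ranking peels Pareto layers and breaks ties deterministically", {
  f <- toy_features(fc = c(1, 0.5, 1), bc = c(1, 0.5, 0.2), deg = 0)
  sc <- score_motifs(f, weight_grid(c(0.1, 0.4)))
  expect_equal(rank_top_motifs(sc, k = 1)$motif_id, "M001")

  # identical motifs: ordered by node key
  fid <- toy_features(fc = rep(1, 4), bc = rep(1, 4), deg = rep(1, 4),
                      ids = c("D", "B", "A", "C"))
  scid <- score_motifs(fid)
  expect_equal(rank_top_motifs(scid, k = 3)$motif_id, c("A", "B", "C"))

  # k beyond the motif count returns all, with a warning
  expect_warning(all3 <- rank_top_motifs(sc, k = 100), "exceeds")
  expect_equal(nrow(all3), 3)
  expect_equal(all3$rank, 1:3)
  # layers are consistent: earlier layers never dominated by later ones
  expect_true(all(diff(all3$pareto_layer) >= 0))
})

test_that("a planted high-score motif cluster dominates the top-100 selection", {
  spec <- synthetic_spec(seed = 19)
  nw <- gen_network(spec)
  net <- prune_by_expression(nw$network)
  inst <- enumerate_motifs(net)
  topo <- topology_features(net)
  de <- dplyr::filter(net$nodes, !is.na(log2fc))
  sc <- score_motifs(motif_features(inst, de, topo))
  top <- rank_top_motifs(sc, k = 100)
  core_nodes <- unique(unlist(inst$nodes[match(top$motif_id, inst$motif_id)]))
  expect_gte(mean(nw$planted_nodes %in% core_nodes), 0.8)
})
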