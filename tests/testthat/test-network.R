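write_sif <- function(lines) {
  path <- withr::local_tempfile(fileext = ".sif", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("SIF reading parses, case-normalizes and deduplicates", {
  net <- read_network(write_sif(c("A\tactivation\tB", "B\tinhibition\tA")))
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$kind, c("activation", "inhibition"))

  dup <- read_network(write_sif(c("A\tactivation\tB", "A\tactivation\tB")))
  expect_equal(nrow(dup$edges), 1)

  lc <- read_network(write_sif("nfkb1\tactivation\til6"))
  expect_setequal(lc$nodes$gene, c("NFKB1", "IL6"))

  unk <- read_network(write_sif("A\tbinds\tB"))
  expect_equal(unk$edges$kind, "unspecified")
})

test_that("a self-loop in a toy SIF is retained as an edge", {
  rows <- c("A\tactivation\tB", "B\tactivation\tC", "C\tactivation\tC",
            "C\tinhibition\tD", "D\tactivation\tE", "E\tactivation\tA",
            "A\tactivation\tC", "B\tinhibition\tD", "D\tactivation\tA",
            "E\tinhibition\tB")
  net <- read_network(write_sif(rows))
  expect_equal(nrow(net$edges), 10)
  expect_true(any(net$edges$from == "C" & net$edges$to == "C"))
})

test_that("malformed and empty SIF files raise informative errors", {
  expect_error(read_network(write_sif(c("A\tactivation\tB", "B\tactivation"))),
               "line 2")
  expect_error(read_network(write_sif(character())), "empty")
  expect_error(read_network(tempfile()), "not found")
})

test_that("networks round-trip through SIF and GraphML", {
  net <- regulatory_network(
    data.frame(from = c("A", "B", "C"), to = c("B", "A", "C"),
               kind = c("activation", "inhibition", "unspecified")),
    nodes = data.frame(gene = c("A", "B", "C", "D"),
                       mean_tpm = c(12, 80, 5, 30),
                       log2fc = c(1.5, NA, -0.3, NA),
                       p_adj = c(0.01, NA, 0.2, NA),
                       is_tf = c(FALSE, TRUE, FALSE, FALSE))
  )
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(net, sif)
  back <- read_network(sif)
  expect_setequal(back$nodes$gene, c("A", "B", "C"))  # SIF drops isolates
  expect_equal(dplyr::arrange(back$edges, from, to),
               dplyr::arrange(net$edges, from, to))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml)
  back2 <- read_network(gml)
  ord <- match(net$nodes$gene, back2$nodes$gene)
  expect_false(any(is.na(ord)))
  expect_equal(back2$nodes$mean_tpm[ord], net$nodes$mean_tpm)
  expect_equal(back2$nodes$log2fc[ord], net$nodes$log2fc)
  expect_equal(back2$nodes$p_adj[ord], net$nodes$p_adj)
  expect_equal(back2$nodes$is_tf[ord], net$nodes$is_tf)
  expect_equal(dplyr::arrange(back2$edges, from, to),
               dplyr::arrange(net$edges, from, to))
})

test_that("an empty network writes a valid SIF", {
  net <- regulatory_network()
  path <- withr::local_tempfile(fileext = ".sif")
  write_network(net, path)
  expect_true(file.exists(path))
  expect_equal(length(readLines(path)), 0)
})

test_that("network invariants are enforced", {
  expect_error(regulatory_network(data.frame(from = "", to = "B")), "non-empty")
  expect_error(
    regulatory_network(data.frame(from = "A", to = "B"),
                       nodes = data.frame(gene = "A", mean_tpm = -1)),
    "non-negative")
  expect_error(
    regulatory_network(data.frame(from = "A", to = "B"),
                       nodes = data.frame(gene = "A", log2fc = 1)),
    "together")
})

test_that("pruning applies a strict TPM threshold and removes isolates", {
  # node exactly at the threshold is removed ("above 10")
  net <- regulatory_network(
    data.frame(from = c("A", "B"), to = c("B", "A")),
    nodes = data.frame(gene = c("A", "B"), mean_tpm = c(10, 50)))
  pruned <- prune_by_expression(net, 10)
  expect_equal(nrow(pruned$nodes), 0)

  # cascade: removing the middle of a chain orphans both ends
  chain <- regulatory_network(
    data.frame(from = c("A", "B"), to = c("B", "C")),
    nodes = data.frame(gene = c("A", "B", "C"), mean_tpm = c(100, 5, 100)))
  expect_equal(nrow(prune_by_expression(chain)$nodes), 0)

  # fully expressed connected graph is untouched
  ok <- regulatory_network(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "A")),
    nodes = data.frame(gene = c("A", "B", "C"), mean_tpm = rep(100, 3)))
  expect_equal(prune_by_expression(ok), ok)

  expect_error(prune_by_expression(ok, -1), "tpm_threshold")
})

test_that("pruning is idempotent and yields an induced subgraph", {
  net <- rand_digraph(40, 0.08, seed = 11)
  net <- annotate_network(net, data.frame(
    gene = net$nodes$gene,
    mean_tpm = withr::with_seed(12, stats::runif(40, 0, 200))))
  p1 <- prune_by_expression(net)
  expect_equal(prune_by_expression(p1), p1)
  expect_true(all(p1$nodes$gene %in% net$nodes$gene))
  induced <- dplyr::filter(net$edges, from %in% p1$nodes$gene,
                           to %in% p1$nodes$gene)
  expect_equal(dplyr::arrange(p1$edges, from, to, kind),
               dplyr::arrange(induced, from, to, kind))
  # retained nodes all satisfy both conditions
  expect_true(all(p1$nodes$mean_tpm > 10))
  deg <- node_degree(p1)
  expect_true(all(deg$degree >= 1) || nrow(p1$nodes) == 0)
})

test_that("glance reports component counts and tidy returns edges", {
  net <- regulatory_network(data.frame(from = c("A", "C"), to = c("B", "D")))
  g <- glance(net)
  expect_equal(g$n_components, 2)
  expect_equal(tidy(net), net$edges)
})
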