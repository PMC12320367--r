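test_that("TPM follows the length-normalized formula and sums to 1e6", {
  one <- matrix(5, 1, 1, dimnames = list("A", "s1"))
  expect_equal(compute_tpm(one, c(A = 500))[1, 1], 1e6)

  two <- matrix(c(10, 10), 2, 1, dimnames = list(c("A", "B"), "s1"))
  tpm <- compute_tpm(two, c(A = 1000, B = 2000))
  expect_equal(tpm[, 1], c(A = 2e6 / 3, B = 1e6 / 3), tolerance = 1e-8)

  withr::with_seed(5, {
    counts <- matrix(rpois(60, 20), 10, 6,
                     dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    lens <- setNames(sample(200:5000, 10), rownames(counts))
    tpm <- compute_tpm(counts, lens)
    expect_equal(unname(colSums(tpm)), rep(1e6, 6), tolerance = 1e-6)
    # matches the formula recomputed gene by gene
    manual <- (counts[3, 2] / lens[3]) / sum(counts[, 2] / lens) * 1e6
    expect_equal(tpm[3, 2], unname(manual))
  })
})

test_that("TPM rejects bad lengths and handles all-zero samples per flag", {
  m <- matrix(c(1, 0), 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_error(compute_tpm(m, c(A = 100)), "B")
  expect_error(compute_tpm(m, c(A = 100, B = 0)), "B")
  z <- matrix(0, 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_error(compute_tpm(z, c(A = 100, B = 100)), "zero total")
  expect_equal(unname(compute_tpm(z, c(A = 100, B = 100),
                                  zero_sample = "zero")[, 1]), c(0, 0))
})

test_that("mean TPM is the per-gene arithmetic mean across samples", {
  m <- matrix(c(0, 20, 5, 5), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(mean_tpm(m)$mean_tpm, c(10, 5))
  expect_equal(mean_tpm(m[, 1, drop = FALSE])$mean_tpm, m[, 1],
               ignore_attr = TRUE)
  withr::with_seed(8, {
    big <- matrix(runif(120), 10, 12, dimnames = list(paste0("g", 1:10), NULL))
    brute <- vapply(seq_len(10), function(i) sum(big[i, ]) / 12, numeric(1))
    expect_equal(mean_tpm(big)$mean_tpm, brute)
  })
})

test_that("cell QC applies the feature and mitochondrial thresholds exactly", {
  ng <- 200
  genes <- c(paste0("G", 1:(ng - 1)), "MT-1")
  make_cell <- function(n_feat) {
    x <- numeric(ng)
    x[seq_len(n_feat)] <- 1
    x
  }
  counts <- rbind(
    at_threshold = make_cell(120),   # 120 features -> kept
    below = make_cell(119),          # 119 features -> removed
    mito_ok = make_cell(150),
    high_mito = make_cell(150)
  )
  colnames(counts) <- genes
  counts["mito_ok", "MT-1"] <- 50     # 50 / (150 + 50): exactly 25%
  counts["high_mito", "MT-1"] <- 150  # 50% mitochondrial
  kept <- qc_filter_cells(counts, mito_genes = "MT-1")
  expect_setequal(rownames(kept), c("at_threshold", "mito_ok"))

  # empty mito set: only the feature criterion applies
  kept2 <- qc_filter_cells(counts, mito_genes = character())
  expect_setequal(rownames(kept2), c("at_threshold", "mito_ok", "high_mito"))
  expect_error(qc_filter_cells(counts, min_features = -1), "min_features")
})

test_that("TAM gating needs strict expression in enough markers", {
  expr <- rbind(
    pass = c(CD68 = 2, CD163 = 1.5, CD14 = 0, OTHER = 9),
    one_marker = c(CD68 = 3, CD163 = 0, CD14 = 0, OTHER = 9),
    at_threshold = c(CD68 = 1, CD163 = 1, CD14 = 1, OTHER = 9)
  )
  expect_equal(gate_tams(expr, normalize = FALSE), "pass")
  expect_equal(gate_tams(matrix(0, 0, 4,
                                dimnames = list(NULL, colnames(expr))),
                         normalize = FALSE), character())
  expect_error(gate_tams(expr, min_markers = 4), "min_markers")
  expect_warning(
    gate_tams(expr[, 1:2], markers = c("CD68", "CD163", "CD14"),
              normalize = FALSE),
    "CD14")
})

test_that("QC and TAM gating commute as per-cell predicates", {
  spec <- synthetic_spec(seed = 3, n_cells_per_group = 60, n_genes = 400)
  ex <- gen_expression(spec)
  qc_first <- gate_tams(qc_filter_cells(ex$counts, ex$mito_genes))
  gated <- gate_tams(ex$counts)
  gate_first <- rownames(qc_filter_cells(ex$counts[gated, , drop = FALSE],
                                         ex$mito_genes))
  expect_setequal(qc_first, gate_first)
})

test_that("the rank-sum p matches exhaustive enumeration, with and without ties", {
  withr::with_seed(21, {
    for (i in 1:30) {
      n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
      x <- if (i %% 2 == 0) rpois(n1, 3) else rnorm(n1)   # ties on even runs
      y <- if (i %% 2 == 0) rpois(n2, 4) else rnorm(n2, 0.5)
      expect_equal(wilcox_rank_sum_p(x, y), brute_force_wilcox_p(x, y),
                   tolerance = 1e-12)
    }
  })
  # degenerate all-tied input
  expect_equal(wilcox_rank_sum_p(rep(1, 4), rep(1, 5)), 1)
})

test_that("differential expression is symmetric, gated by detection, and exact on a toy", {
  genes <- paste0("g", 1:5)
  cells <- paste0("c", 1:8)
  withr::with_seed(9, {
    counts <- matrix(rpois(40, 4), 8, 5, dimnames = list(cells, genes))
  })
  # identical groups: zero fold change, nothing called
  dup <- rbind(counts, counts)
  rownames(dup) <- c(paste0("a", 1:8), paste0("b", 1:8))
  labels <- setNames(rep(c("TAM", "CTRL"), each = 8), rownames(dup))
  de <- differential_expression(dup, labels)
  expect_equal(de$log2fc, rep(0, nrow(de)))
  expect_false(any(de$called))
  expect_true(all(de$p_adj >= de$p_raw))

  # gene detected in under 1% of one group is not tested
  big <- matrix(1, 300, 2, dimnames = list(paste0("c", 1:300), c("lo", "hi")))
  big[, "lo"] <- 0
  big[1, "lo"] <- 1   # 1 of 150 TAM cells = 0.7%
  lab <- setNames(rep(c("TAM", "CTRL"), each = 150), rownames(big))
  de2 <- differential_expression(big, lab)
  expect_false("lo" %in% de2$gene)

  expect_error(differential_expression(counts, setNames(rep("TAM", 8), cells)),
               "non-empty")
})

test_that("a planted four-fold gene gets the smallest, oracle-exact p on a 20-cell toy", {
  withr::with_seed(33, {
    genes <- paste0("g", 1:12)
    counts <- matrix(rpois(20 * 12, 5), 20, 12,
                     dimnames = list(paste0("c", 1:20), genes))
    counts[1:10, "g1"] <- rpois(10, 20)   # planted in the TAM half
    labels <- setNames(rep(c("TAM", "CTRL"), each = 10), rownames(counts))
    de <- differential_expression(counts, labels)
    expect_equal(de$gene[1], "g1")
    norm <- log_normalize(counts)
    expect_equal(de$p_raw[de$gene == "g1"],
                 brute_force_wilcox_p(norm[1:10, "g1"], norm[11:20, "g1"]),
                 tolerance = 1e-12)
  })
})

test_that("Bonferroni correction is monotone in the number of tests", {
  withr::with_seed(14, {
    counts <- matrix(rpois(30 * 40, 3), 30, 40,
                     dimnames = list(paste0("c", 1:30), paste0("g", 1:40)))
    labels <- setNames(rep(c("TAM", "CTRL"), c(15, 15)), rownames(counts))
    de_tested <- differential_expression(counts, labels, bonferroni_m = "tested")
    de_total <- differential_expression(counts, labels, bonferroni_m = "total")
    # called set is a subset of the raw-significant set
    expect_true(all(de_tested$p_raw[de_tested$called] < 0.05))
    # correcting over more tests never calls more genes
    expect_lte(sum(de_total$called), sum(de_tested$called))
    m <- nrow(de_tested)
    expect_equal(de_tested$p_adj, pmin(1, de_tested$p_raw * m))
  })
})

test_that("estimated fold-change sign matches the planted sign for planted genes", {
  spec <- synthetic_spec(seed = 17, planted_log2fc = 2)
  ex <- gen_expression(spec)
  de <- differential_expression(ex$counts, ex$labels)
  planted <- de[de$gene %in% ex$planted_genes, ]
  expect_gte(nrow(planted), 45)
  expect_gte(mean(planted$log2fc > 0), 0.95)
})

test_that("polarization calls follow the marker rules", {
  expr <- rbind(
    m1 = c(CD14 = 3, IL1B = 0, CD163 = 0, IL10 = 0),
    m2 = c(CD14 = 0, IL1B = 0, CD163 = 0, IL10 = 2),
    both = c(CD14 = 3, IL1B = 0, CD163 = 3, IL10 = 0),
    none = c(CD14 = 0, IL1B = 0, CD163 = 0, IL10 = 0)
  )
  pol <- classify_polarization(expr, normalize = FALSE)
  expect_equal(pol$polarization, c("M1", "M2", "double", "none"))
})
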