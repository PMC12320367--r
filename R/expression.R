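#' Convert bulk counts to transcripts per million
#'
#' TPM divides each count by its transcript length, then rescales every
#' sample so the values sum to one million:
#' `TPM_g = (count_g / length_g) / sum_j(count_j / length_j) * 1e6`.
#'
#' @param counts gene x sample numeric matrix of non-negative counts, with
#'   gene row names.
#' @param lengths named numeric vector of transcript lengths in bases; every
#'   gene in `counts` must have a positive length.
#' @param zero_sample what to do with an all-zero sample column, where the
#'   formula is 0/0: `"error"` (default) or `"zero"` to return an all-zero
#'   column.
#' @return gene x sample matrix of TPM values; each non-degenerate column
#'   sums to 1e6.
#' @export
compute_tpm <- function(counts, lengths, zero_sample = c("error", "zero")) {
  zero_sample <- match.arg(zero_sample)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) abort("`counts` needs gene row names")
  if (any(counts < 0)) abort("counts must be non-negative")
  len <- lengths[rownames(counts)]
  bad <- rownames(counts)[is.na(len) | len <= 0]
  if (length(bad) > 0) {
    abort(sprintf("missing or non-positive transcript length for gene(s): %s",
                  paste(utils::head(bad, 3), collapse = ", ")))
  }
  rate <- counts / as.numeric(len)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    if (zero_sample == "error") {
      abort(sprintf("sample(s) with zero total counts: %s",
                    paste(colnames(counts)[tot == 0], collapse = ", ")))
    }
    tot[tot == 0] <- Inf
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Average TPM per gene across samples
#'
#' @param tpm gene x sample TPM matrix (from [compute_tpm()]).
#' @return A tibble with columns `gene` and `mean_tpm`, ready for
#'   [annotate_network()].
#' @export
mean_tpm <- function(tpm) {
  tpm <- as.matrix(tpm)
  if (ncol(tpm) < 1L) abort("need at least one sample")
  tibble(gene = rownames(tpm), mean_tpm = unname(rowMeans(tpm)))
}

#' Per-10k linear and log normalization of single-cell counts
#'
#' Scales each cell to 10,000 counts (`1e4 * count / cell_total`);
#' `log_normalize()` additionally applies `log1p`, i.e. the transform
#' `ln(1 + 1e4 * count / cell_total)` used throughout the single-cell
#' stage. Cells with zero total stay all-zero.
#'
#' @param counts cells x genes count matrix (cells in rows).
#' @return Matrix of the same shape.
#' @export
normalize_per10k <- function(counts) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  tot[tot == 0] <- Inf
  counts / tot * 1e4
}

#' @rdname normalize_per10k
#' @export
log_normalize <- function(counts) log1p(normalize_per10k(counts))

#' Quality-filter single cells
#'
#' Keeps cells with at least `min_features` detected genes (non-zero
#' counts) and a mitochondrial read fraction not exceeding
#' `max_mito_frac`; a cell strictly above the fraction is discarded, one
#' exactly at it is retained.
#'
#' @param counts cells x genes count matrix with cell row names and gene
#'   column names.
#' @param mito_genes character vector of mitochondrial gene symbols (may be
#'   empty, in which case only the feature criterion applies).
#' @param min_features minimum detected-gene count per cell.
#' @param max_mito_frac maximum tolerated mitochondrial read fraction.
#' @return The filtered count matrix (possibly with zero rows).
#' @export
qc_filter_cells <- function(counts, mito_genes = character(),
                            min_features = 120, max_mito_frac = 0.25) {
  if (!is.numeric(min_features) || length(min_features) != 1 || min_features < 0) {
    abort("`min_features` must be a non-negative number")
  }
  check_number(max_mito_frac, "max_mito_frac", min = 0, max = 1)
  counts <- as.matrix(counts)
  n_feat <- rowSums(counts > 0)
  mito <- intersect(mito_genes, colnames(counts))
  tot <- rowSums(counts)
  mito_frac <- if (length(mito) > 0) {
    rowSums(counts[, mito, drop = FALSE]) / pmax(tot, 1)
  } else {
    rep(0, nrow(counts))
  }
  counts[n_feat >= min_features & mito_frac <= max_mito_frac, , drop = FALSE]
}

#' Gate tumor-associated macrophages by marker expression
#'
#' A cell is called a TAM when strictly more than `expr_threshold`
#' expression is seen in at least `min_markers` of the marker genes
#' (defaults: CD68, CD163 and CD14, at least two of the three above 1).
#' The stringency reduces contamination from other cell types.
#'
#' @param expr cells x genes expression matrix on the scale the threshold
#'   refers to; with `normalize = TRUE` (default) raw counts are first
#'   converted to the per-10k linear scale of [normalize_per10k()].
#' @param markers marker gene symbols; markers absent from the matrix never
#'   pass and trigger a warning.
#' @param min_markers how many markers must pass (at most `length(markers)`).
#' @param expr_threshold strict lower bound on marker expression.
#' @param normalize apply [normalize_per10k()] before thresholding.
#' @return Character vector of retained cell identifiers.
#' @export
gate_tams <- function(expr, markers = c("CD68", "CD163", "CD14"),
                      min_markers = 2, expr_threshold = 1, normalize = TRUE) {
  if (min_markers > length(markers)) {
    abort("`min_markers` cannot exceed the number of markers")
  }
  expr <- as.matrix(expr)
  if (nrow(expr) == 0L) return(character())
  if (normalize) expr <- normalize_per10k(expr)
  present <- intersect(markers, colnames(expr))
  if (length(present) < length(markers)) {
    warn(sprintf("marker(s) absent from the matrix and counted as never passing: %s",
                 paste(setdiff(markers, present), collapse = ", ")))
  }
  if (length(present) == 0L) return(character())
  n_pass <- rowSums(expr[, present, drop = FALSE] > expr_threshold)
  rownames(expr)[n_pass >= min_markers]
}

# Exact two-sided Wilcoxon rank-sum p-value, conditional on the observed
# values (ties allowed). Computes the null distribution of the group-1 rank
# sum by a shift-algorithm DP over doubled ranks (midranks live on a half-
# integer grid), counting size-n1 subsets per achievable sum.
wilcox_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r2 <- as.integer(round(2 * rank(c(x, y))))
  w_obs <- sum(r2[seq_len(n1)])
  max_sum <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # dp[k+1, s+1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = n1 + 1, ncol = max_sum + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in kmax:1) {
      src <- dp[k, seq_len(max_sum + 1 - v)]
      if (any(src != 0)) {
        idx <- (v + 1):(max_sum + 1)
        dp[k + 1, idx] <- dp[k + 1, idx] + src
      }
    }
  }
  probs <- dp[n1 + 1, ]
  total <- sum(probs)
  sums <- 0:max_sum
  mu <- sum(probs * sums) / total
  dev <- abs(w_obs - mu)
  sum(probs[abs(sums - mu) >= dev - 1e-9]) / total
}

# Normal approximation with tie correction and continuity correction,
# matching the classical large-sample rank-sum test.
wilcox_approx_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact by dynamic programming over the tie-aware rank distribution when
#' the combined sample size is at most `exact_limit`, otherwise the normal
#' approximation with tie and continuity corrections. The exact branch
#' conditions on the observed values, so ties are handled without
#' approximation.
#'
#' @param x,y numeric vectors for the two groups (both non-empty).
#' @param exact_limit largest combined sample size for the exact branch.
#' @return A single p-value in (0, 1].
#' @export
wilcox_rank_sum_p <- function(x, y, exact_limit = 30) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  if (length(x) + length(y) <= exact_limit) wilcox_exact_p(x, y)
  else wilcox_approx_p(x, y)
}

#' Two-group single-cell differential expression
#'
#' Log-normalizes counts (`ln(1 + 1e4 * count / cell_total)`), tests every
#' gene detected in at least `min_pct` of cells in *both* groups with a
#' two-sided Wilcoxon rank-sum test, and Bonferroni-corrects over the
#' tested genes (or over all genes, via `bonferroni_m = "total"`). The fold
#' change is computed on the de-logged normalized scale with a pseudocount
#' of one: `log2((mean(expm1(case)) + 1) / (mean(expm1(control)) + 1))`.
#'
#' @param counts cells x genes count matrix with cell row names.
#' @param groups named character vector or factor mapping each cell (row of
#'   `counts`) to one of two labels.
#' @param case,control the two group labels (defaults `"TAM"` and `"CTRL"`);
#'   fold changes are case over control.
#' @param min_pct minimum detection fraction required in both groups.
#' @param alpha significance level for the `called` flag (on adjusted p).
#' @param bonferroni_m `"tested"` (default) corrects over the tested genes,
#'   `"total"` over all genes in the matrix.
#' @return A tibble with one row per tested gene: `gene`, `log2fc`,
#'   `p_raw`, `p_adj`, `pct_case`, `pct_ctrl`, `called`; sorted by `p_raw`.
#' @export
differential_expression <- function(counts, groups, case = "TAM",
                                    control = "CTRL", min_pct = 0.01,
                                    alpha = 0.05,
                                    bonferroni_m = c("tested", "total")) {
  bonferroni_m <- match.arg(bonferroni_m)
  counts <- as.matrix(counts)
  groups <- setNames(as.character(groups), names(groups))
  if (!is.null(names(groups))) {
    missing <- setdiff(names(groups), rownames(counts))
    if (length(missing) > 0) abort("labeled cells absent from the matrix")
    groups <- groups[rownames(counts)]
  }
  idx_case <- which(groups == case)
  idx_ctrl <- which(groups == control)
  if (length(idx_case) == 0 || length(idx_ctrl) == 0) {
    abort(sprintf("both groups must be non-empty (%s: %d, %s: %d cells)",
                  case, length(idx_case), control, length(idx_ctrl)))
  }
  norm <- log_normalize(counts)
  pct_case <- colMeans(counts[idx_case, , drop = FALSE] > 0)
  pct_ctrl <- colMeans(counts[idx_ctrl, , drop = FALSE] > 0)
  tested <- which(pct_case >= min_pct & pct_ctrl >= min_pct)
  m <- if (bonferroni_m == "tested") length(tested) else ncol(counts)
  res <- purrr::map_dfr(tested, function(j) {
    xc <- norm[idx_case, j]
    xs <- norm[idx_ctrl, j]
    tibble(
      gene = colnames(counts)[j],
      log2fc = log2((mean(expm1(xc)) + 1) / (mean(expm1(xs)) + 1)),
      p_raw = wilcox_rank_sum_p(xc, xs),
      pct_case = pct_case[[j]],
      pct_ctrl = pct_ctrl[[j]]
    )
  })
  if (nrow(res) == 0L) {
    return(tibble(gene = character(), log2fc = double(), p_raw = double(),
                  p_adj = double(), pct_case = double(), pct_ctrl = double(),
                  called = logical()))
  }
  res |>
    mutate(p_adj = pmin(1, .data$p_raw * m),
           called = .data$p_adj < alpha) |>
    select("gene", "log2fc", "p_raw", "p_adj", "pct_case", "pct_ctrl",
           "called") |>
    arrange(.data$p_raw, .data$gene)
}

#' Classify macrophage polarization from marker genes
#'
#' A marker is positive when its expression strictly exceeds
#' `expr_threshold`. Cells with at least one positive M1 marker and no
#' positive M2 marker are `M1` (and symmetrically `M2`); both kinds
#' positive gives `double`, neither gives `none`. Ties are reported, not
#' resolved.
#'
#' @param expr cells x genes expression matrix; with `normalize = TRUE`
#'   raw counts are first put on the per-10k linear scale.
#' @param m1_markers,m2_markers marker sets for the pro-inflammatory (M1)
#'   and alternatively activated (M2) phenotypes.
#' @param expr_threshold strict positivity threshold.
#' @param normalize apply [normalize_per10k()] first.
#' @return A tibble with columns `cell` and `polarization`
#'   (`M1`/`M2`/`double`/`none`).
#' @export
classify_polarization <- function(expr, m1_markers = c("CD14", "IL1B"),
                                  m2_markers = c("CD163", "IL10"),
                                  expr_threshold = 1, normalize = TRUE) {
  expr <- as.matrix(expr)
  if (normalize) expr <- normalize_per10k(expr)
  pos <- function(markers) {
    present <- intersect(markers, colnames(expr))
    if (length(present) == 0) return(rep(FALSE, nrow(expr)))
    rowSums(expr[, present, drop = FALSE] > expr_threshold) > 0
  }
  m1 <- pos(m1_markers)
  m2 <- pos(m2_markers)
  tibble(
    cell = rownames(expr) %||% as.character(seq_len(nrow(expr))),
    polarization = dplyr::case_when(
      m1 & m2 ~ "double", m1 ~ "M1", m2 ~ "M2", .default = "none"
    )
  )
}

#' Volcano plot of a differential-expression table
#'
#' @param object tibble from [differential_expression()].
#' @param alpha significance level drawn as a horizontal reference.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 geom_hline scale_colour_manual
#' @export
plot_volcano <- function(object, alpha = 0.05, ...) {
  ggplot(object, aes(x = .data$log2fc, y = -log10(pmax(.data$p_adj, 1e-300)),
                     colour = .data$called)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    labs(x = "log2 fold change (case / control)",
         y = "-log10 adjusted p", colour = "called")
}
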