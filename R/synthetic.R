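#' Synthetic study specification
#'
#' Parameters of the seeded generators that stand in for the study's real
#' inputs (a curated macrophage regulatory network, bulk TAM RNA-seq and
#' two-group macrophage scRNA-seq, and external screening tables). The
#' defaults define the package's reference test conditions: a 300-node
#' Erdos-Renyi background with a 20-node planted motif cluster, two groups
#' of 200 cells with negative-binomial counts and a planted four-fold
#' (log2FC = 2) change, and a 40-drug x 13-target screening table with one
#' planted hit.
#'
#' @param seed integer; fully determines every generated object.
#' @param n_nodes,edge_prob background digraph size and edge probability.
#' @param n_planted_core_nodes number of planted core genes wired into
#'   overlapping feedback/feed-forward motifs.
#' @param low_tpm_frac fraction of background nodes given mean TPM at or
#'   below 10, so expression pruning is exercised.
#' @param planted_log2fc log2 fold change planted on core genes (TAM over
#'   control).
#' @param n_genes,n_planted_de standalone expression dimensions (ignored
#'   when a gene universe is supplied to [gen_expression()]).
#' @param n_cells_per_group cells per group before quality filtering.
#' @param nb_mean,nb_dispersion negative-binomial baseline mean per gene
#'   and dispersion (variance = mu + dispersion * mu^2).
#' @param n_mito_genes,mito_frac mitochondrial gene count and their
#'   expected share of reads in a healthy cell.
#' @param frac_low_depth,frac_high_mito fractions of deliberately
#'   low-quality cells planted to exercise the QC filter.
#' @param n_drugs,n_targets,n_planted_covered screening-table dimensions
#'   and how many targets the planted drug covers above the FIT threshold.
#' @param n_planted_tf,n_planted_housekeeping planted annotation flags
#'   among the core genes, exercising the target filter.
#' @return A list of class `tamnet_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_nodes = 300, edge_prob = 0.015,
                           n_planted_core_nodes = 20,
                           low_tpm_frac = 0.3,
                           planted_log2fc = 2,
                           n_genes = 2000, n_planted_de = 50,
                           n_cells_per_group = 200,
                           nb_mean = 1, nb_dispersion = 0.5,
                           n_mito_genes = 10, mito_frac = 0.05,
                           frac_low_depth = 0.02, frac_high_mito = 0.02,
                           n_drugs = 40, n_targets = 13,
                           n_planted_covered = 12,
                           n_planted_tf = 2, n_planted_housekeeping = 2) {
  spec <- as.list(environment())
  for (f in c("n_nodes", "n_planted_core_nodes", "n_genes",
              "n_cells_per_group", "n_drugs", "n_targets")) {
    if (spec[[f]] < 1) abort(sprintf("`%s` must be positive", f))
  }
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be positive")
  if (n_planted_core_nodes > n_nodes) {
    abort("cannot plant more core nodes than the network has")
  }
  if (n_planted_covered > n_targets) {
    abort("planted coverage cannot exceed the number of targets")
  }
  check_number(edge_prob, "edge_prob", 0, 1)
  check_number(low_tpm_frac, "low_tpm_frac", 0, 1)
  check_number(mito_frac, "mito_frac", 0, 1)
  structure(spec, class = "tamnet_spec")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a regulatory network with a planted core
#'
#' An Erdos-Renyi directed background with a planted cluster of core genes
#' wired into overlapping feedback and feed-forward loops (self-loop,
#' 2/3/4-cycles, FFLs), plus bridge edges tying the cluster into the
#' background. Planted genes receive high mean TPM and a planted
#' differential-expression record; a fraction of background nodes receive
#' mean TPM at or below 10 so that expression pruning removes them.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `network` (`tam_network`), `planted_nodes`,
#'   `housekeeping`, `tfs`, `inflammation` (character vectors of planted
#'   annotation sets).
#' @export
gen_network <- function(spec) {
  stopifnot(inherits(spec, "tamnet_spec"))
  with_seed(spec$seed, {
    n <- spec$n_nodes
    genes <- sprintf("G%04d", seq_len(n))
    planted <- sort(sample(genes, spec$n_planted_core_nodes))

    # background: directed Erdos-Renyi, no self-loops
    adj <- matrix(stats::runif(n * n) < spec$edge_prob, n, n)
    diag(adj) <- FALSE
    idx <- which(adj, arr.ind = TRUE)
    edges <- tibble(from = genes[idx[, 1]], to = genes[idx[, 2]])

    # planted motifs: overlapping 3-cycles and FFLs along the core genes,
    # one self-loop, one 2-cycle, one 4-cycle
    p <- planted
    np <- length(p)
    pe <- list()
    add <- function(a, b) pe[[length(pe) + 1L]] <<- c(a, b)
    if (np >= 3) {
      for (i in unique(c(seq(1, np - 2, by = 2), np - 2))) {
        add(p[i], p[i + 1]); add(p[i + 1], p[i + 2]); add(p[i + 2], p[i])
      }
      for (i in seq(1, np - 2, by = 3)) {       # FFL3: i -> i+1 -> i+2, i -> i+2
        add(p[i], p[i + 1]); add(p[i + 1], p[i + 2]); add(p[i], p[i + 2])
      }
    }
    add(p[1], p[1])                              # FBL1
    if (np >= 2) { add(p[1], p[2]); add(p[2], p[1]) }  # FBL2
    if (np >= 4) {                               # FBL4 + FFL4 shortcut
      add(p[1], p[2]); add(p[2], p[3]); add(p[3], p[4]); add(p[4], p[1])
      add(p[1], p[4])
    }
    # bridges into the background
    bg <- setdiff(genes, p)
    for (g in p) {
      add(g, sample(bg, 1)); add(sample(bg, 1), g)
    }
    pe <- do.call(rbind, pe)
    edges <- distinct(bind_rows(edges, tibble(from = pe[, 1], to = pe[, 2])))

    # annotations
    is_planted <- genes %in% p
    mean_tpm <- numeric(n)
    mean_tpm[is_planted] <- stats::runif(sum(is_planted), 100, 500)
    n_bg <- sum(!is_planted)
    low <- stats::runif(n_bg) < spec$low_tpm_frac
    tpm_bg <- numeric(n_bg)
    tpm_bg[low] <- stats::runif(sum(low), 0, 10)
    tpm_bg[!low] <- stats::runif(sum(!low), 15, 300)
    mean_tpm[!is_planted] <- tpm_bg
    log2fc <- rep(NA_real_, n)
    p_adj <- rep(NA_real_, n)
    log2fc[is_planted] <- spec$planted_log2fc +
      stats::rnorm(sum(is_planted), 0, 0.1)
    p_adj[is_planted] <- 1e-6

    tfs <- p[seq_len(min(spec$n_planted_tf, np))]
    hk <- setdiff(p, tfs)[seq_len(min(spec$n_planted_housekeeping, np - length(tfs)))]
    nodes <- tibble(gene = genes, mean_tpm = mean_tpm, log2fc = log2fc,
                    p_adj = p_adj,
                    is_housekeeping = genes %in% hk,
                    is_tf = genes %in% tfs,
                    is_inflammation = is_planted)
    list(network = regulatory_network(edges, nodes),
         planted_nodes = p, housekeeping = hk, tfs = tfs, inflammation = p)
  })
}

#' Generate a two-group single-cell count matrix
#'
#' Negative-binomial counts for two groups of cells (`TAM` and `CTRL`) with
#' a planted fold change of `2^planted_log2fc` on the planted genes,
#' macrophage marker genes (CD68/CD163/CD14) elevated in the TAM group so
#' that [gate_tams()] recovers it, mitochondrial genes at a controlled read
#' fraction, and small planted fractions of low-depth and high-mitochondria
#' cells so the QC filter has work to do.
#'
#' @param spec a [synthetic_spec()].
#' @param genes optional gene universe (e.g. the network's node set);
#'   defaults to `spec$n_genes` synthetic genes.
#' @param planted optional planted differentially expressed genes (must be
#'   in `genes`); defaults to the first `spec$n_planted_de` genes.
#' @return A list: `counts` (cells x genes matrix), `labels` (named vector,
#'   `TAM`/`CTRL`), `planted_genes`, `marker_genes`, `mito_genes`,
#'   `low_quality_cells`.
#' @export
gen_expression <- function(spec, genes = NULL, planted = NULL) {
  stopifnot(inherits(spec, "tamnet_spec"))
  with_seed(spec$seed + 1L, {
    if (is.null(genes)) genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
    if (is.null(planted)) planted <- genes[seq_len(min(spec$n_planted_de,
                                                       length(genes)))]
    stopifnot(all(planted %in% genes))
    markers <- c("CD68", "CD163", "CD14")
    mito <- sprintf("MT-GENE%02d", seq_len(spec$n_mito_genes))
    all_genes <- unique(c(genes, markers, mito))
    ng <- length(all_genes)
    nc <- spec$n_cells_per_group
    cells <- c(sprintf("TAM_%04d", seq_len(nc)), sprintf("CTRL_%04d", seq_len(nc)))
    labels <- setNames(rep(c("TAM", "CTRL"), each = nc), cells)

    base_mu <- stats::rlnorm(ng, meanlog = log(spec$nb_mean), sdlog = 1)
    names(base_mu) <- all_genes
    total_mu <- sum(base_mu)
    base_mu[mito] <- spec$mito_frac / (1 - spec$mito_frac) *
      (total_mu - sum(base_mu[mito])) / length(mito)
    mu_tam <- mu_ctrl <- base_mu
    mu_tam[planted] <- mu_ctrl[planted] * 2^spec$planted_log2fc
    mu_tam[markers] <- 5
    mu_ctrl[markers] <- 0.05

    depth <- rep(1, 2 * nc)
    n_low <- round(spec$frac_low_depth * 2 * nc)
    n_hm <- round(spec$frac_high_mito * 2 * nc)
    low_cells <- if (n_low > 0) sample(cells, n_low) else character()
    hm_cells <- if (n_hm > 0) sample(setdiff(cells, low_cells), n_hm) else character()
    depth[match(low_cells, cells)] <- 0.02

    size <- 1 / spec$nb_dispersion
    counts <- matrix(0L, nrow = 2 * nc, ncol = ng,
                     dimnames = list(cells, all_genes))
    for (i in seq_along(cells)) {
      mu <- (if (labels[[i]] == "TAM") mu_tam else mu_ctrl) * depth[i]
      if (cells[i] %in% hm_cells) mu[mito] <- mu[mito] * 15
      counts[i, ] <- stats::rnbinom(ng, size = size, mu = mu)
    }
    list(counts = counts, labels = labels, planted_genes = planted,
         marker_genes = markers, mito_genes = mito,
         low_quality_cells = sort(c(low_cells, hm_cells)))
  })
}

#' Generate screening tables with one planted hit
#'
#' FIT and docking tables in the shapes produced by external screening
#' software. One planted drug passes the FIT filter on at least
#' `min_targets` targets and holds the single lowest docking energy (on a
#' designated target); every other drug fails the coverage filter, so the
#' post-processing stage must rank the planted drug-target pair first.
#'
#' @param spec a [synthetic_spec()].
#' @param targets optional target identifiers (defaults to
#'   `spec$n_targets` synthetic proteins).
#' @return A list: `fit`, `dock` (tibbles), `planted_drug`,
#'   `planted_target`.
#' @export
gen_screening <- function(spec, targets = NULL) {
  stopifnot(inherits(spec, "tamnet_spec"))
  with_seed(spec$seed + 2L, {
    if (is.null(targets)) targets <- sprintf("T%02d", seq_len(spec$n_targets))
    nt <- length(targets)
    drugs <- sprintf("ZINC%06d", sample(1e5:9e5, spec$n_drugs))
    planted_drug <- drugs[1]
    drugs <- sample(drugs)   # shuffle so the planted drug sits anywhere

    rows <- purrr::map_dfr(drugs, function(d) {
      if (d == planted_drug) {
        cov <- sample(targets, spec$n_planted_covered)
        fit <- ifelse(targets %in% cov,
                      stats::runif(nt, 0.35, 0.9), stats::runif(nt, 0, 0.25))
      } else {
        n_cov <- sample(0:min(9L, nt - 1L), 1)
        cov <- if (n_cov > 0) sample(targets, n_cov) else character()
        fit <- ifelse(targets %in% cov,
                      stats::runif(nt, 0.3, 0.8), stats::runif(nt, 0, 0.29))
      }
      tibble(drug_id = d, target_id = targets, fit = round(fit, 4))
    })
    covered <- filter(rows, .data$drug_id == planted_drug, .data$fit >= 0.3)
    planted_target <- covered$target_id[1]

    dock <- tidyr::expand_grid(drug_id = drugs, target_id = targets,
                               pose_id = 1:3)
    dock$energy <- round(stats::runif(nrow(dock), -45, -5), 2)
    best <- min(dock$energy)
    dock <- bind_rows(dock, tibble(drug_id = planted_drug,
                                   target_id = planted_target,
                                   pose_id = 4L, energy = round(best - 10, 2)))
    list(fit = rows, dock = dock, planted_drug = planted_drug,
         planted_target = planted_target)
  })
}
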