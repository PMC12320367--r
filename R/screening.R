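#' Filter a pharmacophore FIT-score table
#'
#' Keeps drug-target rows whose FIT value (pharmacophore alignment
#' accuracy) is at least `min_fit` — the bound is inclusive, so a FIT of
#' exactly 0.3 passes at the default.
#'
#' @param fit tibble/data frame with columns `drug_id`, `target_id`, `fit`.
#' @param min_fit non-negative inclusive threshold.
#' @return The filtered tibble.
#' @export
filter_fit <- function(fit, min_fit = 0.3) {
  check_number(min_fit, "min_fit", min = 0)
  fit <- as_tibble(fit)
  filter(fit, .data$fit >= min_fit)
}

#' Per-drug target coverage
#'
#' Counts the distinct targets each drug interacts with in a (filtered) FIT
#' table and keeps drugs covering at least `min_targets` of the
#' `n_targets_total` screened proteins (default: at least ten of thirteen).
#'
#' @param fit filtered FIT tibble (see [filter_fit()]).
#' @param n_targets_total total number of screened target proteins.
#' @param min_targets minimum distinct-target coverage to retain a drug.
#' @return A tibble `drug_id`, `coverage` for the retained drugs, coverage
#'   descending.
#' @export
drug_coverage <- function(fit, n_targets_total = 13, min_targets = 10) {
  if (min_targets > n_targets_total) {
    abort("`min_targets` cannot exceed `n_targets_total`")
  }
  as_tibble(fit) |>
    distinct(.data$drug_id, .data$target_id) |>
    count(.data$drug_id, name = "coverage") |>
    filter(.data$coverage >= min_targets) |>
    arrange(desc(.data$coverage), .data$drug_id)
}

#' Rank drug-target pairs by docking energy
#'
#' Collapses docking poses to the best (lowest) energy per (drug, target)
#' pair and sorts pairs ascending by that energy — CDOCKER-style energies
#' are more favorable when more negative. Restricted to the drugs that
#' passed coverage. Ties are broken lexicographically by drug then target.
#'
#' @param dock tibble/data frame with columns `drug_id`, `target_id`,
#'   `energy` and optionally `pose_id`.
#' @param drugs character vector (or `drug_coverage()` tibble) of drugs to
#'   retain; `NULL` keeps all.
#' @param lower_is_better set to `FALSE` for score-style tables where
#'   larger values are better.
#' @param synonyms optional named character vector mapping compound
#'   identifiers to a canonical drug id (e.g. merging multiple ZINC entries
#'   of one marketed compound) applied before ranking.
#' @return A tibble `drug_id`, `target_id`, `best_energy`, `rank`.
#' @export
rank_pairs <- function(dock, drugs = NULL, lower_is_better = TRUE,
                       synonyms = NULL) {
  dock <- as_tibble(dock)
  if (!is.null(synonyms)) {
    hit <- dock$drug_id %in% names(synonyms)
    dock$drug_id[hit] <- unname(synonyms[dock$drug_id[hit]])
  }
  if (!is.null(drugs)) {
    if (is.data.frame(drugs)) drugs <- drugs$drug_id
    dock <- filter(dock, .data$drug_id %in% drugs)
  }
  best <- if (lower_is_better) min else max
  dock |>
    group_by(.data$drug_id, .data$target_id) |>
    summarise(best_energy = best(.data$energy), .groups = "drop") |>
    arrange(if (lower_is_better) .data$best_energy else desc(.data$best_energy),
            .data$drug_id, .data$target_id) |>
    mutate(rank = row_number())
}

#' Full screening-table post-processing
#'
#' FIT filter, coverage filter, then docking-energy ranking — the complete
#' post-processing of externally produced screening tables.
#'
#' @param fit FIT table (`drug_id`, `target_id`, `fit`).
#' @param dock docking table (`drug_id`, `target_id`, `pose_id`, `energy`).
#' @param n_targets_total,min_targets,min_fit see [drug_coverage()] and
#'   [filter_fit()].
#' @param ... passed to [rank_pairs()].
#' @return A list with `passing_drugs` (coverage tibble) and `ranking`
#'   (ranked pair tibble).
#' @export
screen_rank <- function(fit, dock, n_targets_total = 13, min_targets = 10,
                        min_fit = 0.3, ...) {
  passing <- drug_coverage(filter_fit(fit, min_fit), n_targets_total,
                           min_targets)
  list(passing_drugs = passing,
       ranking = rank_pairs(dock, passing$drug_id, ...))
}

#' Plot a drug-target docking ranking
#'
#' @param object ranking tibble from [rank_pairs()].
#' @param top how many best pairs to show.
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 geom_col coord_flip
#' @export
plot_pair_ranking <- function(object, top = 20, ...) {
  d <- utils::head(object, top)
  d$pair <- stats::reorder(paste(d$drug_id, d$target_id, sep = " / "),
                           -d$best_energy)
  ggplot(d, aes(x = .data$pair, y = .data$best_energy)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "best docking energy")
}
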