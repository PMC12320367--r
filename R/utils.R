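#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   distinct left_join anti_join bind_rows bind_cols count across desc n
#'   row_number
#' @importFrom stats setNames
NULL

# Normalize a gene-symbol vector: uppercase, trimmed. Empty symbols are an error.
normalize_symbols <- function(x, what = "gene symbol") {
  x <- toupper(trimws(as.character(x)))
  if (any(is.na(x) | x == "")) {
    abort(sprintf("%ss must be non-empty strings", what))
  }
  x
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}
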