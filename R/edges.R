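#' Group-level edge thresholding
#'
#' Ranks every candidate edge of the parcellation by its mean weight across
#' all observed participant-timepoint matrices (pairs absent from a matrix
#' count as zero) and retains the strongest fraction. A single group-level
#' mask is computed over the pooled longitudinal data so that the same edge
#' set is compared across all timepoints; the default retains the strongest
#' 30% of candidate edges, which suppresses spurious tractography
#' connections. The number retained is `round(fraction * n_candidates)`.
#' Ties at the cutoff rank are broken deterministically in favour of the
#' lexicographically smallest region pair.
#'
#' @param data A long connectome tibble ([as_connectomes()]).
#' @param regions The region table the cohort was validated against.
#' @param fraction Retention fraction in (0, 1].
#' @return An edge-mask tibble: `region_a`, `region_b`, `type`,
#'   `mean_weight`, `retained`, sorted by descending mean weight with the
#'   lexicographic tie-break; the retention fraction is kept in the
#'   `"retention_fraction"` attribute.
#' @export
group_threshold <- function(data, regions, fraction = 0.30) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must be a single number in (0, 1]")
  }
  cand <- candidate_edges(regions)
  mats <- observed_matrices(data)
  if (nrow(mats) == 0) abort("no matrices in the cohort")
  sums <- data |>
    group_by(.data$region_a, .data$region_b) |>
    summarise(total = sum(.data$weight), .groups = "drop")
  mask <- cand |>
    left_join(sums, by = c("region_a", "region_b")) |>
    mutate(mean_weight = dplyr::coalesce(.data$total, 0) / nrow(mats)) |>
    select(-"total") |>
    arrange(dplyr::desc(.data$mean_weight), .data$region_a, .data$region_b)
  n_keep <- round(fraction * nrow(mask))
  mask |>
    mutate(retained = row_number() <= n_keep) |>
    structure(retention_fraction = fraction)
}

#' Retained edges of a mask
#'
#' @param mask An edge-mask tibble from [group_threshold()].
#' @return The retained rows, sorted canonically.
#' @export
retained_edges <- function(mask) {
  mask |>
    filter(.data$retained) |>
    arrange(.data$region_a, .data$region_b)
}

#' Export an edge mask
#'
#' Writes the mask as a TSV edge list
#' (`region_a  region_b  mean_weight  retained`).
#'
#' @param mask An edge-mask tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_mask <- function(mask, path) {
  readr::write_tsv(select(mask, "region_a", "region_b", "mean_weight", "retained"),
                   path)
  invisible(path)
}
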