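#' Hemispheric network strengths and lateralization
#'
#' For every participant-timepoint matrix, sums the retained edge weights
#' into three network strengths: `left_strength` and `right_strength` (sum of
#' retained intra-hemispheric cortical-cortical weights per hemisphere) and
#' `interhemispheric_strength` (sum of retained cortical-to-CC weights,
#' pooling both hemispheres' cortical regions, i.e. the connections routed
#' across the corpus callosum). The lateralization index is the standard
#' laterality quotient
#' \deqn{LI = (L - R) / (L + R)}
#' taken as 0 when both hemispheric strengths are 0.
#'
#' @param data A long connectome tibble.
#' @param mask An edge mask from [group_threshold()] (pass a
#'   `fraction = 1` mask for unthresholded sums).
#' @param regions The region table.
#' @return A tibble of class `"hemi_summary"`: one row per observed
#'   participant-timepoint with columns `participant`, `timepoint`,
#'   `left_strength`, `right_strength`, `interhemispheric_strength`,
#'   `lateralization_index`.
#' @export
hemispheric_summary <- function(data, mask, regions) {
  keep <- retained_edges(mask) |> select("region_a", "region_b", "type")
  mats <- observed_matrices(data)
  strengths <- data |>
    inner_join(keep, by = c("region_a", "region_b")) |>
    group_by(.data$participant, .data$timepoint, .data$type) |>
    summarise(strength = sum(.data$weight), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "type", values_from = "strength")
  for (col in c("intra_L", "intra_R", "cortico_cc")) {
    if (!col %in% names(strengths)) strengths[[col]] <- 0
  }
  out <- mats |>
    left_join(strengths, by = c("participant", "timepoint")) |>
    mutate(across(c("intra_L", "intra_R", "cortico_cc"),
                  ~ dplyr::coalesce(.x, 0))) |>
    rename(left_strength = "intra_L", right_strength = "intra_R",
           interhemispheric_strength = "cortico_cc") |>
    select("participant", "timepoint", "left_strength", "right_strength",
           "interhemispheric_strength") |>
    mutate(lateralization_index = if_else(
      .data$left_strength + .data$right_strength > 0,
      (.data$left_strength - .data$right_strength) /
        (.data$left_strength + .data$right_strength),
      0
    ))
  class(out) <- c("hemi_summary", class(out))
  out
}

#' Plot hemispheric strength trajectories
#'
#' Boxplots of left and right intra-hemispheric strength and of
#' interhemispheric (cortico-callosal) strength per timepoint, with
#' individual participant points overlaid.
#'
#' @param object A `"hemi_summary"` tibble from [hemispheric_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hemi_summary <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("left_strength", "right_strength",
                          "interhemispheric_strength"),
                        names_to = "measure", values_to = "strength") |>
    mutate(measure = factor(.data$measure,
                            levels = c("left_strength", "right_strength",
                                       "interhemispheric_strength"),
                            labels = c("left intra", "right intra",
                                       "interhemispheric")))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$timepoint),
                                     y = .data$strength,
                                     fill = .data$measure)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.08, dodge.width = 0.75), size = 0.5, alpha = 0.4) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "timepoint (months)", y = "network strength") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
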