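#' Plot an NBS result
#'
#' Circular network layout of the suprathreshold components: regions on a
#' circle (sorted by id, left hemisphere first), component edges drawn as
#' chords coloured by direction, with FWE-significant components at full
#' opacity.
#'
#' @param object An `"nbs_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbs_result <- function(object, ...) {
  comps <- object$components
  stats <- reduce_edge_stats(object$edge_stats)
  verts <- sort(unique(c(stats$region_a, stats$region_b)))
  ang <- setNames(2 * pi * (seq_along(verts) - 1) / length(verts), verts)
  vx <- cos(ang); vy <- sin(ang)
  nodes <- tibble(region = verts, x = cos(ang), y = sin(ang))
  if (nrow(comps) > 0) {
    edges <- comps |>
      select("component", "direction", "p_fwe", "significant", "edges") |>
      tidyr::unnest("edges") |>
      mutate(x = vx[.data$region_a], y = vy[.data$region_a],
             xend = vx[.data$region_b], yend = vy[.data$region_b])
  } else {
    edges <- tibble(direction = character(), significant = logical(),
                    x = numeric(), y = numeric(),
                    xend = numeric(), yend = numeric())
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$direction,
                   alpha = .data$significant)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 0.8) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL,
                  title = paste0("NBS ", object$fixed, " model: ",
                                 sum(comps$significant), " significant component(s)"))
}

#' Histogram of the permutation null with observed components
#'
#' @param object An `"nbs_result"`.
#' @return A ggplot object.
#' @export
plot_nbs_null <- function(object) {
  comps <- object$components
  ggplot2::ggplot(tibble(null = object$null_max),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = comps,
                        ggplot2::aes(xintercept = .data$statistic_value,
                                     colour = .data$direction)) +
    ggplot2::labs(x = paste0("max component ", object$config$statistic,
                             " under permutation"),
                  y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}
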