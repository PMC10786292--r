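#' NBS configuration
#'
#' Parameters of the network-based statistic: the primary edge-level
#' p-threshold that admits edges into the suprathreshold graph, the number
#' of permutations building the null distribution of the maximal component
#' statistic, the component-level family-wise error level, and the component
#' statistic itself (`"extent"` = edge count, `"intensity"` = sum of |t|
#' over component edges).
#'
#' @param p_threshold Edge-level threshold in (0, 1).
#' @param n_perm Number of permutations K.
#' @param alpha Component-level FWE level in (0, 1).
#' @param seed Integer seed for the permutation stream.
#' @param statistic `"extent"` or `"intensity"`.
#' @return A list of class `"nbs_config"`.
#' @export
nbs_config <- function(p_threshold = 0.01, n_perm = 5000, alpha = 0.05,
                       seed = 1L, statistic = c("extent", "intensity")) {
  statistic <- match.arg(statistic)
  if (p_threshold <= 0 || p_threshold >= 1) abort("`p_threshold` must be in (0, 1)")
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  structure(list(p_threshold = p_threshold, n_perm = as.integer(n_perm),
                 alpha = alpha, seed = as.integer(seed), statistic = statistic),
            class = "nbs_config")
}

# Per-edge reduction of a per-contrast stat map: an edge is represented by
# its maximal-|t| contrast (for the omnibus time model an edge enters the
# suprathreshold graph if either baseline contrast passes the threshold; the
# minimal p and the maximal |t| coincide at shared df).
reduce_edge_stats <- function(stats) {
  as_tibble(stats) |>
    group_by(.data$region_a, .data$region_b) |>
    summarise(t = .data$t[which.max(abs(.data$t))],
              p = min(.data$p),
              flagged = any(.data$flagged), .groups = "drop")
}

# connected components of an edge set, largest first, deterministic order
component_table <- function(edges_df) {
  if (nrow(edges_df) == 0) {
    return(tibble(component = integer(), extent = integer(),
                  intensity = numeric(), edges = list(), regions = list()))
  }
  g <- igraph::graph_from_edgelist(
    as.matrix(edges_df[, c("region_a", "region_b")]), directed = FALSE)
  memb <- igraph::components(g)$membership
  edges_df$.comp <- unname(memb[edges_df$region_a])
  out <- edges_df |>
    group_by(.data$.comp) |>
    summarise(extent = dplyr::n(), intensity = sum(abs(.data$t)),
              edges = list(tibble(region_a = region_a, region_b = region_b,
                                  t = t, p = p)),
              regions = list(sort(unique(c(.data$region_a, .data$region_b)))),
              .first_region = min(.data$region_a), .groups = "drop") |>
    arrange(dplyr::desc(.data$extent), dplyr::desc(.data$intensity),
            .data$.first_region) |>
    mutate(component = row_number()) |>
    select("component", "extent", "intensity", "edges", "regions")
  out
}

#' Suprathreshold connected components
#'
#' Forms the graph of edges whose (reduced, per-edge) p-value is below the
#' primary threshold and whose t has the requested sign, and returns its
#' connected components largest-first with deterministic ordering. Flagged
#' (degenerate) edges never enter the graph.
#'
#' @param stats An `"edge_stat_map"` from [edgewise_stats()] (or any tibble
#'   with `region_a`, `region_b`, `t`, `p`, `flagged`).
#' @param p_threshold Edge-level threshold.
#' @param direction `"increase"` (t > 0) or `"decrease"` (t < 0).
#' @return A tibble of components: `component`, `extent`, `intensity`,
#'   `edges` (list of edge tibbles), `regions` (list of member region ids).
#' @export
suprathreshold_components <- function(stats, p_threshold = 0.01,
                                      direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "increase") 1 else -1
  red <- reduce_edge_stats(stats)
  sel <- red |>
    filter(!.data$flagged, .data$p < p_threshold, sign(.data$t) == sgn)
  component_table(sel)
}

# maximal component statistic of a suprathreshold edge set (0 if empty)
max_component_stat <- function(ra, rb, tval, statistic) {
  if (length(ra) == 0) return(0)
  g <- igraph::graph_from_edgelist(cbind(ra, rb), directed = FALSE)
  memb <- igraph::components(g)$membership
  em <- unname(memb[ra])
  if (statistic == "extent") max(tabulate(em)) else max(rowsum(abs(tval), em))
}

# within-participant permutation of timepoint labels (integer codes),
# respecting each participant's observed timepoints
permute_time_codes <- function(gt, idx_by_participant) {
  out <- gt
  for (ix in idx_by_participant) {
    if (length(ix) > 1) out[ix] <- gt[ix][sample.int(length(ix))]
  }
  out
}

#' Network-based statistic over the longitudinal time model
#'
#' Edge-wise participant random-intercept LMEs with time as the fixed
#' effect, thresholded at the primary p-level, reduced to signed connected
#' components, and tested against a permutation null of the maximal
#' component statistic: each of K permutations shuffles timepoint labels
#' within participants (exchangeable under the null given the random
#' intercept), recomputes every edge statistic, and records the maximal
#' component statistic pooled over both directions. Component family-wise
#' error p-values are `p_fwe = (1 + #\{null >= observed\}) / (K + 1)`.
#'
#' @param data A long connectome tibble.
#' @param mask An edge mask from [group_threshold()].
#' @param config An [nbs_config()].
#' @param engine Passed to the edge engine (`"auto"` picks the balanced
#'   fast path when possible).
#' @param theta_grid REML profiling grid for unbalanced designs.
#' @return An object of class `"nbs_result"`: component table with `p_fwe`
#'   and significance flags, the observed edge stat map, the permutation
#'   null distribution and the configuration.
#' @export
nbs_test <- function(data, mask, config = nbs_config(), engine = "auto",
                     theta_grid = reml_theta_grid()) {
  stopifnot(inherits(config, "nbs_config"))
  if (1 / (config$n_perm + 1) > config$alpha) {
    warn("n_perm is too small to reach alpha: the smallest attainable p_fwe exceeds alpha")
  }
  edges <- retained_edges(mask)
  em <- build_edge_matrix(data, edges)
  stats <- edgewise_stats(data, mask, fixed = "time", engine = engine,
                          theta_grid = theta_grid)
  observed <- bind_rows(
    suprathreshold_components(stats, config$p_threshold, "increase") |>
      mutate(direction = "increase"),
    suprathreshold_components(stats, config$p_threshold, "decrease") |>
      mutate(direction = "decrease")
  )
  df2 <- attr(stats, "df")
  tcrit <- qt(1 - config$p_threshold / 2, df2)
  gp <- factor(em$obs$participant)
  tps <- sort(unique(em$obs$timepoint))
  gt <- match(em$obs$timepoint, tps)
  idx_by_p <- split(seq_along(gt), gp)
  balanced <- attr(stats, "engine") == "balanced"
  ekey_a <- edges$region_a
  ekey_b <- edges$region_b
  Y <- em$Y
  n_edge <- ncol(Y)
  null_max <- numeric(config$n_perm)

  if (balanced) {
    n <- nlevels(gp); T_ <- length(tps); N <- nrow(Y)
    S2 <- T_ * colSums((rowsum(Y, as.integer(gp)) / T_)^2)
    q0 <- colSums(Y^2)
    Ngm2 <- N * colMeans(Y)^2
    df2 <- (n - 1) * (T_ - 1)
    perm_tstats <- function(codes) {
      M <- rowsum(Y, codes) / n
      RSS <- pmax(q0 - n * colSums(M^2) - S2 + Ngm2, 0)
      se <- sqrt(2 * (RSS / df2) / n)
      est <- M[-1, , drop = FALSE] - rep(M[1, ], each = T_ - 1)
      tmat <- est / rep(se, each = T_ - 1)
      tmat[is.na(tmat)] <- 0
      tmat
    }
  } else {
    # shared REML context: within-participant label permutations change
    # only X'Y (= rowsum(Y, codes) in the cell-means coding)
    X <- outer(gt, seq_along(tps), `==`) * 1
    p <- ncol(X)
    cons <- lapply(seq_along(tps)[-1], function(j) {
      v <- numeric(p); v[j] <- 1; v[1] <- -1; v
    })
    gpi <- as.integer(gp)
    ctx <- make_reml_ctx(X, gpi, rowsum(Y, gpi), colSums(Y^2), cons,
                         theta_grid)
    perm_tstats <- function(codes) {
      res <- reml_core(rowsum(Y, codes), ctx)
      tmat <- res$t
      tmat[!is.finite(tmat)] <- 0
      tmat
    }
  }

  withr::with_seed(config$seed, {
    for (k in seq_len(config$n_perm)) {
      codes <- permute_time_codes(gt, idx_by_p)
      tmat <- perm_tstats(codes)
      amax <- apply(abs(tmat), 2, max)
      jmax <- max.col(t(abs(tmat)), ties.method = "first")
      tsel <- tmat[cbind(jmax, seq_len(n_edge))]
      hit <- which(amax > tcrit)
      if (length(hit) == 0) {
        null_max[k] <- 0
      } else {
        pos <- hit[tsel[hit] > 0]
        neg <- hit[tsel[hit] < 0]
        null_max[k] <- max(
          max_component_stat(ekey_a[pos], ekey_b[pos], tsel[pos], config$statistic),
          max_component_stat(ekey_a[neg], ekey_b[neg], tsel[neg], config$statistic)
        )
      }
    }
  })

  statv <- if (config$statistic == "extent") observed$extent else observed$intensity
  observed$statistic_value <- as.numeric(statv)
  if (nrow(observed) > 0) {
    observed$p_fwe <- vapply(observed$statistic_value, function(s) {
      (1 + sum(null_max >= s)) / (config$n_perm + 1)
    }, 0)
    observed$significant <- observed$p_fwe < config$alpha
  } else {
    observed$p_fwe <- numeric(0)
    observed$significant <- logical(0)
  }
  observed <- observed |>
    select("component", "direction", "extent", "intensity",
           "statistic_value", "p_fwe", "significant", "edges", "regions") |>
    arrange(dplyr::desc(.data$statistic_value), .data$direction) |>
    mutate(component = row_number())
  structure(list(components = observed, edge_stats = stats,
                 null_max = null_max, config = config,
                 engine = attr(stats, "engine"), df = attr(stats, "df"),
                 fixed = "time"),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("Network-based statistic (", x$fixed, " model, ", x$engine,
      " engine)\n", sep = "")
  cat("edges tested:", length(unique(paste(x$edge_stats$region_a,
                                           x$edge_stats$region_b))),
      "| K =", x$config$n_perm, "| p-threshold =", x$config$p_threshold,
      "| alpha =", x$config$alpha, "\n\n")
  if (nrow(x$components) == 0) {
    cat("no suprathreshold components\n")
  } else {
    print(select(x$components, -"edges", -"regions"))
  }
  invisible(x)
}

#' Tidy an NBS result
#'
#' @param x An `"nbs_result"`.
#' @param ... Unused.
#' @return One row per suprathreshold component: direction, extent,
#'   intensity, the component statistic, `p_fwe`, significance and the
#'   number of member regions.
#' @export
tidy.nbs_result <- function(x, ...) {
  x$components |>
    mutate(n_regions = purrr::map_int(.data$regions, length)) |>
    select("component", "direction", "extent", "intensity",
           "statistic_value", "p_fwe", "significant", "n_regions")
}

#' One-row summary of an NBS result
#'
#' @param x An `"nbs_result"`.
#' @param ... Unused.
#' @return A one-row tibble with the test dimensions and counts.
#' @export
glance.nbs_result <- function(x, ...) {
  tibble(n_edges = nrow(reduce_edge_stats(x$edge_stats)),
         n_components = nrow(x$components),
         n_significant = sum(x$components$significant),
         n_perm = x$config$n_perm, p_threshold = x$config$p_threshold,
         alpha = x$config$alpha, statistic = x$config$statistic,
         engine = x$engine, df = x$df)
}

#' Post-hoc adjacent-period subnetworks
#'
#' Localizes omnibus NBS components in time: for every edge of the selected
#' components, the adjacent-timepoint contrast (releveled two-timepoint
#' refit) is computed for each period, and edges significant at `alpha` are
#' regrouped into signed connected sub-components per period.
#'
#' @param data A long connectome tibble.
#' @param nbs An `"nbs_result"` from [nbs_test()].
#' @param pairs List of adjacent timepoint pairs.
#' @param alpha Edge-level post-hoc threshold.
#' @param which `"significant"` (default) restricts to FWE-significant
#'   components; `"all"` uses every suprathreshold component.
#' @return A tibble: `period`, `direction`, `component`, `extent`,
#'   `intensity`, `edges`, `regions`.
#' @export
posthoc_adjacent <- function(data, nbs, pairs = list(c(0, 3), c(3, 6)),
                             alpha = 0.05, which = c("significant", "all")) {
  which <- match.arg(which)
  comps <- nbs$components
  if (which == "significant") comps <- filter(comps, .data$significant)
  pool <- if (nrow(comps) == 0) {
    tibble(region_a = character(), region_b = character())
  } else {
    bind_rows(comps$edges) |> distinct(.data$region_a, .data$region_b)
  }
  out <- list()
  for (pair in pairs) {
    period <- paste(pair, collapse = "-")
    if (nrow(pool) == 0) next
    sub <- data |> filter(.data$timepoint %in% pair)
    em <- build_edge_matrix(sub, pool)
    res <- edge_stats_engine(em$Y, em$obs$participant,
                             timepoint = em$obs$timepoint)
    per_edge <- tibble(region_a = pool$region_a, region_b = pool$region_b,
                       t = res$t[1, ], p = res$p[1, ],
                       flagged = res$flagged)
    for (dir in c("increase", "decrease")) {
      ct <- suprathreshold_components(per_edge, alpha, dir)
      if (nrow(ct) > 0) {
        out[[length(out) + 1]] <- ct |>
          mutate(period = period, direction = dir)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(period = character(), direction = character(),
                  component = integer(), extent = integer(),
                  intensity = numeric(), edges = list(), regions = list()))
  }
  bind_rows(out) |>
    select("period", "direction", "component", "extent", "intensity",
           "edges", "regions")
}

#' Network-based statistic over the behavioural score model
#'
#' The same component-permutation machinery with the score slope of
#' `y ~ score + (1 | participant)` as the edge statistic, over the
#' timepoints at which scores exist. The permutation null exchanges whole
#' score trajectories between participants with matching timepoint
#' availability, preserving within-participant score ordering while
#' breaking the brain-behaviour coupling. Components are reported per slope
#' sign (`"positive"`, `"negative"`).
#'
#' @param data A long connectome tibble.
#' @param scores A tibble `participant`, `timepoint`, `score`.
#' @param mask An edge mask.
#' @param config An [nbs_config()].
#' @param theta_grid REML profiling grid.
#' @return An `"nbs_result"` with `fixed = "score"`.
#' @export
nbs_score <- function(data, scores, mask, config = nbs_config(),
                      theta_grid = reml_theta_grid()) {
  stopifnot(inherits(config, "nbs_config"))
  if (1 / (config$n_perm + 1) > config$alpha) {
    warn("n_perm is too small to reach alpha: the smallest attainable p_fwe exceeds alpha")
  }
  stats <- edgewise_stats(data, mask, fixed = "score", scores = scores,
                          theta_grid = theta_grid)
  observed <- bind_rows(
    suprathreshold_components(stats, config$p_threshold, "increase") |>
      mutate(direction = "positive"),
    suprathreshold_components(stats, config$p_threshold, "decrease") |>
      mutate(direction = "negative")
  )
  # rebuild the response/design exactly as edgewise_stats saw them
  scores <- as_tibble(scores) |>
    mutate(participant = as.character(.data$participant),
           timepoint = as.numeric(.data$timepoint))
  data2 <- data |>
    filter(.data$timepoint %in% unique(scores$timepoint)) |>
    semi_join(scores, by = c("participant", "timepoint"))
  edges <- retained_edges(mask)
  em <- build_edge_matrix(data2, edges)
  sc <- (em$obs |> left_join(scores, by = c("participant", "timepoint")))$score
  gp <- factor(em$obs$participant)
  gpi <- as.integer(gp)
  V <- rowsum(em$Y, gpi)
  q0 <- colSums(em$Y^2)
  df2 <- attr(stats, "df")
  tcrit <- qt(1 - config$p_threshold / 2, df2)
  # availability groups: participants exchange score trajectories only with
  # participants tested at the same timepoints
  avail <- em$obs |>
    group_by(.data$participant) |>
    summarise(sig = paste(sort(.data$timepoint), collapse = ","),
              .groups = "drop")
  avail <- avail[match(levels(gp), avail$participant), ]
  groups_by_avail <- split(seq_len(nlevels(gp)), avail$sig)
  ekey_a <- edges$region_a
  ekey_b <- edges$region_b
  n_edge <- ncol(em$Y)
  null_max <- numeric(config$n_perm)
  withr::with_seed(config$seed, {
    for (k in seq_len(config$n_perm)) {
      pmap_idx <- seq_len(nlevels(gp))
      for (ix in groups_by_avail) {
        if (length(ix) > 1) pmap_idx[ix] <- ix[sample.int(length(ix))]
      }
      # observation score becomes the matched participant's score at the
      # same timepoint
      donor <- pmap_idx[gpi]
      key <- paste(levels(gp)[donor], em$obs$timepoint)
      sc_perm <- scores$score[match(key, paste(scores$participant,
                                               scores$timepoint))]
      res <- stat_reml(em$Y, cbind(1, sc_perm), gpi, list(c(0, 1)),
                       theta_grid, V = V, q0 = q0)
      tv <- res$t[1, ]
      tv[!is.finite(tv)] <- 0
      hit <- which(abs(tv) > tcrit & !res$flagged)
      if (length(hit) == 0) {
        null_max[k] <- 0
      } else {
        pos <- hit[tv[hit] > 0]
        neg <- hit[tv[hit] < 0]
        null_max[k] <- max(
          max_component_stat(ekey_a[pos], ekey_b[pos], tv[pos], config$statistic),
          max_component_stat(ekey_a[neg], ekey_b[neg], tv[neg], config$statistic)
        )
      }
    }
  })
  statv <- if (config$statistic == "extent") observed$extent else observed$intensity
  observed$statistic_value <- as.numeric(statv)
  if (nrow(observed) > 0) {
    observed$p_fwe <- vapply(observed$statistic_value, function(s) {
      (1 + sum(null_max >= s)) / (config$n_perm + 1)
    }, 0)
    observed$significant <- observed$p_fwe < config$alpha
  } else {
    observed$p_fwe <- numeric(0)
    observed$significant <- logical(0)
  }
  observed <- observed |>
    select("component", "direction", "extent", "intensity",
           "statistic_value", "p_fwe", "significant", "edges", "regions") |>
    arrange(dplyr::desc(.data$statistic_value), .data$direction) |>
    mutate(component = row_number())
  structure(list(components = observed, edge_stats = stats,
                 null_max = null_max, config = config,
                 engine = attr(stats, "engine"), df = attr(stats, "df"),
                 fixed = "score"),
            class = "nbs_result")
}

#' Split participants by a behavioural value
#'
#' Partitions participants into an above-criterion and an at-or-below
#' group (default criterion: the sample mean), for subgroup reruns of the
#' score-based NBS.
#'
#' @param data A data frame with one value per participant.
#' @param value Name of the value column.
#' @param participant Name of the participant column.
#' @param criterion Function of the values giving the split point.
#' @return A list: `above`, `below` (character vectors of participant ids)
#'   and `threshold`.
#' @export
subgroup_split <- function(data, value = "score", participant = "participant",
                           criterion = mean) {
  data <- as_tibble(data)
  vals <- data[[value]]
  ids <- as.character(data[[participant]])
  if (anyDuplicated(ids)) abort("one value per participant required")
  thr <- criterion(vals)
  above <- ids[vals > thr]
  below <- ids[vals <= thr]
  if (length(above) < 4 || length(below) < 4) {
    warn("a subgroup has fewer than 4 participants; downstream tests will be underpowered")
  }
  list(above = above, below = below, threshold = thr)
}
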