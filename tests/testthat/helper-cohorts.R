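# shared fixtures: tiny parcellations, random cohorts, brute-force oracles

toy_regions <- function() {
  validate_region_table(tibble::tibble(
    region_id = c("L_a", "L_b", "R_a", "R_b", "L_cc", "R_cc"),
    hemisphere = c("L", "L", "R", "R", "L", "R"),
    system = c("CTX", "CTX", "CTX", "CTX", "aCC", "pCC")
  ))
}

# a small null cohort; defaults keep every participant at every timepoint
small_cohort <- function(seed, n = 10, regions = make_region_table(4, 1),
                         dropout = c(0, 0), ...) {
  cfg <- sim_config(n_participants = n, dropout_per_period = dropout,
                    seed = seed, ...)
  simulate_connectomes(cfg, regions)
}

# single-response balanced two-timepoint dataset with participant effects
balanced_two_tp <- function(seed, n = 12) {
  withr::with_seed(seed, {
    b <- rnorm(n, 0, runif(1, 0, 1.5))
    y0 <- 1 + b + rnorm(n, 0, 0.5)
    y1 <- 1.2 + b + rnorm(n, 0, 0.5)
    tibble::tibble(
      participant = rep(sprintf("p%02d", seq_len(n)), 2),
      timepoint = rep(c(0, 3), each = n),
      y = c(y0, y1)
    )
  })
}

# brute-force union-find connected components over an edge table;
# returns a list of sorted edge-index vectors, one per component
oracle_components <- function(edges) {
  verts <- unique(c(edges$region_a, edges$region_b))
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$region_a[i])
    rb <- find(edges$region_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(edges$region_a, find, "")
  unname(lapply(split(seq_len(nrow(edges)), roots), sort))
}
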