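fake_stats <- function(edges, t, p = NULL) {
  tibble::tibble(region_a = edges[, 1], region_b = edges[, 2],
                 contrast = "time3", estimate = t, se = 1, t = t,
                 p = if (is.null(p)) 2 * stats::pt(-abs(t), 20) else p,
                 flagged = FALSE)
}

test_that("component extraction handles canonical small graphs", {
  # 4-edge path over 5 regions -> one component of extent 4
  path <- cbind(paste0("r", 1:4), paste0("r", 2:5))
  ct <- suprathreshold_components(fake_stats(path, t = rep(5, 4)), 0.01,
                                  "increase")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$extent, 4)
  expect_equal(ct$regions[[1]], paste0("r", 1:5))

  # two disjoint triangles -> two components of extent 3
  tri <- rbind(cbind(c("a1", "a2", "a1"), c("a2", "a3", "a3")),
               cbind(c("b1", "b2", "b1"), c("b2", "b3", "b3")))
  ct2 <- suprathreshold_components(fake_stats(tri, t = rep(4, 6)), 0.01,
                                   "increase")
  expect_equal(ct2$extent, c(3, 3))

  # sign and threshold filters
  mixed <- fake_stats(path, t = c(5, -5, 5, 0.1))
  expect_equal(sum(suprathreshold_components(mixed, 0.01, "increase")$extent), 2)
  expect_equal(sum(suprathreshold_components(mixed, 0.01, "decrease")$extent), 1)
})

test_that("component extraction agrees with a union-find oracle on random graphs", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n_vert <- sample(4:12, 1)
      n_edge <- sample(3:min(50, choose(n_vert, 2)), 1)
      all_pairs <- t(utils::combn(paste0("v", 1:n_vert), 2))
      sel <- all_pairs[sample(nrow(all_pairs), min(n_edge, nrow(all_pairs))), ,
                       drop = FALSE]
      st <- fake_stats(sel, t = rep(6, nrow(sel)))
      ct <- suprathreshold_components(st, 0.01, "increase")
      oracle <- oracle_components(tibble::tibble(region_a = sel[, 1],
                                                 region_b = sel[, 2]))
      expect_equal(nrow(ct), length(oracle))
      expect_setequal(
        sort(vapply(ct$edges, nrow, 0L)),
        sort(vapply(oracle, length, 0L))
      )
      # identical edge partitions, not just matching sizes
      key <- function(e) paste(sort(paste(e$region_a, e$region_b)), collapse = ";")
      sel_tbl <- tibble::tibble(region_a = sel[, 1], region_b = sel[, 2])
      expect_setequal(
        vapply(ct$edges, key, ""),
        vapply(oracle, function(ix) key(sel_tbl[ix, ]), "")
      )
    }
  })
})

test_that("permutation p-values respect their arithmetic bounds", {
  reg <- make_region_table(4, 1)
  cand <- candidate_edges(reg)
  pl <- select_connected_edges(cand, 4, seed = 2)
  cfg <- sim_config(n_participants = 15, dropout_per_period = c(0, 0),
                    seed = 9, plasticity_sd = 0,
                    planted_effects = list(planted_effect(pl, "second",
                                                          "increase", 3)))
  dat <- simulate_connectomes(cfg, reg)
  mask <- group_threshold(dat, reg, 1)
  res <- nbs_test(dat, mask, nbs_config(n_perm = 99, seed = 1))
  expect_true(all(res$components$p_fwe >= 1 / 100))
  expect_true(all(res$components$p_fwe <= 1))

  expect_warning(res1 <- nbs_test(dat, mask, nbs_config(n_perm = 1, seed = 1)),
                 "too small")
  expect_true(all(res1$components$p_fwe %in% c(0.5, 1)))
})

test_that("NBS runs are reproducible given the seed", {
  reg <- make_region_table(5, 1)
  dat <- small_cohort(seed = 33, n = 12, regions = reg, dropout = c(0, 3))
  mask <- group_threshold(dat, reg, 0.5)
  r1 <- nbs_test(dat, mask, nbs_config(n_perm = 60, seed = 4))
  r2 <- nbs_test(dat, mask, nbs_config(n_perm = 60, seed = 4))
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(tidy(r1), tidy(r2))
  r3 <- nbs_test(dat, mask, nbs_config(n_perm = 60, seed = 5))
  expect_false(identical(r1$null_max, r3$null_max))
})

test_that("lowering the primary threshold never grows a component", {
  reg <- make_region_table(6, 1)
  cand <- candidate_edges(reg)
  pl <- select_connected_edges(cand, 6, seed = 8)
  cfg <- sim_config(n_participants = 20, dropout_per_period = c(0, 0),
                    seed = 13, plasticity_sd = 0,
                    planted_effects = list(planted_effect(pl, "second",
                                                          "increase", 1.5)))
  dat <- simulate_connectomes(cfg, reg)
  mask <- group_threshold(dat, reg, 1)
  st <- edgewise_stats(dat, mask)
  for (dir in c("increase", "decrease")) {
    prev_max <- Inf
    for (thr in c(0.05, 0.01, 0.001)) {
      ct <- suprathreshold_components(st, thr, dir)
      cur <- if (nrow(ct) == 0) 0 else max(ct$extent)
      expect_lte(cur, prev_max)
      prev_max <- cur
    }
  }
})

test_that("a planted connected effect is detected and localized to its period", {
  reg <- make_region_table(8, 2)
  cand <- candidate_edges(reg)
  pl <- select_connected_edges(cand, 8, seed = 5)
  cfg <- sim_config(n_participants = 40, dropout_per_period = c(0, 0),
                    seed = 21, plasticity_sd = 0,
                    planted_effects = list(planted_effect(pl, "second",
                                                          "decrease", 1.2)))
  dat <- simulate_connectomes(cfg, reg)
  mask <- group_threshold(dat, reg, 1)
  res <- nbs_test(dat, mask, nbs_config(n_perm = 300, seed = 31))
  sig <- dplyr::filter(res$components, significant, direction == "decrease")
  expect_gte(nrow(sig), 1)
  got <- sig$edges[[1]]
  inter <- nrow(dplyr::semi_join(got, pl, by = c("region_a", "region_b")))
  expect_gte(inter / (nrow(got) + nrow(pl) - inter), 0.6)

  ph <- posthoc_adjacent(dat, res)
  late <- dplyr::filter(ph, period == "3-6", direction == "decrease")
  early <- dplyr::filter(ph, period == "0-3")
  expect_gte(sum(late$extent), 5)
  expect_lte(sum(early$extent), 2)
})

test_that("two opposite-signed planted effects are reported with correct signs", {
  reg <- make_region_table(8, 2)
  cand <- candidate_edges(reg)
  up <- select_connected_edges(dplyr::filter(cand, type == "intra_L"), 5,
                               seed = 3)
  down <- select_connected_edges(dplyr::filter(cand, type == "cortico_cc"), 5,
                                 seed = 4)
  cfg <- sim_config(n_participants = 40, dropout_per_period = c(0, 0),
                    seed = 77, plasticity_sd = 0,
                    planted_effects = list(
                      planted_effect(up, "second", "increase", 1.3),
                      planted_effect(down, "second", "decrease", 1.3)))
  dat <- simulate_connectomes(cfg, reg)
  mask <- group_threshold(dat, reg, 1)
  res <- nbs_test(dat, mask, nbs_config(n_perm = 300, seed = 5))
  sig <- dplyr::filter(res$components, significant)
  expect_setequal(unique(sig$direction), c("increase", "decrease"))
  ph <- posthoc_adjacent(dat, res)
  late <- dplyr::filter(ph, period == "3-6")
  expect_setequal(unique(late$direction), c("increase", "decrease"))
  inc_regions <- unlist(dplyr::filter(late, direction == "increase")$regions)
  expect_true(all(grepl("^L_C", inc_regions)))
})

test_that("score-coupled subnetworks are recovered with matching sign", {
  reg <- make_region_table(8, 2)
  cand <- candidate_edges(reg)
  pl <- select_connected_edges(cand, 8, seed = 601)
  cfg <- sim_config(n_participants = 40, dropout_per_period = c(0, 0),
                    seed = 7002, plasticity_sd = 2.5,
                    planted_effects = list(planted_effect(pl, "second",
                                                          "increase", 1.2)),
                    score_model = list(coupling = 0.85, coupling_edges = pl,
                                       gain_sd = 8))
  dat <- simulate_connectomes(cfg, reg)
  sc <- simulate_scores(cfg, dat)
  mask <- group_threshold(dat, reg, 1)
  res <- nbs_score(dat, sc, mask,
                   nbs_config(n_perm = 300, seed = 8002,
                              statistic = "intensity"))
  sig <- dplyr::filter(res$components, significant, direction == "positive")
  expect_gte(nrow(sig), 1)
  got <- sig$edges[[1]]
  inter <- nrow(dplyr::semi_join(got, pl, by = c("region_a", "region_b")))
  expect_gte(inter / (nrow(got) + nrow(pl) - inter), 0.5)
})

test_that("subgroup_split partitions on the mean with warnings when tiny", {
  df <- tibble::tibble(participant = c("a", "b", "c", "d"),
                       score = c(1, 2, 3, 4))
  expect_warning(sp <- subgroup_split(df), "fewer than 4")
  expect_setequal(sp$above, c("c", "d"))
  expect_setequal(sp$below, c("a", "b"))
  expect_equal(sp$threshold, 2.5)

  same <- tibble::tibble(participant = letters[1:10], score = 5)
  expect_warning(sp2 <- subgroup_split(same), "fewer than 4")
  expect_equal(length(sp2$above), 0)
  expect_equal(length(sp2$below), 10)

  withr::with_seed(1, {
    big <- tibble::tibble(participant = sprintf("p%02d", 1:40),
                          score = rnorm(40, 60, 10))
  })
  sp3 <- subgroup_split(big)
  expect_equal(length(sp3$above) + length(sp3$below), 40)
  expect_error(subgroup_split(dplyr::bind_rows(big, big[1, ])),
               "one value per participant")
})
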