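test_that("simulation is deterministic given the seed and respects dropout", {
  reg <- make_region_table(4, 1)
  cfg <- sim_config(n_participants = 12, dropout_per_period = c(2, 3), seed = 4)
  d1 <- simulate_connectomes(cfg, reg)
  d2 <- simulate_connectomes(cfg, reg)
  expect_identical(d1, d2)
  per_tp <- dplyr::count(dplyr::distinct(d1, participant, timepoint), timepoint)
  expect_equal(per_tp$n, c(12, 10, 7))
  # everyone has a baseline; weights are nonnegative
  expect_true(all(d1$weight >= 0))
  expect_equal(sum(per_tp$n[1] == 12), 1)
})

test_that("the default design emulates the 59-to-51 attrition cohort", {
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$n_participants, 59L)
  expect_equal(cfg$timepoints, c(0, 3, 6))
  expect_equal(cfg$dropout_per_period, c(0L, 8L))
  reg <- make_region_table(3, 1)
  dat <- simulate_connectomes(cfg, reg)
  per_tp <- dplyr::count(dplyr::distinct(dat, participant, timepoint), timepoint)
  expect_equal(per_tp$n, c(59, 59, 51))
})

test_that("a noise-free configuration collapses to identical matrices", {
  reg <- make_region_table(3, 1)
  cfg <- sim_config(n_participants = 4, dropout_per_period = c(0, 0),
                    subject_sd = 0, noise_sd = 0, plasticity_sd = 0, seed = 8)
  dat <- simulate_connectomes(cfg, reg)
  spread <- dat |>
    dplyr::group_by(region_a, region_b) |>
    dplyr::summarise(v = stats::var(weight), .groups = "drop")
  expect_true(all(spread$v == 0))
})

test_that("the asymmetry offset lateralizes the network to the left", {
  reg <- make_region_table(6, 1)
  cfg <- sim_config(n_participants = 40, dropout_per_period = c(0, 0),
                    asymmetry_delta = 0.15, seed = 31)
  dat <- simulate_connectomes(cfg, reg)
  hs <- hemispheric_summary(dat, group_threshold(dat, reg, 1), reg)
  expect_gt(mean(hs$left_strength), mean(hs$right_strength))
})

test_that("planted second-period decreases shift the sample mean by the stated amount", {
  reg <- make_region_table(6, 1)
  cand <- candidate_edges(reg)
  pl <- select_connected_edges(cand, 4, seed = 2)
  cfg <- sim_config(n_participants = 220, dropout_per_period = c(0, 0),
                    plasticity_sd = 0, seed = 77,
                    planted_effects = list(planted_effect(pl, "second",
                                                          "decrease", 1)))
  dat <- simulate_connectomes(cfg, reg)
  means <- dat |>
    dplyr::semi_join(pl, by = c("region_a", "region_b")) |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(m = mean(weight), .groups = "drop")
  shift <- means$m[means$timepoint == 6] - means$m[means$timepoint == 3]
  # expected -magnitude * noise_sd = -0.2; MC SE ~ noise_sd*sqrt(2/(220*4))
  mc_se <- cfg$noise_sd * sqrt(2 / (220 * 4))
  expect_lt(abs(shift - (-1 * cfg$noise_sd)), 3 * mc_se)
  # first period untouched
  drift <- means$m[means$timepoint == 3] - means$m[means$timepoint == 0]
  expect_lt(abs(drift), 3 * mc_se)
})

test_that("planting outside the candidate set is an error", {
  reg <- make_region_table(3, 1)
  bad <- tibble::tibble(region_a = "L_C01", region_b = "R_C01")  # cross-hemispheric
  cfg <- sim_config(n_participants = 4, seed = 1, dropout_per_period = c(0, 0),
                    planted_effects = list(planted_effect(bad, "second",
                                                          "increase", 1)))
  expect_error(simulate_connectomes(cfg, reg), "outside the candidate set")
})

test_that("the intraclass correlation grows with the subject SD", {
  reg <- make_region_table(4, 0)
  icc_of <- function(ssd) {
    cfg <- sim_config(n_participants = 60, dropout_per_period = c(0, 0),
                      subject_sd = ssd, seed = 55)
    dat <- simulate_connectomes(cfg, reg)
    wide <- dat |>
      dplyr::filter(timepoint %in% c(0, 3)) |>
      tidyr::pivot_wider(names_from = timepoint, values_from = weight)
    mean(dplyr::summarise(
      dplyr::group_by(wide, region_a, region_b),
      r = stats::cor(`0`, `3`), .groups = "drop")$r)
  }
  expect_gt(icc_of(0.6), icc_of(0.1))
  expect_gt(icc_of(0.6), 0.5)
})

test_that("edge_baselines reproduces the generator's deterministic baselines", {
  reg <- make_region_table(5, 1)
  cfg <- sim_config(n_participants = 300, dropout_per_period = c(0, 0),
                    subject_sd = 0, noise_sd = 0.05, plasticity_sd = 0, seed = 12)
  eb <- edge_baselines(cfg, reg)
  dat <- simulate_connectomes(cfg, reg)
  obs <- dat |>
    dplyr::group_by(region_a, region_b) |>
    dplyr::summarise(m = mean(weight), .groups = "drop") |>
    dplyr::inner_join(eb, by = c("region_a", "region_b"))
  expect_lt(max(abs(obs$m - obs$baseline)), 0.01)
})

test_that("every simulated participant improves between the two tests", {
  reg <- make_region_table(4, 1)
  for (seed in c(1, 7, 23)) {
    cfg <- sim_config(n_participants = 30, dropout_per_period = c(0, 4),
                      seed = seed)
    dat <- simulate_connectomes(cfg, reg)
    sc <- simulate_scores(cfg, dat)
    wide <- tidyr::pivot_wider(sc, names_from = timepoint, values_from = score)
    expect_true(all(wide$`6` > wide$`3`))
    # only completers are scored
    expect_equal(nrow(wide), 26)
  }
})

test_that("uncoupled gains are uncorrelated with edge changes", {
  reg <- make_region_table(4, 1)
  cand <- candidate_edges(reg)
  ce <- select_connected_edges(cand, 4, seed = 5)
  rs <- vapply(1:12, function(i) {
    cfg <- sim_config(n_participants = 40, dropout_per_period = c(0, 0),
                      seed = 100 + i,
                      score_model = list(coupling = 0, coupling_edges = ce))
    dat <- simulate_connectomes(cfg, reg)
    sc <- simulate_scores(cfg, dat)
    gain <- tidyr::pivot_wider(sc, names_from = timepoint,
                               values_from = score)
    gain <- gain$`6` - gain$`3`
    d <- dat |>
      dplyr::filter(timepoint %in% c(3, 6)) |>
      dplyr::semi_join(ce, by = c("region_a", "region_b")) |>
      dplyr::group_by(participant, timepoint) |>
      dplyr::summarise(m = mean(weight), .groups = "drop") |>
      tidyr::pivot_wider(names_from = timepoint, values_from = m)
    stats::cor(gain, d$`6` - d$`3`)
  }, 0)
  expect_lt(abs(mean(rs)), 2 * stats::sd(rs) / sqrt(length(rs)) + 0.05)
})

test_that("lognormal weights are positive and deterministic", {
  reg <- make_region_table(3, 0)
  cfg <- sim_config(n_participants = 5, dropout_per_period = c(0, 0),
                    weight_model = "lognormal", seed = 3)
  d1 <- simulate_connectomes(cfg, reg)
  expect_true(all(d1$weight > 0))
  expect_identical(d1, simulate_connectomes(cfg, reg))
})

test_that("null_cohort strips planted effects but keeps the generative model", {
  reg <- make_region_table(4, 1)
  pl <- select_connected_edges(candidate_edges(reg), 3, seed = 1)
  cfg <- sim_config(n_participants = 8, dropout_per_period = c(0, 0), seed = 6,
                    planted_effects = list(planted_effect(pl, "second",
                                                          "increase", 5)))
  with_eff <- simulate_connectomes(cfg, reg)
  null <- null_cohort(cfg, reg)
  cfg0 <- cfg; cfg0$planted_effects <- list()
  expect_identical(null, simulate_connectomes(cfg0, reg))
  expect_false(identical(null, with_eff))
})
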