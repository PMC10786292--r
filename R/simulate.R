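#' Simulation configuration for a synthetic longitudinal cohort
#'
#' Bundles the generative parameters of the synthetic cohort generator.
#' Edge weights follow a truncated-Gaussian random-intercept model,
#' \deqn{w_{pet} = \max(0,\; \beta_e + a_e + b_p + u_p s_e(t) + \epsilon_{pet})}
#' with per-edge baseline \eqn{\beta_e \sim N(\mu_0, \sigma_0^2)}, a
#' left-hemisphere asymmetry offset \eqn{a_e}, a participant random intercept
#' \eqn{b_p \sim N(0, \sigma_b^2)}, planted period-specific shifts
#' \eqn{s_e(t)} scaled by a participant plasticity multiplier
#' \eqn{u_p \sim N(1, \sigma_u^2)}, and residual noise
#' \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)}.
#'
#' Defaults emulate the reference study design: 59 participants measured at
#' 0, 3 and 6 months with 8 participants lost (missing-at-random) during the
#' second learning period (59 complete the first phase, 51 both), a
#' left-lateralized network, and behavioural scores at 3 and 6 months that
#' improve for every participant.
#'
#' @param n_participants Cohort size at baseline.
#' @param timepoints Measurement months, ascending.
#' @param dropout_per_period Participants lost during each period (length
#'   `length(timepoints) - 1`); dropped participants miss all later
#'   timepoints.
#' @param baseline_edge_mean,baseline_edge_sd Mean and SD of per-edge
#'   baseline weights (arbitrary connectivity units).
#' @param subject_sd SD of the participant random intercept.
#' @param noise_sd Residual SD; planted-effect magnitudes are expressed in
#'   units of this SD.
#' @param asymmetry_delta Additive weight offset for left intra-hemispheric
#'   cortical edges (left > right lateralization).
#' @param plasticity_sd SD of the participant-level multiplier on planted
#'   shifts (individual differences in plasticity; drives brain-behaviour
#'   coupling).
#' @param planted_effects List of [planted_effect()] objects.
#' @param score_model List with elements `baseline_mean`, `baseline_sd`
#'   (score level at the first test), `gain_mean`, `gain_sd` (improvement
#'   between tests, kept strictly positive), `coupling` (target correlation
#'   in \[-1, 1\] between gains and the participant's mean change on
#'   `coupling_edges`) and `coupling_edges` (tibble `region_a`, `region_b`
#'   or `NULL`).
#' @param weight_model `"gaussian"` (truncated at zero; default, keeps
#'   planted magnitudes interpretable as standardized mean shifts) or
#'   `"lognormal"` (exponentiates the linear predictor).
#' @param seed Integer seed fixing the full output stream.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 59,
                       timepoints = c(0, 3, 6),
                       dropout_per_period = c(0, 8),
                       baseline_edge_mean = 1,
                       baseline_edge_sd = 0.3,
                       subject_sd = 0.25,
                       noise_sd = 0.2,
                       asymmetry_delta = 0.15,
                       plasticity_sd = 0.5,
                       planted_effects = list(),
                       score_model = list(),
                       weight_model = c("gaussian", "lognormal"),
                       seed = 1L) {
  weight_model <- match.arg(weight_model)
  score_defaults <- list(baseline_mean = 60, baseline_sd = 8,
                         gain_mean = 15, gain_sd = 5,
                         coupling = 0, coupling_edges = NULL)
  score_model <- modifyList(score_defaults, score_model)
  cfg <- list(n_participants = as.integer(n_participants),
              timepoints = sort(as.numeric(timepoints)),
              dropout_per_period = as.integer(dropout_per_period),
              baseline_edge_mean = baseline_edge_mean,
              baseline_edge_sd = baseline_edge_sd,
              subject_sd = subject_sd, noise_sd = noise_sd,
              asymmetry_delta = asymmetry_delta,
              plasticity_sd = plasticity_sd,
              planted_effects = planted_effects,
              score_model = score_model,
              weight_model = weight_model,
              seed = as.integer(seed))
  stopifnot(cfg$n_participants >= 2, length(cfg$timepoints) >= 2)
  if (length(cfg$dropout_per_period) != length(cfg$timepoints) - 1) {
    abort("`dropout_per_period` needs one entry per learning period")
  }
  sds <- c(cfg$baseline_edge_sd, cfg$subject_sd, cfg$noise_sd,
           cfg$plasticity_sd, score_model$baseline_sd, score_model$gain_sd)
  if (any(sds < 0)) abort("all SD parameters must be >= 0")
  if (sum(cfg$dropout_per_period) >= cfg$n_participants) {
    abort("dropout exceeds the cohort size")
  }
  if (abs(score_model$coupling) > 1) abort("`coupling` is a correlation in [-1, 1]")
  structure(cfg, class = "sim_config")
}

#' Define a planted subnetwork effect
#'
#' A connected set of candidate edges whose weights shift in a given period:
#' `"first"` effects appear from the second timepoint on (a persistent change
#' acquired in the first period), `"second"` effects from the third
#' timepoint, `"both"` effects accumulate one magnitude unit per period. The
#' magnitude is a standardized mean shift (in units of the residual SD).
#'
#' @param edges Tibble with columns `region_a`, `region_b`.
#' @param period `"first"`, `"second"` or `"both"`.
#' @param direction `"increase"` or `"decrease"`.
#' @param magnitude Positive standardized effect size.
#' @return A list of class `"planted_effect"`.
#' @export
planted_effect <- function(edges, period = c("second", "first", "both"),
                           direction = c("increase", "decrease"),
                           magnitude = 1) {
  period <- match.arg(period)
  direction <- match.arg(direction)
  if (magnitude <= 0) abort("`magnitude` must be > 0")
  edges <- as_tibble(edges)[, c("region_a", "region_b")] |>
    mutate(canonical_pair(.data$region_a, .data$region_b))
  structure(list(edges = edges, period = period, direction = direction,
                 magnitude = magnitude),
            class = "planted_effect")
}

#' Per-edge baseline weights implied by a configuration
#'
#' Returns the deterministic per-edge baseline means the generator will use
#' for a given config and parcellation (the asymmetry offset included), so a
#' study can plant effects on strong connections that survive thresholding.
#'
#' @param config A [sim_config()].
#' @param regions A region table.
#' @return The candidate-edge tibble with a `baseline` column.
#' @export
edge_baselines <- function(config, regions) {
  cand <- candidate_edges(regions)
  z <- withr::with_seed(config$seed, rnorm(nrow(cand)))
  cand |>
    mutate(baseline = config$baseline_edge_mean + config$baseline_edge_sd * z +
             if_else(.data$type == "intra_L", config$asymmetry_delta, 0))
}

# period activation multiplier at each timepoint position (1 = baseline)
effect_multiplier <- function(period, n_timepoints) {
  pos <- seq_len(n_timepoints)
  switch(period,
         first = as.numeric(pos >= 2),
         second = as.numeric(pos >= 3),
         both = pmax(pos - 1, 0))
}

#' Simulate a longitudinal connectome cohort
#'
#' Draws a full cohort from the generative model described in
#' [sim_config()]. The random stream is fixed by `config$seed`; identical
#' configurations regenerate bitwise-identical cohorts. Dropout removes a
#' random participant subset (missing-at-random) from all timepoints after
#' the period in which they leave.
#'
#' @param config A [sim_config()].
#' @param regions A region table; planted-effect edges must belong to its
#'   candidate edge set.
#' @return A long connectome tibble covering every candidate edge of every
#'   observed participant-timepoint matrix.
#' @export
simulate_connectomes <- function(config, regions) {
  stopifnot(inherits(config, "sim_config"))
  regions <- validate_region_table(regions)
  cand <- candidate_edges(regions)
  ne <- nrow(cand)
  tp <- config$timepoints
  nt <- length(tp)
  np <- config$n_participants
  key <- paste(cand$region_a, cand$region_b)
  for (eff in config$planted_effects) {
    miss <- setdiff(paste(eff$edges$region_a, eff$edges$region_b), key)
    if (length(miss) > 0) {
      abort(paste0("planted edge(s) outside the candidate set: ",
                   paste(miss, collapse = ", ")))
    }
  }
  # per-edge planted shift at each timepoint position (weight units)
  shift <- matrix(0, ne, nt)
  for (eff in config$planted_effects) {
    sgn <- if (eff$direction == "increase") 1 else -1
    rows <- match(paste(eff$edges$region_a, eff$edges$region_b), key)
    mult <- effect_multiplier(eff$period, nt)
    shift[rows, ] <- shift[rows, ] +
      sgn * eff$magnitude * config$noise_sd * rep(mult, each = length(rows))
  }
  withr::with_seed(config$seed, {
    baseline <- config$baseline_edge_mean + config$baseline_edge_sd * rnorm(ne) +
      if_else(cand$type == "intra_L", config$asymmetry_delta, 0)
    b_p <- rnorm(np, 0, config$subject_sd)
    u_p <- 1 + config$plasticity_sd * rnorm(np)
    # missing-at-random attrition: who is still enrolled at each timepoint
    ids <- sprintf("P%03d", seq_len(np))
    remaining <- seq_len(np)
    present <- matrix(TRUE, np, nt)
    for (j in seq_len(nt - 1)) {
      k <- config$dropout_per_period[j]
      if (k > 0) {
        lost <- sample(remaining, k)
        remaining <- setdiff(remaining, lost)
        present[lost, (j + 1):nt] <- FALSE
      }
    }
    obs <- which(present, arr.ind = TRUE)
    obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
    n_obs <- nrow(obs)
    p_idx <- rep(obs[, 1], each = ne)
    t_idx <- rep(obs[, 2], each = ne)
    e_idx <- rep.int(seq_len(ne), n_obs)
    lin <- baseline[e_idx] + b_p[p_idx] +
      u_p[p_idx] * shift[cbind(e_idx, t_idx)] +
      rnorm(n_obs * ne, 0, config$noise_sd)
    w <- if (config$weight_model == "lognormal") exp(lin) else pmax(0, lin)
    tibble(participant = ids[p_idx],
           timepoint = tp[t_idx],
           region_a = cand$region_a[e_idx],
           region_b = cand$region_b[e_idx],
           weight = w) |>
      arrange(.data$participant, .data$timepoint, .data$region_a, .data$region_b)
  })
}

#' Simulate behavioural scores for a cohort
#'
#' Generates proficiency scores at the last two timepoints (tests are taken
#' after each learning phase) for every participant observed at both. The
#' second score always exceeds the first: gains are drawn from a Gaussian
#' floored well above zero, matching the universal improvement the analysis
#' assumes. When `score_model$coupling` is nonzero, gains are linearly tied
#' to the participant's mean weight change on `score_model$coupling_edges`
#' between the two test timepoints, with `coupling` the target correlation.
#'
#' @param config A [sim_config()].
#' @param data The cohort simulated from `config` (or any long connectome
#'   tibble containing the last two timepoints).
#' @return A tibble `participant`, `timepoint`, `score`.
#' @export
simulate_scores <- function(config, data) {
  sm <- config$score_model
  tp <- config$timepoints
  t1 <- tp[length(tp) - 1]
  t2 <- tp[length(tp)]
  have <- data |>
    distinct(.data$participant, .data$timepoint) |>
    filter(.data$timepoint %in% c(t1, t2)) |>
    count(.data$participant) |>
    filter(.data$n == 2) |>
    pull(.data$participant) |>
    sort()
  if (length(have) == 0) abort("no participant observed at both test timepoints")
  np <- length(have)
  withr::with_seed(config$seed + 1L, {
    base <- sm$baseline_mean + sm$baseline_sd * rnorm(np)
    e <- rnorm(np)
    rho <- sm$coupling
    if (rho != 0 && !is.null(sm$coupling_edges)) {
      ce <- as_tibble(sm$coupling_edges) |>
        mutate(canonical_pair(.data$region_a, .data$region_b))
      delta <- data |>
        filter(.data$participant %in% have, .data$timepoint %in% c(t1, t2)) |>
        semi_join(ce, by = c("region_a", "region_b")) |>
        group_by(.data$participant, .data$timepoint) |>
        summarise(m = mean(.data$weight), .groups = "drop") |>
        tidyr::pivot_wider(names_from = "timepoint", values_from = "m") |>
        arrange(.data$participant)
      if (nrow(delta) != np) abort("coupling edges missing from the cohort")
      d <- delta[[as.character(t2)]] - delta[[as.character(t1)]]
      z <- as.numeric(scale(d))
      gain <- sm$gain_mean + sm$gain_sd * (rho * z + sqrt(1 - rho^2) * e)
    } else {
      gain <- sm$gain_mean + sm$gain_sd * e
    }
    gain <- pmax(gain, 0.02 * abs(sm$gain_mean) + 1e-8)
    tibble(participant = rep(have, 2),
           timepoint = rep(c(t1, t2), each = np),
           score = c(base, base + gain)) |>
      arrange(.data$participant, .data$timepoint)
  })
}

#' Null cohort (no planted effects)
#'
#' The identical generative model with `planted_effects` emptied; the
#' harness for type-I-error and family-wise-error calibration.
#'
#' @inheritParams simulate_connectomes
#' @return A long connectome tibble.
#' @export
null_cohort <- function(config, regions) {
  config$planted_effects <- list()
  simulate_connectomes(config, regions)
}

#' Pick a connected edge set from a pool
#'
#' Grows a connected subgraph of `n_edges` edges by seeded breadth-first
#' expansion within a pool of candidate edges; used to place planted effects
#' and coupling sets.
#'
#' @param pool Tibble with columns `region_a`, `region_b`.
#' @param n_edges Number of edges required.
#' @param seed Integer seed.
#' @return A tibble of `n_edges` rows forming one connected component.
#' @export
select_connected_edges <- function(pool, n_edges, seed = 1L) {
  pool <- as_tibble(pool) |>
    mutate(canonical_pair(.data$region_a, .data$region_b)) |>
    distinct(.data$region_a, .data$region_b) |>
    arrange(.data$region_a, .data$region_b)
  if (nrow(pool) < n_edges) abort("pool smaller than requested edge count")
  withr::with_seed(seed, {
    for (attempt in seq_len(50)) {
      start <- sample(nrow(pool), 1)
      chosen <- pool[start, ]
      verts <- unique(c(chosen$region_a, chosen$region_b))
      while (nrow(chosen) < n_edges) {
        frontier <- pool |>
          filter(.data$region_a %in% verts | .data$region_b %in% verts) |>
          anti_join(chosen, by = c("region_a", "region_b"))
        if (nrow(frontier) == 0) break
        nxt <- frontier[sample(nrow(frontier), 1), ]
        chosen <- bind_rows(chosen, nxt)
        verts <- unique(c(verts, nxt$region_a, nxt$region_b))
      }
      if (nrow(chosen) == n_edges) {
        return(arrange(chosen, .data$region_a, .data$region_b))
      }
    }
  })
  abort("could not grow a connected edge set of the requested size")
}
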