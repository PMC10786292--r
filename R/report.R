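#' Hemispheric and behavioural summary analyses
#'
#' Runs the cohort-level summary battery on a thresholded cohort:
#' per-timepoint left-vs-right paired t-tests (lateralization of the
#' intra-hemispheric network), random-intercept LME contrasts over time for
#' the left, right and interhemispheric strengths and the lateralization
#' index (every timepoint pair), and -- when scores are supplied -- the
#' behavioural improvement LME and, when a vocabulary table is supplied,
#' its Pearson correlation with the final proficiency score.
#'
#' @param data A long connectome tibble.
#' @param mask An edge mask from [group_threshold()].
#' @param regions The region table.
#' @param scores Optional tibble `participant`, `timepoint`, `score`.
#' @param vocabulary Optional tibble `participant`, `vocabulary`.
#' @return A list of class `"plasticity_summary"`: `hemispheric` (the
#'   per-matrix strength table), `lateralization` (per-timepoint paired t),
#'   `strength_contrasts` (measure x timepoint-pair LME contrasts),
#'   `behavioral` (improvement coefficients or `NULL`), and
#'   `vocabulary_correlation` (or `NULL`).
#' @export
run_summary <- function(data, mask, regions, scores = NULL,
                        vocabulary = NULL) {
  hemi <- hemispheric_summary(data, mask, regions)
  tps <- sort(unique(hemi$timepoint))
  lat <- purrr::map_dfr(tps, function(tt) {
    sub <- filter(hemi, .data$timepoint == tt)
    paired_t(sub$left_strength, sub$right_strength) |>
      mutate(timepoint = tt, .before = 1)
  })
  measures <- c(left = "left_strength", right = "right_strength",
                interhemispheric = "interhemispheric_strength",
                lateralization_index = "lateralization_index")
  pairs <- utils::combn(tps, 2, simplify = FALSE)
  strength <- purrr::map_dfr(names(measures), function(m) {
    purrr::map_dfr(pairs, function(pr) {
      contrast(hemi, measures[[m]], pr) |>
        mutate(measure = m, period = paste(pr, collapse = "-"), .before = 1)
    })
  })
  behavioral <- NULL
  vocab_cor <- NULL
  if (!is.null(scores)) {
    fit <- fit_lme(scores, "score", fixed = "time")
    behavioral <- tidy(fit)
    if (!is.null(vocabulary)) {
      last_tp <- max(scores$timepoint)
      joined <- scores |>
        filter(.data$timepoint == last_tp) |>
        inner_join(as_tibble(vocabulary), by = "participant")
      vocab_cor <- pearson(joined$vocabulary, joined$score)
    }
  }
  structure(list(hemispheric = hemi, lateralization = lat,
                 strength_contrasts = strength, behavioral = behavioral,
                 vocabulary_correlation = vocab_cor),
            class = "plasticity_summary")
}

#' @export
print.plasticity_summary <- function(x, ...) {
  cat("Lateralization (left vs right paired t):\n")
  print(x$lateralization)
  cat("\nStrength contrasts (random-intercept LME):\n")
  print(x$strength_contrasts, n = 20)
  if (!is.null(x$behavioral)) {
    cat("\nBehavioural improvement LME:\n")
    print(x$behavioral)
  }
  if (!is.null(x$vocabulary_correlation)) {
    cat("\nVocabulary correlation:\n")
    print(x$vocabulary_correlation)
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Assembles a validated configuration for [run_full_pipeline()]. With
#' `connectomes = NULL` the pipeline simulates a cohort from `simulation`
#' (a [sim_config()] or list of its arguments); otherwise it reads the
#' referenced files. One global `seed` fans out deterministically to the
#' stages: the simulation uses `seed`, the omnibus NBS `seed + 1000`, the
#' score NBS `seed + 2000`, and subgroup reruns `seed + 2000 + group`.
#'
#' @param region_table Path to a region table, or `NULL` for the packaged
#'   [language_parcellation()].
#' @param connectomes Path to a long-format connectome file, or `NULL` to
#'   simulate.
#' @param scores Path to a score CSV, `TRUE` to simulate scores alongside a
#'   simulated cohort, or `NULL`/`FALSE` to skip score analyses.
#' @param simulation A [sim_config()] or argument list for one.
#' @param fraction Edge retention fraction for [group_threshold()].
#' @param nbs An [nbs_config()] or argument list for one.
#' @param analyses Named logical toggles: `lateralization`,
#'   `interhemispheric`, `omnibus`, `posthoc`, `score_nbs`, `subgroup`.
#' @param posthoc_alpha Edge-level alpha for the post-hoc period contrasts.
#' @param output_dir Directory for the JSON report and TSV tables, or
#'   `NULL` to skip writing.
#' @param seed Global integer seed.
#' @param quiet Suppress progress messages.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(region_table = NULL, connectomes = NULL,
                            scores = TRUE, simulation = list(),
                            fraction = 0.30, nbs = list(),
                            analyses = list(), posthoc_alpha = 0.05,
                            output_dir = NULL, seed = 1L, quiet = FALSE) {
  toggles <- modifyList(list(lateralization = TRUE, interhemispheric = TRUE,
                             omnibus = TRUE, posthoc = TRUE,
                             score_nbs = TRUE, subgroup = FALSE),
                        analyses)
  if (!inherits(simulation, "sim_config")) {
    simulation$seed <- simulation$seed %||% seed
    simulation <- do.call(sim_config, simulation)
  }
  if (!inherits(nbs, "nbs_config")) {
    nbs$seed <- nbs$seed %||% (seed + 1000L)
    nbs <- do.call(nbs_config, nbs)
  }
  for (pth in c(region_table, if (is.character(connectomes)) connectomes,
                if (is.character(scores)) scores)) {
    if (!file.exists(pth)) abort(paste0("configured path does not exist: ", pth))
  }
  structure(list(region_table = region_table, connectomes = connectomes,
                 scores = scores, simulation = simulation,
                 fraction = fraction, nbs = nbs, analyses = toggles,
                 posthoc_alpha = posthoc_alpha, output_dir = output_dir,
                 seed = as.integer(seed), quiet = quiet),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Planted effects are given as a list of mappings with keys `edges` (list
#' of `[region_a, region_b]` pairs), `period`, `direction`, `magnitude`;
#' coupling edges likewise as pairs.
#'
#' @param path Path to a YAML file of [pipeline_config()] arguments.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pair_tbl <- function(x) {
    tibble(region_a = vapply(x, `[[`, "", 1), region_b = vapply(x, `[[`, "", 2))
  }
  if (!is.null(raw$simulation$planted_effects)) {
    raw$simulation$planted_effects <-
      lapply(raw$simulation$planted_effects, function(pe) {
        planted_effect(pair_tbl(pe$edges), period = pe$period,
                       direction = pe$direction, magnitude = pe$magnitude)
      })
  }
  if (!is.null(raw$simulation$score_model$coupling_edges)) {
    raw$simulation$score_model$coupling_edges <-
      pair_tbl(raw$simulation$score_model$coupling_edges)
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, quiet, expr) {
  if (!quiet) message("[connplast] stage: ", name)
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes read/simulate, group thresholding, the summary battery, the
#' omnibus time NBS, post-hoc period localization, the score NBS and the
#' optional vocabulary-style subgroup split, and assembles everything into
#' a report with a provenance block. Identical configurations (including
#' the seed) reproduce the report byte-for-byte.
#'
#' @param config A [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @return A list of class `"plasticity_report"`; written as JSON plus TSV
#'   tables when `output_dir` is configured.
#' @export
run_full_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  quiet <- isTRUE(config$quiet)
  regions <- stage("regions", quiet, {
    if (is.null(config$region_table)) language_parcellation()
    else read_region_table(config$region_table)
  })
  data <- stage("connectomes", quiet, {
    if (is.null(config$connectomes)) {
      simulate_connectomes(config$simulation, regions)
    } else {
      read_connectomes(config$connectomes, regions,
                       timepoints = config$simulation$timepoints)
    }
  })
  scores <- stage("scores", quiet, {
    if (is.character(config$scores)) {
      readr::read_csv(config$scores, show_col_types = FALSE, progress = FALSE)
    } else if (isTRUE(config$scores) && is.null(config$connectomes)) {
      simulate_scores(config$simulation, data)
    } else {
      NULL
    }
  })
  mask <- stage("threshold", quiet,
                group_threshold(data, regions, fraction = config$fraction))
  summary_res <- stage("summary", quiet,
                       run_summary(data, mask, regions, scores = scores))
  omnibus <- posthoc <- score_nbs <- subgroup <- NULL
  if (config$analyses$omnibus) {
    omnibus <- stage("omnibus NBS", quiet,
                     nbs_test(data, mask, config$nbs))
    if (config$analyses$posthoc) {
      posthoc <- stage("post-hoc contrasts", quiet,
                       posthoc_adjacent(data, omnibus,
                                        alpha = config$posthoc_alpha))
    }
  }
  if (config$analyses$score_nbs && !is.null(scores)) {
    cfg2 <- config$nbs
    cfg2$seed <- config$seed + 2000L
    score_nbs <- stage("score NBS", quiet,
                       nbs_score(data, scores, mask, cfg2))
    if (config$analyses$subgroup) {
      subgroup <- stage("subgroup analysis", quiet, {
        last_tp <- max(scores$timepoint)
        vals <- filter(scores, .data$timepoint == last_tp)
        split_res <- subgroup_split(vals, value = "score")
        groups <- list(above = split_res$above, below = split_res$below)
        res <- imap(groups, function(ids, nm) {
          cfgg <- config$nbs
          cfgg$seed <- config$seed + 2000L + match(nm, names(groups))
          sub_data <- filter(data, .data$participant %in% ids)
          sub_scores <- filter(scores, .data$participant %in% ids)
          list(n = length(ids), result = tidy(
            nbs_score(sub_data, sub_scores, mask, cfgg)))
        })
        c(list(threshold = split_res$threshold), res)
      })
    }
  }
  report <- structure(list(
    summary = list(
      lateralization = if (config$analyses$lateralization)
        summary_res$lateralization,
      strength_contrasts = if (config$analyses$interhemispheric)
        summary_res$strength_contrasts,
      behavioral = summary_res$behavioral,
      vocabulary_correlation = summary_res$vocabulary_correlation
    ),
    omnibus = if (!is.null(omnibus)) tidy(omnibus),
    omnibus_components = if (!is.null(omnibus))
      component_edge_rows(omnibus$components),
    posthoc = if (!is.null(posthoc)) component_edge_rows(posthoc),
    score_nbs = if (!is.null(score_nbs)) tidy(score_nbs),
    score_nbs_components = if (!is.null(score_nbs))
      component_edge_rows(score_nbs$components),
    subgroup = subgroup,
    skipped = names(Filter(isFALSE, config$analyses)),
    provenance = list(
      package_version = as.character(utils::packageVersion("connplast")),
      seed = config$seed,
      fraction = config$fraction,
      nbs = unclass(config$nbs),
      # hash the scientific configuration only (not output paths/verbosity)
      config_hash = rlang::hash(unclass_deep(
        config[setdiff(names(config), c("output_dir", "quiet"))]))
    )
  ), class = "plasticity_report")
  attr(report, "objects") <- list(mask = mask, omnibus = omnibus,
                                  posthoc = posthoc, score_nbs = score_nbs,
                                  summary = summary_res, data = data,
                                  scores = scores)
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir, quiet = quiet)
  }
  report
}

# flatten component list-columns into one edge-per-row table for export
component_edge_rows <- function(components) {
  if (is.null(components) || nrow(components) == 0) {
    return(tibble(component = integer(), direction = character(),
                  p_fwe = numeric(), region_a = character(),
                  region_b = character(), t = numeric(), p = numeric()))
  }
  components |>
    mutate(.edges = .data$edges) |>
    select(dplyr::any_of(c("component", "direction", "period", "p_fwe",
                           "significant")), ".edges") |>
    tidyr::unnest(".edges")
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
  }
  if (!is.null(attr(x, "class"))) x <- unclass(x)
  x
}

#' Write a pipeline report
#'
#' Serializes the report to `report.json` (deterministic, full precision)
#' and the flat tables to TSV files in `dir`.
#'
#' @param report A `"plasticity_report"`.
#' @param dir Output directory (created if needed).
#' @param quiet Suppress messages.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, quiet = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json <- jsonlite::toJSON(unclass_deep(unclass(report)),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  writeLines(json, file.path(dir, "report.json"))
  objs <- attr(report, "objects")
  if (!is.null(objs$mask)) write_edge_mask(objs$mask, file.path(dir, "edge_mask.tsv"))
  for (nm in c("omnibus_components", "posthoc", "score_nbs_components")) {
    if (!is.null(report[[nm]])) {
      readr::write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  if (!quiet) message("[connplast] report written to ", dir)
  invisible(dir)
}

#' Check the structural validity of a report
#'
#' Verifies that a report carries the sections and fields the JSON schema
#' (`inst/schema/report-schema.json`) promises and that every number is
#' finite where required.
#'
#' @param report A `"plasticity_report"` (or a list parsed back from
#'   `report.json`).
#' @return `TRUE`, invisibly; aborts with the first violation otherwise.
#' @export
validate_report <- function(report) {
  need <- c("summary", "provenance")
  missing <- setdiff(need, names(report))
  if (length(missing) > 0) {
    abort(paste0("report is missing section(s): ", paste(missing, collapse = ", ")))
  }
  prov <- report$provenance
  for (f in c("package_version", "seed", "fraction", "config_hash")) {
    if (is.null(prov[[f]])) abort(paste0("provenance is missing `", f, "`"))
  }
  if (!is.null(report$omnibus)) {
    om <- as_tibble(report$omnibus)
    if (nrow(om) > 0 &&
        (any(om$p_fwe <= 0) || any(om$p_fwe > 1))) {
      abort("omnibus p_fwe outside (0, 1]")
    }
  }
  invisible(TRUE)
}
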