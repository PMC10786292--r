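#' Validate and canonicalise a longitudinal connectome table
#'
#' The package's working representation of a longitudinal connectome cohort
#' is a long tibble with columns `participant`, `timepoint`, `region_a`,
#' `region_b`, `weight`: one row per observed region pair in one
#' participant-timepoint matrix. This function canonicalises region-pair
#' orientation (lexicographic), symmetrises directed duplicates by averaging
#' the two directed weights, and enforces the cohort invariants: nonnegative
#' finite weights, known regions, timepoints within the measurement schedule,
#' no self-loops, and a baseline matrix for every participant. Region pairs
#' absent from a matrix are interpreted as zero-weight wherever the matrix is
#' summarised.
#'
#' @param data A data frame with columns `participant`, `timepoint`,
#'   `region_a`, `region_b`, `weight`.
#' @param regions A region table ([validate_region_table()]).
#' @param timepoints Allowed measurement timepoints in months; the smallest
#'   is the baseline every participant must have.
#' @return A validated long tibble sorted by participant, timepoint, pair.
#' @export
as_connectomes <- function(data, regions, timepoints = c(0, 3, 6)) {
  regions <- validate_region_table(regions)
  data <- as_tibble(data)
  required <- c("participant", "timepoint", "region_a", "region_b", "weight")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("connectome table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- data |>
    mutate(participant = as.character(.data$participant),
           timepoint = as.numeric(.data$timepoint),
           region_a = as.character(.data$region_a),
           region_b = as.character(.data$region_b),
           weight = as.numeric(.data$weight))
  unknown <- setdiff(c(data$region_a, data$region_b), regions$region_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown region(s) in connectome table: ",
                 paste(unique(unknown), collapse = ", ")))
  }
  if (any(!is.finite(data$weight))) abort("non-finite connectivity weight")
  if (any(data$weight < 0)) {
    bad <- data |> filter(.data$weight < 0) |> head(3)
    abort(paste0("negative connectivity weight, e.g. ",
                 bad$region_a[1], "-", bad$region_b[1], " = ", bad$weight[1]))
  }
  if (any(data$region_a == data$region_b)) abort("self-loop (region_a == region_b)")
  bad_tp <- setdiff(unique(data$timepoint), timepoints)
  if (length(bad_tp) > 0) {
    abort(paste0("timepoint(s) outside the measurement schedule {",
                 paste(timepoints, collapse = ", "), "}: ",
                 paste(bad_tp, collapse = ", ")))
  }
  # undirected: average the two directed entries when both are present
  data <- data |>
    mutate(canonical_pair(.data$region_a, .data$region_b)) |>
    group_by(.data$participant, .data$timepoint, .data$region_a, .data$region_b) |>
    summarise(weight = mean(.data$weight), .groups = "drop")
  baseline <- min(timepoints)
  with_base <- data |> filter(.data$timepoint == baseline) |> pull(.data$participant)
  orphans <- setdiff(unique(data$participant), with_base)
  if (length(orphans) > 0) {
    abort(paste0("participant(s) without a baseline (", baseline, " mo) matrix: ",
                 paste(orphans, collapse = ", ")))
  }
  arrange(data, .data$participant, .data$timepoint, .data$region_a, .data$region_b)
}

#' Read a longitudinal connectome table
#'
#' Reads a long-format connectivity file (`participant, timepoint, region_a,
#' region_b, weight`; TSV or CSV by extension) and validates it against a
#' region table via [as_connectomes()].
#'
#' @inheritParams as_connectomes
#' @param path Path to the file.
#' @return A validated long connectome tibble.
#' @export
read_connectomes <- function(path, regions, timepoints = c(0, 3, 6)) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as_connectomes(df, regions, timepoints = timepoints)
}

#' Write a longitudinal connectome table
#'
#' @param data A long connectome tibble.
#' @param path Output path (TSV or CSV by extension).
#' @return `path`, invisibly.
#' @export
write_connectomes <- function(data, path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Read one square connectivity matrix
#'
#' Reads a square-matrix CSV (first row and first column hold region ids)
#' for a single participant and timepoint and returns it in long form. Both
#' triangles are read; directed asymmetry is resolved by averaging.
#'
#' @param path Path to the CSV file.
#' @param participant,timepoint Identifiers to attach to every row.
#' @return A long tibble (`participant`, `timepoint`, `region_a`, `region_b`,
#'   `weight`) containing the upper triangle.
#' @export
read_connectome_matrix <- function(path, participant, timepoint) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- as.character(df[[1]])
  if (nrow(m) != ncol(m)) abort("connectivity matrix is not square")
  m <- (m + t(m)) / 2
  ut <- which(upper.tri(m), arr.ind = TRUE)
  tibble(participant = as.character(participant),
         timepoint = as.numeric(timepoint),
         region_a = rownames(m)[ut[, 1]],
         region_b = colnames(m)[ut[, 2]],
         weight = m[ut]) |>
    mutate(canonical_pair(.data$region_a, .data$region_b))
}

# distinct observed (participant, timepoint) matrices in a cohort
observed_matrices <- function(data) {
  distinct(data, .data$participant, .data$timepoint) |>
    arrange(.data$participant, .data$timepoint)
}
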