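#' Read a region table
#'
#' A region table defines the parcellation underlying a connectome: one row
#' per region with a unique `region_id`, a `hemisphere` (`"L"` or `"R"`) and a
#' `system` label. Corpus-callosum (CC) waypoint regions are those with system
#' `"aCC"` or `"pCC"`; all other systems are treated as cortical.
#'
#' The table must be hemispherically balanced: the number of cortical regions
#' and the number of CC regions must match between the left and right
#' hemisphere, so that hemispheric strengths and the lateralization index are
#' comparable.
#'
#' @param path Path to a tab- or comma-separated file with columns
#'   `region_id`, `hemisphere`, `system`.
#' @return A tibble with columns `region_id`, `hemisphere`, `system`, `is_cc`.
#' @seealso [language_parcellation()], [make_region_table()]
#' @export
read_region_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  validate_region_table(df)
}

cc_systems <- c("aCC", "pCC")

#' Validate a region table
#'
#' @param regions A data frame with columns `region_id`, `hemisphere`,
#'   `system`.
#' @return A validated tibble with an `is_cc` column added.
#' @export
validate_region_table <- function(regions) {
  regions <- as_tibble(regions)
  required <- c("region_id", "hemisphere", "system")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    abort(paste0("region table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  regions <- regions |>
    mutate(region_id = as.character(.data$region_id),
           hemisphere = as.character(.data$hemisphere),
           system = as.character(.data$system))
  dup <- regions$region_id[duplicated(regions$region_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate region_id(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_hemi <- regions$region_id[!regions$hemisphere %in% c("L", "R")]
  if (length(bad_hemi) > 0) {
    abort(paste0("unknown hemisphere for region(s): ",
                 paste(bad_hemi, collapse = ", "), " (expected L or R)"))
  }
  if (any(is.na(regions$system) | regions$system == "")) {
    abort("every region needs a non-empty system label")
  }
  regions <- regions |> mutate(is_cc = .data$system %in% cc_systems)
  counts <- regions |>
    count(.data$hemisphere, .data$is_cc) |>
    tidyr::pivot_wider(names_from = "hemisphere", values_from = "n",
                       values_fill = 0L)
  if (!all(c("L", "R") %in% names(counts)) || any(counts$L != counts$R)) {
    abort("unbalanced hemispheres: cortical and CC region counts must match between L and R")
  }
  regions
}

#' The bilateral language parcellation
#'
#' Builds the 76-region bilateral language network parcellation used
#' throughout the package: per hemisphere, 33 cortical regions spanning the
#' inferior frontal gyrus (IFG), temporal lobe (TL) and inferior parietal lobe
#' (IPL), plus 5 corpus-callosum waypoint regions (2 anterior, 3 posterior).
#' Region identifiers follow an HCP-style `"<hemi>_<label>"` convention.
#'
#' @return A region table tibble with 76 rows.
#' @examples
#' language_parcellation() |> dplyr::count(hemisphere, system)
#' @export
language_parcellation <- function() {
  ifg <- c("44", "45", "47l", "IFJa", "IFJp", "IFSa", "IFSp", "FOP4", "6r")
  tl  <- c("STGa", "STSda", "STSdp", "STSva", "STSvp", "TA2", "A4", "A5",
           "TPOJ1", "TE1a", "TE1m", "TE1p", "TE2a", "TE2p")
  ipl <- c("PF", "PFm", "PFop", "PFt", "PGi", "PGp", "PGs", "PSL", "STV", "TPOJ2")
  cc  <- c("aCC1", "aCC2", "pCC1", "pCC2", "pCC3")
  one_hemi <- function(h) {
    tibble(
      region_id = paste(h, c(ifg, tl, ipl, cc), sep = "_"),
      hemisphere = h,
      system = c(rep("IFG", length(ifg)), rep("TL", length(tl)),
                 rep("IPL", length(ipl)), rep("aCC", 2), rep("pCC", 3))
    )
  }
  validate_region_table(bind_rows(one_hemi("L"), one_hemi("R")))
}

#' Build a generic balanced region table
#'
#' Convenience constructor for simulation studies at arbitrary scale: a
#' balanced bilateral table with `n_cortical` cortical and `n_cc`
#' corpus-callosum regions per hemisphere. Cortical regions are labelled with
#' a single generic `CTX` system.
#'
#' @param n_cortical Cortical regions per hemisphere.
#' @param n_cc CC regions per hemisphere (split between `aCC` and `pCC`).
#' @return A region table tibble with `2 * (n_cortical + n_cc)` rows.
#' @export
make_region_table <- function(n_cortical, n_cc = 0) {
  stopifnot(n_cortical >= 1, n_cc >= 0)
  one_hemi <- function(h) {
    ctx <- tibble(
      region_id = sprintf("%s_C%02d", h, seq_len(n_cortical)),
      hemisphere = h, system = "CTX"
    )
    if (n_cc > 0) {
      n_a <- ceiling(n_cc / 2)
      ccr <- tibble(
        region_id = sprintf("%s_CC%02d", h, seq_len(n_cc)),
        hemisphere = h,
        system = c(rep("aCC", n_a), rep("pCC", n_cc - n_a))
      )
      ctx <- bind_rows(ctx, ccr)
    }
    ctx
  }
  validate_region_table(bind_rows(one_hemi("L"), one_hemi("R")))
}

# canonical (lexicographically sorted) pair orientation for undirected edges
canonical_pair <- function(a, b) {
  tibble(region_a = pmin(a, b), region_b = pmax(a, b))
}

#' Classify an edge by its endpoints
#'
#' @param region_a,region_b Character vectors of region ids.
#' @param regions A validated region table.
#' @return Character vector: `"intra_L"`, `"intra_R"` (intra-hemispheric
#'   cortical-cortical), `"cortico_cc"` (cortical to corpus callosum) or
#'   `"excluded"` (CC-CC and direct cross-hemispheric cortical pairs).
#' @export
edge_type <- function(region_a, region_b, regions) {
  idx <- setNames(seq_len(nrow(regions)), regions$region_id)
  unknown <- setdiff(c(region_a, region_b), regions$region_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown region(s): ", paste(unique(unknown), collapse = ", ")))
  }
  ia <- idx[region_a]; ib <- idx[region_b]
  cc_a <- regions$is_cc[ia]; cc_b <- regions$is_cc[ib]
  h_a <- regions$hemisphere[ia]; h_b <- regions$hemisphere[ib]
  out <- rep("excluded", length(region_a))
  intra <- !cc_a & !cc_b & h_a == h_b
  out[intra & h_a == "L"] <- "intra_L"
  out[intra & h_a == "R"] <- "intra_R"
  out[xor(cc_a, cc_b)] <- "cortico_cc"
  out
}

#' Candidate edge set of a parcellation
#'
#' The candidate edges over which thresholding and all statistics operate:
#' intra-hemispheric cortical-cortical pairs in each hemisphere, plus
#' cortical-to-CC pairs (a cortical region may pair with any CC region, on
#' either side of the midline). Direct cross-hemispheric cortical-cortical
#' pairs are excluded -- tractography cannot estimate them robustly, which is
#' why the CC waypoints stand in for interhemispheric connectivity -- and
#' CC-CC pairs are excluded as anatomically meaningless.
#'
#' @param regions A validated region table.
#' @return A tibble with columns `region_a`, `region_b` (canonical
#'   lexicographic orientation) and `type`, sorted by (`region_a`,
#'   `region_b`).
#' @examples
#' nrow(candidate_edges(language_parcellation())) # 1716
#' @export
candidate_edges <- function(regions) {
  regions <- validate_region_table(regions)
  ids <- regions$region_id
  pairs <- t(utils::combn(ids, 2L))
  cp <- canonical_pair(pairs[, 1], pairs[, 2])
  cp$type <- edge_type(cp$region_a, cp$region_b, regions)
  cp |>
    filter(.data$type != "excluded") |>
    arrange(.data$region_a, .data$region_b)
}
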