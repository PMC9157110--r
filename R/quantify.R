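# The numbered lipid quantification procedure: isotopic correction,
# transition summation, subclass totals with reference normalization,
# mol% profiles, saturation classes, and sphingolipid modification
# occurrence.

#' Five temperature regimes of the growth design
#'
#' RT3 (3 h at 22 degrees C), RT6 (6 h at 22), HS3+3 (3 h RT then 3 h at
#' 37), HS3+6 (3 h RT then 6 h at 37), HSR (3 h RT, 3 h HS, 3 h relief
#' at RT).
#'
#' @return Character vector of condition labels in temporal order.
#' @export
default_conditions <- function() c("RT3", "RT6", "HS3+3", "HS3+6", "HSR")

assert_peak_table <- function(peaks) {
  needed <- c("sample_id", "subclass", "species", "transition_id", "area")
  missing <- setdiff(needed, names(peaks))
  if (length(missing) > 0) {
    stop("peak table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(peaks$area) || anyNA(peaks$area) || any(peaks$area < 0)) {
    stop("peak areas must be nonnegative numbers", call. = FALSE)
  }
  key <- paste(peaks$sample_id, peaks$species, peaks$transition_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- peaks[duplicated(key), c("sample_id", "species", "transition_id")]
    stop("duplicate (sample, species, transition) keys, e.g. ",
         paste(unlist(dup[1, ]), collapse = " / "), call. = FALSE)
  }
  invisible(peaks)
}

assert_sample_sheet <- function(sheet) {
  needed <- c("sample_id", "condition", "replicate")
  missing <- setdiff(needed, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample sheet has duplicate sample_id values", call. = FALSE)
  }
  invisible(sheet)
}

#' Apply the 13C isotopic correction to raw MRM peak areas
#'
#' Step 1 of the quantification procedure: each raw transition area is
#' multiplied by the species' isotopic correction factor ([icf()]),
#' computed from its elemental formula. The factor depends only on the
#' species, never on the sample. Species that fail to parse or are absent
#' from the registry are removed from the output and reported via the
#' `"rejects"` attribute (and a warning), never silently dropped.
#'
#' @param peaks Long-format peak table: columns `sample_id`, `subclass`,
#'   `species`, `transition_id`, `area` (raw, nonnegative).
#' @inheritParams parse_species
#' @param p13c Natural 13C abundance; default 0.0107.
#' @return The peak table with added `icf` and `corrected_area` columns;
#'   attribute `rejects` holds a tibble of unquantifiable rows with the
#'   parse error message.
#' @export
correct_areas <- function(peaks, registry = default_registry(),
                          steryl_pool = default_steryl_pool(),
                          p13c = 0.0107) {
  assert_peak_table(peaks)
  uniq <- unique(peaks$species)
  info_list <- lapply(uniq, function(nm) {
    tryCatch(annotate_one_species(nm, registry, steryl_pool, p13c),
             error = function(e) conditionMessage(e))
  })
  ok <- vapply(info_list, is.data.frame, logical(1))
  info <- dplyr::bind_rows(info_list[ok])
  rejects <- tibble::tibble(species = uniq[!ok],
                            reason = unlist(info_list[!ok], use.names = FALSE))
  if (nrow(rejects) > 0) {
    warning(nrow(rejects), " species could not be quantified; see ",
            "attr(, 'rejects')", call. = FALSE)
  }
  out <- peaks |>
    dplyr::inner_join(info[, c("input_name", "icf")],
                      by = c(species = "input_name")) |>
    dplyr::mutate(corrected_area = .data$area * .data$icf)
  attr(out, "rejects") <- rejects
  out
}

#' Sum icf-corrected areas over mass transitions
#'
#' Step 2: all transitions monitored for the same species in the same
#' sample are added, yielding one area per (sample, species). Species with
#' a single transition pass through unchanged.
#'
#' @param corrected Output of [correct_areas()] (needs `corrected_area`).
#' @return A tibble with columns `sample_id`, `subclass`, `species`, `area`
#'   (corrected, transition-summed).
#' @export
sum_transitions <- function(corrected) {
  if (!"corrected_area" %in% names(corrected)) {
    stop("run correct_areas() first (no corrected_area column)",
         call. = FALSE)
  }
  corrected |>
    dplyr::group_by(.data$sample_id, .data$subclass, .data$species) |>
    dplyr::summarise(area = sum(.data$corrected_area), .groups = "drop")
}

#' Subclass totals and reference-normalized abundances
#'
#' Step 3: the total area of a subclass in a sample is the sum over all its
#' detected species; relative abundance is the total divided by the mean
#' total of the reference-condition replicates, so the reference condition
#' mean equals 1 by construction.
#'
#' @param species_areas Transition-summed table from [sum_transitions()].
#' @param sheet Sample sheet with `sample_id`, `condition`, `replicate`.
#' @param reference_condition Condition the abundances are normalized to;
#'   default `"RT3"` (3 h growth at room temperature).
#' @return A tibble with columns `sample_id`, `condition`, `subclass`,
#'   `total_area`, `rel_abundance`. Subclasses whose reference mean is zero
#'   get `NA` relative abundance and a warning.
#' @export
subclass_abundance <- function(species_areas, sheet,
                               reference_condition = "RT3") {
  assert_sample_sheet(sheet)
  if (!reference_condition %in% sheet$condition) {
    stop("reference condition '", reference_condition,
         "' absent from sample sheet", call. = FALSE)
  }
  totals <- species_areas |>
    dplyr::group_by(.data$sample_id, .data$subclass) |>
    dplyr::summarise(total_area = sum(.data$area), .groups = "drop") |>
    dplyr::inner_join(sheet[, c("sample_id", "condition")], by = "sample_id")
  ref <- totals |>
    dplyr::filter(.data$condition == reference_condition) |>
    dplyr::group_by(.data$subclass) |>
    dplyr::summarise(ref_mean = mean(.data$total_area), .groups = "drop")
  out <- totals |>
    dplyr::left_join(ref, by = "subclass") |>
    dplyr::mutate(rel_abundance = ifelse(
      is.na(.data$ref_mean) | .data$ref_mean == 0,
      NA_real_, .data$total_area / .data$ref_mean)) |>
    dplyr::select("sample_id", "condition", "subclass", "total_area",
                  "rel_abundance")
  bad <- unique(out$subclass[is.na(out$rel_abundance)])
  if (length(bad) > 0) {
    warning("undefined reference normalization (zero or missing reference ",
            "total) for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Relative lipid subclass profiles (mol%)
#'
#' The relative proportion of each species' corrected area on the total
#' area of its subclass, per sample, in percent. When a sample sheet is
#' supplied, a `major` flag marks species whose condition-mean mol%
#' strictly exceeds `major_threshold` (default 1%) in at least one
#' condition — the rule used to display only major species.
#'
#' @inheritParams subclass_abundance
#' @param sheet Optional sample sheet; needed for the major-species flag.
#' @param major_threshold Mol% a condition mean must strictly exceed;
#'   default 1.
#' @return A tibble `sample_id`, `subclass`, `species`, `mol_pct` (plus
#'   `major` if `sheet` was given). Samples with zero subclass total get
#'   `NA` mol% and a warning.
#' @export
species_profile <- function(species_areas, sheet = NULL,
                            major_threshold = 1) {
  prof <- species_areas |>
    dplyr::group_by(.data$sample_id, .data$subclass) |>
    dplyr::mutate(total = sum(.data$area)) |>
    dplyr::ungroup() |>
    dplyr::mutate(mol_pct = ifelse(.data$total == 0, NA_real_,
                                   100 * .data$area / .data$total)) |>
    dplyr::select("sample_id", "subclass", "species", "mol_pct")
  if (anyNA(prof$mol_pct)) {
    warning("mol% undefined for samples with zero subclass total",
            call. = FALSE)
  }
  if (!is.null(sheet)) {
    assert_sample_sheet(sheet)
    major <- prof |>
      dplyr::inner_join(sheet[, c("sample_id", "condition")],
                        by = "sample_id") |>
      dplyr::group_by(.data$subclass, .data$species, .data$condition) |>
      dplyr::summarise(m = mean(.data$mol_pct, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::group_by(.data$subclass, .data$species) |>
      dplyr::summarise(major = any(.data$m > major_threshold, na.rm = TRUE),
                       .groups = "drop")
    prof <- dplyr::left_join(prof, major, by = c("subclass", "species"))
  }
  prof
}

#' Acyl-chain saturation profile per subclass
#'
#' Species are classified by the total number of double bonds across their
#' fatty acid residues — zero (saturated), one (monounsaturated), more than
#' one (polyunsaturated) — their corrected areas are summed per class, and
#' the class sums are expressed as relative molar proportions of the
#' subclass total.
#'
#' @inheritParams subclass_abundance
#' @inheritParams parse_species
#' @return A tibble `sample_id`, `subclass`, `saturated`,
#'   `monounsaturated`, `polyunsaturated`; the three fractions sum to 1.
#' @export
saturation_profile <- function(species_areas, registry = default_registry(),
                               steryl_pool = default_steryl_pool()) {
  info <- species_info(unique(species_areas$species), registry, steryl_pool)
  species_areas |>
    dplyr::inner_join(info[, c("input_name", "sat_class")],
                      by = c(species = "input_name")) |>
    dplyr::group_by(.data$sample_id, .data$subclass) |>
    dplyr::summarise(
      saturated = sum(.data$area[.data$sat_class == "saturated"]) /
        sum(.data$area),
      monounsaturated = sum(.data$area[.data$sat_class == "monounsaturated"]) /
        sum(.data$area),
      polyunsaturated = sum(.data$area[.data$sat_class == "polyunsaturated"]) /
        sum(.data$area),
      .groups = "drop")
}

#' Sphingolipid modification occurrence
#'
#' For each sphingolipid subclass and sample, the percentage-wise occurrence
#' of the structural modifications: C4 hydroxylation of the sphingoid base,
#' double bonds at the base d4 and d8 positions, C2 hydroxylation of the
#' amide-linked acyl chain, and a very-long-chain fatty acid (acyl carbons
#' >= 20). By default the occurrence is abundance-weighted: the share of the
#' subclass' corrected area carried by species bearing the modification.
#' Species whose annotation leaves a modification unresolved are excluded
#' from that modification's numerator and reported separately in
#' `pct_unresolved`.
#'
#' @inheritParams saturation_profile
#' @param weight `"abundance"` (area-weighted, default) or `"count"`
#'   (each detected species counts once).
#' @return A long tibble `sample_id`, `subclass`, `modification`, `pct`,
#'   `pct_unresolved`.
#' @export
modification_occurrence <- function(species_areas,
                                    registry = default_registry(),
                                    steryl_pool = default_steryl_pool(),
                                    weight = c("abundance", "count")) {
  weight <- match.arg(weight)
  info <- species_info(unique(species_areas$species), registry, steryl_pool)
  feats <- c("c4_hydroxyl", "d4_double_bond", "d8_double_bond",
             "c2_acyl_hydroxyl", "vlcfa")
  df <- species_areas |>
    dplyr::inner_join(
      info[, c("input_name", "category", feats)],
      by = c(species = "input_name")) |>
    dplyr::filter(.data$category == "sphingolipid")
  if (nrow(df) == 0) {
    return(tibble::tibble(sample_id = character(), subclass = character(),
                          modification = character(), pct = numeric(),
                          pct_unresolved = numeric()))
  }
  if (weight == "count") df$area <- as.numeric(df$area > 0)
  long <- tidyr::pivot_longer(df, dplyr::all_of(feats),
                              names_to = "modification",
                              values_to = "status")
  long |>
    dplyr::group_by(.data$sample_id, .data$subclass, .data$modification) |>
    dplyr::summarise(
      pct = 100 * sum(.data$area[.data$status == "yes"]) / sum(.data$area),
      pct_unresolved = 100 * sum(.data$area[.data$status == "unresolved"]) /
        sum(.data$area),
      .groups = "drop")
}
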