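# Internal-standard absolute quantification: TG via GC-FID FAMEs with a
# triheptadecanoate standard, central metabolites via GC-MS with an
# allo-inositol standard.

#' Absolute TG quantification from GC-FID FAME peak areas
#'
#' Each fatty acid's mass is obtained from its peak area relative to the
#' internal standard (17:0 from spiked triheptadecanoate), assuming a
#' mass-proportional and FA-independent FID response. The TG amount per mg
#' dry pollen is the sum of the analyte FA masses (FAME-equivalent, no
#' glycerol-backbone reconstruction) scaled by the dry pollen mass; the
#' per-FA contribution is each FA's share of that sum.
#'
#' @param fames Long table with columns `sample_id`, `fatty_acid`
#'   (`"16:0"` style), `area` (nonnegative).
#' @param is_fa Internal standard fatty acid, excluded from the analytes;
#'   default `"17:0"`.
#' @param is_mass_mg Spiked internal standard mass in mg; default 0.05.
#' @param pollen_dry_mass_mg Dry pollen mass grown per sample in mg;
#'   default 20.
#' @return A list with `totals` (tibble `sample_id`, `tg_ug_per_mg`) and
#'   `contributions` (tibble `sample_id`, `fatty_acid`, `mass_mg`,
#'   `contribution` summing to 1 per sample).
#' @examples
#' fames <- tibble::tibble(sample_id = "s1",
#'                         fatty_acid = c("17:0", "18:1"),
#'                         area = c(1000, 1000))
#' tg_absolute(fames)$totals$tg_ug_per_mg  # 2.5
#' @export
tg_absolute <- function(fames, is_fa = "17:0", is_mass_mg = 0.05,
                        pollen_dry_mass_mg = 20) {
  needed <- c("sample_id", "fatty_acid", "area")
  missing <- setdiff(needed, names(fames))
  if (length(missing) > 0) {
    stop("FAME table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(fames$area < 0, na.rm = TRUE)) {
    bad <- sum(fames$area < 0, na.rm = TRUE)
    warning(bad, " rows with negative areas rejected", call. = FALSE)
    fames <- fames[is.na(fames$area) | fames$area >= 0, ]
  }
  is_rows <- fames |>
    dplyr::filter(.data$fatty_acid == is_fa) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(is_area = sum(.data$area), .groups = "drop")
  if (any(is_rows$is_area == 0) ||
      !all(unique(fames$sample_id) %in% is_rows$sample_id)) {
    stop("internal standard '", is_fa,
         "' missing or zero in at least one sample", call. = FALSE)
  }
  contrib <- fames |>
    dplyr::filter(.data$fatty_acid != is_fa) |>
    dplyr::inner_join(is_rows, by = "sample_id") |>
    dplyr::mutate(mass_mg = .data$area / .data$is_area * is_mass_mg) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(contribution = if (sum(.data$mass_mg) == 0) NA_real_
                  else .data$mass_mg / sum(.data$mass_mg)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "fatty_acid", "mass_mg", "contribution")
  totals <- contrib |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      tg_ug_per_mg = sum(.data$mass_mg) / pollen_dry_mass_mg * 1000,
      .groups = "drop")
  list(totals = totals, contributions = contrib)
}

#' Internal-standard-normalized metabolite responses, folded to a reference
#'
#' Each analyte's quantifier-ion area is divided by the sample's internal
#' standard (spiked allo-inositol) area and optionally by a per-row dilution
#' factor (`dilution` column, default 1; used for analytes measured on
#' diluted runs). The normalized response is then expressed as a fold of
#' the mean response over the reference-condition samples, so the reference
#' mean fold is 1.
#'
#' @param met Long table with columns `sample_id`, `analyte`, `area`
#'   (quantifier-ion area) and optionally `dilution`.
#' @param sheet Sample sheet with `sample_id`, `condition`.
#' @param is_analyte Internal standard analyte name; default
#'   `"allo-inositol"`. Samples without it are excluded with a warning.
#' @param reference_condition Condition folds are anchored to; default
#'   `"RT3"`.
#' @return A tibble `sample_id`, `condition`, `analyte`, `response`,
#'   `fold`.
#' @export
metabolite_relative <- function(met, sheet, is_analyte = "allo-inositol",
                                reference_condition = "RT3") {
  needed <- c("sample_id", "analyte", "area")
  missing <- setdiff(needed, names(met))
  if (length(missing) > 0) {
    stop("metabolite table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  assert_sample_sheet(sheet)
  if (!"dilution" %in% names(met)) met$dilution <- 1
  is_rows <- met |>
    dplyr::filter(.data$analyte == is_analyte) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(is_area = sum(.data$area), .groups = "drop") |>
    dplyr::filter(.data$is_area > 0)
  dropped <- setdiff(unique(met$sample_id), is_rows$sample_id)
  if (length(dropped) > 0) {
    warning("samples without internal standard excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  resp <- met |>
    dplyr::filter(.data$analyte != is_analyte) |>
    dplyr::inner_join(is_rows, by = "sample_id") |>
    dplyr::mutate(response = .data$area / .data$is_area / .data$dilution) |>
    dplyr::inner_join(sheet[, c("sample_id", "condition")], by = "sample_id")
  ref <- resp |>
    dplyr::filter(.data$condition == reference_condition) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(ref_mean = mean(.data$response), .groups = "drop")
  resp |>
    dplyr::left_join(ref, by = "analyte") |>
    dplyr::mutate(fold = ifelse(is.na(.data$ref_mean) | .data$ref_mean == 0,
                                NA_real_,
                                .data$response / .data$ref_mean)) |>
    dplyr::select("sample_id", "condition", "analyte", "response", "fold")
}
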