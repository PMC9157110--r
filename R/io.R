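# Readers, writers and the pipeline orchestrator. All tables are tidy TSV
# with '#'-prefixed provenance header lines; the decimal separator is the
# point and missing values are written as NA, independent of locale.

prov_header <- function(meta) {
  c(paste0("# ", names(meta), ": ", unlist(meta)))
}

#' Write a tidy table with a provenance header
#'
#' @param x Data frame.
#' @param path Output TSV path.
#' @param meta Named list written as `# key: value` header lines (config
#'   hash, seed, package version, timestamp, ...).
#' @return `path`, invisibly.
#' @export
write_table_prov <- function(x, path, meta = list()) {
  meta <- c(list(package = paste0("pollenomics ",
                                  as.character(utils::packageVersion("pollenomics")))),
            meta)
  writeLines(prov_header(meta), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_table_prov <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, na = "NA")
}

#' Read and validate a long-format peak table
#'
#' Expects columns `sample_id`, `subclass`, `species`, `transition_id`,
#' `area`; enforces nonnegative numeric areas and unique
#' (sample, species, transition) keys, naming the offending rows otherwise.
#'
#' @param path TSV/CSV path (delimiter inferred from the extension;
#'   `.csv` uses comma).
#' @return A validated tibble.
#' @export
read_peak_table <- function(path) {
  tab <- if (grepl("\\.csv$", path)) {
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE)
  } else {
    read_table_prov(path)
  }
  assert_peak_table(tab)
  tab
}

#' Write a peak table
#'
#' @param peaks Peak table tibble.
#' @inheritParams write_table_prov
#' @export
write_peak_table <- function(peaks, path, meta = list()) {
  assert_peak_table(peaks)
  write_table_prov(peaks, path, meta)
}

#' Read and validate a sample sheet
#'
#' Expects `sample_id`, `condition`, `replicate` (and optionally
#' `dry_mass_mg`); sample ids must be unique.
#'
#' @param path TSV path.
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path) {
  assert_sample_sheet(read_table_prov(path))
}

#' Write a sample sheet
#'
#' @param sheet Sample sheet tibble.
#' @inheritParams write_table_prov
#' @export
write_sample_sheet <- function(sheet, path, meta = list()) {
  assert_sample_sheet(sheet)
  write_table_prov(sheet, path, meta)
}

#' Read a gene x sample counts matrix
#'
#' Either a TSV whose first column holds gene identifiers, or a
#' MatrixMarket file accompanied by one-column gene and sample index files.
#' Zero-sum libraries are rejected.
#'
#' @param path Counts TSV or MatrixMarket (.mtx) path.
#' @param genes_path,samples_path Index files for the MatrixMarket layout.
#' @return A base matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, genes_path = NULL, samples_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes_path) || is.null(samples_path)) {
      stop("MatrixMarket counts need genes_path and samples_path",
           call. = FALSE)
    }
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("reading MatrixMarket counts requires the Matrix package",
           call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(samples_path)
  } else {
    tab <- read_table_prov(path)
    m <- as.matrix(tab[, -1])
    rownames(m) <- as.character(tab[[1]])
  }
  assert_counts(m)$counts
}

#' Run the full lipidomics quantification pipeline
#'
#' Executes the stages in order: isotopic correction, transition summation,
#' subclass totals with reference normalization, mol% species profiles with
#' the major-species flag, saturation profiles, sphingolipid modification
#' occurrence, and per-subclass condition statistics (ANOVA, Tukey HSD,
#' compact letter display) on the relative abundances. When `out_dir` is
#' given, every result is written as a TSV with a provenance header
#' carrying the configuration hash and seed.
#'
#' @param peaks Raw peak table (tibble or path accepted by
#'   [read_peak_table()]).
#' @param sheet Sample sheet (tibble or path).
#' @param reference_condition Normalization reference; default `"RT3"`.
#' @param p13c Natural 13C abundance; default 0.0107.
#' @param major_threshold Major-species mol% threshold; default 1.
#' @param alpha Significance level for letters; default 0.05.
#' @param weight Modification weighting, `"abundance"` or `"count"`.
#' @param out_dir Optional output directory for TSV results.
#' @param seed Optional seed recorded in the provenance header (the
#'   pipeline itself is deterministic).
#' @inheritParams parse_species
#' @return List with `corrected`, `species_areas`, `abundance`, `profile`,
#'   `saturation`, `modifications`, `abundance_stats`, and `config_hash`.
#' @export
run_pipeline <- function(peaks, sheet, reference_condition = "RT3",
                         p13c = 0.0107, major_threshold = 1, alpha = 0.05,
                         weight = "abundance", out_dir = NULL, seed = NULL,
                         registry = default_registry(),
                         steryl_pool = default_steryl_pool()) {
  if (is.character(peaks)) peaks <- read_peak_table(peaks)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  assert_peak_table(peaks)
  assert_sample_sheet(sheet)

  config <- list(reference_condition = reference_condition, p13c = p13c,
                 major_threshold = major_threshold, alpha = alpha,
                 weight = weight, seed = seed)
  config_hash <- rlang::hash(list(config, peaks, sheet))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  corrected <- stage("correct_areas",
                     correct_areas(peaks, registry, steryl_pool, p13c))
  species_areas <- stage("sum_transitions", sum_transitions(corrected))
  abundance <- stage("subclass_abundance",
                     subclass_abundance(species_areas, sheet,
                                        reference_condition))
  profile <- stage("species_profile",
                   species_profile(species_areas, sheet, major_threshold))
  saturation <- stage("saturation_profile",
                      saturation_profile(species_areas, registry,
                                         steryl_pool))
  modifications <- stage("modification_occurrence",
                         modification_occurrence(species_areas, registry,
                                                 steryl_pool, weight))
  abundance_stats <- stage("condition_stats",
                           condition_stats(abundance, "rel_abundance",
                                           "subclass", sheet, alpha))

  result <- list(corrected = corrected, species_areas = species_areas,
                 abundance = abundance, profile = profile,
                 saturation = saturation, modifications = modifications,
                 abundance_stats = abundance_stats,
                 config_hash = config_hash)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    meta <- list(config_hash = config_hash,
                 seed = if (is.null(seed)) "NA" else seed,
                 generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    write_table_prov(abundance,
                     file.path(out_dir, "subclass_abundance.tsv"), meta)
    write_table_prov(profile,
                     file.path(out_dir, "species_profile.tsv"), meta)
    write_table_prov(saturation, file.path(out_dir, "saturation.tsv"), meta)
    write_table_prov(modifications,
                     file.path(out_dir, "modifications.tsv"), meta)
    write_table_prov(abundance_stats,
                     file.path(out_dir, "abundance_stats.tsv"), meta)
  }
  result
}
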