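# Combinatorial enumeration of the MRM target species universe.

#' Default acyl residue pool
#'
#' The 25 acyl residues screened for glycerolipid, glycerophospholipid and
#' sterol-ester subclasses: 16:0-16:3, 17:0-17:3, 18:0-18:3, 19:0-19:3,
#' 20:0-20:2, 22:0, 22:1, 24:0, 24:1, 26:0, 26:1.
#'
#' @return Character vector of `"C:DB"` tokens, length 25.
#' @export
default_acyl_pool <- function() {
  c("16:0", "16:1", "16:2", "16:3",
    "17:0", "17:1", "17:2", "17:3",
    "18:0", "18:1", "18:2", "18:3",
    "19:0", "19:1", "19:2", "19:3",
    "20:0", "20:1", "20:2",
    "22:0", "22:1", "24:0", "24:1", "26:0", "26:1")
}

#' Default sphingoid base pool
#'
#' The five screened sphingoid base residues: 18:0;O2, 18:1;O2, 18:2;O2,
#' 18:0;O3 and 18:1;O3.
#'
#' @return Character vector of SPB tokens, length 5.
#' @export
default_spb_pool <- function() {
  c("18:0;O2", "18:1;O2", "18:2;O2", "18:0;O3", "18:1;O3")
}

acyl_sort_key <- function(tokens) {
  c_db <- do.call(rbind, strsplit(sub(";O.*$", "", tokens), ":", fixed = TRUE))
  order(as.integer(c_db[, 1]), as.integer(c_db[, 2]),
        grepl(";O", tokens, fixed = TRUE))
}

finish_target_list <- function(subclass, names, registry, steryl_pool,
                               p13c = 0.0107) {
  stopifnot(!anyDuplicated(names))
  info <- species_info(names, registry, steryl_pool, p13c = p13c)
  out <- tibble::tibble(
    subclass = subclass,
    display_name = info$species,
    n_carbons = info$n_carbons,
    total_double_bonds = info$total_double_bonds,
    icf = info$icf
  )
  stopifnot(!anyDuplicated(out$display_name))
  out
}

#' Enumerate glycerolipid target species
#'
#' All unordered combinations with replacement of the acyl pool taken
#' `n_chains` at a time, as molecular species (`"PC 16:0_18:2"` style), in a
#' deterministic canonical order. With `sum_level = TRUE` the molecular
#' combinations are collapsed to distinct sum compositions (`"PC 34:2"`).
#'
#' @param subclass Subclass code present in `registry` (1-3 chains).
#' @param pool Character vector of `"C:DB"` acyl tokens;
#'   default [default_acyl_pool()].
#' @param sum_level Collapse to sum compositions? Default `FALSE`.
#' @inheritParams parse_species
#' @return A tibble with columns `subclass`, `display_name`, `n_carbons`,
#'   `total_double_bonds`, `icf`.
#' @examples
#' nrow(enumerate_glycerolipids("DG"))  # choose(26, 2) = 325
#' @export
enumerate_glycerolipids <- function(subclass, pool = default_acyl_pool(),
                                    sum_level = FALSE,
                                    registry = default_registry(),
                                    steryl_pool = default_steryl_pool()) {
  if (length(pool) == 0) stop("acyl pool is empty", call. = FALSE)
  if (anyDuplicated(pool)) stop("acyl pool contains duplicates", call. = FALSE)
  entry <- registry_entry(registry, subclass)
  k <- entry$n_chains
  if (!k %in% 1:3) {
    stop("enumerate_glycerolipids requires 1-3 chains; '", subclass,
         "' has ", k, call. = FALSE)
  }
  pool <- pool[acyl_sort_key(pool)]
  idx <- utils::combn(seq_len(length(pool) + k - 1), k)
  # combinations with replacement via the standard index shift
  combos <- apply(idx, 2, function(ix) pool[ix - seq_len(k) + 1L],
                  simplify = FALSE)
  names <- vapply(combos, function(ch) paste0(subclass, " ",
                                              paste(ch, collapse = "_")),
                  character(1))
  if (sum_level) {
    parts <- lapply(combos, function(ch) {
      m <- do.call(rbind, strsplit(ch, ":", fixed = TRUE))
      c(sum(as.integer(m[, 1])), sum(as.integer(m[, 2])))
    })
    sums <- unique(do.call(rbind, parts))
    sums <- sums[order(sums[, 1], sums[, 2]), , drop = FALSE]
    names <- paste0(subclass, " ", sums[, 1], ":", sums[, 2])
  }
  finish_target_list(subclass, names, registry, steryl_pool)
}

#' Enumerate sphingolipid target species
#'
#' Cartesian product of the sphingoid base pool with amide-linked fatty
#' acids of the given chain lengths, each saturated or monounsaturated and
#' unhydroxylated or monohydroxylated. Subclasses with a single chain
#' (SPB, SPBP) enumerate the bases alone.
#'
#' @param subclass Sphingolipid subclass code.
#' @param spb_pool Character vector of SPB tokens;
#'   default [default_spb_pool()].
#' @param fa_lengths Integer vector of acyl carbon numbers; default 16:28.
#' @inheritParams enumerate_glycerolipids
#' @return A tibble as in [enumerate_glycerolipids()].
#' @examples
#' nrow(enumerate_sphingolipids("Cer"))  # 5 * 13 * 2 * 2 = 260
#' @export
enumerate_sphingolipids <- function(subclass, spb_pool = default_spb_pool(),
                                    fa_lengths = 16:28,
                                    registry = default_registry(),
                                    steryl_pool = default_steryl_pool()) {
  entry <- registry_entry(registry, subclass)
  if (entry$category != "sphingolipid") {
    stop("'", subclass, "' is not a sphingolipid subclass", call. = FALSE)
  }
  if (entry$n_chains == 1) {
    names <- paste0(subclass, " ", spb_pool)
  } else {
    fa <- expand.grid(c = fa_lengths, db = 0:1, oh = c("", ";O"),
                      stringsAsFactors = FALSE)
    fa_tok <- paste0(fa$c, ":", fa$db, fa$oh)
    grid <- expand.grid(spb = spb_pool, fa = fa_tok,
                        stringsAsFactors = FALSE)
    names <- paste0(subclass, " ", grid$spb, "/", grid$fa)
  }
  finish_target_list(subclass, sort(names, method = "radix"), registry, steryl_pool)
}

#' Enumerate sterol lipid target species
#'
#' Free sterols and sterylglycosides enumerate the steryl pool alone; sterol
#' esters and acylsterylglycosides take the product of the steryl pool with
#' the acyl pool.
#'
#' @param subclass Sterol lipid subclass code (FS, SG, SE, ASG).
#' @param steryl_names Steryl residues to use; default all residues in
#'   `steryl_pool`.
#' @inheritParams enumerate_glycerolipids
#' @return A tibble as in [enumerate_glycerolipids()].
#' @examples
#' nrow(enumerate_sterol_lipids("SE"))  # 6 * 25 = 150
#' @export
enumerate_sterol_lipids <- function(subclass, steryl_names = NULL,
                                    pool = default_acyl_pool(),
                                    registry = default_registry(),
                                    steryl_pool = default_steryl_pool()) {
  entry <- registry_entry(registry, subclass)
  if (entry$category != "sterol_lipid") {
    stop("'", subclass, "' is not a sterol lipid subclass", call. = FALSE)
  }
  if (is.null(steryl_names)) steryl_names <- steryl_pool$name
  if (entry$n_chains == 0) {
    names <- paste0(subclass, " ", steryl_names)
  } else {
    if (length(pool) == 0) stop("acyl pool is empty", call. = FALSE)
    pool <- pool[acyl_sort_key(pool)]
    grid <- expand.grid(st = steryl_names, fa = pool,
                        stringsAsFactors = FALSE)
    names <- paste0(subclass, " ", grid$st, "/", grid$fa)
  }
  finish_target_list(subclass, sort(names, method = "radix"), registry, steryl_pool)
}

#' Enumerate the target universe for one subclass
#'
#' Dispatches to the category-appropriate enumerator.
#'
#' @inheritParams enumerate_glycerolipids
#' @return A tibble as in [enumerate_glycerolipids()].
#' @export
enumerate_targets <- function(subclass, registry = default_registry(),
                              steryl_pool = default_steryl_pool(), ...) {
  entry <- registry_entry(registry, subclass)
  switch(entry$category,
         sphingolipid = enumerate_sphingolipids(
           subclass, registry = registry, steryl_pool = steryl_pool, ...),
         sterol_lipid = enumerate_sterol_lipids(
           subclass, registry = registry, steryl_pool = steryl_pool, ...),
         enumerate_glycerolipids(
           subclass, registry = registry, steryl_pool = steryl_pool, ...))
}
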