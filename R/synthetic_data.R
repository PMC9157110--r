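# Seeded synthetic-data generators with recorded ground truth. They emulate
# the statistical structure the analysis assumes — the five temperature
# regimes with five replicates (lipids, FAMEs, metabolites), three regimes
# with three replicates (counts), multiplicative lognormal replicate noise,
# and injected condition effects — so every pipeline stage is testable
# without the deposited raw measurements.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# mean-preserving multiplicative lognormal noise with the given CV
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Sphingoid base pool with resolved positional annotations
#'
#' The five screened bases expanded into their positional variants: the d4
#' and/or d8 double bonds of the unsaturated O2 bases, and C4 hydroxylation
#' (mutually exclusive with d4) of the O3 bases. Used by the synthetic
#' generator so modification-occurrence profiles have resolved features.
#'
#' @return Character vector of annotated SPB tokens.
#' @export
annotated_spb_pool <- function() {
  c("18:0;O2", "18:1(d4);O2", "18:1(d8);O2", "18:2(d4,d8);O2",
    "18:0;O3(4OH)", "18:1(d8);O3(4OH)")
}

default_abundance_folds <- function(conditions = default_conditions(),
                                    subclasses) {
  base <- c(RT3 = 1, RT6 = 1.8, `HS3+3` = 2.2, `HS3+6` = 3, HSR = 3)
  overrides <- list(
    SPBP   = c(RT3 = 1, RT6 = 2.0, `HS3+3` = 11.6, `HS3+6` = 14,  HSR = 5),
    HexCer = c(RT3 = 1, RT6 = 2.0, `HS3+3` = 2.6,  `HS3+6` = 3.4, HSR = 2.6),
    TG     = c(RT3 = 1, RT6 = 1.5, `HS3+3` = 3.1,  `HS3+6` = 4.2, HSR = 3.5),
    DGDG   = c(RT3 = 1, RT6 = 1.8, `HS3+3` = 4.0,  `HS3+6` = 6,   HSR = 5),
    PS     = c(RT3 = 1, RT6 = 1.8, `HS3+3` = 3.5,  `HS3+6` = 5,   HSR = 4),
    SE     = c(RT3 = 1, RT6 = 1.5, `HS3+3` = 0.9,  `HS3+6` = 0.8, HSR = 1.2),
    SG     = c(RT3 = 1, RT6 = 1.5, `HS3+3` = 2.76, `HS3+6` = 3,   HSR = 2.5),
    ASG    = c(RT3 = 1, RT6 = 1.5, `HS3+3` = 2.13, `HS3+6` = 2.3, HSR = 2)
  )
  folds <- lapply(subclasses, function(sc) {
    f <- if (sc %in% names(overrides)) overrides[[sc]] else base
    f[conditions]
  })
  names(folds) <- subclasses
  folds
}

#' Configuration for the synthetic lipidome generator
#'
#' Defaults encode the study design: five temperature regimes with five
#' replicates, lognormal replicate noise with CV 0.15, a strong sphingoid
#' base phosphate induction (5.8-fold at HS3+3 relative to RT6, 2.8-fold
#' comparing extended heat stress to stress relief), a 30 percent
#' hexosylceramide increase, TG accumulation, a saturation shift of +15
#' percentage points toward saturated species in membrane glycerolipids
#' under heat stress, and a d4-to-C4-hydroxyl shift in hexosylceramides.
#'
#' @param seed Integer seed; every draw derives from it.
#' @param conditions Condition labels; default [default_conditions()].
#' @param replicates Replicates per condition; default 5.
#' @param cv Coefficient of variation of the multiplicative lognormal
#'   replicate noise; default 0.15. `cv = 0` is the noise-free limit.
#' @param subclasses Subclass codes to simulate.
#' @param n_species Species simulated per subclass; default 12 (about the
#'   study-wide average of detected species per subclass; abundant membrane
#'   subclasses carry more).
#' @param species_weight_sdlog Log-SD of the lognormal species baseline
#'   weights within a subclass; default 0.5 (moderate dominance, a 2-3-fold
#'   typical spread between species).
#' @param baseline_total Geometric-mean corrected-area total of a subclass
#'   in the reference condition; default 1e6.
#' @param abundance_folds Named list: subclass -> named vector of
#'   per-condition fold relative to the reference condition.
#' @param saturation_shift List with `subclasses` (codes the shift applies
#'   to) and `delta` (named per-condition vector, percentage points moved
#'   from polyunsaturated to saturated species).
#' @param baseline_saturation Reference-condition class composition imposed
#'   on subclasses under a saturation shift, so the injected shift is
#'   well-defined and feasible; default 25/25/50
#'   saturated/monounsaturated/polyunsaturated (membranes at growth
#'   temperature are predominantly polyunsaturated).
#' @param modification_shift List with `subclass`, and `delta` (named
#'   per-condition vector, fraction of subclass mass moved from d4-modified
#'   to C4-hydroxylated species).
#' @param baseline_modification Reference composition over the d4 / C4-OH /
#'   other strata for the modification-shift subclass; default 60/30/10.
#' @param transitions Possible transition counts per species; default 1:3.
#' @return A list of class `lipidome_truth_config`.
#' @export
lipidome_truth_config <- function(
    seed = 1L,
    conditions = default_conditions(),
    replicates = 5L,
    cv = 0.15,
    subclasses = c("PC", "PE", "PI", "PG", "PS", "PA", "MGDG", "DGDG",
                   "DG", "TG", "LPC", "SPB", "SPBP", "Cer", "HexCer",
                   "SE", "SG", "ASG"),
    n_species = 12L,
    species_weight_sdlog = 0.5,
    baseline_total = 1e6,
    abundance_folds = default_abundance_folds(conditions, subclasses),
    saturation_shift = list(
      subclasses = intersect(c("PC", "PE", "PI", "PG", "MGDG", "DGDG"),
                             subclasses),
      delta = c(RT3 = 0, RT6 = 0, `HS3+3` = 15, `HS3+6` = 18, HSR = 8)),
    baseline_saturation = c(saturated = 0.25, monounsaturated = 0.25,
                            polyunsaturated = 0.50),
    modification_shift = list(
      subclass = "HexCer",
      delta = c(RT3 = 0, RT6 = 0, `HS3+3` = 0.093, `HS3+6` = 0.11,
                HSR = 0.05)),
    baseline_modification = c(d4 = 0.60, c4oh = 0.30, other = 0.10),
    transitions = 1:3) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (replicates < 2) stop("need >= 2 replicates", call. = FALSE)
  stopifnot(all(vapply(abundance_folds, function(f) all(f > 0), logical(1))))
  structure(list(seed = seed, conditions = conditions,
                 replicates = replicates, cv = cv, subclasses = subclasses,
                 n_species = n_species,
                 species_weight_sdlog = species_weight_sdlog,
                 baseline_total = baseline_total,
                 abundance_folds = abundance_folds,
                 saturation_shift = saturation_shift,
                 baseline_saturation = baseline_saturation,
                 modification_shift = modification_shift,
                 baseline_modification = baseline_modification,
                 transitions = transitions),
            class = "lipidome_truth_config")
}

# draw n_species from a subclass universe; with `strata` (a label per
# universe row) and `strata_target` (named fractions), the draw is
# stratified so the panel's class composition mirrors the baseline the
# generator imposes, as a measured panel would
sample_species <- function(universe, n_species, strata = NULL,
                           strata_target = NULL) {
  n <- min(n_species, nrow(universe))
  if (is.null(strata)) {
    return(universe[sort(sample.int(nrow(universe), n)), , drop = FALSE])
  }
  levs <- intersect(names(strata_target), unique(strata[!is.na(strata)]))
  tgt <- strata_target[levs] / sum(strata_target[levs])
  want <- pmax(1L, round(n * tgt))
  # trim/extend to n, respecting per-stratum availability
  avail <- vapply(levs, function(l) sum(strata == l, na.rm = TRUE),
                  integer(1))
  want <- pmin(want, avail)
  while (sum(want) > n) want[which.max(want)] <- want[which.max(want)] - 1L
  picked <- integer(0)
  for (i in seq_along(levs)) {
    cand <- which(strata == levs[i])
    picked <- c(picked, cand[sample.int(length(cand), want[i])])
  }
  rest <- setdiff(seq_len(nrow(universe)), picked)
  if (sum(want) < n && length(rest) > 0) {
    picked <- c(picked,
                rest[sample.int(length(rest), min(n - sum(want),
                                                  length(rest)))])
  }
  universe[sort(picked), , drop = FALSE]
}

shift_weights <- function(w, class, from, to, delta_frac) {
  # move delta_frac of total mass from `from`-class species to `to`-class,
  # preserving the total
  if (delta_frac == 0) return(w)
  from_sum <- sum(w[class == from])
  to_sum <- sum(w[class == to])
  if (delta_frac > from_sum) {
    stop("infeasible shift: ", round(delta_frac, 3),
         " exceeds available mass ", round(from_sum, 3), call. = FALSE)
  }
  if (to_sum == 0) stop("no species in target class to receive the shift",
                        call. = FALSE)
  w[class == from] <- w[class == from] * (1 - delta_frac / from_sum)
  w[class == to] <- w[class == to] * (1 + delta_frac / to_sum)
  w
}

# rescale species weights so per-class masses match `target` fractions
# (renormalized over the classes actually present)
rescale_classes <- function(w, class, target) {
  present <- intersect(names(target), unique(class))
  tgt <- target[present] / sum(target[present])
  out <- w
  out[!class %in% present] <- 0
  for (cl in present) {
    idx <- class == cl
    out[idx] <- w[idx] / sum(w[idx]) * tgt[[cl]]
  }
  out
}

#' Generate a synthetic lipidome peak table with recorded truth
#'
#' Enumerates each subclass' target universe (sphingolipids with the
#' positionally annotated base pool), draws species baselines, applies the
#' configured per-condition subclass folds, saturation shifts
#' (polyunsaturated to saturated mass transfer, preserving the subclass
#' total so abundance and saturation effects stay independently testable)
#' and modification shifts (d4 to C4-OH), multiplies mean-preserving
#' lognormal replicate noise, splits each species across 1-3 mass
#' transitions with fixed proportions, and divides by the isotopic
#' correction factor so the emitted areas are raw (the pipeline's icf
#' correction restores the injected corrected-scale means). The same seed
#' reproduces the output exactly.
#'
#' @param config A [lipidome_truth_config()].
#' @inheritParams parse_species
#' @return List with `peaks` (raw PeakTable tibble), `sheet` (sample
#'   sheet), and `truth` (injected parameters: per-condition subclass
#'   totals, species weights, folds and shifts).
#' @export
gen_lipidome <- function(config = lipidome_truth_config(),
                         registry = default_registry(),
                         steryl_pool = default_steryl_pool()) {
  stopifnot(inherits(config, "lipidome_truth_config"))
  with_seed(config$seed, {
    conditions <- config$conditions
    sheet <- tibble::tibble(
      condition = rep(conditions, each = config$replicates),
      replicate = rep(seq_len(config$replicates), length(conditions)))
    sheet$sample_id <- paste0(sheet$condition, "_r", sheet$replicate)
    sheet <- sheet[, c("sample_id", "condition", "replicate")]

    acc <- list(sample_id = list(), subclass = list(), species = list(),
                transition_id = list(), area = list())
    truth_species <- list()
    tt <- list(subclass = character(), condition = character(),
               total = numeric(), fold = numeric())

    for (sc in config$subclasses) {
      entry <- registry_entry(registry, sc)
      universe <- if (entry$category == "sphingolipid") {
        enumerate_sphingolipids(sc, spb_pool = annotated_spb_pool(),
                                fa_lengths = c(16L, 20L, 24L, 26L),
                                registry = registry,
                                steryl_pool = steryl_pool)
      } else {
        enumerate_targets(sc, registry = registry, steryl_pool = steryl_pool)
      }
      info <- species_info(universe$display_name, registry, steryl_pool)

      strata <- NULL
      strata_target <- NULL
      if (sc %in% config$saturation_shift$subclasses) {
        strata <- info$sat_class
        strata_target <- config$baseline_saturation
      } else if (!is.null(config$modification_shift) &&
                 sc == config$modification_shift$subclass) {
        strata <- ifelse(info$d4_double_bond == "yes", "d4",
                         ifelse(info$c4_hydroxyl == "yes", "c4oh", "other"))
        strata_target <- config$baseline_modification
      }
      chosen <- sample_species(info, config$n_species, strata,
                               strata_target)
      chosen$k_transitions <- sample(config$transitions, nrow(chosen),
                                     replace = TRUE)
      chosen$transition_props <- lapply(chosen$k_transitions, function(k) {
        g <- stats::rgamma(k, 2, 1)
        g / sum(g)
      })

      w <- stats::rlnorm(nrow(chosen), 0, config$species_weight_sdlog)
      w <- w / sum(w)
      if (sc %in% config$saturation_shift$subclasses) {
        w <- rescale_classes(w, chosen$sat_class,
                             config$baseline_saturation)
      } else if (!is.null(config$modification_shift) &&
                 sc == config$modification_shift$subclass) {
        strata <- ifelse(chosen$d4_double_bond == "yes", "d4",
                         ifelse(chosen$c4_hydroxyl == "yes", "c4oh",
                                "other"))
        w <- rescale_classes(w, strata, config$baseline_modification)
      }
      base_total <- stats::rlnorm(1, log(config$baseline_total), 0.5)
      folds <- config$abundance_folds[[sc]]

      for (cond in conditions) {
        wc <- w
        if (sc %in% config$saturation_shift$subclasses) {
          delta <- config$saturation_shift$delta[[cond]] / 100
          wc <- shift_weights(wc, chosen$sat_class, "polyunsaturated",
                              "saturated", delta)
        }
        if (!is.null(config$modification_shift) &&
            sc == config$modification_shift$subclass) {
          delta <- config$modification_shift$delta[[cond]]
          wc <- shift_weights(wc, ifelse(chosen$d4_double_bond == "yes",
                                         "d4",
                                         ifelse(chosen$c4_hydroxyl == "yes",
                                                "c4oh", "other")),
                              "d4", "c4oh", delta)
        }
        total <- base_total * folds[[cond]]
        tt$subclass <- c(tt$subclass, sc)
        tt$condition <- c(tt$condition, cond)
        tt$total <- c(tt$total, total)
        tt$fold <- c(tt$fold, folds[[cond]])
        samples <- sheet$sample_id[sheet$condition == cond]
        mu <- total * wc
        nsp <- nrow(chosen)
        k <- chosen$k_transitions
        sp_idx <- rep(seq_len(nsp), k)  # species row per transition
        trans_id <- unlist(lapply(k, function(n) paste0("t", seq_len(n))))
        props <- unlist(chosen$transition_props)
        ns <- length(samples)
        noisy <- mu * matrix(lognormal_noise(nsp * ns, config$cv), nsp, ns)
        i <- length(acc$sample_id) + 1
        acc$sample_id[[i]] <- rep(samples, each = length(sp_idx))
        acc$subclass[[i]] <- rep(sc, length(sp_idx) * ns)
        acc$species[[i]] <- rep(chosen$species[sp_idx], ns)
        acc$transition_id[[i]] <- rep(trans_id, ns)
        acc$area[[i]] <- as.vector(
          vapply(seq_len(ns),
                 function(j) noisy[sp_idx, j] * props / chosen$icf[sp_idx],
                 numeric(length(sp_idx))))
      }
      truth_species[[length(truth_species) + 1]] <- tibble::tibble(
        subclass = sc, species = chosen$species, base_weight = w,
        sat_class = chosen$sat_class)
    }

    peaks <- tibble::tibble(
      sample_id = unlist(acc$sample_id),
      subclass = unlist(acc$subclass),
      species = unlist(acc$species),
      transition_id = unlist(acc$transition_id),
      area = unlist(acc$area))
    truth <- list(seed = config$seed, cv = config$cv,
                  abundance_folds = config$abundance_folds,
                  saturation_shift = config$saturation_shift,
                  baseline_saturation = config$baseline_saturation,
                  modification_shift = config$modification_shift,
                  baseline_modification = config$baseline_modification,
                  totals = tibble::as_tibble(tt),
                  species = dplyr::bind_rows(truth_species))
    list(peaks = peaks, sheet = sheet, truth = truth)
  })
}

#' Configuration for the synthetic counts generator
#'
#' Three conditions with three replicates, negative-binomial counts with
#' gene-specific means, a configured fraction of genes shifted by
#' `2^de_log2fc` under heat stress, and GO terms of which a few are
#' enriched in shifted genes.
#'
#' @param seed Integer seed.
#' @param n_genes,conditions,replicates Design; defaults 2000 genes, RT3 /
#'   RT6 / HS3+3, 3 replicates.
#' @param lib_target Expected library size; default 2e6.
#' @param low_expr_fraction Fraction of genes expressed only at trace
#'   level (around `low_expr_mu` counts), emulating the low-expression
#'   tail the CPM detection filter removes (roughly a tenth of detected
#'   genes fail it in pollen tube libraries); default 0.1.
#' @param low_expr_mu Expected count of trace-level genes; default 0.1.
#' @param de_fraction Fraction of genes differentially expressed under heat
#'   stress (drawn from the expressed genes); default 0.08 (half up, half
#'   down).
#' @param de_log2fc Injected absolute log2 fold change; default 2.
#' @param dispersion Negative-binomial dispersion; default 0.05. `0` gives
#'   the noise-free limit (counts equal to their continuous means).
#' @param n_terms,genes_per_term,n_enriched_terms,enriched_de_frac GO-term
#'   structure; enriched terms draw `enriched_de_frac` of their members
#'   from upshifted genes.
#' @return A list of class `counts_truth_config`.
#' @export
counts_truth_config <- function(seed = 1L, n_genes = 2000L,
                                conditions = c("RT3", "RT6", "HS3+3"),
                                replicates = 3L, lib_target = 2e6,
                                low_expr_fraction = 0.1, low_expr_mu = 0.1,
                                de_fraction = 0.08, de_log2fc = 2,
                                dispersion = 0.05, n_terms = 40L,
                                genes_per_term = 15L,
                                n_enriched_terms = 4L,
                                enriched_de_frac = 0.6) {
  stopifnot(de_fraction >= 0, de_fraction <= 1, dispersion >= 0)
  structure(as.list(environment()), class = "counts_truth_config")
}

#' Generate a synthetic count matrix with GO structure and DE truth
#'
#' @param config A [counts_truth_config()].
#' @return List with `counts` (gene x sample matrix), `lengths` (named bp
#'   vector), `go_map` (gene, go_id), `de_table` (externally-computed-style
#'   DE flags: gene, log2fc, fdr), `sheet`, and `truth` (injected log2
#'   fold changes and enriched terms).
#' @export
gen_counts <- function(config = counts_truth_config()) {
  stopifnot(inherits(config, "counts_truth_config"))
  with_seed(config$seed, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    sheet <- tibble::tibble(
      condition = rep(config$conditions, each = config$replicates),
      replicate = rep(seq_len(config$replicates), length(config$conditions)))
    sheet$sample_id <- paste0(sheet$condition, "_r", sheet$replicate)
    sheet <- sheet[, c("sample_id", "condition", "replicate")]

    q <- stats::rlnorm(config$n_genes, 0, 1.5)
    n_low <- round(config$low_expr_fraction * config$n_genes)
    low_genes <- sample(genes, n_low)
    n_de <- round(config$de_fraction * config$n_genes)
    de_genes <- sample(setdiff(genes, low_genes), n_de)
    up <- de_genes[seq_len(ceiling(n_de / 2))]
    down <- setdiff(de_genes, up)
    lfc <- stats::setNames(rep(0, config$n_genes), genes)
    lfc[up] <- config$de_log2fc
    lfc[down] <- -config$de_log2fc

    base_mu <- q / sum(q) * config$lib_target
    base_mu[genes %in% low_genes] <- config$low_expr_mu
    counts <- matrix(0, config$n_genes, nrow(sheet),
                     dimnames = list(genes, sheet$sample_id))
    for (i in seq_len(nrow(sheet))) {
      mu <- base_mu
      if (sheet$condition[i] == "HS3+3") mu <- mu * 2^lfc
      counts[, i] <- if (config$dispersion == 0) {
        mu
      } else {
        stats::rnbinom(config$n_genes, mu = mu,
                       size = 1 / config$dispersion)
      }
    }

    lengths <- stats::setNames(sample(300:5000, config$n_genes,
                                      replace = TRUE), genes)

    terms <- sprintf("GO:%07d", seq_len(config$n_terms))
    enriched <- terms[seq_len(config$n_enriched_terms)]
    go_rows <- lapply(terms, function(tm) {
      members <- if (tm %in% enriched) {
        n_up <- round(config$enriched_de_frac * config$genes_per_term)
        c(sample(up, min(n_up, length(up))),
          sample(setdiff(genes, de_genes),
                 config$genes_per_term - min(n_up, length(up))))
      } else {
        sample(genes, config$genes_per_term)
      }
      tibble::tibble(gene = unique(members), go_id = tm)
    })
    go_map <- dplyr::bind_rows(go_rows)

    de_table <- tibble::tibble(
      gene = genes, log2fc = unname(lfc),
      fdr = ifelse(lfc != 0, 1e-6, 0.9))

    truth <- list(seed = config$seed, log2fc = lfc, up = up, down = down,
                  enriched_terms = enriched, base_mu = base_mu,
                  low_genes = low_genes, dispersion = config$dispersion)
    list(counts = counts, lengths = lengths, go_map = go_map,
         de_table = de_table, sheet = sheet, truth = truth)
  })
}

#' Configuration for the synthetic FAME and metabolite generator
#'
#' Five regimes with five replicates; TG roughly doubles under heat stress
#' relative to RT6 (the GC-FID observation), sucrose doubles and
#' sedoheptulose triples, anchored to internal standards of 0.05 mg
#' triheptadecanoate (17:0) and 0.0125 mg allo-inositol.
#'
#' @param seed Integer seed.
#' @param conditions,replicates,cv Design and noise; defaults five regimes,
#'   5, 0.15.
#' @param fame_composition Named per-FA mass fractions of the TG pool.
#' @param tg_baseline_ug_per_mg TG amount at RT3 in ug per mg dry pollen.
#' @param tg_folds Named per-condition folds of the TG amount.
#' @param metabolite_folds Named list: analyte -> named per-condition fold.
#' @param is_fa,is_mass_mg,pollen_dry_mass_mg,is_analyte Internal-standard
#'   and sample-mass constants.
#' @return A list of class `fame_met_truth_config`.
#' @export
fame_met_truth_config <- function(
    seed = 1L, conditions = default_conditions(), replicates = 5L,
    cv = 0.15,
    fame_composition = c(`16:0` = 0.30, `18:1` = 0.25, `18:2` = 0.30,
                         `18:3` = 0.15),
    tg_baseline_ug_per_mg = 1.5,
    tg_folds = c(RT3 = 1, RT6 = 1.6, `HS3+3` = 3.3, `HS3+6` = 4.2,
                 HSR = 3.2),
    metabolite_folds = list(
      sucrose = c(RT3 = 1, RT6 = 1.5, `HS3+3` = 3.0, `HS3+6` = 3.4,
                  HSR = 3.0),
      sedoheptulose = c(RT3 = 1, RT6 = 1.3, `HS3+3` = 3.9, `HS3+6` = 4.5,
                        HSR = 3.5),
      glucose = c(RT3 = 1, RT6 = 1.4, `HS3+3` = 1.6, `HS3+6` = 1.8,
                  HSR = 1.7),
      proline = c(RT3 = 1, RT6 = 3.0, `HS3+3` = 3.0, `HS3+6` = 3.2,
                  HSR = 3.1)),
    is_fa = "17:0", is_mass_mg = 0.05, pollen_dry_mass_mg = 20,
    is_analyte = "allo-inositol") {
  stopifnot(abs(sum(fame_composition) - 1) < 1e-8, cv >= 0)
  structure(as.list(environment()), class = "fame_met_truth_config")
}

#' Generate synthetic GC-FID FAME and GC-MS metabolite tables
#'
#' FAME areas are emitted relative to a per-sample internal-standard area
#' so that [tg_absolute()] recovers the injected TG amounts; metabolite
#' quantifier areas are emitted relative to the allo-inositol standard so
#' that [metabolite_relative()] recovers the injected folds.
#'
#' @param config A [fame_met_truth_config()].
#' @return List with `fames`, `metabolites`, `sheet`, `truth`.
#' @export
gen_fame_and_metabolites <- function(config = fame_met_truth_config()) {
  stopifnot(inherits(config, "fame_met_truth_config"))
  with_seed(config$seed, {
    sheet <- tibble::tibble(
      condition = rep(config$conditions, each = config$replicates),
      replicate = rep(seq_len(config$replicates),
                      length(config$conditions)))
    sheet$sample_id <- paste0(sheet$condition, "_r", sheet$replicate)
    sheet <- sheet[, c("sample_id", "condition", "replicate")]

    fame_rows <- list()
    met_rows <- list()
    base_resp <- stats::setNames(
      stats::rlnorm(length(config$metabolite_folds), log(0.5), 0.5),
      names(config$metabolite_folds))

    for (i in seq_len(nrow(sheet))) {
      s <- sheet$sample_id[i]
      cond <- sheet$condition[i]
      is_area <- stats::rlnorm(1, log(1e5), 0.1)
      tg_mass_mg <- config$tg_baseline_ug_per_mg / 1000 *
        config$pollen_dry_mass_mg * config$tg_folds[[cond]]
      fa_mass <- tg_mass_mg * config$fame_composition *
        lognormal_noise(length(config$fame_composition), config$cv)
      fame_rows[[i]] <- tibble::tibble(
        sample_id = s,
        fatty_acid = c(config$is_fa, names(config$fame_composition)),
        area = c(is_area, fa_mass / config$is_mass_mg * is_area))

      is_area_m <- stats::rlnorm(1, log(1e5), 0.1)
      resp <- vapply(names(config$metabolite_folds), function(a) {
        base_resp[[a]] * config$metabolite_folds[[a]][[cond]]
      }, numeric(1)) * lognormal_noise(length(base_resp), config$cv)
      met_rows[[i]] <- tibble::tibble(
        sample_id = s,
        analyte = c(config$is_analyte, names(config$metabolite_folds)),
        area = c(is_area_m, resp * is_area_m))
    }

    truth <- list(seed = config$seed, cv = config$cv,
                  tg_ug_per_mg = config$tg_baseline_ug_per_mg *
                    unlist(config$tg_folds[config$conditions]),
                  tg_folds = config$tg_folds,
                  metabolite_folds = config$metabolite_folds,
                  fame_composition = config$fame_composition)
    list(fames = dplyr::bind_rows(fame_rows),
         metabolites = dplyr::bind_rows(met_rows),
         sheet = sheet, truth = truth)
  })
}
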