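# Lipid subclass registry, shorthand-name parsing, elemental formulas and
# isotopic correction factors.

.pollenomics_env <- new.env(parent = emptyenv())

.ELEMENTS <- c("C", "H", "N", "O", "P", "S")

#' Read a lipid subclass registry
#'
#' The registry defines every lipid subclass the quantification pipeline
#' accepts: its short code, lipid category, number of esterified/amidated
#' chains, ionization mode, and the elemental composition of its backbone
#' and headgroup as free (uncondensed) molecules. Species formulas are
#' assembled as backbone + headgroup + chain residues minus one water per
#' condensation bond, so the registry is the single place where subclass
#' chemistry lives.
#'
#' @param path Path to a tab-separated registry file with columns `name`,
#'   `category`, `n_chains`, `ionization` and the twelve element-count
#'   columns `bb_C` ... `bb_S`, `hg_C` ... `hg_S`.
#' @return A tibble, one row per subclass.
#' @seealso [default_registry()] for the registry shipped with the package.
#' @export
read_subclass_registry <- function(path) {
  reg <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  needed <- c("name", "category", "n_chains", "ionization",
              paste0("bb_", .ELEMENTS), paste0("hg_", .ELEMENTS))
  missing <- setdiff(needed, names(reg))
  if (length(missing) > 0) {
    stop("subclass registry is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reg$name)) {
    stop("subclass registry contains duplicate subclass names: ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "),
         call. = FALSE)
  }
  counts <- as.matrix(reg[, c(paste0("bb_", .ELEMENTS), paste0("hg_", .ELEMENTS))])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("registry element counts must be nonnegative integers", call. = FALSE)
  }
  if (any(reg$n_chains < 0)) stop("n_chains must be >= 0", call. = FALSE)
  reg
}

#' Built-in subclass registry
#'
#' Covers the glycerophospholipids (PC, PE, PA, PI, PS, PG, PIP, PIP2),
#' galactoglycerolipids (MGDG, DGDG, SQDG), neutral glycerolipids (MG, DG,
#' TG), lyso-glycerophospholipids (LPC, LPE, LPA, LPI, LPS, LPG),
#' sphingolipids (SPB, SPBP, Cer, CerP, HexCer, IPC, GlcA-IPC,
#' HexNAc-GlcA-IPC, Hex-HexNAc-GlcA-IPC) and sterol lipids (FS, SE, SG, ASG).
#'
#' @return A tibble as documented in [read_subclass_registry()].
#' @export
default_registry <- function() {
  if (is.null(.pollenomics_env$registry)) {
    path <- system.file("extdata", "subclass_registry.tsv",
                        package = "pollenomics", mustWork = TRUE)
    .pollenomics_env$registry <- read_subclass_registry(path)
  }
  .pollenomics_env$registry
}

#' Read a steryl residue pool
#'
#' @param path Tab-separated file with columns `name`, `C`, `H`, `O`
#'   (element counts of the free sterol).
#' @return A tibble, one row per (mass-grouped) steryl residue.
#' @export
read_steryl_pool <- function(path) {
  pool <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  needed <- c("name", "C", "H", "O")
  missing <- setdiff(needed, names(pool))
  if (length(missing) > 0) {
    stop("steryl pool is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pool$name)) stop("duplicate steryl residues", call. = FALSE)
  pool
}

#' Built-in steryl residue pool
#'
#' The six residues resolved by mass: cholesterol, campesterol, sitosterol,
#' cycloeucalenol, and the two mass-ambiguous groups M398
#' (24-methylenecholesterol / delta-5,24-ergostadienol) and M412
#' (stigmasterol / putative methylenepollinastanol / isofucosterol /
#' 24-methylenelophenol), each modeled as a single grouped residue.
#'
#' @return A tibble as documented in [read_steryl_pool()].
#' @export
default_steryl_pool <- function() {
  if (is.null(.pollenomics_env$steryl_pool)) {
    path <- system.file("extdata", "steryl_pool.tsv",
                        package = "pollenomics", mustWork = TRUE)
    .pollenomics_env$steryl_pool <- read_steryl_pool(path)
  }
  .pollenomics_env$steryl_pool
}

registry_entry <- function(registry, code) {
  i <- match(code, registry$name)
  if (is.na(i)) {
    stop("unknown lipid subclass '", code, "' (not in registry)",
         call. = FALSE)
  }
  registry[i, ]
}

# --- chain tokens -----------------------------------------------------------

.CHAIN_RE <- "^([0-9]+):([0-9]+)(\\(([d0-9,]+)\\))?(;O([0-9]*)(\\(([0-9]+)OH\\))?)?$"

parse_chain_token <- function(token, kind = c("acyl", "spb")) {
  kind <- match.arg(kind)
  m <- regmatches(token, regexec(.CHAIN_RE, token))[[1]]
  if (length(m) == 0) {
    stop("malformed chain token '", token, "'", call. = FALSE)
  }
  carbons <- as.integer(m[2])
  db <- as.integer(m[3])
  has_oxy <- nzchar(m[6])
  oxy_digits <- m[7]
  pos_raw <- m[5]
  oh_raw <- m[9]

  if (carbons < 2) stop("chain '", token, "': carbons must be >= 2", call. = FALSE)
  if (db < 0 || db > carbons / 2) {
    stop("chain '", token, "': implausible double bond count", call. = FALSE)
  }

  db_positions <- NULL
  if (nzchar(pos_raw)) {
    parts <- strsplit(pos_raw, ",", fixed = TRUE)[[1]]
    if (!all(grepl("^d[0-9]+$", parts))) {
      stop("chain '", token, "': bad double-bond position annotation '",
           pos_raw, "'", call. = FALSE)
    }
    db_positions <- as.integer(sub("^d", "", parts))
    if (length(db_positions) > db) {
      stop("chain '", token, "': more annotated positions than double bonds",
           call. = FALSE)
    }
  }
  oh_position <- if (nzchar(oh_raw)) as.integer(oh_raw) else NA_integer_

  if (kind == "spb") {
    if (!has_oxy || !nzchar(oxy_digits)) {
      stop("sphingoid base '", token, "' must carry an ;O2 or ;O3 suffix",
           call. = FALSE)
    }
    oxygens <- as.integer(oxy_digits)
    if (!oxygens %in% c(2L, 3L)) {
      stop("sphingoid base '", token, "': oxygens must be 2 or 3", call. = FALSE)
    }
    if (!is.na(oh_position) && oh_position == 4L &&
        !is.null(db_positions) && 4L %in% db_positions) {
      stop("sphingoid base '", token,
           "': C4 hydroxyl and d4 double bond are mutually exclusive",
           call. = FALSE)
    }
    if (!is.na(oh_position) && oxygens == 2L) {
      stop("sphingoid base '", token,
           "': hydroxyl position annotation requires ;O3", call. = FALSE)
    }
    list(kind = "spb", carbons = carbons, double_bonds = db,
         oxygens = oxygens, hydroxyls = NA_integer_,
         db_positions = db_positions, oh_position = oh_position)
  } else {
    hydroxyls <- if (has_oxy) 1L else 0L
    if (has_oxy && nzchar(oxy_digits)) {
      stop("acyl chain '", token,
           "': only a single unnumbered ';O' hydroxyl is supported",
           call. = FALSE)
    }
    if (!is.null(db_positions)) {
      stop("acyl chain '", token,
           "': double-bond position annotations are not supported",
           call. = FALSE)
    }
    if (!is.na(oh_position) && hydroxyls == 0L) {
      stop("acyl chain '", token, "': hydroxyl position without ';O'",
           call. = FALSE)
    }
    list(kind = "acyl", carbons = carbons, double_bonds = db,
         oxygens = NA_integer_, hydroxyls = hydroxyls,
         db_positions = NULL, oh_position = oh_position)
  }
}

chain_token <- function(chain) {
  base <- paste0(chain$carbons, ":", chain$double_bonds)
  if (!is.null(chain$db_positions) && length(chain$db_positions) > 0) {
    base <- paste0(base, "(",
                   paste0("d", sort(chain$db_positions), collapse = ","), ")")
  }
  if (chain$kind == "spb") {
    base <- paste0(base, ";O", chain$oxygens)
    if (!is.na(chain$oh_position)) {
      base <- paste0(base, "(", chain$oh_position, "OH)")
    }
  } else if (chain$kind == "acyl" && chain$hydroxyls > 0) {
    base <- paste0(base, ";O")
    if (!is.na(chain$oh_position)) {
      base <- paste0(base, "(", chain$oh_position, "OH)")
    }
  }
  base
}

# --- species parsing --------------------------------------------------------

#' Parse a lipid species shorthand name
#'
#' Understands sum-composition glycerolipids (`"PC 34:2"`), molecular
#' glycerolipids (`"PC 16:0_18:2"`), sphingolipids with a sphingoid base and
#' optional amide-linked fatty acid (`"SPB 18:1;O2"`,
#' `"HexCer 18:1;O2/24:0;O"`), and sterol conjugates
#' (`"SG sitosterol"`, `"SE cholesterol/16:0"`). Positional annotations are
#' captured when present — base double bonds `"(d4)"`/`"(d8)"`/`"(d4,d8)"`,
#' base C4 hydroxylation `";O3(4OH)"`, acyl C2 hydroxylation `";O(2OH)"` —
#' and recorded as unresolved otherwise, never imputed.
#'
#' @param name Shorthand name: subclass code, a space, then the chain part.
#' @param registry Subclass registry tibble; see [default_registry()].
#' @param steryl_pool Steryl residue pool; see [default_steryl_pool()].
#' @return An object of class `lipid_species`: a list with elements
#'   `subclass`, `category`, `level` (`"molecular"` or `"sum"`), `chains`
#'   (list of chain descriptors), `sum_carbons`/`sum_double_bonds` (sum
#'   level), `steryl` (sterol lipids) and the canonical `display_name`,
#'   which round-trips through this parser.
#' @examples
#' parse_species("PC 34:2")
#' parse_species("HexCer 18:1(d4);O2/24:0;O")
#' parse_species("SE cholesterol/16:0")
#' @export
parse_species <- function(name, registry = default_registry(),
                          steryl_pool = default_steryl_pool()) {
  if (!is.character(name) || length(name) != 1 || is.na(name)) {
    stop("species name must be a single string", call. = FALSE)
  }
  sp <- regmatches(name, regexec("^(\\S+) (\\S+)$", trimws(name)))[[1]]
  if (length(sp) == 0) {
    stop("malformed species name '", name,
         "' (expected '<SUBCLASS> <chains>')", call. = FALSE)
  }
  code <- sp[2]
  rest <- sp[3]
  entry <- registry_entry(registry, code)
  category <- entry$category

  out <- list(subclass = code, category = category, level = "molecular",
              chains = list(), sum_carbons = NA_integer_,
              sum_double_bonds = NA_integer_, steryl = NA_character_,
              display_name = NA_character_)

  if (category == "sterol_lipid") {
    parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
    steryl <- parts[1]
    if (!steryl %in% steryl_pool$name) {
      stop("unknown steryl residue '", steryl, "' in '", name, "'",
           call. = FALSE)
    }
    out$steryl <- steryl
    if (entry$n_chains == 0) {
      if (length(parts) != 1) {
        stop("'", code, "' carries no acyl chain but '", name, "' names one",
             call. = FALSE)
      }
    } else {
      if (length(parts) != 2) {
        stop("'", code, "' requires '<steryl>/<acyl>' in '", name, "'",
             call. = FALSE)
      }
      out$chains <- list(parse_chain_token(parts[2], "acyl"))
    }
  } else if (category == "sphingolipid") {
    parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
    if (length(parts) != entry$n_chains) {
      stop("'", code, "' expects ", entry$n_chains,
           " chain(s); got '", rest, "'", call. = FALSE)
    }
    chains <- list(parse_chain_token(parts[1], "spb"))
    if (entry$n_chains == 2) {
      chains[[2]] <- parse_chain_token(parts[2], "acyl")
    }
    out$chains <- chains
  } else {
    # glycerolipid families: molecular "_"-joined or sum composition
    if (grepl("_", rest, fixed = TRUE) || entry$n_chains == 1) {
      parts <- strsplit(rest, "_", fixed = TRUE)[[1]]
      if (length(parts) != entry$n_chains) {
        stop("'", code, "' expects ", entry$n_chains,
             " chain(s); got ", length(parts), " in '", name, "'",
             call. = FALSE)
      }
      out$chains <- lapply(parts, parse_chain_token, kind = "acyl")
    } else {
      ch <- parse_chain_token(rest, "acyl")
      if (ch$hydroxyls > 0) {
        stop("sum-composition species '", name,
             "' cannot carry hydroxyl annotations", call. = FALSE)
      }
      out$level <- "sum"
      out$sum_carbons <- ch$carbons
      out$sum_double_bonds <- ch$double_bonds
    }
  }

  out$display_name <- build_display_name(out)
  structure(out, class = "lipid_species")
}

build_display_name <- function(species) {
  code <- species$subclass
  if (species$category == "sterol_lipid") {
    if (length(species$chains) > 0) {
      paste0(code, " ", species$steryl, "/", chain_token(species$chains[[1]]))
    } else {
      paste0(code, " ", species$steryl)
    }
  } else if (species$category == "sphingolipid") {
    paste0(code, " ",
           paste(vapply(species$chains, chain_token, character(1)),
                 collapse = "/"))
  } else if (species$level == "sum") {
    paste0(code, " ", species$sum_carbons, ":", species$sum_double_bonds)
  } else {
    chains <- species$chains
    ord <- order(vapply(chains, `[[`, integer(1), "carbons"),
                 vapply(chains, `[[`, integer(1), "double_bonds"),
                 vapply(chains, `[[`, integer(1), "hydroxyls"))
    paste0(code, " ",
           paste(vapply(chains[ord], chain_token, character(1)),
                 collapse = "_"))
  }
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", x$display_name, "\n", sep = "")
  cat("  subclass: ", x$subclass, " (", x$category, "), level: ", x$level,
      "\n", sep = "")
  invisible(x)
}

# --- elemental formulas -----------------------------------------------------

empty_formula <- function() {
  stats::setNames(numeric(length(.ELEMENTS)), .ELEMENTS)
}

acyl_formula <- function(carbons, double_bonds, hydroxyls = 0L) {
  f <- empty_formula()
  f["C"] <- carbons
  f["H"] <- 2 * carbons - 2 * double_bonds
  f["O"] <- 2 + hydroxyls
  f
}

spb_formula <- function(carbons, double_bonds, oxygens) {
  f <- empty_formula()
  f["C"] <- carbons
  f["H"] <- 2 * carbons + 3 - 2 * double_bonds
  f["N"] <- 1
  f["O"] <- oxygens
  f
}

.H2O <- local({
  f <- stats::setNames(numeric(6), c("C", "H", "N", "O", "P", "S"))
  f["H"] <- 2
  f["O"] <- 1
  f
})

#' Elemental formula of a lipid species
#'
#' Assembles the neutral-molecule formula as backbone + headgroup +
#' chain residues (+ steryl residue for sterol lipids) minus one water per
#' condensation bond. For sphingolipids the sphingoid base is the backbone
#' itself, so it contributes no condensation water; its amide-linked fatty
#' acid and headgroup do. Sum-composition species are evaluated on a
#' canonical n-acyl skeleton carrying the summed carbons and double bonds
#' (an approximation: the elemental formula is independent of how the sum
#' composition is split across chains).
#'
#' @param species A `lipid_species` (from [parse_species()]) or a shorthand
#'   name string.
#' @inheritParams parse_species
#' @return Named numeric vector of element counts over C, H, N, O, P, S.
#' @examples
#' formula_of("PC 34:2")  # C42 H80 N O8 P
#' @export
formula_of <- function(species, registry = default_registry(),
                       steryl_pool = default_steryl_pool()) {
  if (is.character(species)) {
    species <- parse_species(species, registry, steryl_pool)
  }
  stopifnot(inherits(species, "lipid_species"))
  entry <- registry_entry(registry, species$subclass)

  f <- empty_formula()
  f[.ELEMENTS] <- as.numeric(entry[1, paste0("bb_", .ELEMENTS)])
  hg <- as.numeric(entry[1, paste0("hg_", .ELEMENTS)])
  head_present <- any(hg > 0)
  f <- f + hg

  if (species$category == "sterol_lipid") {
    i <- match(species$steryl, steryl_pool$name)
    f["C"] <- f["C"] + steryl_pool$C[i]
    f["H"] <- f["H"] + steryl_pool$H[i]
    f["O"] <- f["O"] + steryl_pool$O[i]
  }

  if (species$level == "sum") {
    f["C"] <- f["C"] + species$sum_carbons
    f["H"] <- f["H"] + 2 * species$sum_carbons - 2 * species$sum_double_bonds
    f["O"] <- f["O"] + 2 * entry$n_chains
  } else {
    for (ch in species$chains) {
      f <- f + if (ch$kind == "spb") {
        spb_formula(ch$carbons, ch$double_bonds, ch$oxygens)
      } else {
        acyl_formula(ch$carbons, ch$double_bonds, ch$hydroxyls)
      }
    }
  }

  n_bonds <- if (species$category == "sphingolipid") {
    (entry$n_chains - 1) + as.integer(head_present)
  } else {
    entry$n_chains + as.integer(head_present)
  }
  f <- f - n_bonds * .H2O
  if (any(f < 0)) {
    stop("negative element count assembling formula for '",
         species$display_name, "'", call. = FALSE)
  }
  f
}

#' Format an elemental formula as a Hill-style string
#'
#' @param formula Named numeric vector over C, H, N, O, P, S.
#' @return A string such as `"C42H80NO8P"`.
#' @export
formula_string <- function(formula) {
  parts <- vapply(.ELEMENTS, function(el) {
    n <- formula[[el]]
    if (is.na(n) || n == 0) return("")
    if (n == 1) el else paste0(el, n)
  }, character(1))
  paste(parts[nzchar(parts)], collapse = "")
}

#' Isotopic correction factor for natural 13C abundance
#'
#' Under an independent-atoms binomial model, the monoisotopic (all-12C)
#' peak carries a fraction (1 - p)^nC of a species' total signal, where p is
#' the natural 13C abundance and nC the number of carbon atoms. The
#' correction factor is the reciprocal, `(1 - p)^(-nC)`, and is multiplied
#' into measured monoisotopic peak areas to recover total-species abundance
#' (a type-I, M0-only correction; M+2 overlap between species is not
#' deconvoluted).
#'
#' @param x Either an elemental formula (named vector with a `"C"` entry),
#'   a `lipid_species`, a species name string, or directly a nonnegative
#'   carbon count.
#' @param p13c Natural 13C abundance as a probability; default 0.0107.
#' @inheritParams parse_species
#' @return Correction factor, a scalar `>= 1`.
#' @examples
#' icf(0)                 # 1
#' icf(formula_of("PC 34:2"))
#' @export
icf <- function(x, p13c = 0.0107, registry = default_registry(),
                steryl_pool = default_steryl_pool()) {
  if (!is.numeric(p13c) || length(p13c) != 1 || p13c < 0 || p13c >= 1) {
    stop("p13c must lie in [0, 1)", call. = FALSE)
  }
  nc <- if (is.character(x) || inherits(x, "lipid_species")) {
    formula_of(x, registry, steryl_pool)[["C"]]
  } else if (is.numeric(x) && !is.null(names(x)) && "C" %in% names(x)) {
    x[["C"]]
  } else if (is.numeric(x)) {
    x
  } else {
    stop("cannot interpret 'x' as a carbon count", call. = FALSE)
  }
  if (any(nc < 0)) stop("carbon count must be >= 0", call. = FALSE)
  (1 - p13c)^(-nc)
}

# --- vectorized species annotation -----------------------------------------

feature_status_spb <- function(ch) {
  # three-valued status for d4, d8, c4_hydroxyl on a sphingoid base
  db <- ch$double_bonds
  pos <- ch$db_positions
  status_db <- function(target) {
    if (db == 0) return("no")
    if (is.null(pos)) return("unresolved")
    if (target %in% pos) return("yes")
    if (length(pos) == db) "no" else "unresolved"
  }
  d4 <- status_db(4L)
  d8 <- status_db(8L)
  c4oh <- if (ch$oxygens == 2L) {
    "no"
  } else if (!is.na(ch$oh_position)) {
    if (ch$oh_position == 4L) "yes" else "no"
  } else if (d4 == "yes") {
    "no"  # mutually exclusive with the d4 double bond
  } else {
    "unresolved"
  }
  c(d4 = d4, d8 = d8, c4_hydroxyl = c4oh)
}

feature_status_acyl <- function(ch) {
  if (ch$hydroxyls == 0L) return("no")
  if (!is.na(ch$oh_position)) {
    if (ch$oh_position == 2L) "yes" else "no"
  } else {
    "unresolved"
  }
}

annotate_one_species <- function(name, registry, steryl_pool, p13c) {
  sp <- parse_species(name, registry, steryl_pool)
  f <- formula_of(sp, registry, steryl_pool)
  chains <- sp$chains
  is_spb <- vapply(chains, function(ch) ch$kind == "spb", logical(1))

  if (sp$level == "sum") {
    total_db <- sp$sum_double_bonds
  } else {
    total_db <- sum(vapply(chains, `[[`, integer(1), "double_bonds"))
  }

  d4 <- d8 <- c4 <- c2 <- "no"
  if (any(is_spb)) {
    st <- feature_status_spb(chains[[which(is_spb)[1]]])
    d4 <- st[["d4"]]; d8 <- st[["d8"]]; c4 <- st[["c4_hydroxyl"]]
  }
  acyls <- chains[!is_spb]
  if (sp$category == "sphingolipid" && length(acyls) > 0) {
    c2 <- feature_status_acyl(acyls[[1]])
  }
  vlcfa <- if (length(acyls) > 0 &&
               any(vapply(acyls, `[[`, integer(1), "carbons") >= 20)) {
    "yes"
  } else {
    "no"
  }

  tibble::tibble(
    species = sp$display_name, input_name = name, subclass = sp$subclass,
    category = sp$category, level = sp$level, total_double_bonds = total_db,
    n_carbons = f[["C"]], icf = icf(f, p13c = p13c),
    sat_class = if (total_db == 0) "saturated"
                else if (total_db == 1) "monounsaturated"
                else "polyunsaturated",
    d4_double_bond = d4, d8_double_bond = d8, c4_hydroxyl = c4,
    c2_acyl_hydroxyl = c2, vlcfa = vlcfa
  )
}

#' Annotate a vector of species names
#'
#' Parses each distinct name once and returns the per-species quantities the
#' quantification pipeline consumes: carbon count, isotopic correction
#' factor, total double bonds, saturation class, and three-valued
#' (`"yes"`/`"no"`/`"unresolved"`) sphingolipid modification statuses.
#'
#' @param names Character vector of shorthand species names.
#' @inheritParams parse_species
#' @param p13c Natural 13C abundance used for the correction factor.
#' @return A tibble with one row per distinct input name.
#' @export
species_info <- function(names, registry = default_registry(),
                         steryl_pool = default_steryl_pool(),
                         p13c = 0.0107) {
  uniq <- unique(names)
  key <- rlang::hash(list(uniq, registry, steryl_pool, p13c))
  if (is.null(.pollenomics_env$info_cache)) {
    .pollenomics_env$info_cache <- new.env(parent = emptyenv())
  }
  hit <- .pollenomics_env$info_cache[[key]]
  if (!is.null(hit)) return(hit)
  rows <- lapply(uniq, annotate_one_species, registry = registry,
                 steryl_pool = steryl_pool, p13c = p13c)
  out <- dplyr::bind_rows(rows)
  .pollenomics_env$info_cache[[key]] <- out
  out
}
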