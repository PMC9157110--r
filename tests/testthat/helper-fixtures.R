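# Shared fixtures built in code.

# minimal sample sheet: two conditions, n replicates each
toy_sheet <- function(conditions = c("RT3", "HS3+3"), n = 3) {
  tibble::tibble(
    sample_id = paste0(rep(conditions, each = n), "_r", seq_len(n)),
    condition = rep(conditions, each = n),
    replicate = rep(seq_len(n), length(conditions)))
}

# species-level area table (already transition-summed shape)
toy_species_areas <- function(sample_id, subclass, species, area) {
  tibble::tibble(sample_id = sample_id, subclass = subclass,
                 species = species, area = area)
}

# a random peak table over a fixed small species set
random_peak_table <- function(seed, n_samples = 4) {
  set.seed(seed)
  species <- c("PC 16:0_18:2", "PC 16:0_18:1", "PC 16:0_16:0",
               "DG 16:0_18:3", "DG 18:0_18:1",
               "HexCer 18:1(d4);O2/24:0", "HexCer 18:0;O3(4OH)/16:0",
               "SPB 18:1(d4);O2")
  subclass <- sub(" .*$", "", species)
  rows <- expand.grid(sample_id = paste0("s", seq_len(n_samples)),
                      i = seq_along(species), transition_id = c("t1", "t2"),
                      stringsAsFactors = FALSE)
  tibble::tibble(sample_id = rows$sample_id,
                 subclass = subclass[rows$i],
                 species = species[rows$i],
                 transition_id = rows$transition_id,
                 area = stats::rlnorm(nrow(rows), log(1000), 1))
}

# independent elemental-formula oracle used by the formula tests: assembles
# glycerolipid formulas from scratch (free fatty acids + glycerol +
# headgroup, minus condensation waters), sharing no code with the package
oracle_formula_glycerolipid <- function(head, n_chains, chains) {
  # chains: list of c(C, DB); head: named count vector over C,H,N,O,P,S
  f <- c(C = 3, H = 8, N = 0, O = 3, P = 0, S = 0)  # glycerol
  f <- f + head
  for (ch in chains) {
    f <- f + c(C = ch[1], H = 2 * ch[1] - 2 * ch[2], N = 0, O = 2,
               P = 0, S = 0)
  }
  waters <- n_chains + as.integer(any(head > 0))
  f - waters * c(C = 0, H = 2, N = 0, O = 1, P = 0, S = 0)
}
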