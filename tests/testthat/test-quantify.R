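test_that("isotopic correction multiplies areas by a sample-independent icf", {
  peaks <- tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    subclass = "DG",
    species = c("DG 34:2", "DG 34:2", "DG 34:2"),
    transition_id = c("t1", "t2", "t1"),
    area = c(0, 100, 100))
  out <- correct_areas(peaks)
  expect_equal(out$corrected_area[1], 0)  # zero stays zero
  # DG 34:2 has 37 carbons; hand value (1 - 0.0107)^-37
  expect_equal(out$corrected_area[2], 100 * 0.9893^-37, tolerance = 1e-12)
  expect_equal(out$icf[2], out$icf[3])  # same species, same factor
})

test_that("unknown species go to a rejects report, not silently dropped", {
  peaks <- tibble::tibble(
    sample_id = "s1", subclass = c("DG", "ZZ"),
    species = c("DG 34:2", "ZZ 1:0"), transition_id = "t1",
    area = c(10, 10))
  expect_warning(out <- correct_areas(peaks), "could not be quantified")
  expect_equal(nrow(out), 1)
  rej <- attr(out, "rejects")
  expect_equal(rej$species, "ZZ 1:0")
  expect_match(rej$reason, "unknown lipid subclass")
})

test_that("transition summation preserves totals (brute-force oracle)", {
  one <- tibble::tibble(sample_id = "s", subclass = "DG",
                        species = "DG 34:2",
                        transition_id = c("t1", "t2"),
                        area = c(30, 20), icf = 1,
                        corrected_area = c(30, 20))
  expect_equal(sum_transitions(one)$area, 50)

  tab <- random_peak_table(seed = 1)
  corr <- correct_areas(tab)
  summed <- sum_transitions(corr)
  # grand total preserved
  expect_equal(sum(summed$area), sum(corr$corrected_area))
  # per-key equality against an explicit loop
  for (i in sample(nrow(summed), 10)) {
    key <- summed[i, ]
    manual <- sum(corr$corrected_area[corr$sample_id == key$sample_id &
                                        corr$species == key$species])
    expect_equal(key$area, manual)
  }
})

test_that("subclass abundance normalizes to the reference-condition mean", {
  sheet <- toy_sheet(c("RT3", "HS3+3"), n = 2)
  areas <- toy_species_areas(
    sample_id = rep(sheet$sample_id, each = 1),
    subclass = "PC", species = "PC 34:2",
    area = c(150, 250, 500, 500))  # RT3 mean total = 200
  ab <- subclass_abundance(areas, sheet)
  expect_equal(ab$rel_abundance[ab$condition == "RT3"], c(0.75, 1.25))
  expect_equal(mean(ab$rel_abundance[ab$condition == "RT3"]), 1)
  expect_equal(ab$rel_abundance[ab$condition == "HS3+3"], c(2.5, 2.5))

  # all-identical totals give 1 everywhere
  flat <- toy_species_areas(sheet$sample_id, "PC", "PC 34:2", rep(7, 4))
  expect_true(all(subclass_abundance(flat, sheet)$rel_abundance == 1))

  # zero reference total is flagged
  zero <- toy_species_areas(sheet$sample_id, "PC", "PC 34:2",
                            c(0, 0, 5, 5))
  expect_warning(abz <- subclass_abundance(zero, sheet), "undefined")
  expect_true(all(is.na(abz$rel_abundance)))
})

test_that("mol% profiles sum to 100 and the >1% major rule is strict", {
  areas <- toy_species_areas(
    "s1", "PC", c("PC 34:2", "PC 34:1", "PC 32:0"), c(50, 30, 20))
  prof <- species_profile(areas)
  expect_equal(sort(prof$mol_pct, decreasing = TRUE), c(50, 30, 20))
  expect_equal(sum(prof$mol_pct), 100)

  single <- toy_species_areas("s1", "PC", "PC 34:2", 42)
  expect_equal(species_profile(single)$mol_pct, 100)

  # exactly 1.0% is excluded by the strict > threshold
  sheet <- tibble::tibble(sample_id = "s1", condition = "RT3",
                          replicate = 1)
  edge <- toy_species_areas(
    "s1", "PC", c("PC 34:2", "PC 34:1", "PC 32:0"), c(1, 1.5, 97.5))
  pe <- species_profile(edge, sheet)
  expect_false(pe$major[pe$species == "PC 34:2"])   # exactly 1%
  expect_true(pe$major[pe$species == "PC 34:1"])    # 1.5%
})

test_that("saturation fractions regroup abundances by total double bonds", {
  areas <- toy_species_areas(
    "s1", "PC", c("PC 34:2", "PC 34:1", "PC 32:0"), c(50, 30, 20))
  sat <- saturation_profile(areas)
  expect_equal(sat$polyunsaturated, 0.5)
  expect_equal(sat$monounsaturated, 0.3)
  expect_equal(sat$saturated, 0.2)

  allsat <- toy_species_areas("s1", "PC", c("PC 32:0", "PC 34:0"),
                              c(10, 5))
  expect_equal(saturation_profile(allsat)$saturated, 1)

  # random regroup oracle
  set.seed(3)
  tab <- sum_transitions(correct_areas(random_peak_table(seed = 3)))
  sat <- saturation_profile(tab)
  info <- species_info(unique(tab$species))
  merged <- merge(tab, info[, c("input_name", "sat_class")],
                  by.x = "species", by.y = "input_name")
  for (i in sample(nrow(sat), 5)) {
    sub <- merged[merged$sample_id == sat$sample_id[i] &
                    merged$subclass == sat$subclass[i], ]
    expect_equal(sat$saturated[i],
                 sum(sub$area[sub$sat_class == "saturated"]) / sum(sub$area))
  }
  expect_equal(sat$saturated + sat$monounsaturated + sat$polyunsaturated,
               rep(1, nrow(sat)))
})

test_that("modification occurrence is abundance-weighted with unresolved set aside", {
  areas <- toy_species_areas(
    "s1", "HexCer",
    c("HexCer 18:1(d4);O2/20:0", "HexCer 18:0;O3(4OH)/16:0"),
    c(60, 40))
  mod <- modification_occurrence(areas)
  get <- function(f) mod$pct[mod$modification == f]
  expect_equal(get("d4_double_bond"), 60)
  expect_equal(get("c4_hydroxyl"), 40)
  expect_equal(get("vlcfa"), 60)  # 20:0 counts, 16:0 does not

  # unresolved species leave the numerator and appear separately
  areas2 <- dplyr::bind_rows(
    areas, toy_species_areas("s1", "HexCer", "HexCer 18:1;O2/24:0", 100))
  mod2 <- modification_occurrence(areas2)
  expect_equal(mod2$pct[mod2$modification == "d4_double_bond"], 30)
  expect_equal(mod2$pct_unresolved[mod2$modification == "d4_double_bond"],
               50)

  # count weighting gives each species one vote
  modc <- modification_occurrence(areas, weight = "count")
  expect_equal(modc$pct[modc$modification == "d4_double_bond"], 50)

  # non-sphingolipids are not profiled
  none <- modification_occurrence(
    toy_species_areas("s1", "PC", "PC 34:2", 10))
  expect_equal(nrow(none), 0)
})

test_that("profiles are invariant to per-sample rescaling; totals scale", {
  tab <- random_peak_table(seed = 9)
  scaled <- tab
  k <- 3.7
  scaled$area[scaled$sample_id == "s1"] <-
    scaled$area[scaled$sample_id == "s1"] * k
  a1 <- sum_transitions(correct_areas(tab))
  a2 <- sum_transitions(correct_areas(scaled))
  p1 <- species_profile(a1); p2 <- species_profile(a2)
  expect_equal(p1$mol_pct, p2$mol_pct)
  expect_equal(saturation_profile(a1)[, -1],
               saturation_profile(a2)[, -1])
  expect_equal(modification_occurrence(a1)$pct,
               modification_occurrence(a2)$pct)
  t1 <- aggregate(area ~ sample_id, a1, sum)
  t2 <- aggregate(area ~ sample_id, a2, sum)
  expect_equal(t2$area[t2$sample_id == "s1"],
               k * t1$area[t1$sample_id == "s1"])
})

test_that("full pipeline on a toy table equals hand-computed values", {
  # two DG samples; icf values written out by hand: (1-0.0107)^-nC with
  # nC(DG 32:0) = 35, nC(DG 34:1) = 37, nC(DG 36:5) = 39
  sheet <- tibble::tibble(sample_id = c("s1", "s2"),
                          condition = c("RT3", "HS3+3"), replicate = 1L)
  peaks <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 4),
    subclass = "DG",
    species = rep(c("DG 16:0_16:0", "DG 16:0_16:0", "DG 16:0_18:1",
                    "DG 18:2_18:3"), 2),
    transition_id = rep(c("t1", "t2", "t1", "t1"), 2),
    area = c(100, 50, 200, 50, 200, 100, 100, 100))
  iA <- 0.9893^-35; iB <- 0.9893^-37; iC <- 0.9893^-39
  res <- run_pipeline(peaks, sheet)

  sa <- res$species_areas
  expect_equal(sa$area[sa$sample_id == "s1"][order(sa$species[sa$sample_id == "s1"])],
               c(150 * iA, 200 * iB, 50 * iC))
  tot1 <- 150 * iA + 200 * iB + 50 * iC
  tot2 <- 300 * iA + 100 * iB + 100 * iC
  ab <- res$abundance
  expect_equal(ab$rel_abundance[ab$sample_id == "s1"], 1)
  expect_equal(ab$rel_abundance[ab$sample_id == "s2"], tot2 / tot1)
  p <- res$profile
  expect_equal(p$mol_pct[p$sample_id == "s1" & p$species == "DG 16:0_18:1"],
               100 * 200 * iB / tot1)
  s <- res$saturation
  expect_equal(s$saturated[s$sample_id == "s2"], 300 * iA / tot2)
  expect_equal(s$monounsaturated[s$sample_id == "s2"], 100 * iB / tot2)
  expect_equal(s$polyunsaturated[s$sample_id == "s2"], 100 * iC / tot2)
})
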