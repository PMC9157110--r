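make_counts <- function(seed = 1, n_genes = 100, n_samples = 6) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_genes * n_samples, mu = 50, size = 2),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m
}

test_that("CPM filter applies the strict >0.5-in->=2-libraries rule", {
  m <- matrix(0, 3, 4, dimnames = list(c("zero", "edge", "keep"),
                                       paste0("s", 1:4)))
  m["keep", ] <- 100
  # library sizes ~ 100 per sample from "keep"; make exact CPM boundaries:
  # with lib size 1e6 per library, CPM == count
  m <- rbind(m, filler = 0)
  lib <- rep(1e6, 4)
  m["edge", ] <- 0.5   # CPM exactly 0.5 everywhere: excluded
  m["filler", ] <- 1e6 - colSums(m)  # force exact library sizes
  kept <- cpm_filter(m, lib_size = lib)
  expect_false("zero" %in% kept)
  expect_false("edge" %in% kept)
  expect_true("keep" %in% kept)

  above <- m
  above["edge", 1:2] <- 0.6  # >0.5 in exactly 2 libraries: retained
  expect_true("edge" %in% cpm_filter(above, lib_size = lib))
  above["edge", 2] <- 0.5    # only 1 library above: dropped
  expect_false("edge" %in% cpm_filter(above, lib_size = lib))
})

test_that("CPM filter equals the per-gene brute force and is idempotent", {
  m <- make_counts(seed = 4)
  kept <- cpm_filter(m)
  lib <- colSums(m)
  manual <- rownames(m)[vapply(rownames(m), function(g) {
    sum(m[g, ] / lib * 1e6 > 0.5) >= 2
  }, logical(1))]
  expect_setequal(kept, manual)
  # idempotence: refiltering the filtered matrix changes nothing
  expect_setequal(cpm_filter(m[kept, ]), kept)
  expect_error(cpm_filter(cbind(m, bad = 0)), "> 0")
})

test_that("cpm and rpkm match the edgeR oracle", {
  m <- make_counts(seed = 6)
  expect_equal(cpm(m), edgeR::cpm(m, lib.size = colSums(m)),
               tolerance = 1e-12, ignore_attr = TRUE)
  len <- stats::setNames(sample(200:3000, nrow(m)), rownames(m))
  oracle <- edgeR::rpkm(m, gene.length = len, lib.size = colSums(m))
  expect_equal(rpkm(m, len), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("RPKM follows the count/kb/million formula", {
  m <- matrix(c(10, 0), 2, 1, dimnames = list(c("a", "b"), "s"))
  r <- rpkm(m, c(a = 1000, b = 500), lib_size = 1e6)
  expect_equal(r["a", "s"], 10)
  expect_equal(r["b", "s"], 0)
  r2 <- rpkm(m, c(a = 2000, b = 500), lib_size = 1e6)
  expect_equal(r2["a", "s"], 5)  # doubling length halves RPKM
  expect_error(rpkm(m, c(a = 1000, b = -1), lib_size = 1e6), "> 0")
})

test_that("GO-term scores sum member RPKMs (exhaustive oracle)", {
  sheet <- toy_sheet(c("RT6", "HS3+3"), n = 3)
  set.seed(10)
  r <- matrix(stats::rlnorm(60, 2), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sheet$sample_id))
  # overlapping terms: GO:1 holds genes 1-7, GO:2 holds genes 5-10
  go <- tibble::tibble(
    gene = c(rownames(r)[1:7], rownames(r)[5:10]),
    go_id = rep(c("GO:1", "GO:2"), c(7, 6)))[sample(13), ]
  q <- go_quant(r, go, sheet, "RT6", "HS3+3")
  for (term in unique(go$go_id)) {
    genes <- go$gene[go$go_id == term]
    manual_a <- mean(vapply(sheet$sample_id[sheet$condition == "RT6"],
                            function(s) sum(r[genes, s]), numeric(1)))
    expect_equal(q$mean_a[q$go_id == term], manual_a)
  }
})

test_that("GO log2FC and p behave on constructed inputs", {
  sheet <- toy_sheet(c("RT6", "HS3+3"), n = 3)
  # identical scores: log2FC 0, p = 1
  r <- matrix(5, 1, 6, dimnames = list("g1", sheet$sample_id))
  go <- tibble::tibble(gene = "g1", go_id = "GO:x")
  q <- go_quant(r, go, sheet, "RT6", "HS3+3")
  expect_equal(q$log2fc, 0)
  expect_equal(q$p_value, 1)

  # every member doubled: log2FC exactly 1
  r2 <- matrix(rep(c(3, 7, 11), 4), 2, 6, byrow = TRUE,
               dimnames = list(c("g1", "g2"), sheet$sample_id))
  r2[, sheet$condition == "HS3+3"] <- 2 * r2[, sheet$condition == "RT6"]
  go2 <- tibble::tibble(gene = c("g1", "g2"), go_id = "GO:x")
  q2 <- go_quant(r2, go2, sheet, "RT6", "HS3+3")
  expect_equal(q2$log2fc, 1)

  # additivity: scores of two disjoint halves sum to the whole
  set.seed(12)
  r3 <- matrix(stats::rlnorm(36), 6, 6,
               dimnames = list(sprintf("g%d", 1:6), sheet$sample_id))
  whole <- tibble::tibble(gene = rownames(r3), go_id = "GO:w")
  h1 <- tibble::tibble(gene = rownames(r3)[1:3], go_id = "GO:h1")
  h2 <- tibble::tibble(gene = rownames(r3)[4:6], go_id = "GO:h2")
  qa <- go_quant(r3, dplyr::bind_rows(whole, h1, h2), sheet,
                 "RT6", "HS3+3")
  expect_equal(qa$mean_a[qa$go_id == "GO:w"],
               qa$mean_a[qa$go_id == "GO:h1"] +
                 qa$mean_a[qa$go_id == "GO:h2"])

  # DEG tallies inside terms use the strict thresholds
  de <- tibble::tibble(gene = c("g1", "g2"), log2fc = c(2, 1),
                       fdr = c(1e-6, 1e-6))
  q4 <- go_quant(r2, go2, sheet, "RT6", "HS3+3", de_table = de)
  expect_equal(q4$n_up, 1)  # log2fc exactly 1 excluded
  expect_equal(q4$n_down, 0)
})

test_that("gene-set tallies count strict-threshold DEGs and absences", {
  de <- tibble::tibble(gene = c("a", "b", "c", "d"),
                       log2fc = c(2, -2, 0.5, 1),
                       fdr = c(1e-6, 1e-6, 1e-6, 1e-6))
  sets <- tibble::tibble(gene = c("a", "b", "c", "e"),
                         set = c("fam1", "fam1", "fam1", "fam1"))
  tal <- gene_set_tally(de, sets)
  expect_equal(tal$detected, 3)
  expect_equal(tal$up, 1)
  expect_equal(tal$down, 1)
  expect_equal(tal$missing, 1)

  # boundary: log2fc exactly 1 and fdr exactly 0.005 are excluded
  de2 <- tibble::tibble(gene = c("a", "b"), log2fc = c(1, 2),
                        fdr = c(1e-6, 0.005))
  tal2 <- gene_set_tally(de2, tibble::tibble(gene = c("a", "b"),
                                             set = "s"))
  expect_equal(tal2$up, 0)

  empty <- gene_set_tally(de, tibble::tibble(gene = "zz", set = "none"))
  expect_equal(c(empty$detected, empty$up, empty$down), c(0, 0, 0))
})
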