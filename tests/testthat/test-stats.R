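test_that("one-way ANOVA matches the hand sums-of-squares fixture", {
  fit <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4),
                            c = c(3, 4, 5)))
  expect_equal(fit$F, 3.0)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 6)
  expect_equal(fit$p, stats::pf(3, 2, 6, lower.tail = FALSE))

  # equal means with spread: F = 0
  z <- one_way_anova(list(a = c(-1, 0, 1), b = c(-1, 0, 1)))
  expect_equal(z$F, 0)

  # all values identical: degenerate, flagged
  d <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_true(d$degenerate)
  expect_true(is.na(d$F))
})

test_that("two-group ANOVA F equals the pooled t statistic squared", {
  set.seed(14)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(6, 0.5)
    fit <- one_way_anova(list(a = a, b = b))
    tt <- two_sample_t(a, b)
    expect_equal(fit$F, tt$t^2, tolerance = 1e-10)
    expect_equal(fit$p, tt$p, tolerance = 1e-10)
  }
})

test_that("ANOVA agrees with the stats::aov oracle on random data", {
  set.seed(8)
  for (i in 1:5) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:7, 1), j / 2))
    names(groups) <- paste0("g", seq_len(k))
    df <- data.frame(y = unlist(groups),
                     g = rep(names(groups), lengths(groups)))
    oracle <- summary(stats::aov(y ~ g, df))[[1]]
    fit <- one_way_anova(groups)
    expect_equal(fit$F, oracle$`F value`[1], tolerance = 1e-10)
    expect_equal(fit$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("Tukey HSD reproduces the worked fixture and the TukeyHSD oracle", {
  groups <- list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(10, 11, 12))
  tk <- tukey_hsd(groups)
  # hand arithmetic: MSE = 1, q(A,C) = 9 / sqrt(1/3) = 15.588
  qac <- tk$q[tk$group1 == "A" & tk$group2 == "C"]
  expect_equal(qac, 9 / sqrt(1 / 3), tolerance = 1e-10)
  expect_equal(round(qac, 3), 15.588)
  expect_equal(tk$p_adj[tk$group1 == "A" & tk$group2 == "C"],
               stats::ptukey(15.588457, 3, 6, lower.tail = FALSE),
               tolerance = 1e-6)

  # oracle: stats::TukeyHSD on the same data
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), each = 3)))
  oracle <- stats::TukeyHSD(stats::aov(y ~ g, df))$g
  for (r in seq_len(nrow(tk))) {
    key <- paste0(tk$group2[r], "-", tk$group1[r])
    expect_equal(tk$p_adj[r], oracle[key, "p adj"], tolerance = 1e-8)
  }

  # adjusted p never below the unadjusted pairwise t p on a contrast
  pt <- two_sample_t(groups$A, groups$B)$p
  expect_gte(tk$p_adj[tk$group1 == "A" & tk$group2 == "B"], pt)
})

test_that("Tukey handles unbalanced groups (Tukey-Kramer) and degeneracy", {
  set.seed(2)
  groups <- list(a = rnorm(4), b = rnorm(6, 1), c = rnorm(5, 2))
  tk <- tukey_hsd(groups)
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(names(groups), lengths(groups))))
  oracle <- stats::TukeyHSD(stats::aov(y ~ g, df))$g
  for (r in seq_len(nrow(tk))) {
    key <- paste0(tk$group2[r], "-", tk$group1[r])
    expect_equal(tk$p_adj[r], oracle[key, "p adj"], tolerance = 1e-8)
  }

  expect_warning(dg <- tukey_hsd(list(a = c(1, 1), b = c(1, 1),
                                      c = c(2, 2))),
                 "degenerate")
  expect_equal(dg$p_adj[dg$group1 == "a" & dg$group2 == "b"], 1)
  expect_equal(dg$p_adj[dg$group1 == "a" & dg$group2 == "c"], 0)

  same <- suppressWarnings(tukey_hsd(list(a = c(1, 1), b = c(1, 1))))
  expect_true(all(same$p_adj == 1))
})

test_that("compact letter display encodes exactly the non-significances", {
  mk <- function(v, groups = as.character(seq_len(nrow(v)))) {
    dimnames(v) <- list(groups, groups); v
  }
  # no significant pair: single letter
  p <- mk(matrix(1, 3, 3))
  expect_equal(unname(compact_letter_display(p)), c("a", "a", "a"))
  # all pairs significant: distinct letters
  p <- mk(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3))
  expect_equal(unname(compact_letter_display(p)), c("a", "b", "c"))
  # only (1,3) significant: chain a / ab / b
  p <- mk(matrix(c(1, .5, .01, .5, 1, .5, .01, .5, 1), 3))
  expect_equal(unname(compact_letter_display(p)), c("a", "ab", "b"))
})

test_that("letters are valid for random p matrices (brute-force check)", {
  for (seed in 1:100) {
    set.seed(seed)
    k <- sample(3:6, 1)
    p <- matrix(1, k, k, dimnames = list(letters[1:k], letters[1:k]))
    vals <- runif(k * (k - 1) / 2)
    p[upper.tri(p)] <- vals
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    cld <- compact_letter_display(p, alpha = 0.3)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        share <- length(intersect(strsplit(cld[i], "")[[1]],
                                  strsplit(cld[j], "")[[1]])) > 0
        expect_equal(share, p[i, j] >= 0.3,
                     info = sprintf("seed %d pair %d-%d", seed, i, j))
      }
    }
  }
})

test_that("letter ordering follows descending group means", {
  p <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("lo", "hi"),
                                                c("lo", "hi")))
  cld <- compact_letter_display(p, means = c(lo = 1, hi = 10))
  expect_equal(cld[["hi"]], "a")
  expect_equal(cld[["lo"]], "b")
})

test_that("Student's t and star coding behave at the boundaries", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  sep <- two_sample_t(c(0, 0, 0), c(1, 1, 1))
  expect_equal(sep$p, 0)
  expect_equal(sep$stars, "***")
  expect_equal(p_stars(c(0.004, 0.007, 0.03, 0.2)),
               c("***", "**", "*", ""))
  # Welch variant differs under heteroscedasticity
  set.seed(1)
  a <- rnorm(5); b <- rnorm(20, 1, 4)
  expect_false(isTRUE(all.equal(two_sample_t(a, b)$p,
                                two_sample_t(a, b, "welch")$p)))
})

test_that("pooled t p agrees with the exact permutation oracle", {
  diffs <- numeric(20)
  for (seed in 1:20) {
    set.seed(seed + 100)
    a <- rnorm(6); b <- rnorm(6, 0.8)
    obs <- abs(two_sample_t(a, b)$t)
    pool <- c(a, b)
    idx <- utils::combn(12, 6)
    tperm <- apply(idx, 2, function(ii) {
      abs(two_sample_t(pool[ii], pool[-ii])$t)
    })
    p_perm <- mean(tperm >= obs - 1e-12)
    diffs[seed] <- abs(two_sample_t(a, b)$p - p_perm)
  }
  expect_lt(mean(diffs), 0.05)
  expect_lt(max(diffs), 0.15)
})

test_that("fold changes report ratio and log2 with reciprocal identity", {
  expect_equal(fold_change(c(2, 2), c(2, 2))$ratio, 1)
  expect_equal(fold_change(c(2, 2), c(2, 2))$log2_ratio, 0)
  fc <- fold_change(c(570, 590), c(95, 105))
  expect_equal(fc$ratio, 5.8)
  r1 <- fold_change(c(3, 5), c(7, 9))$ratio
  r2 <- fold_change(c(7, 9), c(3, 5))$ratio
  expect_equal(r1 * r2, 1)
  expect_warning(und <- fold_change(c(1, 2), c(0, 0)), "undefined")
  expect_true(is.na(und$ratio))
})

test_that("condition_stats assembles letters consistent with Tukey", {
  sheet <- toy_sheet(c("RT3", "RT6", "HS3+3"), n = 4)
  set.seed(33)
  df <- tibble::tibble(
    sample_id = sheet$sample_id,
    subclass = "PC",
    value = c(rnorm(4, 0), rnorm(4, 0.2), rnorm(4, 8)))
  st <- condition_stats(df, "value", "subclass", sheet)
  expect_equal(nrow(st), 3)
  # the clearly separated condition gets its own letter
  hs <- st$letters[st$condition == "HS3+3"]
  others <- st$letters[st$condition != "HS3+3"]
  expect_false(any(grepl(hs, others, fixed = TRUE)))
  expect_equal(st$letters[st$condition == "RT3"],
               st$letters[st$condition == "RT6"])
})
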