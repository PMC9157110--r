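# Condition statistics: one-way ANOVA, post hoc Tukey HSD, compact letter
# display, Student's t with star coding, fold changes.

as_group_list <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 numeric group vectors", call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects between/within sums-of-squares decomposition;
#' the p-value comes from the F distribution with (k - 1, N - k) degrees of
#' freedom.
#'
#' @param groups Named list of numeric vectors, one per condition, each of
#'   length >= 2.
#' @return List with `F`, `p`, `df1`, `df2`, `ms_within`, `means`, `n`, and
#'   `degenerate` (`TRUE` when the within-group variance is zero and all
#'   means are equal, leaving F undefined; then `F` and `p` are `NA`).
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))$F  # 3
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  n <- lengths(groups)
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df1 <- k - 1
  df2 <- N - k
  ms_within <- ss_within / df2
  if (ms_within == 0 && ss_between == 0) {
    return(list(F = NA_real_, p = NA_real_, df1 = df1, df2 = df2,
                ms_within = 0, means = means, n = n, degenerate = TRUE))
  }
  f <- (ss_between / df1) / ms_within
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ms_within = ms_within, means = means, n = n,
       degenerate = FALSE)
}

#' Tukey (Tukey-Kramer) honestly-significant-difference post hoc test
#'
#' For each pair of groups the studentized-range statistic
#' q = |mean_i - mean_j| / sqrt(MSE/2 (1/n_i + 1/n_j)) is referred to the
#' studentized range distribution with k groups and N - k error degrees of
#' freedom. Unbalanced designs use the Tukey-Kramer harmonic form above.
#' With zero error variance the test degenerates: p = 0 for unequal means,
#' p = 1 for equal means (flagged).
#'
#' @inheritParams one_way_anova
#' @return Tibble with columns `group1`, `group2`, `diff` (mean2 - mean1),
#'   `q`, `p_adj`; attributes `ms_within` and `degenerate`.
#' @export
tukey_hsd <- function(groups) {
  groups <- as_group_list(groups)
  fit <- one_way_anova(groups)
  k <- length(groups)
  pairs <- utils::combn(names(groups), 2)
  mse <- fit$ms_within
  degenerate <- mse == 0
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    d <- fit$means[[j]] - fit$means[[i]]
    if (degenerate) {
      q <- if (d == 0) 0 else Inf
      p <- if (d == 0) 1 else 0
    } else {
      se <- sqrt(mse / 2 * (1 / fit$n[[i]] + 1 / fit$n[[j]]))
      q <- abs(d) / se
      p <- stats::ptukey(q, nmeans = k, df = fit$df2, lower.tail = FALSE)
    }
    tibble::tibble(group1 = i, group2 = j, diff = d, q = q, p_adj = p)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "ms_within") <- mse
  attr(out, "degenerate") <- degenerate
  if (degenerate) {
    warning("zero within-group variance: Tukey p-values are degenerate",
            call. = FALSE)
  }
  out
}

pairwise_matrix <- function(tukey, groups = NULL) {
  gs <- if (is.null(groups)) unique(c(tukey$group1, tukey$group2)) else groups
  m <- matrix(1, length(gs), length(gs), dimnames = list(gs, gs))
  for (r in seq_len(nrow(tukey))) {
    m[tukey$group1[r], tukey$group2[r]] <- tukey$p_adj[r]
    m[tukey$group2[r], tukey$group1[r]] <- tukey$p_adj[r]
  }
  m
}

#' Compact letter display of all pairwise comparisons
#'
#' Insert-and-absorb letter assignment: two groups share at least one
#' letter if and only if they are not significantly different at `alpha`.
#' Letters are ordered a, b, c, ... over groups sorted by descending group
#' mean (ties by input order); without means the input order is used.
#'
#' @param p Symmetric matrix of adjusted pairwise p-values with group
#'   dimnames, or the tibble returned by [tukey_hsd()].
#' @param alpha Significance level; default 0.05.
#' @param means Optional named vector of group means used to order letters.
#' @return Named character vector: group -> letter string (e.g. `"ab"`).
#' @examples
#' p <- matrix(c(1, .3, .01, .3, 1, .2, .01, .2, 1), 3,
#'             dimnames = list(1:3, 1:3))
#' compact_letter_display(p)
#' @export
compact_letter_display <- function(p, alpha = 0.05, means = NULL) {
  if (is.data.frame(p)) p <- pairwise_matrix(p)
  if (!is.matrix(p) || nrow(p) != ncol(p) ||
      is.null(rownames(p)) || !isTRUE(all.equal(p, t(p)))) {
    stop("p must be a symmetric matrix with group dimnames", call. = FALSE)
  }
  orig <- rownames(p)
  gs <- orig
  if (!is.null(means)) {
    gs <- gs[order(-as.numeric(means[gs]), seq_along(gs))]
    p <- p[gs, gs, drop = FALSE]
  }
  n <- length(gs)
  # columns = letters, as a list of logical membership vectors
  cols <- list(rep(TRUE, n))
  sig <- which(p < alpha & upper.tri(p), arr.ind = TRUE)
  if (nrow(sig) > 0) {
    for (r in seq_len(nrow(sig))) {
      i <- sig[r, 1]; j <- sig[r, 2]
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          newcols <- c(newcols, list(a, b))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(newcols))
      for (x in seq_along(newcols)) {
        for (y in seq_along(newcols)) {
          if (x != y && keep[x] &&
              all(newcols[[x]] <= newcols[[y]]) &&
              (any(newcols[[x]] < newcols[[y]]) || x > y)) {
            keep[x] <- FALSE
            break
          }
        }
      }
      cols <- newcols[keep]
    }
  }
  # order letters by first member group, then assign a, b, c, ...
  first <- vapply(cols, function(col) which(col)[1], integer(1))
  cols <- cols[order(first)]
  if (length(cols) > 26) stop("more than 26 letters needed", call. = FALSE)
  lab <- letters[seq_along(cols)]
  out <- vapply(seq_len(n), function(i) {
    paste(lab[vapply(cols, `[`, logical(1), i)], collapse = "")
  }, character(1))
  stats::setNames(out, gs)[orig]
}

#' Two-sample t test with star coding
#'
#' Student's pooled-variance two-sided t test by default (`variant =
#' "welch"` gives the unequal-variance form). Stars follow the coding
#' * P < 0.05, ** P < 0.01, *** P < 0.005.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param variant `"student"` (pooled, default) or `"welch"`.
#' @return List with `t`, `p`, `df`, `stars`. Zero pooled variance with
#'   equal means yields t = 0, p = 1; with unequal means p = 0.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- mean(a) == mean(b)
    t <- if (equal) 0 else sign(mean(a) - mean(b)) * Inf
    p <- if (equal) 1 else 0
    df <- length(a) + length(b) - 2
  } else {
    ht <- stats::t.test(a, b, var.equal = variant == "student")
    t <- unname(ht$statistic)
    p <- ht$p.value
    df <- unname(ht$parameter)
  }
  list(t = t, p = p, df = df, stars = p_stars(p))
}

#' Star coding of p-values
#'
#' `***` P < 0.005, `**` P < 0.01, `*` P < 0.05, `""` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.005, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Fold change of condition means
#'
#' @param a,b Numeric vectors; the ratio is `mean(a) / mean(b)`.
#' @return List with `ratio` and `log2_ratio`; `mean(b) == 0` yields `NA`
#'   with a warning.
#' @export
fold_change <- function(a, b) {
  ma <- mean(as.numeric(a)); mb <- mean(as.numeric(b))
  if (is.na(mb) || mb == 0) {
    warning("denominator condition mean is zero; fold change undefined",
            call. = FALSE)
    return(list(ratio = NA_real_, log2_ratio = NA_real_))
  }
  r <- ma / mb
  list(ratio = r, log2_ratio = log2(r))
}

#' Per-feature condition statistics with compact letter display
#'
#' For every feature in a tidy table, computes per-condition means, SDs and
#' n, the one-way ANOVA F and p, Tukey HSD adjusted pairwise p-values, and
#' the compact letter display at level `alpha`. Features whose ANOVA is
#' degenerate (all values identical) get all-"a" letters and `NA` F/p.
#'
#' @param data Tidy tibble containing one value per sample and feature.
#' @param value Name of the numeric value column.
#' @param feature Name(s) of the column(s) identifying a feature (e.g.
#'   `c("subclass")` or `c("subclass", "species")`).
#' @param sheet Sample sheet with `sample_id`, `condition` (joined on
#'   `sample_id` unless `data` already has a `condition` column).
#' @param alpha Significance level for the letter display; default 0.05.
#' @return A tibble with one row per feature and condition: group mean, sd,
#'   n, the feature-level `F` and `p_anova`, and `letters`.
#' @export
condition_stats <- function(data, value, feature, sheet = NULL,
                            alpha = 0.05) {
  if (!"condition" %in% names(data)) {
    if (is.null(sheet)) stop("need 'condition' column or a sample sheet",
                             call. = FALSE)
    assert_sample_sheet(sheet)
    data <- dplyr::inner_join(data, sheet[, c("sample_id", "condition")],
                              by = "sample_id")
  }
  split_keys <- interaction(data[feature], drop = TRUE, sep = " / ")
  pieces <- split(data, split_keys)
  out <- lapply(pieces, function(piece) {
    groups <- split(piece[[value]], piece$condition)
    groups <- groups[lengths(groups) > 0]
    base <- piece |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(feature, "condition")))) |>
      dplyr::summarise(mean = mean(.data[[value]]),
                       sd = stats::sd(.data[[value]]),
                       n = dplyr::n(), .groups = "drop")
    if (length(groups) < 2 || any(lengths(groups) < 2) ||
        anyNA(unlist(groups))) {
      base$F <- NA_real_; base$p_anova <- NA_real_
      base$letters <- NA_character_
      return(base)
    }
    fit <- one_way_anova(groups)
    if (isTRUE(fit$degenerate)) {
      base$F <- NA_real_; base$p_anova <- NA_real_
      base$letters <- "a"
      return(base)
    }
    tk <- suppressWarnings(tukey_hsd(groups))
    cld <- compact_letter_display(pairwise_matrix(tk), alpha = alpha,
                                  means = fit$means)
    base$F <- fit$F
    base$p_anova <- fit$p
    base$letters <- unname(cld[base$condition])
    base
  })
  dplyr::bind_rows(out)
}
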