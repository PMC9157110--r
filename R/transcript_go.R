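# Transcript-level aggregation statistics: CPM detection filter, RPKM,
# GO-term summed-RPKM fold changes, and gene-set DEG tallies. Differential
# expression itself is an input (externally fitted flags), not computed
# here.

assert_counts <- function(counts, lib_size = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be nonnegative and complete", call. = FALSE)
  }
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) {
    stop("library sizes must be > 0 (zero-sum library present)",
         call. = FALSE)
  }
  list(counts = counts, lib_size = lib_size)
}

#' Counts per million
#'
#' @param counts Gene x sample matrix of nonnegative raw counts.
#' @param lib_size Optional per-sample library sizes ("mapped reads");
#'   default the column sums of `counts`.
#' @return Matrix of CPM values, same dimensions as `counts`.
#' @export
cpm <- function(counts, lib_size = NULL) {
  v <- assert_counts(counts, lib_size)
  sweep(v$counts, 2, v$lib_size / 1e6, "/")
}

#' CPM detection filter
#'
#' A gene is retained when its CPM strictly exceeds `min_cpm` in at least
#' `min_libs` libraries (default: more than 0.5 CPM in at least 2
#' libraries). The filter is idempotent: the retained set is unchanged when
#' re-filtered with the same library sizes, which is why the original
#' library sizes are used unless overridden.
#'
#' @inheritParams cpm
#' @param min_cpm CPM a gene must strictly exceed; default 0.5.
#' @param min_libs Number of libraries in which it must do so; default 2.
#' @return Character vector of retained gene names.
#' @export
cpm_filter <- function(counts, min_cpm = 0.5, min_libs = 2,
                       lib_size = NULL) {
  x <- cpm(counts, lib_size)
  keep <- rowSums(x > min_cpm) >= min_libs
  rownames(x)[keep]
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM = count / (gene length in kb) / (library size in millions).
#'
#' @inheritParams cpm
#' @param lengths Named numeric vector of gene lengths in bp (> 0),
#'   covering every gene in `counts`.
#' @return Matrix of RPKM values, same dimensions as `counts`.
#' @examples
#' m <- matrix(10, 1, 1, dimnames = list("g", "s"))
#' rpkm(m, c(g = 1000), lib_size = 1e6)  # 10
#' @export
rpkm <- function(counts, lengths, lib_size = NULL) {
  v <- assert_counts(counts, lib_size)
  counts <- v$counts
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts)) {
      stop("unnamed lengths must match nrow(counts)", call. = FALSE)
    }
    names(lengths) <- rownames(counts)
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0) {
    stop("gene lengths missing for ", length(missing), " genes (e.g. ",
         missing[1], ")", call. = FALSE)
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  sweep(counts / (len / 1000), 2, v$lib_size / 1e6, "/")
}

#' GO-term summed-RPKM quantification between two conditions
#'
#' For every GO term, the RPKM values of all member genes present in the
#' matrix are summed per sample; the per-sample term scores are averaged
#' per condition, log2FC = log2(mean_b / mean_a) (a the earlier condition),
#' and a two-sided Student's t test on the per-sample scores gives the
#' p-value. When a differential-expression table is supplied, the number of
#' member genes whose external DE call passes log2FC > `fc_threshold`
#' (up) or < -`fc_threshold` (down) with FDR < `fdr_threshold` is tallied
#' per term.
#'
#' @param rpkm_mat Gene x sample RPKM matrix (see [rpkm()]).
#' @param go_map Tibble/data frame with columns `gene`, `go_id`.
#' @param sheet Sample sheet with `sample_id`, `condition`.
#' @param condition_a,condition_b The two conditions; `condition_a` is the
#'   earlier one and forms the denominator of the fold change.
#' @param de_table Optional externally computed DE table with columns
#'   `gene`, `log2fc`, `fdr`.
#' @param fc_threshold,fdr_threshold DEG thresholds, strict inequalities;
#'   defaults 1 and 0.005.
#' @return Tibble per GO term: `go_id`, `n_genes` (detected member genes),
#'   `mean_a`, `mean_b`, `log2fc`, `p_value`, and `n_up`/`n_down` when
#'   `de_table` is given. Terms with a zero denominator mean get `NA`
#'   log2FC and a warning.
#' @export
go_quant <- function(rpkm_mat, go_map, sheet, condition_a, condition_b,
                     de_table = NULL, fc_threshold = 1,
                     fdr_threshold = 0.005) {
  assert_sample_sheet(sheet)
  stopifnot(all(c("gene", "go_id") %in% names(go_map)))
  a_samples <- sheet$sample_id[sheet$condition == condition_a]
  b_samples <- sheet$sample_id[sheet$condition == condition_b]
  if (length(a_samples) < 2 || length(b_samples) < 2) {
    stop("each condition needs >= 2 samples", call. = FALSE)
  }
  if (!all(c(a_samples, b_samples) %in% colnames(rpkm_mat))) {
    stop("sample sheet names samples absent from the RPKM matrix",
         call. = FALSE)
  }
  go_map <- go_map[go_map$gene %in% rownames(rpkm_mat), ]
  terms <- split(go_map$gene, go_map$go_id)
  rows <- lapply(names(terms), function(id) {
    genes <- unique(terms[[id]])
    score <- colSums(rpkm_mat[genes, c(a_samples, b_samples),
                              drop = FALSE])
    sa <- score[a_samples]; sb <- score[b_samples]
    ma <- mean(sa); mb <- mean(sb)
    lfc <- if (ma == 0) NA_real_ else log2(mb / ma)
    p <- if (stats::var(sa) == 0 && stats::var(sb) == 0) {
      if (ma == mb) 1 else 0
    } else {
      two_sample_t(sb, sa)$p
    }
    tibble::tibble(go_id = id, n_genes = length(genes), mean_a = ma,
                   mean_b = mb, log2fc = lfc, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (anyNA(out$log2fc)) {
    warning("log2FC undefined for terms with zero mean in the denominator ",
            "condition", call. = FALSE)
  }
  if (!is.null(de_table)) {
    stopifnot(all(c("gene", "log2fc", "fdr") %in% names(de_table)))
    de_counts <- lapply(names(terms), function(id) {
      genes <- unique(terms[[id]])
      de <- de_table[de_table$gene %in% genes, ]
      sig <- de$fdr < fdr_threshold
      tibble::tibble(go_id = id,
                     n_up = sum(sig & de$log2fc > fc_threshold),
                     n_down = sum(sig & de$log2fc < -fc_threshold))
    })
    out <- dplyr::left_join(out, dplyr::bind_rows(de_counts), by = "go_id")
  }
  out
}

#' Gene-set tallies of externally provided DE flags
#'
#' Per gene set (e.g. a transcription factor family or a lipid pathway),
#' counts the member genes present in the DE table (`detected`) and those
#' passing the DEG thresholds up (log2FC > `fc_threshold`, FDR <
#' `fdr_threshold`) or down (log2FC < -`fc_threshold`). Genes in a set that
#' are absent from the DE table are reported via the `missing` column.
#'
#' @param de_table Tibble with columns `gene`, `log2fc`, `fdr`.
#' @param set_map Tibble with columns `gene`, `set`.
#' @param fc_threshold,fdr_threshold Strict DEG thresholds; defaults 1 and
#'   0.005.
#' @return Tibble per set: `set`, `detected`, `up`, `down`, `missing`.
#' @export
gene_set_tally <- function(de_table, set_map, fc_threshold = 1,
                           fdr_threshold = 0.005) {
  stopifnot(all(c("gene", "log2fc", "fdr") %in% names(de_table)),
            all(c("gene", "set") %in% names(set_map)))
  sets <- split(set_map$gene, set_map$set)
  rows <- lapply(names(sets), function(s) {
    genes <- unique(sets[[s]])
    de <- de_table[de_table$gene %in% genes, ]
    sig <- de$fdr < fdr_threshold
    tibble::tibble(set = s, detected = nrow(de),
                   up = sum(sig & de$log2fc > fc_threshold),
                   down = sum(sig & de$log2fc < -fc_threshold),
                   missing = length(genes) - nrow(de))
  })
  dplyr::bind_rows(rows)
}
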