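#' @title Differential protein abundance, Venn partition, correlation
#' @description
#' Per-protein comparison of two strain groups from a non-negative
#' abundance matrix: log2 fold-change of group means after flooring zeros,
#' Welch t on log2 abundances, Benjamini-Hochberg adjustment, and the dual
#' significance rule (adjusted P < 0.05 and |log2FC| > 1.5). Two
#' comparisons against the same reference are combined by a Venn partition
#' of their significant sets and a fold-change correlation.
#' @name omics_diff
NULL

check_matrix <- function(matrix, groups) {
  if (is.null(rownames(matrix))) ss_stop("matrix needs protein ids as rownames")
  if (anyDuplicated(rownames(matrix))) ss_stop("duplicate protein ids")
  if (any(matrix < 0)) ss_stop("abundances must be non-negative")
  ss_require_columns(groups, c("sample", "group"), "group map")
  unmapped <- setdiff(colnames(matrix), groups$sample)
  if (length(unmapped)) {
    ss_stop("sample(s) missing from group map: ",
            paste(unmapped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Differential abundance between two groups
#'
#' Zeros (proteins absent in a group) are floored to half the smallest
#' nonzero abundance in the matrix before taking logs, so an absent
#' protein yields a large but finite nominal fold-change; such proteins
#' carry `floored = TRUE`. Proteins with all-zero abundance in both groups
#' are excluded with a warning.
#'
#' @param matrix proteins x samples non-negative matrix with rownames.
#' @param groups data.frame mapping `sample` to `group`.
#' @param group,reference group labels to compare (log2FC is
#'   `group` over `reference`).
#' @param alpha adjusted-significance level (default 0.05).
#' @param lfc_threshold absolute log2FC threshold (default 1.5).
#' @param floor zero-replacement value; default `NULL` = half the smallest
#'   nonzero abundance in the matrix.
#' @return data.frame of class `diff_result`: `protein_id`, `log2fc`, `p`,
#'   `p_adjusted`, `significant`, `floored`.
#' @export
differential <- function(matrix, groups, group, reference, alpha = 0.05,
                         lfc_threshold = 1.5, floor = NULL) {
  check_matrix(matrix, groups)
  gs <- groups$sample[groups$group == group]
  rs <- groups$sample[groups$group == reference]
  if (length(gs) < 2L || length(rs) < 2L) {
    ss_stop("both groups need >= 2 samples (", group, ": ", length(gs),
            ", ", reference, ": ", length(rs), ")")
  }
  xg <- matrix[, gs, drop = FALSE]
  xr <- matrix[, rs, drop = FALSE]
  allzero <- rowSums(xg) == 0 & rowSums(xr) == 0
  if (any(allzero)) {
    warning(sum(allzero), " protein(s) all-zero in both groups excluded",
            call. = FALSE)
    xg <- xg[!allzero, , drop = FALSE]
    xr <- xr[!allzero, , drop = FALSE]
  }
  if (is.null(floor)) {
    nz <- c(xg, xr)
    floor <- min(nz[nz > 0]) / 2
  }
  floored <- rowSums(xg == 0) > 0 | rowSums(xr == 0) > 0
  xg[xg == 0] <- floor
  xr[xr == 0] <- floor
  log2fc <- log2(rowMeans(xg) / rowMeans(xr))
  lg <- log2(xg); lr <- log2(xr)
  p <- vapply(seq_len(nrow(xg)), function(i) {
    welch_t(lg[i, ], lr[i, ])$p
  }, numeric(1))
  p_adjusted <- bh_adjust(p)
  res <- data.frame(protein_id = rownames(xg), log2fc = log2fc, p = p,
                    p_adjusted = p_adjusted,
                    significant = p_adjusted < alpha &
                      abs(log2fc) > lfc_threshold,
                    floored = floored, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "comparison") <- paste(group, "vs", reference)
  class(res) <- c("diff_result", class(res))
  res
}

#' @export
print.diff_result <- function(x, ...) {
  cat("Differential abundance (", attr(x, "comparison") %||% "", "): ",
      sum(x$significant), " significant of ", nrow(x), " proteins (",
      sum(x$significant & x$log2fc > 0), " up, ",
      sum(x$significant & x$log2fc < 0), " down)\n", sep = "")
  invisible(x)
}

#' Directional counts of a differential result
#'
#' @param diff `diff_result` data.frame.
#' @return list with `up`, `down` (significant proteins with positive /
#'   negative log2FC) and `total`.
#' @export
directional_counts <- function(diff) {
  up <- sum(diff$significant & diff$log2fc > 0)
  down <- sum(diff$significant & diff$log2fc < 0)
  list(up = up, down = down, total = up + down)
}

#' Venn partition of two differential comparisons
#'
#' Partitions the significant sets of two comparisons over the same
#' protein universe; counts satisfy inclusion-exclusion exactly.
#'
#' @param diff_a,diff_b `diff_result` data.frames over identical protein
#'   sets.
#' @return list of class `venn_partition`: `shared`, `unique_a`,
#'   `unique_b`, `union`, `shared_pct` (share of the union, percent), and
#'   the id lists `ids_shared`, `ids_a_only`, `ids_b_only`.
#' @export
venn <- function(diff_a, diff_b) {
  if (!setequal(diff_a$protein_id, diff_b$protein_id)) {
    ss_stop("comparisons cover different protein universes")
  }
  a <- diff_a$protein_id[diff_a$significant]
  b <- diff_b$protein_id[diff_b$significant]
  shared <- intersect(a, b)
  a_only <- setdiff(a, b)
  b_only <- setdiff(b, a)
  un <- length(shared) + length(a_only) + length(b_only)
  structure(list(shared = length(shared), unique_a = length(a_only),
                 unique_b = length(b_only), union = un,
                 shared_pct = if (un > 0) 100 * length(shared) / un else
                   NA_real_,
                 ids_shared = shared, ids_a_only = a_only,
                 ids_b_only = b_only),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition: |A| = ", x$shared + x$unique_a,
      ", |B| = ", x$shared + x$unique_b,
      ", shared = ", x$shared, " (", round(x$shared_pct), "% of union ",
      x$union, "), unique A = ", x$unique_a, ", unique B = ", x$unique_b,
      "\n", sep = "")
  invisible(x)
}

#' Fold-change correlation between two comparisons
#'
#' Correlation of per-protein log2 fold-changes across the shared universe,
#' with a flag for proteins non-significant in both comparisons (the gray
#' points of a correlation plot).
#'
#' @param diff_a,diff_b `diff_result` data.frames over the same universe.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `n`, `method` and `table` (protein_id, lfc_a,
#'   lfc_b, nonsignificant_both).
#' @export
fc_correlation <- function(diff_a, diff_b, method = c("pearson",
                                                      "spearman")) {
  method <- match.arg(method)
  if (!setequal(diff_a$protein_id, diff_b$protein_id)) {
    ss_stop("comparisons cover different protein universes")
  }
  idx <- match(diff_a$protein_id, diff_b$protein_id)
  if (nrow(diff_a) < 3L) ss_stop("need >= 3 shared proteins")
  tab <- data.frame(protein_id = diff_a$protein_id,
                    lfc_a = diff_a$log2fc, lfc_b = diff_b$log2fc[idx],
                    nonsignificant_both = !diff_a$significant &
                      !diff_b$significant[idx],
                    stringsAsFactors = FALSE)
  list(r = stats::cor(tab$lfc_a, tab$lfc_b, method = method),
       n = nrow(tab), method = method, table = tab)
}
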