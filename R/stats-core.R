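#' @title ANOVA, Tukey HSD, Welch t and FDR machinery
#' @description
#' The statistical operations every stage shares: one- and two-way ANOVA
#' (balanced complete designs), Tukey honest-significant-difference
#' pairwise comparisons with studentized-range adjusted p-values, Welch's
#' t-test, Benjamini-Hochberg step-up adjustment, and the conventional
#' significance stars (* < 0.05, ** < 0.01, *** < 0.001). All delegate to
#' the standard R implementations (`aov`, `TukeyHSD`, `t.test`,
#' `p.adjust`) behind a uniform tabular interface.
#' @name stats_core
NULL

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    ss_stop("need a list of >= 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    ss_stop("every group needs >= 2 values (got sizes ",
            paste(sizes, collapse = ", "), ")")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  groups
}

groups_to_df <- function(groups) {
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups)),
                            levels = names(groups)))
}

anova_table <- function(fit) {
  s <- summary(fit)[[1]]
  out <- data.frame(term = trimws(rownames(s)),
                    sum_sq = s[["Sum Sq"]], df = s[["Df"]],
                    mean_sq = s[["Mean Sq"]], F = s[["F value"]],
                    p = s[["Pr(>F)"]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # a term explaining (numerically) zero variation has F = 0, not 0/0 or a
  # roundoff ratio, even when the residual variance is also zero
  degen <- if (sum(out$sum_sq) < 1e-20) !is.na(out$F) | is.nan(out$F) else
    is.nan(out$F) & out$sum_sq == 0
  out$F[degen] <- 0
  out$p[degen] <- 1
  out
}

#' One-way analysis of variance
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2
#'   values).
#' @return data.frame with one row per term (`group`, `Residuals`) and
#'   columns `term`, `sum_sq`, `df`, `mean_sq`, `F`, `p`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups) {
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  anova_table(stats::aov(value ~ group, data = df))
}

#' Two-way analysis of variance with interaction
#'
#' Supports balanced complete designs only (every cell present with the
#' same replicate count >= 2); unbalanced data is a hard error rather than
#' a silent sums-of-squares-type choice.
#'
#' @param values numeric response vector.
#' @param a,b factor vectors (same length as `values`).
#' @return data.frame with rows for `a`, `b`, `a:b` and `Residuals`.
#' @export
two_way_anova <- function(values, a, b) {
  if (length(values) != length(a) || length(values) != length(b)) {
    ss_stop("values, a and b must have equal length")
  }
  a <- factor(a); b <- factor(b)
  tab <- table(a, b)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    ss_stop("missing cell(s) in the a x b design: ",
            paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
                  sep = ":", collapse = ", "))
  }
  if (length(unique(as.vector(tab))) != 1L) {
    ss_stop("unbalanced design (unequal cell counts); rebalance the input")
  }
  if (any(tab < 2)) ss_stop("need >= 2 replicates per cell")
  anova_table(stats::aov(values ~ a * b,
                         data = data.frame(values = values, a = a, b = b)))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted p-values for all group pairs of a one-way
#' layout, with significance stars.
#'
#' @param groups named list of numeric vectors.
#' @param alpha family significance level (only affects the confidence
#'   level of the interval bounds).
#' @return data.frame with `group_a`, `group_b`, `mean_diff`
#'   (`group_b - group_a`), `q` (studentized-range statistic),
#'   `p_adjusted`, `stars`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  ns <- lengths(groups)
  gb <- vapply(pairs, `[`, "", 1L)  # TukeyHSD labels are "b-a"
  ga <- vapply(pairs, `[`, "", 2L)
  se_q <- sqrt(mse / 2 * (1 / ns[ga] + 1 / ns[gb]))
  out <- data.frame(group_a = ga, group_b = gb,
                    mean_diff = unname(tk[, "diff"]),
                    q = unname(abs(tk[, "diff"]) / se_q),
                    p_adjusted = unname(tk[, "p adj"]),
                    stars = p_stars(unname(tk[, "p adj"])),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Tukey HSD on the cells of a two-way design
#'
#' Applies [tukey_hsd()] to the `a x b` cell means (the per-panel starring
#' convention for strain x treatment comparisons).
#'
#' @inheritParams two_way_anova
#' @param alpha family significance level.
#' @return as [tukey_hsd()], with cell labels `a.b`.
#' @export
tukey_cells <- function(values, a, b, alpha = 0.05) {
  cell <- interaction(a, b, drop = TRUE, sep = ".")
  tukey_hsd(split(values, cell), alpha = alpha)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return adjusted p-values (same order as input, each >= its raw value,
#'   capped at 1).
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1)) {
    ss_stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' When both groups are (numerically) constant the test is degenerate:
#' p = 1 for equal means, p = 0 otherwise.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    ss_stop("each group needs >= 2 values")
  }
  va <- stats::var(a); vb <- stats::var(b)
  scale2 <- max(mean(a)^2, mean(b)^2, 1)
  if ((va + vb) / scale2 < 1e-24) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (same) 0 else Inf, df = length(a) + length(b) - 2,
                p = if (same) 1 else 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
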