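#' @title Succinate:2-ketoglutarate ratio and metabolite comparisons
#' @description
#' Succinate competitively inhibits 2-ketoglutarate (2KG)-dependent
#' dioxygenases, so the succinate:2KG concentration ratio, not either
#' metabolite alone, governs dioxygenase activity. This module computes
#' per-sample ratios summarised by strain and treatment, per-strain fold
#' changes against a reference strain, and the two-way ANOVA / Tukey
#' comparison of metabolite concentrations across strain x treatment.
#' Cross-metabolite ratios require absolute quantitation; relative-only
#' metabolites are permitted in folds and ANOVA but barred from ratios.
#' @name metabolite_analysis
NULL

check_metabolite_table <- function(table) {
  ss_require_columns(table, c("sample_id", "strain", "treatment",
                              "replicate", "metabolite",
                              "concentration_uM"), "metabolite table")
  if (anyDuplicated(paste(table$sample_id, table$metabolite, sep = "\r"))) {
    ss_stop("duplicate (sample_id, metabolite) record(s)")
  }
  if (any(table$concentration_uM < 0)) {
    ss_stop("concentrations must be >= 0")
  }
  invisible(TRUE)
}

#' Succinate:2KG ratio summary
#'
#' Per-sample succinate / 2-ketoglutarate concentration ratio, summarised
#' as mean, sd and n over replicates for every strain x treatment.
#'
#' @param table long-format metabolite data.frame (see
#'   [simulate_metabolites()] for the columns).
#' @param numerator,denominator metabolite names (defaults `"succinate"`,
#'   `"2-ketoglutarate"`).
#' @return list of class `ratio_summary` with `samples` (per-sample
#'   ratios) and `summary` (strain, treatment, mean_ratio, sd, n).
#' @export
succ_kg_ratio <- function(table, numerator = "succinate",
                          denominator = "2-ketoglutarate") {
  check_metabolite_table(table)
  if ("quantitation" %in% names(table)) {
    rel <- table$metabolite %in% c(numerator, denominator) &
      table$quantitation != "absolute"
    if (any(rel)) {
      ss_stop("cross-metabolite ratios require absolute quantitation; ",
              "relative records present for: ",
              paste(unique(table$metabolite[rel]), collapse = ", "))
    }
  }
  num <- table[table$metabolite == numerator, ]
  den <- table[table$metabolite == denominator, ]
  idx <- match(num$sample_id, den$sample_id)
  if (anyNA(idx) || nrow(num) == 0L) {
    ss_stop("every sample needs both ", numerator, " and ", denominator)
  }
  if (any(den$concentration_uM[idx] == 0)) {
    bad <- num$sample_id[den$concentration_uM[idx] == 0]
    ss_stop("ratio undefined (", denominator, " = 0) in sample(s): ",
            paste(bad, collapse = ", "))
  }
  samples <- data.frame(sample_id = num$sample_id, strain = num$strain,
                        treatment = num$treatment,
                        replicate = num$replicate,
                        ratio = num$concentration_uM /
                          den$concentration_uM[idx],
                        stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(
    split(samples, paste(samples$strain, samples$treatment, sep = "\r")),
    function(s) data.frame(strain = s$strain[1], treatment = s$treatment[1],
                           mean_ratio = mean(s$ratio),
                           sd = stats::sd(s$ratio), n = nrow(s),
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(list(samples = samples, summary = agg),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat("Succinate:2KG ratio by strain x treatment:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-strain fold change of a metabolite
#'
#' Fold change of strain means against a reference strain, computed within
#' each treatment level.
#'
#' @param table long-format metabolite data.frame.
#' @param metabolite metabolite name.
#' @param reference_strain reference (default `"WT"`).
#' @return data.frame with `strain`, `treatment`, `fold` (strain mean /
#'   reference mean), `strain_mean`, `reference_mean`.
#' @export
strain_fold <- function(table, metabolite, reference_strain = "WT") {
  check_metabolite_table(table)
  m <- table[table$metabolite == metabolite, ]
  if (nrow(m) == 0L) ss_stop("metabolite not present: ", metabolite)
  if (!reference_strain %in% m$strain) {
    ss_stop("reference strain absent: ", reference_strain)
  }
  out <- list()
  for (tr in unique(m$treatment)) {
    sub <- m[m$treatment == tr, ]
    ref <- mean(sub$concentration_uM[sub$strain == reference_strain])
    if (!is.finite(ref) || ref <= 0) {
      ss_stop("reference mean is zero for treatment ", tr)
    }
    for (st in unique(sub$strain)) {
      sm <- mean(sub$concentration_uM[sub$strain == st])
      out[[length(out) + 1L]] <- data.frame(
        strain = st, treatment = tr, fold = sm / ref, strain_mean = sm,
        reference_mean = ref, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-way strain x treatment test of one metabolite
#'
#' Two-way ANOVA (strain, treatment, interaction) of the metabolite's
#' concentrations plus Tukey HSD on the strain x treatment cells.
#'
#' @param table long-format metabolite data.frame (balanced design).
#' @param metabolite metabolite name.
#' @param alpha significance level for the Tukey stars.
#' @return list with `anova` (term table) and `tukey` (pairwise cell
#'   comparisons).
#' @export
treatment_test <- function(table, metabolite, alpha = 0.05) {
  check_metabolite_table(table)
  m <- table[table$metabolite == metabolite, ]
  if (nrow(m) == 0L) ss_stop("metabolite not present: ", metabolite)
  an <- two_way_anova(m$concentration_uM, m$strain, m$treatment)
  tk <- tukey_cells(m$concentration_uM, m$strain, m$treatment,
                    alpha = alpha)
  list(anova = an, tukey = tk)
}
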