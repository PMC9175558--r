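#' @title Pipeline driver and configuration
#' @description
#' `run_pipeline()` chains the stages end to end — simulate (or load) a
#' screen, score it, call hits, validate hit selectivity, run the
#' proteomic differential and the metabolite comparison — and writes every
#' report as CSV next to a run log and the resolved configuration. With a
#' fixed seed the whole bundle is reproducible bit for bit.
#' @name cli_config
NULL

#' Default pipeline configuration
#'
#' @param seed integer seed for every stochastic stage.
#' @param stages character vector of stages to run, any of `"simulate"`,
#'   `"score"`, `"hits"`, `"validate"`, `"omics"`, `"metabolites"`.
#' @param min_positive,n_timepoints hit-calling thresholds.
#' @param alpha significance level.
#' @param adjusted_p,abs_log2fc dual differential thresholds.
#' @param screen arguments forwarded to [screen_config()].
#' @param paths optional named list of input CSV paths (`measurements`,
#'   `annotations`, `library`); when given, the simulate stage is skipped
#'   and the files are read instead.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("simulate", "score", "hits",
                                       "validate", "omics", "metabolites"),
                            min_positive = 6, n_timepoints = 7,
                            alpha = 0.05, adjusted_p = 0.05,
                            abs_log2fc = 1.5, screen = list(),
                            paths = NULL) {
  stopifnot(adjusted_p > 0, abs_log2fc > 0, alpha > 0)
  structure(list(seed = as.integer(seed), stages = stages,
                 min_positive = min_positive, n_timepoints = n_timepoints,
                 alpha = alpha, adjusted_p = adjusted_p,
                 abs_log2fc = abs_log2fc, screen = screen, paths = paths),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) ss_stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the analysis pipeline
#'
#' @param config `pipeline_config` list (or path to a YAML config).
#' @param out_dir output directory for the CSV reports, run log and
#'   resolved config (created if missing).
#' @return invisible list with the stage results (`sim`, `stats`, `hits`,
#'   `ranked`, `selectivity`, `omics`, `metabolites`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  log_line(logf, "suppscreen ", as.character(utils::packageVersion("suppscreen")),
           " | seed ", config$seed)
  res <- list()
  want <- function(s) s %in% config$stages

  if (want("simulate") && is.null(config$paths)) {
    log_line(logf, "stage simulate: screen")
    sc <- do.call(screen_config, config$screen)
    res$sim <- simulate_screen(sc, seed = config$seed)
    write_measurements(res$sim$measurements,
                       file.path(out_dir, "measurements.csv"))
    utils::write.csv(res$sim$annotations,
                     file.path(out_dir, "annotations.csv"),
                     row.names = FALSE)
    utils::write.csv(res$sim$library, file.path(out_dir, "library.csv"),
                     row.names = FALSE)
    utils::write.csv(res$sim$truth, file.path(out_dir, "truth_screen.csv"),
                     row.names = FALSE)
    annotated <- join_annotations(res$sim$measurements,
                                  res$sim$annotations, res$sim$library)
    library <- res$sim$library
  } else {
    p <- config$paths
    if (is.null(p) || !all(c("measurements", "annotations", "library") %in%
                             names(p))) {
      ss_stop("paths must name measurements, annotations and library files")
    }
    log_line(logf, "stage load: ", p$measurements)
    annotated <- join_annotations(read_measurements(p$measurements),
                                  read_annotations(p$annotations),
                                  read_library(p$library))
    library <- read_library(p$library)
  }

  if (want("score")) {
    log_line(logf, "stage score: ", length(unique(stats::na.omit(
      annotated$compound_id))), " compounds")
    res$stats <- score_screen(annotated)
    utils::write.csv(res$stats, file.path(out_dir, "screen_stats.csv"),
                     row.names = FALSE)
  }
  if (want("hits")) {
    if (is.null(res$stats)) ss_stop("stage 'hits' requires stage 'score'")
    res$hits <- call_hits(res$stats, library,
                          min_positive = config$min_positive,
                          n_timepoints = config$n_timepoints)
    res$ranked <- rank_hits(res$hits)
    log_line(logf, "stage hits: ", sum(res$hits$is_hit), " hits")
    utils::write.csv(res$ranked, file.path(out_dir, "hit_report.csv"),
                     row.names = FALSE)
  }
  if (want("validate")) {
    if (is.null(res$sim)) {
      log_line(logf, "stage validate: skipped (no simulated truth)")
    } else {
      hit_ids <- res$hits$compound_id[res$hits$is_hit | res$hits$excluded]
      take <- utils::head(hit_ids, 8L)
      eff <- default_effects(res$sim$config$library_size,
                             seed = config$seed)
      eff <- eff[eff$compound_id %in% take, , drop = FALSE]
      log_line(logf, "stage validate: ", nrow(eff), " compounds")
      if (nrow(eff)) {
        val <- simulate_validation(eff, seed = config$seed + 1L)
        ge <- growth_effects(val, alpha = config$alpha)
        verd <- do.call(rbind, lapply(split(ge, ge$compound_id),
          function(g) data.frame(compound_id = g$compound_id[1],
                                 verdict = classify_selectivity(
                                   g, alpha = config$alpha)$verdict)))
        res$selectivity <- list(effects = ge, verdicts = verd)
        utils::write.csv(ge, file.path(out_dir, "growth_effects.csv"),
                         row.names = FALSE)
        utils::write.csv(verd, file.path(out_dir, "selectivity.csv"),
                         row.names = FALSE)
      }
    }
  }
  if (want("omics")) {
    log_line(logf, "stage omics")
    ab <- simulate_abundance(seed = config$seed + 2L)
    da <- differential(ab$matrix, ab$groups, "sdh1", "WT",
                       alpha = config$adjusted_p,
                       lfc_threshold = config$abs_log2fc)
    db <- differential(ab$matrix, ab$groups, "sdh2", "WT",
                       alpha = config$adjusted_p,
                       lfc_threshold = config$abs_log2fc)
    vp <- venn(da, db)
    fc <- fc_correlation(da, db)
    res$omics <- list(diff_a = da, diff_b = db, venn = vp,
                      correlation = fc, truth = ab$truth)
    utils::write.csv(da, file.path(out_dir, "diff_sdh1.csv"),
                     row.names = FALSE)
    utils::write.csv(db, file.path(out_dir, "diff_sdh2.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(shared = vp$shared,
                                unique_a = vp$unique_a,
                                unique_b = vp$unique_b, union = vp$union,
                                shared_pct = vp$shared_pct),
                     file.path(out_dir, "venn.csv"), row.names = FALSE)
  }
  if (want("metabolites")) {
    log_line(logf, "stage metabolites")
    ms <- simulate_metabolites(seed = config$seed + 3L)
    ratio <- succ_kg_ratio(ms$table)
    folds <- strain_fold(ms$table, "succinate")
    tt <- treatment_test(ms$table, "succinate")
    res$metabolites <- list(sim = ms, ratio = ratio, folds = folds,
                            test = tt)
    utils::write.csv(ratio$summary, file.path(out_dir, "ratio_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(folds, file.path(out_dir, "succinate_folds.csv"),
                     row.names = FALSE)
    utils::write.csv(tt$anova, file.path(out_dir, "succinate_anova.csv"),
                     row.names = FALSE)
  }
  log_line(logf, "done")
  invisible(res)
}
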