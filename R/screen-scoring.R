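#' @title Screening-window Z statistic, hit calling and exclusions
#' @description
#' The screen statistic is the conventional screening-window score
#' `z = 1 - 3 (sigma_p + sigma_n) / |mu_p - mu_n|`, bounded above by 1,
#' positive only when the experimental and negative-control distributions
#' are separated by more than three standard deviations each. Screened
#' compounds occupy a single well, so the control wells' sample sd stands
#' in for the unavailable experimental sd (the mock-sd rule). A compound is
#' a hit when z > 0, with growth stimulation (`mu_p > mu_n`), at a minimum
#' number of timepoints (6 of 7 by default), unless its formulation
#' excludes it (sulfate content feeds the sulfur pathway directly; colored
#' solutions corrupt the absorbance readout).
#' @name screen_scoring
NULL

#' Screening-window Z score
#'
#' @param mu_p,sigma_p experimental mean and sd (for a single-well compound
#'   `sigma_p` is the mock value, equal to `sigma_n`).
#' @param mu_n,sigma_n negative-control mean and sample sd.
#' @return z value (vectorised); `NA` when `mu_p == mu_n` (zero separation,
#'   the statistic is undefined rather than -Inf).
#' @examples
#' zscore(0.30, 0.01, 0.20, 0.01) # 0.40
#' @export
zscore <- function(mu_p, sigma_p, mu_n, sigma_n) {
  if (any(sigma_p < 0 | sigma_n < 0, na.rm = TRUE)) {
    ss_stop("sigmas must be >= 0")
  }
  sep <- abs(mu_p - mu_n)
  z <- 1 - 3 * (sigma_p + sigma_n) / sep
  z[sep == 0] <- NA_real_
  z
}

#' Per-timepoint screen statistics for one compound
#'
#' Controls are pooled per plate: at each timepoint `mu_n` and `sigma_n`
#' are the mean and sample (n-1) sd of that plate's vehicle wells. A
#' single-well compound takes `mu_p` from its one well and `sigma_p :=
#' sigma_n` (mock-sd rule); a multi-well compound uses its own mean and sd.
#'
#' @param annotated joined measurement table (see [join_annotations()]).
#' @param compound_id the compound to score.
#' @return data.frame of class `screen_stats`: one row per timepoint with
#'   `compound_id`, `time_h`, `mu_p`, `sigma_p`, `mu_n`, `sigma_n`, `z`,
#'   `z_defined`.
#' @export
compound_series <- function(annotated, compound_id) {
  rows <- annotated[!is.na(annotated$compound_id) &
                      annotated$compound_id == compound_id, ]
  if (nrow(rows) == 0L) ss_stop("compound not present: ", compound_id)
  plates <- unique(rows$plate_id)
  ctrl <- annotated[annotated$role == "negative_control" &
                      annotated$plate_id %in% plates, ]
  n_ctrl_wells <- length(unique(paste(ctrl$plate_id, ctrl$well)))
  if (n_ctrl_wells < 2L) {
    ss_stop("need >= 2 negative-control wells on plate(s) ",
            paste(plates, collapse = ", "))
  }
  out <- list()
  for (t in sort(unique(rows$time_h))) {
    ct <- ctrl$od600[ctrl$time_h == t]
    if (length(ct) < 2L) {
      warning("timepoint ", t, " h missing for controls; skipped",
              call. = FALSE)
      next
    }
    mu_n <- mean(ct)
    sigma_n <- stats::sd(ct)
    exp_od <- rows$od600[rows$time_h == t]
    mu_p <- mean(exp_od)
    sigma_p <- if (length(exp_od) >= 2L) stats::sd(exp_od) else sigma_n
    z <- zscore(mu_p, sigma_p, mu_n, sigma_n)
    out[[length(out) + 1L]] <- data.frame(
      compound_id = compound_id, time_h = t, mu_p = mu_p,
      sigma_p = sigma_p, mu_n = mu_n, sigma_n = sigma_n, z = z,
      z_defined = !is.na(z), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("screen_stats", class(res))
  res
}

#' Score every compound in an annotated screen
#'
#' @param annotated joined measurement table.
#' @return single `screen_stats` data.frame over all compounds.
#' @export
score_screen <- function(annotated) {
  ids <- sort(unique(stats::na.omit(annotated$compound_id)))
  # per-plate control summaries once, then vectorised join
  ctrl <- annotated[annotated$role == "negative_control", ]
  csum <- do.call(rbind, lapply(split(ctrl, ctrl$plate_id), function(cp) {
    if (length(unique(cp$well)) < 2L) {
      ss_stop("need >= 2 negative-control wells on plate ", cp$plate_id[1])
    }
    agg_m <- tapply(cp$od600, cp$time_h, mean)
    agg_s <- tapply(cp$od600, cp$time_h, stats::sd)
    data.frame(plate_id = cp$plate_id[1],
               time_h = as.numeric(names(agg_m)),
               mu_n = as.numeric(agg_m), sigma_n = as.numeric(agg_s),
               stringsAsFactors = FALSE)
  }))
  rows <- annotated[!is.na(annotated$compound_id), ]
  exp1 <- stats::aggregate(od600 ~ compound_id + plate_id + time_h,
                           data = rows, FUN = mean)
  sds <- stats::aggregate(od600 ~ compound_id + plate_id + time_h,
                          data = rows,
                          FUN = function(x) {
                            if (length(x) >= 2) stats::sd(x) else NA_real_
                          })
  key <- paste(exp1$plate_id, exp1$time_h)
  ckey <- paste(csum$plate_id, csum$time_h)
  idx <- match(key, ckey)
  if (anyNA(idx)) {
    warning("control timepoint(s) missing; affected rows skipped",
            call. = FALSE)
  }
  res <- data.frame(compound_id = exp1$compound_id, time_h = exp1$time_h,
                    mu_p = exp1$od600,
                    sigma_p = ifelse(is.na(sds$od600), csum$sigma_n[idx],
                                     sds$od600),
                    mu_n = csum$mu_n[idx], sigma_n = csum$sigma_n[idx],
                    stringsAsFactors = FALSE)
  res <- res[!is.na(res$mu_n), ]
  res$z <- zscore(res$mu_p, res$sigma_p, res$mu_n, res$sigma_n)
  res$z_defined <- !is.na(res$z)
  res <- res[order(res$compound_id, res$time_h), ]
  rownames(res) <- NULL
  class(res) <- c("screen_stats", class(res))
  res
}

#' Assay-window check between two strain groups
#'
#' Computes the per-timepoint z between a positive group (e.g. WT wells in
#' ISE) and a negative group (the SDH-loss wells), each with its own mean
#' and sample sd. The screen design passes when every timepoint separates
#' (all z > 0).
#'
#' @param annotated joined measurement table.
#' @param positive_strain,negative_strains strain labels for the two
#'   groups.
#' @param medium medium to restrict to (default `ISE`).
#' @return list with `z` (data.frame time_h, z) and `pass`.
#' @export
assay_window <- function(annotated, positive_strain = "WT",
                         negative_strains = c("sdh1", "sdh2"),
                         medium = "ISE") {
  pos <- annotated[annotated$strain == positive_strain &
                     annotated$medium == medium, ]
  neg <- annotated[annotated$strain %in% negative_strains &
                     annotated$medium == medium, ]
  if (length(unique(paste(pos$plate_id, pos$well))) < 2L ||
      length(unique(paste(neg$plate_id, neg$well))) < 2L) {
    ss_stop("each group needs >= 2 wells")
  }
  times <- sort(intersect(unique(pos$time_h), unique(neg$time_h)))
  z <- vapply(times, function(t) {
    p <- pos$od600[pos$time_h == t]; n <- neg$od600[neg$time_h == t]
    zscore(mean(p), stats::sd(p), mean(n), stats::sd(n))
  }, numeric(1))
  list(z = data.frame(time_h = times, z = z),
       pass = all(!is.na(z) & z > 0))
}

#' Call hits from per-compound screen statistics
#'
#' A timepoint counts as positive when `z > 0` and `mu_p > mu_n` (growth
#' stimulation, so inhibitors never score). A compound is a hit when at
#' least `min_positive` of `n_timepoints` are positive and its formulation
#' does not exclude it.
#'
#' @param stats `screen_stats` data.frame (all compounds).
#' @param library compound-library data.frame carrying the
#'   `contains_sulfate` and `colored_solution` flags.
#' @param min_positive minimum positive timepoints (default 6).
#' @param n_timepoints expected timepoints per compound (default 7).
#' @return data.frame of class `hit_calls`: `compound_id`, `name`,
#'   `n_timepoints`, `n_positive`, `summary_z` (median z), `is_hit`,
#'   `excluded`, `exclusion_reason`.
#' @export
call_hits <- function(stats, library, min_positive = 6, n_timepoints = 7) {
  library <- validate_library(library)
  ids <- unique(stats$compound_id)
  unknown <- setdiff(ids, library$compound_id)
  if (length(unknown)) {
    ss_stop("compound(s) absent from library: ",
            paste(unknown, collapse = ", "))
  }
  pos <- !is.na(stats$z) & stats$z > 0 & stats$mu_p > stats$mu_n
  n_pos <- tapply(pos, stats$compound_id, sum)
  n_tp <- tapply(pos, stats$compound_id, length)
  med_z <- tapply(stats$z, stats$compound_id, stats::median, na.rm = TRUE)
  ids <- names(n_pos)
  li <- match(ids, library$compound_id)
  excluded <- library$contains_sulfate[li] | library$colored_solution[li]
  reason <- ifelse(library$contains_sulfate[li], "sulfate_formulation",
                   ifelse(library$colored_solution[li], "colored_solution",
                          "none"))
  res <- data.frame(
    compound_id = ids, name = library$name[li],
    n_timepoints = as.integer(n_tp), n_positive = as.integer(n_pos),
    summary_z = as.numeric(med_z),
    is_hit = as.integer(n_pos) >= min_positive & !excluded,
    excluded = excluded, exclusion_reason = reason,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("hit_calls", class(res))
  res
}

#' @export
print.hit_calls <- function(x, ...) {
  n_wb <- if (nrow(x)) {
    sum(x$excluded & x$n_positive >= max(x$n_timepoints) - 1)
  } else 0L
  cat("Screen hit calls: ", sum(x$is_hit), " hits / ", nrow(x),
      " compounds (", n_wb,
      " would-be hits excluded by formulation)\n", sep = "")
  invisible(x)
}

#' Rank compounds by summary Z
#'
#' Orders compounds by the median z across timepoints, descending, ties
#' broken lexicographically by compound id, and carries the exclusion
#' annotations (the +/- sulfate column of the hit report).
#'
#' @param calls `hit_calls` data.frame.
#' @param min_summary_z drop compounds below this summary z (`-Inf` keeps
#'   all; the reporting convention uses -5).
#' @return the ranked report data.frame with a `rank` column.
#' @export
rank_hits <- function(calls, min_summary_z = -Inf) {
  keep <- calls[!is.na(calls$summary_z) &
                  calls$summary_z > min_summary_z, , drop = FALSE]
  ord <- order(-keep$summary_z, keep$compound_id)
  keep <- keep[ord, , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  class(keep) <- "data.frame"
  keep
}
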