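#' @title Endpoint growth, diauxic detection, percent change, selectivity
#' @description
#' Growth readouts for validation assays: 24-h endpoint OD, percent growth
#' change between treated and untreated wells with first-order (delta
#' method) error propagation, detection of the diauxic shift that separates
#' fermentative from oxidative growth phases, and the selectivity verdict
#' that a validated suppressor must raise only the SDH-loss strains and
#' only on ISE medium.
#' @name growth_metrics
NULL

#' Endpoint OD of a growth series
#'
#' Returns the OD at the latest timepoint not exceeding `target_h`; if every
#' timepoint is later than the target, the earliest timepoint is used with
#' a warning.
#'
#' @param time_h,od600 numeric vectors of equal length (one well's series).
#' @param target_h assay endpoint in hours (default 24).
#' @return single OD600 value.
#' @export
endpoint_growth <- function(time_h, od600, target_h = 24) {
  if (length(time_h) == 0L || length(time_h) != length(od600)) {
    ss_stop("series must be non-empty with matching time and OD vectors")
  }
  eligible <- which(time_h <= target_h)
  if (length(eligible) == 0L) {
    warning(sprintf(
      "no timepoint at or before %g h; using earliest (%g h)",
      target_h, min(time_h)), call. = FALSE)
    return(od600[which.min(time_h)])
  }
  od600[eligible[which.max(time_h[eligible])]]
}

#' Percent growth change with propagated error
#'
#' `pct = 100 (t - u) / u` for treated mean `t` and untreated mean `u`;
#' the error is first-order propagation of independent errors:
#' `err = 100 sqrt((s_t/u)^2 + (t s_u / u^2)^2)`.
#'
#' @param treated_mean,treated_sd treated endpoint OD mean and sd.
#' @param untreated_mean,untreated_sd untreated endpoint OD mean and sd
#'   (`untreated_mean` must be > 0).
#' @return list with `pct` and `err`, both in percent.
#' @examples
#' percent_change(0.44, 0.02, 0.40, 0.02)
#' @export
percent_change <- function(treated_mean, treated_sd = 0,
                           untreated_mean, untreated_sd = 0) {
  ss_check_number(untreated_mean, "untreated_mean", lower = 1e-300)
  ss_check_number(treated_sd, "treated_sd", lower = 0)
  ss_check_number(untreated_sd, "untreated_sd", lower = 0)
  pct <- 100 * (treated_mean - untreated_mean) / untreated_mean
  err <- 100 * sqrt((treated_sd / untreated_mean)^2 +
                      (treated_mean * untreated_sd / untreated_mean^2)^2)
  list(pct = pct, err = err)
}

#' Detect a diauxic shift in a growth series
#'
#' Works on the centered-moving-average of the first-difference growth rate
#' (OD/h). A shift is called when two local rate maxima, each at least
#' `min_phase_rate`, are separated by a local minimum below half the
#' smaller maximum; the shift time is the time of that minimum. The
#' statistic is invariant to constant OD offsets (it only sees
#' differences).
#'
#' @param time_h,od600 the series (>= 5 points).
#' @param smooth_window centered moving-average window in points (odd,
#'   default 3).
#' @param min_phase_rate minimum rate (OD/h) for a phase maximum.
#' @return list with `detected`, `shift_time_h` (`NA` when not detected),
#'   `phase1_rate_max`, `phase2_rate_max`.
#' @export
detect_diauxic <- function(time_h, od600, smooth_window = 3,
                           min_phase_rate = 0.02) {
  if (length(time_h) < 5L) ss_stop("need at least 5 timepoints")
  if (length(time_h) != length(od600)) ss_stop("length mismatch")
  o <- order(time_h)
  time_h <- time_h[o]; od600 <- od600[o]
  rate <- diff(od600) / diff(time_h)
  tmid <- (time_h[-1] + time_h[-length(time_h)]) / 2
  if (smooth_window > 1) {
    k <- min(smooth_window, length(rate))
    if (k %% 2 == 0) k <- k - 1
    if (k >= 3) {
      sm <- stats::filter(rate, rep(1 / k, k), sides = 2)
      keep <- !is.na(sm)
      rate <- as.numeric(sm[keep]); tmid <- tmid[keep]
    }
  }
  n <- length(rate)
  none <- list(detected = FALSE, shift_time_h = NA_real_,
               phase1_rate_max = NA_real_, phase2_rate_max = NA_real_)
  if (n < 3L) return(none)
  interior <- 2:(n - 1)
  is_max <- vapply(interior, function(i) {
    rate[i] >= rate[i - 1] && rate[i] >= rate[i + 1] &&
      (rate[i] > rate[i - 1] || rate[i] > rate[i + 1])
  }, logical(1))
  # series endpoints count as candidate maxima (phases truncated by the
  # observation window)
  cand <- c(1L, interior[is_max], n)
  cand <- cand[rate[cand] >= min_phase_rate]
  cand <- cand[!duplicated(cand)]
  if (length(cand) < 2L) return(none)
  best <- none
  for (a in seq_len(length(cand) - 1L)) {
    for (b in (a + 1L):length(cand)) {
      i <- cand[a]; j <- cand[b]
      if (j - i < 2L) next
      seg <- (i + 1L):(j - 1L)
      m <- seg[which.min(rate[seg])]
      if (rate[m] < 0.5 * min(rate[i], rate[j])) {
        if (!best$detected ||
            min(rate[i], rate[j]) >
              min(best$phase1_rate_max, best$phase2_rate_max)) {
          best <- list(detected = TRUE, shift_time_h = tmid[m],
                       phase1_rate_max = rate[i], phase2_rate_max = rate[j])
        }
      }
    }
  }
  best
}

#' Summarise growth effects from a validation experiment
#'
#' For every strain x medium x compound x dose cell, compares treated
#' endpoint replicates against the untreated replicates of the same strain
#' and medium: percent growth change with propagated error, plus a
#' significance decision taken from the medium-wide two-way layout
#' (strain x dose): a protected Tukey HSD on the strain x dose cell means,
#' consulted only when the two-way ANOVA shows a significant dose or
#' strain:dose term, so the family-wise error of the eight-cell panel is
#' controlled the way starred growth panels conventionally are.
#'
#' @param validation long data.frame as from [simulate_validation()]
#'   (columns `strain`, `medium`, `compound_id`, `concentration_uM`,
#'   `replicate`, `time_h`, `od600`).
#' @param target_h endpoint time (hours).
#' @param alpha significance level for the adjusted decisions.
#' @param se use standard error of the mean instead of sd in the
#'   propagation (default `FALSE`: sample sd).
#' @return data.frame of class `growth_effects`: one row per cell with
#'   `pct_change`, `pct_change_err`, `n_replicates`, endpoint means/sds,
#'   `p_adjusted`, `significant`, `stars`.
#' @export
growth_effects <- function(validation, target_h = 24, alpha = 0.05,
                           se = FALSE) {
  need <- c("strain", "medium", "compound_id", "concentration_uM",
            "replicate", "time_h", "od600")
  ss_require_columns(validation, need, "validation table")
  v <- validation
  v$compound_id <- ifelse(is.na(v$compound_id), "<none>", v$compound_id)
  keys <- c("strain", "medium", "compound_id", "concentration_uM",
            "replicate")
  sp <- split(seq_len(nrow(v)), v[keys], drop = TRUE)
  ends <- do.call(rbind, lapply(sp, function(i) {
    cbind(v[i[1], keys, drop = FALSE],
          od600 = endpoint_growth(v$time_h[i], v$od600[i], target_h))
  }))
  rownames(ends) <- NULL

  out <- list()
  compounds <- setdiff(unique(ends$compound_id), "<none>")
  for (md in unique(ends$medium)) for (cid in compounds) {
    sub <- ends[ends$medium == md &
                  (ends$compound_id == cid | ends$compound_id == "<none>"), ]
    sub$dose <- sub$concentration_uM
    if (!all(ss_strains() %in% sub$strain[sub$dose == 0])) {
      ss_stop("missing untreated replicates in medium ", md)
    }
    an <- two_way_anova(sub$od600, sub$strain, factor(sub$dose))
    gate <- any(an$p[an$term %in% c("b", "a:b")] < alpha, na.rm = TRUE)
    tk <- tukey_cells(sub$od600, sub$strain, factor(sub$dose),
                      alpha = alpha)
    for (st in unique(sub$strain)) {
      untr <- sub$od600[sub$strain == st & sub$dose == 0]
      for (d in sort(unique(sub$dose[sub$dose > 0]))) {
        tr <- sub$od600[sub$strain == st & sub$dose == d]
        denom <- if (se) sqrt(length(tr)) else 1
        pc <- percent_change(mean(tr), stats::sd(tr) / denom,
                             mean(untr), stats::sd(untr) / denom)
        ca <- paste0(st, ".", d); cb <- paste0(st, ".", 0)
        pair <- tk[(tk$group_a == ca & tk$group_b == cb) |
                     (tk$group_b == ca & tk$group_a == cb), ]
        p_adj <- pair$p_adjusted[1]
        out[[length(out) + 1L]] <- data.frame(
          strain = st, medium = md, compound_id = cid,
          concentration_uM = d, pct_change = pc$pct,
          pct_change_err = pc$err, n_replicates = length(tr),
          treated_mean = mean(tr), treated_sd = stats::sd(tr),
          untreated_mean = mean(untr), untreated_sd = stats::sd(untr),
          p_adjusted = p_adj, significant = gate && p_adj < alpha,
          stars = if (gate) p_stars(p_adj) else "ns",
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("growth_effects", class(res))
  res
}

#' Classify compound selectivity across strains and media
#'
#' A validated suppressor must raise growth significantly in both SDH-loss
#' strains on ISE and nowhere else. Verdicts, in order of precedence:
#' `bypass_suspect` when jlp1 on ISE is significantly rescued (the compound
#' feeds sulfur downstream of the dioxygenase); `selective_suppressor` when
#' both `sdh1`/ISE and `sdh2`/ISE show a significant positive change and no
#' other cell (WT or jlp1 on ISE, or any AS cell) does; `toxic` when
#' significant effects exist and all are negative; `inactive` when nothing
#' is significant; otherwise `nonspecific`.
#'
#' @param effects `growth_effects` rows covering all 8 strain x medium
#'   cells for one compound (any number of doses; a cell counts as
#'   significant positive if any dose is).
#' @param alpha significance level (decisions already adjusted).
#' @return list of class `selectivity_verdict` with `compound_id`,
#'   `verdict` and the per-cell significance `table`.
#' @export
classify_selectivity <- function(effects, alpha = 0.05) {
  cid <- unique(effects$compound_id)
  if (length(cid) != 1L) ss_stop("effects must cover exactly one compound")
  cells <- expand.grid(strain = ss_strains(), medium = ss_media(),
                       stringsAsFactors = FALSE)
  have <- paste(effects$strain, effects$medium)
  missing <- setdiff(paste(cells$strain, cells$medium), have)
  if (length(missing)) {
    ss_stop("missing strain x medium cell(s): ",
            paste(missing, collapse = ", "))
  }
  sig_pos <- function(st, md) {
    any(effects$significant[effects$strain == st & effects$medium == md] &
          effects$pct_change[effects$strain == st &
                               effects$medium == md] > 0)
  }
  sig_neg <- function(st, md) {
    any(effects$significant[effects$strain == st & effects$medium == md] &
          effects$pct_change[effects$strain == st &
                               effects$medium == md] < 0)
  }
  cells$sig_positive <- mapply(sig_pos, cells$strain, cells$medium)
  cells$sig_negative <- mapply(sig_neg, cells$strain, cells$medium)
  as_pos <- any(cells$sig_positive[cells$medium == "AS"])
  verdict <- if (cells$sig_positive[cells$strain == "jlp1" &
                                      cells$medium == "ISE"]) {
    "bypass_suspect"
  } else if (cells$sig_positive[cells$strain == "sdh1" &
                                  cells$medium == "ISE"] &&
             cells$sig_positive[cells$strain == "sdh2" &
                                  cells$medium == "ISE"] &&
             !cells$sig_positive[cells$strain == "WT" &
                                   cells$medium == "ISE"] && !as_pos) {
    "selective_suppressor"
  } else if (any(cells$sig_negative) && !any(cells$sig_positive)) {
    "toxic"
  } else if (!any(cells$sig_negative) && !any(cells$sig_positive)) {
    "inactive"
  } else {
    "nonspecific"
  }
  structure(list(compound_id = cid, verdict = verdict, table = cells),
            class = "selectivity_verdict")
}

#' @export
print.selectivity_verdict <- function(x, ...) {
  cat("Compound ", x$compound_id, ": ", x$verdict, "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
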