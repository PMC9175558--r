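# Independent re-statement of the screening-window score, kept deliberately
# separate from the implementation for oracle comparisons.
oracle_z <- function(mu_p, sigma_p, mu_n, sigma_n) {
  d <- mu_p - mu_n
  if (d == 0) return(NA_real_)
  1 - (3 * sigma_p + 3 * sigma_n) / abs(d)
}

test_that("zscore matches hand arithmetic and its degenerate cases", {
  expect_equal(zscore(0.30, 0.01, 0.20, 0.01), 0.40)
  expect_equal(zscore(0.5, 0, 0.2, 0), 1.0)
  expect_true(is.na(zscore(0.3, 0.01, 0.3, 0.01)))
  expect_error(zscore(0.3, -0.1, 0.2, 0.01), "sigmas")
})

test_that("zscore agrees with an independent oracle on random inputs", {
  set.seed(77)
  for (i in 1:10000) {
    mu <- runif(2, 0, 2)
    sg <- runif(2, 0, 0.2)
    expect_equal(zscore(mu[1], sg[1], mu[2], sg[2]),
                 oracle_z(mu[1], sg[1], mu[2], sg[2]), tolerance = 1e-12)
  }
})

test_that("zscore is scale-invariant and monotone in separation and noise", {
  base <- zscore(0.45, 0.02, 0.30, 0.03)
  for (g in c(0.1, 3, 42)) {
    expect_equal(zscore(g * 0.45, g * 0.02, g * 0.30, g * 0.03), base,
                 tolerance = 1e-12)
  }
  # strictly decreasing in sigma_n, strictly increasing in |mu_p - mu_n|
  sig <- seq(0, 0.05, by = 0.005)
  expect_true(all(diff(zscore(0.5, 0.01, 0.3, sig)) < 0))
  sep <- seq(0.31, 0.6, by = 0.01)
  expect_true(all(diff(zscore(sep, 0.01, 0.3, 0.01)) > 0))
  expect_true(all(zscore(runif(100, 0, 2), runif(100, 0, 1),
                         runif(100, 0, 2), runif(100, 0, 1)) <= 1,
                  na.rm = TRUE))
})

make_screen_fixture <- function(well_od, ctrl_od, times = 0:6) {
  wells <- c("A1", paste0(LETTERS[1:4], "12"))
  meas <- do.call(rbind, lapply(seq_along(times), function(i) {
    data.frame(plate_id = "P01", well = wells, time_h = times[i],
               od600 = c(well_od[i], ctrl_od[, i]),
               stringsAsFactors = FALSE)
  }))
  ann <- tiny_annotations(wells,
                          compound_id = c("C1", rep(NA, 4)),
                          concentration_uM = c(10, rep(0, 4)),
                          role = c("experimental",
                                   rep("negative_control", 4)))
  join_annotations(meas, ann, tiny_library("C1"))
}

test_that("compound series applies the mock-sd rule per timepoint", {
  ctrl <- matrix(rep(c(0.19, 0.20, 0.20, 0.21), 7), nrow = 4)
  ann <- make_screen_fixture(rep(0.25, 7), ctrl)
  ser <- compound_series(ann, "C1")
  expect_equal(nrow(ser), 7L)
  expect_equal(ser$mu_n[1], 0.20)
  expect_equal(ser$sigma_n[1], sd(c(0.19, 0.20, 0.20, 0.21)))
  expect_equal(ser$sigma_p, ser$sigma_n) # single well: mock sd
  expect_equal(ser$z[1], 1 - 6 * sd(c(0.19, 0.20, 0.20, 0.21)) / 0.05,
               tolerance = 1e-9)
  expect_equal(round(ser$z[1], 4), 0.0202)

  # identical controls, distinct well -> zero-noise ceiling z = 1
  ann2 <- make_screen_fixture(rep(0.25, 7),
                              matrix(rep(0.2, 28), nrow = 4))
  expect_equal(compound_series(ann2, "C1")$z, rep(1, 7))

  # fewer than 2 control wells is an error
  one_ctrl <- ann[ann$well %in% c("A1", "A12"), ]
  expect_error(compound_series(one_ctrl, "C1"), "control")
})

test_that("score_screen matches compound_series and skips missing control times", {
  ctrl <- matrix(rnorm(28, 0.2, 0.01), nrow = 4)
  ann <- make_screen_fixture(seq(0.22, 0.34, by = 0.02), ctrl)
  ser <- compound_series(ann, "C1")
  all <- score_screen(ann)
  expect_equal(all$z, ser$z, tolerance = 1e-12)

  # drop controls at one timepoint: that timepoint is skipped with warning
  ann_miss <- ann[!(ann$role == "negative_control" & ann$time_h == 3), ]
  expect_warning(s2 <- score_screen(ann_miss), "skipped")
  expect_equal(nrow(s2), 6L)
})

test_that("assay window separates well-separated groups and fails overlap", {
  times <- 0:6
  mk <- function(mean_wt, mean_sdh, sd = 0.02, overlap_at = NULL) {
    wells_wt <- c("A1", "A2", "A3")
    wells_sd <- c("B1", "B2", "B3")
    set.seed(5)
    meas <- do.call(rbind, lapply(times, function(t) {
      m_s <- if (!is.null(overlap_at) && t == overlap_at) mean_wt else
        mean_sdh
      data.frame(plate_id = "P01", well = c(wells_wt, wells_sd),
                 time_h = t,
                 od600 = c(rnorm(3, mean_wt, sd), rnorm(3, m_s, sd)),
                 stringsAsFactors = FALSE)
    }))
    ann <- tiny_annotations(c(wells_wt, wells_sd),
                            strain = rep(c("WT", "sdh1"), each = 3),
                            role = "untreated_reference")
    join_annotations(meas, ann)
  }
  aw <- assay_window(mk(0.8, 0.4))
  expect_true(aw$pass)
  expect_true(all(aw$z$z > 0))

  ident <- assay_window(mk(0.5, 0.5))
  expect_false(ident$pass)

  part <- assay_window(mk(0.8, 0.4, overlap_at = 3))
  expect_false(part$pass)
  expect_true(sum(part$z$z <= 0 | is.na(part$z$z)) >= 1)
})

test_that("hit calling enforces the 6-of-7 rule, direction and exclusions", {
  mk_stats <- function(id, z, mu_p = 0.3, mu_n = 0.2) {
    data.frame(compound_id = id, time_h = seq_along(z), mu_p = mu_p,
               sigma_p = 0.01, mu_n = mu_n, sigma_n = 0.01, z = z,
               z_defined = !is.na(z), stringsAsFactors = FALSE)
  }
  lib <- tiny_library(c("H", "N", "S"),
                      contains_sulfate = c(FALSE, FALSE, TRUE))
  st <- rbind(mk_stats("H", c(0.1, 0.2, 0.05, 0.3, -0.1, 0.15, 0.2)),
              mk_stats("N", rep(-0.2, 7)),
              mk_stats("S", rep(0.5, 7)))
  calls <- call_hits(st, lib)
  h <- calls[calls$compound_id == "H", ]
  expect_equal(h$n_positive, 6L)
  expect_true(h$is_hit)
  expect_false(calls$is_hit[calls$compound_id == "N"])
  s <- calls[calls$compound_id == "S", ]
  expect_false(s$is_hit)
  expect_true(s$excluded)
  expect_equal(s$exclusion_reason, "sulfate_formulation")

  # positive z but declining growth must not count
  decl <- mk_stats("H", rep(0.4, 7), mu_p = 0.1, mu_n = 0.2)
  expect_equal(call_hits(decl, lib)$n_positive, 0L)

  expect_error(call_hits(mk_stats("UNKNOWN", rep(0, 7)), lib), "UNKNOWN")
})

test_that("ranking is by median z, descending, with lexicographic ties", {
  mk <- function(id, z) data.frame(compound_id = id, time_h = 1:7,
                                   mu_p = 0.3, sigma_p = 0.01, mu_n = 0.2,
                                   sigma_n = 0.01, z = z, z_defined = TRUE)
  lib <- tiny_library(c("A", "B", "Z"))
  st <- rbind(mk("Z", rep(0.4, 7)), mk("B", rep(0.1, 7)),
              mk("A", rep(0.1, 7)))
  r <- rank_hits(call_hits(st, lib))
  expect_equal(r$compound_id, c("Z", "A", "B"))
  expect_equal(r$rank, 1:3)
  r5 <- rank_hits(call_hits(st, lib), min_summary_z = 0.2)
  expect_equal(r5$compound_id, "Z")
})
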