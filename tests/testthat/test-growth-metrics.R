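test_that("endpoint growth picks the latest timepoint within the target", {
  expect_equal(endpoint_growth(c(0, 6, 12, 18, 24), c(1, 2, 3, 4, 5)), 5)
  expect_equal(endpoint_growth(c(0, 23.5), c(0.1, 0.8)), 0.8)
  expect_warning(v <- endpoint_growth(c(25, 26), c(0.3, 0.4)), "earliest")
  expect_equal(v, 0.3)
  expect_error(endpoint_growth(numeric(0), numeric(0)), "non-empty")
})

test_that("percent change follows the delta-method propagation formula", {
  expect_equal(percent_change(0.44, 0, 0.40, 0), list(pct = 10, err = 0))
  null <- percent_change(0.40, 0.02, 0.40, 0.02)
  expect_equal(null$pct, 0)
  expect_equal(null$err,
               100 * sqrt((0.02 / 0.4)^2 + (0.4 * 0.02 / 0.4^2)^2))
  expect_error(percent_change(0.44, 0, 0, 0), "untreated_mean")

  # scaling both means and sds by c > 0 leaves pct unchanged
  for (cc in c(0.5, 2, 10)) {
    a <- percent_change(0.44, 0.02, 0.40, 0.01)
    b <- percent_change(cc * 0.44, cc * 0.02, cc * 0.40, cc * 0.01)
    expect_equal(a$pct, b$pct)
    expect_equal(a$err, b$err)
  }
})

test_that("propagated error tracks a Monte-Carlo sd in the first-order regime", {
  set.seed(101)
  n <- 2e5
  t_draw <- rnorm(n, 0.44, 0.02)
  u_draw <- rnorm(n, 0.40, 0.02)
  mc_sd <- sd(100 * (t_draw - u_draw) / u_draw)
  prop <- percent_change(0.44, 0.02, 0.40, 0.02)$err
  expect_lt(abs(prop - mc_sd) / mc_sd, 0.05)
  expect_equal(prop, 7.43, tolerance = 0.01)
})

test_that("diauxic detection finds the inter-phase rate minimum", {
  # well-separated double logistic; the analytic rate has two maxima near
  # the phase midpoints and a minimum between them
  kin <- data.frame(strain = "WT", medium = "AS", od0 = 0.05, cap1 = 0.6,
                    rate1 = 0.9, mid1 = 4, cap2 = 0.4, rate2 = 0.8,
                    mid2 = 16, diauxic = TRUE)
  times <- seq(0, 24, by = 0.5)
  od <- growth_curve(kin, NULL, times)
  call <- detect_diauxic(times, od)
  expect_true(call$detected)

  # independent oracle: minimise the analytic derivative on a fine grid
  deriv <- function(t) {
    kin$cap1 * kin$rate1 * dlogis(kin$rate1 * (t - kin$mid1)) +
      kin$cap2 * kin$rate2 * dlogis(kin$rate2 * (t - kin$mid2))
  }
  grid <- seq(kin$mid1, kin$mid2, by = 0.001)
  t_min <- grid[which.min(deriv(grid))]
  expect_lt(abs(call$shift_time_h - t_min), 0.5 + 1e-9)
  expect_gt(call$shift_time_h, kin$mid1)
  expect_lt(call$shift_time_h, kin$mid2)

  # invariance to a constant OD offset
  shifted <- detect_diauxic(times, od + 0.7)
  expect_equal(shifted$shift_time_h, call$shift_time_h)

  # single logistic and constant series never trigger
  single <- growth_curve(strain_kinetics("sdh1", "ISE"), NULL, times)
  expect_false(detect_diauxic(times, single)$detected)
  expect_false(detect_diauxic(times, rep(0.3, length(times)))$detected)
  expect_error(detect_diauxic(c(0, 1, 2), c(1, 2, 3)), "5 timepoints")
})

test_that("selectivity verdicts follow the significance pattern", {
  sel <- make_effects("A", sig_cells = list(`sdh1.ISE` = TRUE,
                                            `sdh2.ISE` = TRUE),
                      pct_cells = list(`sdh1.ISE` = 15, `sdh2.ISE` = 14))
  expect_equal(classify_selectivity(sel)$verdict, "selective_suppressor")

  byp <- make_effects("B", sig_cells = list(`sdh1.ISE` = TRUE,
                                            `sdh2.ISE` = TRUE,
                                            `jlp1.ISE` = TRUE,
                                            `WT.ISE` = TRUE),
                      pct_cells = list(`sdh1.ISE` = 20, `sdh2.ISE` = 18,
                                       `jlp1.ISE` = 60, `WT.ISE` = 5))
  expect_equal(classify_selectivity(byp)$verdict, "bypass_suspect")

  expect_equal(classify_selectivity(make_effects("C"))$verdict, "inactive")

  tox <- make_effects("D", sig_cells = list(`WT.AS` = TRUE,
                                            `sdh1.ISE` = TRUE),
                      pct_cells = list(`WT.AS` = -30, `sdh1.ISE` = -40))
  expect_equal(classify_selectivity(tox)$verdict, "toxic")

  # suppressor pattern spoiled by an AS response -> nonspecific
  non <- make_effects("E", sig_cells = list(`sdh1.ISE` = TRUE,
                                            `sdh2.ISE` = TRUE,
                                            `sdh1.AS` = TRUE),
                      pct_cells = list(`sdh1.ISE` = 15, `sdh2.ISE` = 14,
                                       `sdh1.AS` = 12))
  expect_equal(classify_selectivity(non)$verdict, "nonspecific")

  expect_error(classify_selectivity(sel[sel$strain != "jlp1", ]),
               "jlp1")
})

test_that("growth_effects recovers planted validation effects with protected significance", {
  eff <- compound_effects(c("S1", "I1"), c("suppressor", "inert"),
                         c(0.15, 0))
  val <- simulate_validation(eff, seed = 21)
  ge <- growth_effects(val)
  s_ise <- ge[ge$compound_id == "S1" & ge$medium == "ISE", ]
  expect_true(all(s_ise$significant[s_ise$strain %in% c("sdh1", "sdh2")]))
  expect_true(all(s_ise$pct_change[s_ise$strain %in% c("sdh1", "sdh2")] > 5))
  expect_false(any(ge$significant[ge$compound_id == "I1"]))
  expect_equal(classify_selectivity(
    ge[ge$compound_id == "S1", ])$verdict, "selective_suppressor")
})
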