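test_that("noiseless growth curves match the closed logistic form", {
  kin <- strain_kinetics("sdh1", "ISE")
  times <- c(0, 100)
  od <- growth_curve(kin, NULL, times)
  expect_equal(od[2], kin$od0 + kin$cap1, tolerance = 1e-9)

  kinw <- strain_kinetics("WT", "AS")
  odw <- growth_curve(kinw, NULL, c(0, 1000))
  expect_equal(odw[2], kinw$od0 + kinw$cap1 + kinw$cap2, tolerance = 1e-9)
})

test_that("a matching suppressor scales capacity by 1 + magnitude", {
  kin <- strain_kinetics("sdh1", "ISE")
  eff <- compound_effects("S", "suppressor", 0.15)
  times <- seq(0, 48, by = 4)
  inert <- growth_curve(kin, NULL, times)
  lifted <- growth_curve(kin, eff, times)
  expect_equal(lifted - kin$od0, 1.15 * (inert - kin$od0), tolerance = 1e-9)

  # non-matching strain/medium: no change
  kin_as <- strain_kinetics("sdh1", "AS")
  expect_equal(growth_curve(kin_as, eff, times),
               growth_curve(kin_as, NULL, times))

  # colored compounds add a constant offset, not growth
  col <- compound_effects("X", "colored", 0.3)
  expect_equal(growth_curve(kin, col, times), inert + 0.3)
})

test_that("growth curves are deterministic under a seed and reject bad input", {
  kin <- strain_kinetics("sdh1", "ISE")
  t7 <- seq(0, 24, by = 4)
  a <- growth_curve(kin, NULL, t7, noise_sd = 0.01, seed = 11)
  b <- growth_curve(kin, NULL, t7, noise_sd = 0.01, seed = 11)
  c <- growth_curve(kin, NULL, t7, noise_sd = 0.01, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(growth_curve(kin, NULL, rev(t7)), "sorted")
  expect_error(growth_curve(kin, NULL, t7, noise_sd = -1), "noise_sd")
})

test_that("noiseless curves are monotone and diauxic curves have one rate dip", {
  times <- seq(0, 24, by = 0.25)
  for (st in c("WT", "sdh1", "sdh2", "jlp1")) for (md in c("AS", "ISE")) {
    od <- growth_curve(strain_kinetics(st, md), NULL, times)
    expect_true(all(diff(od) >= -1e-12), label = paste(st, md, "monotone"))
  }
  kin <- strain_kinetics("WT", "AS")
  rate <- diff(growth_curve(kin, NULL, times)) / diff(times)
  peaks <- which(diff(sign(diff(rate))) == -2) + 1
  dips <- which(diff(sign(diff(rate))) == 2) + 1
  expect_equal(length(dips), 1L)
  expect_true(length(peaks) >= 1L && dips > min(peaks))
})

test_that("screen simulation lays out plates, controls and truth as configured", {
  sim <- simulate_screen(screen_config(library_size = 40,
                                       compounds_per_plate = 20), seed = 5)
  ann <- sim$annotations
  expect_equal(length(unique(ann$plate_id)), 2L)
  expect_equal(sum(ann$role == "experimental"), 40L)
  expect_equal(sum(ann$role == "negative_control"), 8L)
  expect_equal(nrow(sim$measurements), (40 + 8) * 7)

  # single compound: 1 experimental + 4 control wells x 7 timepoints
  one <- simulate_screen(screen_config(library_size = 1,
                                       compounds_per_plate = 80), seed = 5)
  expect_equal(nrow(one$measurements), 35L)
  expect_equal(length(unique(one$measurements$plate_id)), 1L)

  expect_error(simulate_screen(screen_config(compounds_per_plate = 95)),
               "capacity")

  # truth conservation under configured class counts
  eff <- default_effects(200, seed = 3, suppressor_frac = 0.05,
                         n_bypass = 7, n_colored = 2, n_toxic = 11)
  cnt <- table(eff$effect_class)
  expect_equal(unname(cnt["suppressor"]), 10, ignore_attr = TRUE)
  expect_equal(unname(cnt["sulfate_bypass"]), 7, ignore_attr = TRUE)
  expect_equal(unname(cnt["colored"]), 2, ignore_attr = TRUE)
  expect_equal(unname(cnt["toxic"]), 11, ignore_attr = TRUE)
  expect_true(all(eff$magnitude[eff$effect_class == "suppressor"] >= 0.10 &
                    eff$magnitude[eff$effect_class == "suppressor"] <= 0.20))

  # determinism of the full simulated bundle
  s1 <- simulate_screen(screen_config(library_size = 10,
                                      compounds_per_plate = 10), seed = 9)
  s2 <- simulate_screen(screen_config(library_size = 10,
                                      compounds_per_plate = 10), seed = 9)
  expect_identical(s1$measurements, s2$measurements)
})

test_that("abundance simulation plants the configured differential structure", {
  sim <- simulate_abundance(n_proteins = 300, de_shared = 40, de_a_only = 5,
                            de_b_only = 10, seed = 2)
  expect_equal(sum(sim$truth$membership == "shared"), 40L)
  expect_equal(sum(sim$truth$membership == "a_only"), 5L)
  expect_equal(sum(sim$truth$membership == "b_only"), 10L)
  expect_equal(dim(sim$matrix), c(300L, 9L))

  none <- simulate_abundance(n_proteins = 50, de_shared = 0, de_a_only = 0,
                             de_b_only = 0, seed = 2)
  expect_equal(sum(none$truth$differential), 0L)

  expect_error(simulate_abundance(n_reps = 1), "replicates")
  expect_error(simulate_abundance(n_proteins = 10, de_shared = 11,
                                  de_a_only = 0, de_b_only = 0),
               "exceed")

  # default partition mirrors the observed two-comparison structure
  d <- formals(simulate_abundance)
  expect_equal(d$de_shared + d$de_a_only + d$de_b_only, 1092)
})

test_that("metabolite simulation plants folds and treatment effects in truth", {
  sim <- simulate_metabolites(succinate_fold = 5, noise_cv = 0, seed = 1)
  truth <- sim$truth
  wt <- truth$mean_uM[truth$strain == "WT" & truth$treatment == "untreated" &
                        truth$metabolite == "succinate"]
  mut <- truth$mean_uM[truth$strain == "sdh1" &
                         truth$treatment == "untreated" &
                         truth$metabolite == "succinate"]
  expect_equal(mut / wt, 5.0)
  tab <- sim$table
  f <- strain_fold(tab, "succinate")
  expect_equal(f$fold[f$strain == "sdh1" & f$treatment == "untreated"], 5.0)

  null <- simulate_metabolites(treatment_effect = 0, seed = 1)
  tu <- null$truth
  for (m in unique(tu$metabolite)) for (s in unique(tu$strain)) {
    expect_equal(tu$mean_uM[tu$metabolite == m & tu$strain == s &
                              tu$treatment == "untreated"],
                 tu$mean_uM[tu$metabolite == m & tu$strain == s &
                              tu$treatment == "DMAE"])
  }
  expect_error(simulate_metabolites(succinate_fold = 0), "positive")
})
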