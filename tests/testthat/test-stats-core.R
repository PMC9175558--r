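test_that("one-way ANOVA reproduces the hand decomposition", {
  tab <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4),
                            c = c(3, 4, 5)))
  between <- tab[tab$term == "group", ]
  within <- tab[tab$term == "Residuals", ]
  expect_equal(between$sum_sq, 6)
  expect_equal(between$df, 2)
  expect_equal(within$sum_sq, 6)
  expect_equal(within$df, 6)
  expect_equal(between$F, 3.0)
  expect_equal(between$p, pf(3, 2, 6, lower.tail = FALSE))

  ident <- one_way_anova(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(ident[ident$term == "group", ]$F, 0)
  expect_equal(ident[ident$term == "group", ]$p, 1)

  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), ">= 2 values")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(6, 0, 1); b <- rnorm(9, 0.8, 1)
    f <- one_way_anova(list(a = a, b = b))
    t_stat <- t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f[f$term == "group", ]$F, unname(t_stat)^2,
                 tolerance = 1e-9)
  }
})

test_that("two-way ANOVA handles balanced designs and rejects broken ones", {
  # all cells equal: no variation anywhere
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), r = 1:3)
  flat <- two_way_anova(rep(1, nrow(d)), d$a, d$b)
  expect_equal(flat$F[1:3], c(0, 0, 0))

  # additive planted effects, tiny noise: interaction stays null
  set.seed(3)
  eff_a <- ifelse(d$a == "x", 0, 2)
  eff_b <- ifelse(d$b == "u", 0, 1)
  y <- 10 + eff_a + eff_b + rnorm(nrow(d), 0, 1e-3)
  add <- two_way_anova(y, d$a, d$b)
  expect_gt(add$F[add$term == "a"], 1e4)
  expect_gt(add$F[add$term == "b"], 1e4)
  expect_gt(add$p[add$term == "a:b"], 0.05)

  # planted interaction is detected at realistic noise
  y2 <- 10 + ifelse(d$a == "y" & d$b == "v", 3, 0) + rnorm(nrow(d), 0, 0.5)
  int <- two_way_anova(y2, d$a, d$b)
  expect_lt(int$p[int$term == "a:b"], 0.05)

  expect_error(two_way_anova(y[-1], d$a[-1], d$b[-1]), "unbalanced")
  miss <- d$a == "x" & d$b == "u"
  expect_error(two_way_anova(y[!miss], d$a[!miss], d$b[!miss]),
               "missing cell")
})

test_that("Tukey HSD matches the pooled t-test for two groups", {
  set.seed(12)
  a <- rnorm(5); b <- rnorm(5, 1)
  tk <- tukey_hsd(list(a = a, b = b))
  expect_equal(tk$p_adjusted,
               t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-6)
  # q = |t| * sqrt(2) identity
  expect_equal(tk$q,
               abs(unname(t.test(a, b, var.equal = TRUE)$statistic)) *
                 sqrt(2), tolerance = 1e-8)
})

test_that("Tukey HSD separates a far-shifted group and stars it", {
  set.seed(14)
  g <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5, 10))
  tk <- tukey_hsd(g)
  far <- tk[tk$group_a == "a" & tk$group_b == "c", ]
  near <- tk[tk$group_a == "a" & tk$group_b == "b", ]
  expect_equal(far$stars, "***")
  expect_equal(near$stars, "ns")

  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_true(all(same$p_adjusted > 0.9))
  expect_true(all(same$stars == "ns"))
})

test_that("BH adjustment is the step-up procedure with its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(20)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # step-up output is monotone in the input order statistics
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
})

test_that("Welch t handles equal groups, balanced identity and shifts", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(31)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  w <- welch_t(a, b)
  pooled <- t.test(a, b, var.equal = TRUE)
  # equal n and near-equal variances: Welch t equals pooled t exactly
  expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-9)

  shift <- welch_t(rnorm(3, 0, 1), rnorm(3, 5, 1))
  expect_lt(shift$p, 0.05)
  expect_error(welch_t(1, c(1, 2)), ">= 2 values")
})

test_that("stars map the conventional thresholds", {
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
})
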