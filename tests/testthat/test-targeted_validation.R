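test_that("Mann-Whitney switches between exact enumeration and tie-corrected normal", {
  res <- mw_test(1:3, 4:6)
  expect_equal(res$method, "exact")
  expect_equal(res$p, 0.1)
  expect_equal(res$U, 0)
  # agreement with the reference implementation on clean small samples
  expect_equal(mw_test(c(1, 5, 9, 11), c(2, 3, 4, 10))$p,
               stats::wilcox.test(c(1, 5, 9, 11), c(2, 3, 4, 10),
                                  exact = TRUE)$p.value)
  # two-tie-group hand computation: ranks a -> 10, b -> 29
  z <- mw_test(c(rep("a", 8), rep("b", 10)) == "b",
               c(rep("a", 11), rep("b", 9)) == "b")
  expect_equal(z$method, "normal")
  expect_equal(z$z, 19 / sqrt(878.1081), tolerance = 1e-4)
  # all values tied: zero variance, p = 1
  expect_equal(mw_test(rep(2, 10), rep(2, 12))$p, 1)
  expect_error(mw_test(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(15)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  p0 <- mw_test(x, y)$p
  expect_equal(mw_test(exp(x), exp(y))$p, p0)
  expect_equal(mw_test(x^3, y^3)$p, p0)
  p_swap <- mw_test(y, x)$p
  expect_equal(p_swap, p0)
})

test_that("per-CpG and mean comparisons run over all contrasts", {
  cfg <- sim_config(seed = 33)
  tp <- simulate_targeted_panel(cfg, list(G1 = c(-3, -4), G2 = c(0)))
  for (ct in c("all", "igdm", "dgdm")) {
    res <- mw_compare_cpgs(tp$panel, tp$samples, ct)
    expect_setequal(res$cpg[res$gene == "G1"], c("1", "2", "mean"))
    expect_true(all(res$p[res$gene == "G1"] < 0.01))
    expect_true(all(res$delta_pp[res$gene == "G1"] < 0))
  }
})

test_that("adjusted regression recovers planted effects exactly at zero noise", {
  cfg <- sim_config(seed = 41)
  tp <- simulate_targeted_panel(
    cfg, list(ATP5A1 = c(-2.2)), noise_sd = 0,
    covariate_effects = c(bmi = 0.3, gestational_week = -0.8, sex_male = 1.5))
  adj <- adjusted_effect_regression(tp$panel, tp$samples, "all")
  expect_equal(adj$adj_delta_pp[adj$cpg == "1"], -2.2, tolerance = 1e-9)
  # with confounding active, the unadjusted difference is biased away
  mw <- mw_compare_cpgs(tp$panel, tp$samples, "all")
  expect_gt(abs(mw$delta_pp[mw$cpg == "1"] - (-2.2)), 0.1)
})

test_that("adjusted regression matches the unadjusted contrast without confounding", {
  cfg <- sim_config(seed = 43)
  tp <- simulate_targeted_panel(cfg, list(G = c(3.1)), noise_sd = 0)
  adj <- adjusted_effect_regression(tp$panel, tp$samples, "all")
  mw <- mw_compare_cpgs(tp$panel, tp$samples, "all")
  expect_equal(adj$adj_delta_pp[adj$cpg == "1"],
               mw$delta_pp[mw$cpg == "1"], tolerance = 1e-9)
  expect_equal(adj$adj_delta_pp[adj$cpg == "1"], 3.1, tolerance = 1e-9)
})

test_that("noisy adjusted effects are recovered at the validation scale", {
  hits <- sapply(1:10, function(s) {
    cfg <- sim_config(seed = 500 + s)
    tp <- simulate_targeted_panel(
      cfg, list(SLC17A4 = c(5.3)), noise_sd = 1.5,
      covariate_effects = c(bmi = 0.1, gestational_week = -0.3,
                            sex_male = 0.5))
    adj <- adjusted_effect_regression(tp$panel, tp$samples, "all")
    abs(adj$adj_delta_pp[adj$cpg == "1"] - 5.3) < 0.5
  })
  expect_gte(sum(hits), 9)
})

test_that("rank-deficient designs are reported explicitly", {
  cfg <- sim_config(seed = 47)
  tp <- simulate_targeted_panel(cfg, list(G = c(1)))
  sam <- tp$samples
  sam$fetal_sex <- "M"  # single-sex data: sex column collinear with intercept
  expect_error(adjusted_effect_regression(tp$panel, sam, "all"),
               "rank-deficient")
})

test_that("neighboring-CpG differences behave additively and antisymmetrically", {
  cfg <- sim_config(seed = 51)
  tp <- simulate_targeted_panel(cfg, list(SLC17A4 = c(0, 4.4, -0.8)),
                                noise_sd = 0)
  nd <- neighbor_cpg_difference(tp$panel, tp$samples, "SLC17A4", c(2, 3),
                                "all")
  expect_equal(nd$adjusted$adj_delta_pp, 5.2, tolerance = 1e-9)
  nd_swap <- neighbor_cpg_difference(tp$panel, tp$samples, "SLC17A4",
                                     c(3, 2), "all")
  expect_equal(nd_swap$adjusted$adj_delta_pp, -5.2, tolerance = 1e-9)
  # i = j: all differences zero, p = 1
  nd0 <- neighbor_cpg_difference(tp$panel, tp$samples, "SLC17A4", c(2, 2),
                                 "all")
  expect_equal(nd0$mw$p, 1)
  expect_error(neighbor_cpg_difference(tp$panel, tp$samples, "SLC17A4",
                                       c(2, 9), "all"), "missing")
})
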