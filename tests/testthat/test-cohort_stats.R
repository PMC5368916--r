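test_that("Fisher's exact test reproduces published sex-distribution p-values", {
  # cohort A sex row: 8M/10F controls vs 11M/9F I-GDM
  expect_equal(round(fisher_exact_2x2(matrix(c(8, 10, 11, 9), 2,
                                             byrow = TRUE)), 3), 0.746)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("Fisher p is invariant under transposition and row/column swaps", {
  tab <- matrix(c(8, 10, 11, 9), 2, byrow = TRUE)
  p <- fisher_exact_2x2(tab)
  expect_equal(fisher_exact_2x2(t(tab)), p)
  expect_equal(fisher_exact_2x2(tab[2:1, ]), p)
  expect_equal(fisher_exact_2x2(tab[, 2:1]), p)
})

test_that("Pearson chi-square reproduces the three-group sex-row p-values", {
  b <- pearson_chisq_rxc(matrix(c(22, 24, 12, 12, 12, 12), 3, byrow = TRUE))
  expect_equal(b$df, 2)
  expect_equal(round(b$p, 3), 0.978)
  pyro <- pearson_chisq_rxc(matrix(c(29, 27, 25, 38, 34, 26), 3,
                                   byrow = TRUE))
  expect_equal(round(pyro$p, 3), 0.152)
  flat <- pearson_chisq_rxc(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_error(pearson_chisq_rxc(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("chi-square p falls as a planted association strengthens", {
  ps <- sapply(0:6, function(k)
    pearson_chisq_rxc(matrix(c(10 + k, 10 - k, 10 - k, 10 + k), 2))$p)
  expect_false(is.unsorted(rev(ps), strictly = TRUE))
  # permutation invariance
  tab <- matrix(c(12, 30, 25, 8, 14, 19), 3)
  expect_equal(pearson_chisq_rxc(tab)$p, pearson_chisq_rxc(tab[c(3, 1, 2), ])$p)
})

test_that("Fisher and Pearson converge as tables fill", {
  # the exact conditional two-sided p stays within ~0.1 of the chi-square p
  # at expected counts near 80 and within 0.05 once cells reach the hundreds
  set.seed(77)
  d_mid <- replicate(50, {
    tab <- matrix(rpois(4, 60) + 20, 2)
    abs(fisher_exact_2x2(tab) - pearson_chisq_rxc(tab)$p)
  })
  expect_lt(max(d_mid), 0.10)
  expect_lt(mean(d_mid), 0.05)
  d_big <- replicate(20, {
    tab <- matrix(rpois(4, 300) + 100, 2)
    abs(fisher_exact_2x2(tab) - pearson_chisq_rxc(tab)$p)
  })
  expect_lt(max(d_big), 0.05)
})

test_that("continuous group tests dispatch by number of groups", {
  # three separated groups: Kruskal-Wallis H = 7.2
  v <- 1:9
  g <- factor(rep(c("a", "b", "c"), each = 3))
  expect_equal(continuous_group_test(v, g),
               stats::pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(continuous_group_test(rep(1, 9), g), 1)
  # two groups delegate to the Mann-Whitney test
  v2 <- c(1, 2, 3, 4, 5, 6)
  g2 <- factor(rep(c("a", "b"), each = 3))
  expect_equal(continuous_group_test(v2, g2), mw_test(1:3, 4:6)$p)
})

test_that("the characteristics table reproduces the published sex-row p-values", {
  sex_sheet <- function(counts) {
    # counts: list(group = c(M, F))
    do.call(rbind, lapply(names(counts), function(g)
      data.frame(group = g,
                 fetal_sex = rep(c("M", "F"), counts[[g]]),
                 stringsAsFactors = FALSE)))
  }
  tabA <- build_characteristics_table(
    sex_sheet(list(control = c(8, 10), igdm = c(11, 9))),
    c(fetal_sex = "categorical"))
  expect_equal(round(tabA$p, 3), 0.746)
  tabB <- build_characteristics_table(
    sex_sheet(list(control = c(22, 24), dgdm = c(12, 12), igdm = c(12, 12))),
    c(fetal_sex = "categorical"))
  expect_equal(round(tabB$p, 3), 0.978)
  tabP <- build_characteristics_table(
    sex_sheet(list(control = c(29, 27), dgdm = c(25, 38), igdm = c(34, 26))),
    c(fetal_sex = "categorical"))
  expect_equal(round(tabP$p, 3), 0.152)
})

test_that("characteristics rows handle continuous, constant and missing data", {
  set.seed(19)
  sheet <- data.frame(
    group = rep(c("control", "igdm"), each = 12),
    maternal_bmi = c(rnorm(12, 25, 3), rnorm(12, 30, 3)),
    gestational_week = rep(39, 24),
    hba1c = c(rep(NA, 12), rnorm(12, 5.9, 0.5)),
    fetal_sex = sample(c("M", "F"), 24, TRUE), stringsAsFactors = FALSE)
  tab <- build_characteristics_table(
    sheet, c(maternal_bmi = "continuous", gestational_week = "continuous",
             fetal_sex = "categorical"))
  expect_equal(nrow(tab), 3)
  expect_lt(tab$p[tab$variable == "maternal_bmi"], 0.05)
  expect_equal(tab$p[tab$variable == "gestational_week"], 1)
  expect_error(build_characteristics_table(sheet, c(maternal_bmi = "weird")),
               "unknown variable type")
})
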