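test_that("configuration validation rejects impossible study designs", {
  expect_error(sim_config(group_sizes = list(A = c(control = 0, igdm = 5))),
               "positive")
  expect_error(sim_config(effect_range_pp = c(1, 150)), "\\[-100, 100\\]")
  expect_error(sim_config(frac_differential = 1.5), "frac_differential")
  expect_error(sim_config(type2_bias = 0), "type2_bias")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_probes = 300, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$beadcount, s2$beadcount)
  expect_identical(s1$detection_p, s2$detection_p)
})

test_that("all betas lie in [0,1] and cell weights are convex", {
  sim <- simulate_cohort(sim_config(n_probes = 400, seed = 2))
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
  expect_true(all(abs(rowSums(sim$cell_weights) - 1) < 1e-12))
  expect_true(all(sim$cell_weights >= 0))
})

test_that("zero differential fraction yields an all-zero truth table", {
  sim <- simulate_cohort(sim_config(n_probes = 200, frac_differential = 0,
                                    seed = 3))
  expect_false(any(sim$truth$is_differential))
  expect_true(all(sim$truth$true_effect_pp == 0))
})

test_that("planted group effects are recovered from group mean differences", {
  cfg <- sim_config(n_probes = 1000, frac_differential = 0.10,
                    effect_range_pp = c(1, 4.5), n_cell_types = 1,
                    type2_bias = 1, cohort_effect_scale = c(B = 1),
                    group_sizes = list(B = c(control = 46, igdm = 24)),
                    seed = 11)
  sim <- simulate_cohort(cfg)
  grp <- sim$samples$group
  d <- 100 * (rowMeans(sim$beta[, grp == "igdm"]) -
                rowMeans(sim$beta[, grp == "control"]))
  diffp <- sim$truth$is_differential
  # aggregate recovery: mean absolute observed difference tracks the planted
  # magnitudes within half a percentage point
  expect_lt(abs(mean(abs(d[diffp])) -
                  mean(abs(sim$truth$true_effect_pp[diffp]))), 0.5)
  # and signs agree at planted probes
  expect_true(all(sign(d[diffp]) == sign(sim$truth$true_effect_pp[diffp])))
  # null probes show no systematic difference
  expect_lt(abs(mean(d[!diffp])), 0.1)
})

test_that("non-differential probes are distributionally identical across groups", {
  cfg <- sim_config(n_probes = 300, frac_differential = 0, n_cell_types = 1,
                    type2_bias = 1,
                    group_sizes = list(B = c(control = 100, igdm = 100)),
                    seed = 8)
  sim <- simulate_cohort(cfg)
  grp <- sim$samples$group
  ks_p <- apply(sim$beta, 1, function(r)
    suppressWarnings(stats::ks.test(r[grp == "control"],
                                    r[grp == "igdm"])$p.value))
  expect_gte(mean(ks_p > 0.01), 0.97)
})

test_that("targeted panel recovers planted per-CpG effects and validates input", {
  cfg <- sim_config(seed = 21)
  expect_error(simulate_targeted_panel(cfg, list(G1 = numeric(0))),
               "at least one CpG")
  expect_error(simulate_targeted_panel(cfg, list(1:3)), "named list")

  # zero effects, zero noise: group means identical
  tp0 <- simulate_targeted_panel(cfg, list(G1 = c(0, 0)), noise_sd = 0)
  m <- merge(tp0$panel, tp0$samples[, c("sample_id", "group")])
  gm <- tapply(m$methylation_pct, list(m$group, m$cpg_index), mean)
  expect_lt(max(apply(gm, 2, function(col) max(col) - min(col))), 1e-12)

  # planted per-CpG hypomethylation recovered within noise standard error
  eff <- c(-1.1, -1.9, -1.2)
  tp <- simulate_targeted_panel(cfg, list(PRKCH = eff))
  m <- merge(tp$panel, tp$samples[, c("sample_id", "group")])
  for (k in 1:3) {
    sub <- m[m$cpg_index == k, ]
    d <- mean(sub$methylation_pct[sub$group != "control"]) -
      mean(sub$methylation_pct[sub$group == "control"])
    se <- 1.5 * sqrt(1 / 56 + 1 / 125)
    expect_lt(abs(d - eff[k]), 3 * se)
  }
})

test_that("cell reference enforces the discrimination margin and is full rank", {
  expect_error(simulate_cell_reference(1, 100, 10), "at least 2")
  expect_error(simulate_cell_reference(3, 10, 20), "exceed")
  ref <- simulate_cell_reference(2, 100, 20, margin = 0.5, seed = 4)
  disc <- ref$profiles[ref$discriminating, ]
  expect_true(all(apply(disc, 1, function(r) max(r) - min(r)) >= 0.5 - 1e-9))
  expect_identical(ref$profiles,
                   simulate_cell_reference(2, 100, 20, margin = 0.5,
                                           seed = 4)$profiles)
  ref6 <- simulate_cell_reference(6, 400, 200, seed = 7)
  expect_equal(qr(ref6$profiles[ref6$discriminating, ])$rank, 6)
})
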