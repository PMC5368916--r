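test_that("variance prior reports infinite df for homogeneous variances", {
  pr <- estimate_variance_prior(rep(0.01, 100), 36)
  expect_true(is.infinite(pr$df_prior))
  # the log-scale moment estimate carries a small-sample factor
  # (d/2)/exp(digamma(d/2)) ~ 1.03 at d = 36
  expect_equal(pr$var_prior, 0.01, tolerance = 0.03)
  expect_error(estimate_variance_prior(c(-1, 1), 10), "non-negative")
  expect_error(estimate_variance_prior(c(0.1), 10), "at least 2")
})

test_that("variance prior recovers hierarchy hyperparameters", {
  set.seed(2)
  d0 <- 4; s02 <- 0.01; dg <- 36; m <- 5000
  sigma2 <- s02 * d0 / rchisq(m, d0)
  s2 <- sigma2 * rchisq(m, dg) / dg
  pr <- estimate_variance_prior(s2, dg)
  expect_lt(abs(pr$df_prior - d0), 1)
  expect_lt(abs(pr$var_prior - s02) / s02, 0.10)
})

test_that("variance prior agrees with the limma empirical-Bayes fit", {
  set.seed(9)
  mu <- runif(2000, 0.05, 0.95)
  prec <- exp(runif(2000, log(50), log(3000)))
  b <- t(sapply(seq_along(mu), function(i)
    rbeta(12, mu[i] * prec[i], (1 - mu[i]) * prec[i])))
  rownames(b) <- paste0("p", seq_along(mu))
  g <- factor(rep(c("ctrl", "gdm"), each = 6), levels = c("ctrl", "gdm"))
  mine <- moderated_t_test(b, g)
  fit <- limma::eBayes(limma::lmFit(b, stats::model.matrix(~g)))
  expect_equal(attr(mine, "prior")$df_prior, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "prior")$var_prior, fit$s2.prior, tolerance = 1e-6)
  expect_lt(max(abs(mine$t - fit$t[, 2])), 1e-10)
  expect_lt(max(abs(mine$p - fit$p.value[, 2])), 1e-10)
})

test_that("zero prior df reduces the moderated t to the classical pooled t", {
  set.seed(4)
  b <- matrix(rbeta(500 * 10, 5, 5), 500,
              dimnames = list(paste0("p", 1:500), paste0("s", 1:10)))
  g <- factor(rep(c("a", "b"), each = 5))
  res <- moderated_t_test(b, g, prior = list(df_prior = 0, var_prior = 1))
  classical <- apply(b, 1, function(r)
    stats::t.test(r[6:10], r[1:5], var.equal = TRUE)$statistic)
  expect_lt(max(abs(res$t - classical)), 1e-10)
})

test_that("degenerate probes give t = 0, p = 1 and signs track the effect", {
  b <- rbind(p1 = rep(0.5, 8),
             p2 = c(0.3, 0.31, 0.29, 0.30, 0.5, 0.52, 0.48, 0.50))
  colnames(b) <- paste0("s", 1:8)
  g <- factor(rep(c("ctrl", "gdm"), each = 4), levels = c("ctrl", "gdm"))
  res <- moderated_t_test(b, g, prior = list(df_prior = 0, var_prior = 1))
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(sign(res$t[2]), sign(res$delta_beta_pp[2]))
  expect_true(all(res$p_adj >= res$p))
  expect_error(moderated_t_test(b, factor(rep("x", 8))), "two levels")
})

test_that("BH adjustment matches the hand-computed step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(200)
  adj <- bh_adjust(p)
  o <- order(p)
  expect_false(is.unsorted(adj[o]))
})

test_that("subset summaries detect planted subset-specific shifts only", {
  cfg <- sim_config(n_probes = 1200, frac_differential = 0, n_cell_types = 1,
                    type2_bias = 1,
                    group_sizes = list(B = c(control = 20, igdm = 20)),
                    seed = 23)
  sim <- simulate_cohort(cfg)
  grp <- factor(sim$samples$group, levels = c("control", "igdm"))

  res0 <- subset_global_summary(sim$beta, sim$manifest, grp)
  expect_true(all(c("all", "island", "open_sea") %in% res0$subset))
  diffs0 <- res0$mean_pp_igdm - res0$mean_pp_control
  expect_lt(max(abs(diffs0)), 0.5)

  # +2 pp shift at island probes of the exposed group only
  beta <- sim$beta
  isl <- sim$manifest$cgi_relation == "island"
  beta[isl, grp == "igdm"] <- pmin(beta[isl, grp == "igdm"] + 0.02, 1)
  res <- subset_global_summary(beta, sim$manifest, grp)
  d <- stats::setNames(res$mean_pp_igdm - res$mean_pp_control, res$subset)
  expect_gt(d["island"], 1.5)
  expect_lt(max(abs(d[setdiff(names(d), c("island", "all"))])), 0.5)

  # uniform +1 pp shift moves every subset by one point
  beta1 <- sim$beta
  beta1[, grp == "igdm"] <- beta1[, grp == "igdm"] + 0.01
  res1 <- subset_global_summary(beta1, sim$manifest, grp)
  expect_equal(res1$mean_pp_igdm - res1$mean_pp_control - diffs0,
               rep(1, nrow(res1)), tolerance = 1e-9)
})

test_that("covariate scan recovers a planted slope and stays null-calibrated", {
  set.seed(12)
  n <- 94
  hba1c <- runif(n, 4.5, 7)
  b0 <- matrix(rbeta(100 * n, 30, 30), 100,
               dimnames = list(paste0("p", 1:100), paste0("s", 1:n)))
  b <- b0 + matrix(0.004 * (hba1c - mean(hba1c)), 100, n, byrow = TRUE)
  res <- cov_res <- covariate_scan(b, hba1c)
  expect_lt(abs(mean(res$slope) - 0.004) / 0.004, 0.10)
  expect_error(covariate_scan(b, rep(1, n)), "distinct")

  # independent covariate: no BH discoveries in nearly all seeded runs
  hits <- sapply(1:10, function(s) {
    set.seed(100 + s)
    bn <- matrix(rbeta(10000 * 30, 20, 20), 10000,
                 dimnames = list(paste0("p", 1:10000), paste0("s", 1:30)))
    sum(covariate_scan(bn, rnorm(30))$p_adj < 0.05)
  })
  expect_gte(sum(hits == 0), 9)
})
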