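#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior for probe-wise residual variances
#' by the log-variance moment method: with
#' `e_g = ln s2_g - digamma(d_g/2) + ln(d_g/2)`, the prior degrees of freedom
#' `d0` solve `trigamma(d0/2) = mean[(e_g - ebar)^2 * m/(m-1) -
#' trigamma(d_g/2)]` (monotone bisection; if the right-hand side is not
#' positive the prior is infinite), and the prior variance is
#' `s0^2 = exp(ebar + digamma(d0/2) - ln(d0/2))` (`exp(ebar)` when `d0` is
#' infinite).
#'
#' @param s2 Vector of probe-wise sample variances (non-positive or
#'   non-finite entries are dropped and counted).
#' @param df Residual degrees of freedom, a scalar or vector matching `s2`.
#' @return An object of class `variance_prior`: list with `df_prior` (d0,
#'   possibly `Inf`), `var_prior` (s0^2), `n_used`, `n_dropped`.
#' @export
estimate_variance_prior <- function(s2, df) {
  if (any(s2 < 0, na.rm = TRUE)) stop("variances must be non-negative")
  if (length(df) == 1) df <- rep(df, length(s2))
  if (length(df) != length(s2)) stop("df must be scalar or match s2")
  if (any(df < 1)) stop("residual degrees of freedom must be >= 1")
  ok <- is.finite(s2) & s2 > 0
  n_dropped <- sum(!ok)
  s2 <- s2[ok]; df <- df[ok]
  m <- length(s2)
  if (m < 2) stop("need at least 2 positive finite variances")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * m / (m - 1) - trigamma(df / 2))
  if (rhs <= 0 || trigamma(0.5e6) >= rhs) {
    d0 <- Inf
    s02 <- exp(ebar)
  } else {
    g <- function(y) trigamma(y) - rhs  # decreasing in y
    lo <- 1e-8; hi <- 0.5e6
    for (i in 1:200) {                  # bisection to high precision
      mid <- sqrt(lo * hi)
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    d0 <- 2 * sqrt(lo * hi)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(df_prior = d0, var_prior = s02, n_used = m,
                 n_dropped = n_dropped),
            class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("Variance prior: d0 = %s, s0^2 = %.4g (from %d probes)\n",
              format(x$df_prior), x$var_prior, x$n_used))
  invisible(x)
}

#' Moderated two-sample t-test on beta values
#'
#' Per-probe empirical-Bayes moderated t-test of a two-group contrast. For
#' each probe the pooled residual variance `s2_g` (with `d_g = n1 + n2 - 2`
#' degrees of freedom) is shrunk toward the prior,
#' `s2~ = (d0 s0^2 + d_g s2_g) / (d0 + d_g)`, and the statistic
#' `t = delta / (s~ sqrt(1/n1 + 1/n2))` is referred to a t distribution with
#' `d0 + d_g` degrees of freedom (normal when `d0` is infinite). The reported
#' effect is `delta = mean(second level) - mean(first level)`; order the group
#' factor with the control group first so that positive effects mean
#' hypermethylation in the exposed group.
#'
#' @param beta Probes x samples beta matrix.
#' @param groups Factor (or coercible) of length `ncol(beta)` with exactly two
#'   levels, each represented by at least 2 samples.
#' @param prior A `variance_prior`; estimated from this matrix's own pooled
#'   variances when `NULL`. Pass `list(df_prior = 0)` for the classical
#'   unmoderated pooled t-test.
#' @return A `data.frame` (class `dm_result`) with columns `probe_id`, group
#'   means, `delta_beta_pp` (percentage points), `s2`, `df_residual`, `t`,
#'   `p`, `p_adj` (Benjamini-Hochberg), with the prior attached as attribute
#'   `prior`.
#' @export
moderated_t_test <- function(beta, groups, prior = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (length(groups) != ncol(beta))
    stop("groups length must match the number of samples")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (min(n1, n2) < 2) stop("each group needs at least 2 samples")
  x1 <- beta[, groups == levels(groups)[1], drop = FALSE]
  x2 <- beta[, groups == levels(groups)[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  if (is.null(prior)) prior <- estimate_variance_prior(s2, dg)
  d0 <- prior$df_prior
  s02 <- if (is.null(prior$var_prior)) 0 else prior$var_prior
  stilde2 <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dg * s2) / (d0 + dg)
  delta <- m2 - m1
  se <- sqrt(stilde2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, Inf * sign(delta)))
  p <- 2 * stats::pt(-abs(tstat), df = d0 + dg)
  p[se == 0 & delta == 0] <- 1
  out <- data.frame(probe_id = rownames(beta), mean_1 = m1, mean_2 = m2,
                    delta_beta_pp = 100 * delta, s2 = s2, df_residual = dg,
                    t = tstat, p = p, p_adj = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:3] <- paste0("mean_", make.names(levels(groups)))
  attr(out, "prior") <- prior
  attr(out, "groups") <- levels(groups)
  class(out) <- c("dm_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' `p~_(i) = min(min_{j>=i} p_(j) m / j, 1)`; order-preserving with stable
#' ties. Thin wrapper around [stats::p.adjust()] with input validation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Global methylation summaries by CpG-island relation
#'
#' Computes, for each CGI-relation subset of probes (and for all probes
#' combined), the per-sample mean beta, reports group means in percentage
#' points, and compares groups by rank test (Mann-Whitney for two groups,
#' Kruskal-Wallis for more).
#'
#' @param beta Probes x samples beta matrix.
#' @param manifest Probe manifest with `probe_id` and `cgi_relation`.
#' @param groups Factor of group memberships, length `ncol(beta)`.
#' @return Data.frame with one row per subset: `subset`, `n_probes`, one
#'   `mean_pp_<group>` column per group, and `p`.
#' @export
subset_global_summary <- function(beta, manifest, groups) {
  groups <- droplevels(as.factor(groups))
  idx <- match(rownames(beta), manifest$probe_id)
  if (anyNA(idx)) stop("manifest is missing probes present in beta")
  rel <- manifest$cgi_relation[idx]
  subsets <- c(list(all = rep(TRUE, nrow(beta))),
               lapply(split(seq_len(nrow(beta)), rel), function(i)
                 seq_len(nrow(beta)) %in% i))
  rows <- lapply(names(subsets), function(nm) {
    sel <- subsets[[nm]]
    if (!any(sel)) stop("empty probe subset: ", nm)
    sample_means <- colMeans(beta[sel, , drop = FALSE])
    gm <- tapply(sample_means, groups, mean)
    p <- if (nlevels(groups) == 2) {
      mw_test(sample_means[groups == levels(groups)[1]],
              sample_means[groups == levels(groups)[2]])$p
    } else {
      stats::kruskal.test(sample_means, groups)$p.value
    }
    c(list(subset = nm, n_probes = sum(sel)),
      as.list(stats::setNames(100 * as.numeric(gm),
                              paste0("mean_pp_", make.names(names(gm))))),
      list(p = p))
  })
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

#' Per-probe association scan against a continuous covariate
#'
#' Simple linear regression of each probe's beta values on a continuous
#' covariate (e.g. HbA1c, birth weight, gestational age), with the residual
#' variance moderated by a prior estimated from the scan's own variances,
#' two-sided p-values and Benjamini-Hochberg adjustment. Samples with missing
#' covariate values are dropped (count reported as attribute `n_dropped`).
#'
#' @param beta Probes x samples beta matrix.
#' @param covariate Numeric vector of length `ncol(beta)`; needs at least 3
#'   distinct non-missing values.
#' @param prior Optional `variance_prior` to reuse; estimated from this scan
#'   when `NULL`.
#' @return Data.frame with `probe_id`, `slope` (beta per covariate unit),
#'   `t`, `p`, `p_adj`.
#' @export
covariate_scan <- function(beta, covariate, prior = NULL) {
  if (length(covariate) != ncol(beta))
    stop("covariate length must match the number of samples")
  ok <- is.finite(covariate)
  n_dropped <- sum(!ok)
  x <- covariate[ok]
  b <- beta[, ok, drop = FALSE]
  if (length(unique(x)) < 3)
    stop("covariate must have at least 3 distinct values")
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.numeric(b %*% xc) / sxx
  syy <- rowSums((b - rowMeans(b))^2)
  rss <- pmax(syy - slope^2 * sxx, 0)
  dg <- n - 2
  s2 <- rss / dg
  if (is.null(prior)) prior <- estimate_variance_prior(s2, dg)
  d0 <- prior$df_prior
  stilde2 <- if (is.infinite(d0)) rep(prior$var_prior, length(s2)) else
    (d0 * prior$var_prior + dg * s2) / (d0 + dg)
  se <- sqrt(stilde2 / sxx)
  tstat <- ifelse(se > 0, slope / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = d0 + dg)
  p[se == 0] <- 1
  out <- data.frame(probe_id = rownames(beta), slope = slope, t = tstat,
                    p = p, p_adj = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "prior") <- prior
  attr(out, "n_dropped") <- n_dropped
  out
}
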