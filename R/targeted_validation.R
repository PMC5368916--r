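#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. With at most 8
#' observations per group and no ties, the exact null distribution of U is
#' enumerated over all group assignments; otherwise the normal approximation
#' is used with the tie-corrected variance
#' `Var = (n1 n2 / 12) [(N + 1) - sum(t^3 - t) / (N (N - 1))]`
#' and no continuity correction. When all values are tied the variance is
#' zero and p = 1.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `U` (for the first sample), `p`, `method`
#'   (`"exact"`/`"normal"`) and `z` (normal case only).
#' @export
mw_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_v)
  no_ties <- all(ties == 1)
  if (n1 <= 8 && n2 <= 8 && no_ties) {
    N <- n1 + n2
    idx <- utils::combn(N, n1)
    u_null <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_null <= U), mean(u_null >= U)))
    return(list(U = U, p = p, method = "exact", z = NA_real_))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(list(U = U, p = 1, method = "normal", z = 0))
  z <- (U - mu) / sqrt(v)
  list(U = U, p = 2 * stats::pnorm(-abs(z)), method = "normal", z = z)
}

panel_groups <- function(samples, contrast = c("all", "igdm", "dgdm")) {
  contrast <- match.arg(contrast)
  gdm <- switch(contrast, all = c("dgdm", "igdm"), igdm = "igdm",
                dgdm = "dgdm")
  ifelse(samples$group %in% gdm, "gdm",
         ifelse(samples$group == "control", "control", NA_character_))
}

panel_wide <- function(panel, gene) {
  sub <- panel[panel$gene == gene, ]
  if (nrow(sub) == 0) stop("gene not present in panel: ", gene)
  wide <- stats::reshape(sub, idvar = "sample_id", timevar = "cpg_index",
                         direction = "wide", drop = "gene")
  names(wide) <- sub("^methylation_pct\\.", "cpg", names(wide))
  wide
}

#' Per-CpG and mean-methylation Mann-Whitney comparisons for a targeted panel
#'
#' For each gene, compares the methylation percentage at every individual CpG
#' and the per-sample mean over all CpGs of the region between GDM and
#' control samples with the two-sided Mann-Whitney U test of [mw_test()].
#'
#' @param panel Long data.frame with columns `sample_id`, `gene`,
#'   `cpg_index`, `methylation_pct` (0-100 scale).
#' @param samples Sample sheet with `sample_id` and `group`
#'   (control/dgdm/igdm).
#' @param contrast `"all"` (both GDM subgroups vs control), `"igdm"` or
#'   `"dgdm"`.
#' @return Data.frame with `gene`, `cpg` (index or `"mean"`), group sizes,
#'   `delta_pp` (GDM minus control mean, percentage points), `U`, `p`.
#' @export
mw_compare_cpgs <- function(panel, samples, contrast = c("all", "igdm",
                                                         "dgdm")) {
  contrast <- match.arg(contrast)
  grp <- panel_groups(samples, contrast)
  keep <- samples$sample_id[!is.na(grp)]
  glab <- stats::setNames(grp[!is.na(grp)], keep)
  rows <- list()
  for (g in unique(panel$gene)) {
    wide <- panel_wide(panel, g)
    wide <- wide[wide$sample_id %in% keep, ]
    cols <- grep("^cpg", names(wide), value = TRUE)
    mat <- as.matrix(wide[, cols, drop = FALSE])
    vals <- cbind(mat, mean = rowMeans(mat))
    lab <- glab[wide$sample_id]
    if (min(table(lab)) < 2) stop("both groups need at least 2 samples")
    for (cn in colnames(vals)) {
      ctrl <- vals[lab == "control", cn]; gdm <- vals[lab == "gdm", cn]
      mt <- mw_test(gdm, ctrl)
      rows[[paste(g, cn)]] <- data.frame(
        gene = g, cpg = sub("^cpg", "", cn), n_gdm = length(gdm),
        n_control = length(ctrl), delta_pp = mean(gdm) - mean(ctrl),
        U = mt$U, p = mt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confounder-adjusted effect estimation for a targeted panel
#'
#' Ordinary least squares of the methylation percentage on the design
#' `[intercept, group indicator, maternal BMI, gestational week, fetal sex]`
#' per CpG and for the per-sample mean over the region. The group coefficient
#' is the adjusted methylation difference in percentage points (positive =
#' hypermethylation in GDM); its two-sided p-value comes from the t
#' distribution with `n - 5` degrees of freedom.
#'
#' @inheritParams mw_compare_cpgs
#' @param samples Sample sheet additionally carrying `maternal_bmi`,
#'   `gestational_week`, `fetal_sex` (`"M"`/`"F"`).
#' @return Data.frame with `gene`, `cpg`, `adj_delta_pp`, `se`, `p`.
#' @export
adjusted_effect_regression <- function(panel, samples,
                                       contrast = c("all", "igdm", "dgdm")) {
  contrast <- match.arg(contrast)
  grp <- panel_groups(samples, contrast)
  keep <- !is.na(grp)
  sam <- samples[keep, ]
  sam$g01 <- as.numeric(grp[keep] == "gdm")
  sam$sex01 <- as.numeric(sam$fetal_sex == "M")
  rows <- list()
  for (g in unique(panel$gene)) {
    wide <- panel_wide(panel, g)
    wide <- merge(wide, sam, by = "sample_id")
    cols <- grep("^cpg", names(wide), value = TRUE)
    mat <- as.matrix(wide[, cols, drop = FALSE])
    vals <- cbind(mat, mean = rowMeans(mat))
    X <- cbind(1, wide$g01, wide$maternal_bmi, wide$gestational_week,
               wide$sex01)
    if (qr(X)$rank < ncol(X))
      stop("design matrix is rank-deficient for gene ", g,
           " (collinear covariates or single-sex data)")
    if (nrow(X) <= ncol(X) + 1) stop("too few samples for the adjusted model")
    for (cn in colnames(vals)) {
      fit <- stats::lm.fit(X, vals[, cn])
      df <- nrow(X) - ncol(X)
      sigma2 <- sum(fit$residuals^2) / df
      xtx_inv <- chol2inv(chol(crossprod(X)))
      se <- sqrt(sigma2 * xtx_inv[2, 2])
      coef <- fit$coefficients[2]
      p <- if (se > 0) 2 * stats::pt(-abs(coef / se), df) else
        as.numeric(coef != 0) * 0 + ifelse(coef == 0, 1, 0)
      rows[[paste(g, cn)]] <- data.frame(
        gene = g, cpg = sub("^cpg", "", cn), adj_delta_pp = unname(coef),
        se = se, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neighboring-CpG methylation difference analysis
#'
#' Treats the per-sample difference `methylation(i) - methylation(j)` between
#' two CpGs of one gene as a derived phenotype and reports both the
#' unadjusted Mann-Whitney comparison and the confounder-adjusted regression
#' contrast between GDM and control samples. A pair of neighboring CpGs whose
#' difference shifts in exposed samples captures local methylation profile
#' changes that single-CpG statistics can miss.
#'
#' @inheritParams adjusted_effect_regression
#' @param gene Gene name present in the panel.
#' @param cpg_pair Integer vector `c(i, j)`: the difference is CpG i minus
#'   CpG j.
#' @return List with `mw` (from [mw_compare_cpgs()] on the difference) and
#'   `adjusted` (from [adjusted_effect_regression()]).
#' @export
neighbor_cpg_difference <- function(panel, samples, gene, cpg_pair,
                                    contrast = c("all", "igdm", "dgdm")) {
  contrast <- match.arg(contrast)
  sub <- panel[panel$gene == gene, ]
  if (nrow(sub) == 0) stop("gene not present in panel: ", gene)
  for (k in cpg_pair)
    if (!k %in% sub$cpg_index) stop("CpG ", k, " missing for gene ", gene)
  wide <- panel_wide(sub, gene)
  d <- wide[[paste0("cpg", cpg_pair[1])]] - wide[[paste0("cpg", cpg_pair[2])]]
  dpanel <- data.frame(sample_id = wide$sample_id,
                       gene = paste0(gene, "_d", cpg_pair[1], cpg_pair[2]),
                       cpg_index = 1, methylation_pct = d,
                       stringsAsFactors = FALSE)
  mw <- mw_compare_cpgs(dpanel, samples, contrast)
  adj <- adjusted_effect_regression(dpanel, samples, contrast)
  list(mw = mw[mw$cpg == "1", ], adjusted = adj[adj$cpg == "1", ])
}
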