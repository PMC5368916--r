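check_prob <- function(p, what = "p-values") {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop(what, " must lie in [0, 1]")
  invisible(p)
}

#' First-order (minimum) combination of two cohort p-values
#'
#' Combined p-value from the null CDF of the minimum of two independent
#' uniform random variables: `1 - (1 - min(pa, pb))^2`. Sensitive: a strong
#' signal in either cohort suffices.
#'
#' @param p_a,p_b Per-probe p-values from the two cohorts (vectorized).
#' @return Combined p-values, uniform under independent uniform inputs.
#' @export
combine_first_order <- function(p_a, p_b) {
  check_prob(p_a); check_prob(p_b)
  1 - (1 - pmin(p_a, p_b))^2
}

#' Second-order (maximum) combination of two cohort p-values
#'
#' Combined p-value from the null CDF of the maximum of two independent
#' uniforms: `max(pa, pb)^2`. Robust: significance requires support from both
#' cohorts (`max(pa,pb)^2 < c` iff both are below `sqrt(c)`).
#'
#' @inheritParams combine_first_order
#' @return Combined p-values, uniform under independent uniform inputs.
#' @export
combine_second_order <- function(p_a, p_b) {
  check_prob(p_a); check_prob(p_b)
  pmax(p_a, p_b)^2
}

#' General i-of-k order-statistic p-value combination
#'
#' Null CDF of the i-th smallest of k independent uniforms, evaluated at the
#' observed i-th order statistic: `pbeta(p_(i), i, k - i + 1)`. With k = 2
#' this reduces to [combine_first_order()] (i = 1) and
#' [combine_second_order()] (i = 2).
#'
#' @param p Matrix of p-values, probes x cohorts.
#' @param order Which order statistic (1 = minimum, `ncol(p)` = maximum).
#' @return Vector of combined p-values.
#' @export
order_stat_combine <- function(p, order = 1) {
  p <- as.matrix(p)
  check_prob(p)
  k <- ncol(p)
  if (order < 1 || order > k) stop("order must be between 1 and ncol(p)")
  sorted_i <- apply(p, 1, function(r) sort(r)[order])
  stats::pbeta(sorted_i, order, k - order + 1)
}

#' Combine two cohort differential-methylation results
#'
#' Intersects the probe sets of two [moderated_t_test()] results, computes
#' first- and second-order combined p-values and their Benjamini-Hochberg
#' adjustments across all shared probes.
#'
#' @param res_a,res_b `dm_result` data.frames (one per cohort).
#' @return A `combined_result` data.frame with columns `probe_id`, `p_a`,
#'   `p_b`, `p_first`, `p_second`, `p_first_adj`, `p_second_adj`.
#' @export
combine_cohorts <- function(res_a, res_b) {
  common <- intersect(res_a$probe_id, res_b$probe_id)
  if (length(common) < 1) stop("no common probes between cohorts")
  pa <- res_a$p[match(common, res_a$probe_id)]
  pb <- res_b$p[match(common, res_b$probe_id)]
  out <- data.frame(probe_id = common, p_a = pa, p_b = pb,
                    p_first = combine_first_order(pa, pb),
                    p_second = combine_second_order(pa, pb),
                    stringsAsFactors = FALSE)
  out$p_first_adj <- bh_adjust(out$p_first)
  out$p_second_adj <- bh_adjust(out$p_second)
  class(out) <- c("combined_result", "data.frame")
  out
}

#' Cross-cohort concordance of differential methylation
#'
#' Pearson correlations, between two cohorts over their shared probes, of
#' (a) per-probe mean beta values, (b) methylation differences (delta beta)
#' and (c) t statistics, each with a two-sided p-value from the t transform
#' of the correlation coefficient.
#'
#' @param res_a,res_b `dm_result` data.frames with at least 10 shared probes.
#' @return Data.frame with columns `quantity`, `r`, `p`, `n_probes`.
#' @export
cross_cohort_concordance <- function(res_a, res_b) {
  common <- intersect(res_a$probe_id, res_b$probe_id)
  if (length(common) < 10) stop("need at least 10 common probes")
  ia <- match(common, res_a$probe_id); ib <- match(common, res_b$probe_id)
  mean_cols <- function(r) rowMeans(as.matrix(
    r[, grep("^mean_", names(r)), drop = FALSE]))
  pairs <- list(
    mean_beta = cbind(mean_cols(res_a)[ia], mean_cols(res_b)[ib]),
    delta_beta = cbind(res_a$delta_beta_pp[ia], res_b$delta_beta_pp[ib]),
    t = cbind(res_a$t[ia], res_b$t[ib]))
  rows <- lapply(names(pairs), function(nm) {
    ct <- stats::cor.test(pairs[[nm]][, 1], pairs[[nm]][, 2])
    data.frame(quantity = nm, r = unname(ct$estimate), p = ct$p.value,
               n_probes = length(common), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract the FDR-significant probe set from a combined result
#'
#' Applies Benjamini-Hochberg to the chosen combined p-value across all
#' probes and returns the probes with adjusted p below `fdr`, sorted by
#' combined p-value.
#'
#' @param combined A `combined_result` from [combine_cohorts()].
#' @param fdr FDR threshold in (0, 1).
#' @param order `"first"` or `"second"` order combination.
#' @return Character vector of significant probe ids.
#' @export
significant_set <- function(combined, fdr = 0.05,
                            order = c("second", "first")) {
  order <- match.arg(order)
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  p <- if (order == "first") combined$p_first else combined$p_second
  adj <- bh_adjust(p)
  sig <- which(adj < fdr)
  combined$probe_id[sig[order(p[sig])]]
}
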