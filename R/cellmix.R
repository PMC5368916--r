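# exact least squares on {w >= 0, sum(w) = 1} by active set on the
# equality-constrained KKT system
solve_simplex_ls <- function(R, b, tol = 1e-10) {
  k <- ncol(R)
  G <- crossprod(R); h <- crossprod(R, b)
  active <- rep(FALSE, k)          # TRUE = clamped at zero
  for (outer in seq_len(2 * k + 5)) {
    free <- which(!active)
    K <- rbind(cbind(2 * G[free, free, drop = FALSE], 1),
               c(rep(1, length(free)), 0))
    sol <- solve(K, c(2 * h[free], 1))
    w_free <- sol[seq_along(free)]
    lambda <- sol[length(sol)]
    if (any(w_free < -tol)) {
      active[free[which.min(w_free)]] <- TRUE
      next
    }
    w <- numeric(k); w[free] <- pmax(w_free, 0)
    # dual feasibility of clamped coordinates
    grad <- 2 * (G %*% w - h) + lambda
    viol <- which(active & grad < -tol)
    if (length(viol) == 0) return(w)
    active[viol[which.min(grad[viol])]] <- FALSE
  }
  w / sum(w)
}

#' Estimate cell-type proportions by constrained projection
#'
#' Houseman-style reference-based deconvolution: for every sample, solves
#' `minimize ||b - R w||^2` subject to `w >= 0` and `sum(w) <= 1` over the
#' reference's discriminating probes. The unconstrained-sum problem is solved
#' by non-negative least squares; if the solution violates the sum constraint
#' it is re-solved with the constraint active (exact active-set on the
#' simplex).
#'
#' @param beta Probes x samples beta matrix containing the discriminating
#'   probes (by rowname).
#' @param reference A `cell_reference` (see [simulate_cell_reference()]), or
#'   a list with `profiles` (probes x cell types) and `discriminating`.
#' @param normalize If `TRUE`, rescale each sample's weights to sum to 1.
#' @return Samples x cell-types matrix of proportions (class
#'   `cell_proportions` via attribute).
#' @export
estimate_cell_proportions <- function(beta, reference, normalize = FALSE) {
  probes <- intersect(reference$discriminating, rownames(beta))
  if (length(probes) < ncol(reference$profiles))
    stop("too few discriminating probes present in the beta matrix")
  R <- reference$profiles[probes, , drop = FALSE]
  if (qr(R)$rank < ncol(R))
    stop("reference is rank-deficient on the available probes")
  B <- beta[probes, , drop = FALSE]
  W <- t(vapply(seq_len(ncol(B)), function(j) {
    w <- pracma::lsqnonneg(R, B[, j])$x
    if (sum(w) > 1 + 1e-8) w <- solve_simplex_ls(R, B[, j])
    w
  }, numeric(ncol(R))))
  dimnames(W) <- list(colnames(B), colnames(R))
  if (normalize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  W
}

#' Compare cell-type proportions between two groups
#'
#' Per cell type, a two-sided Mann-Whitney rank test of the estimated
#' proportions between two groups.
#'
#' @param props Samples x cell-types proportion matrix.
#' @param groups Factor with two levels, each with at least 3 samples.
#' @return Data.frame with `cell_type`, group medians and `p`.
#' @export
compare_cell_proportions <- function(props, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (length(groups) != nrow(props))
    stop("groups length must match the number of samples")
  if (any(table(groups) < 3)) stop("each group needs at least 3 samples")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  rows <- lapply(colnames(props), function(ct) {
    x <- props[groups == g1, ct]; y <- props[groups == g2, ct]
    data.frame(cell_type = ct, median_1 = stats::median(x),
               median_2 = stats::median(y), p = mw_test(x, y)$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("median_", make.names(c(g1, g2)))
  out
}
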