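#' Compute beta values from methylated/unmethylated intensities
#'
#' The standard Illumina definition `beta = M / (M + U + offset)`, applied
#' elementwise. With a positive offset the result lies in `[0, 1)` and is
#' monotone in M for fixed U.
#'
#' @param m,u Non-negative methylated / unmethylated intensity matrices of
#'   identical dimension.
#' @param offset Non-negative stabilizing offset (default 100).
#' @return Beta matrix with the dimnames of `m`.
#' @export
compute_beta <- function(m, u, offset = 100) {
  if (!all(dim(m) == dim(u))) stop("M and U dimensions differ")
  if (any(m < 0) || any(u < 0)) stop("intensities must be non-negative")
  if (offset < 0) stop("offset must be non-negative")
  m / (m + u + offset)
}

quantile_normalize_stratum <- function(x) {
  # background alignment: shift each sample so its 1st percentile equals the
  # across-sample median of 1st percentiles, then full quantile normalization
  q1 <- apply(x, 2, stats::quantile, probs = 0.01, names = FALSE)
  x <- sweep(x, 2, q1 - stats::median(q1))
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  pmax(out, 0)
}

#' Dasen-style between-array normalization of intensities
#'
#' Normalizes methylated and unmethylated intensities separately within probe
#' design type (four strata: M x type I, M x type II, U x type I, U x type
#' II). Within each stratum every sample is first background-aligned by
#' shifting it so that its 1st percentile equals the across-sample median of
#' 1st percentiles, and then quantile-normalized so that all samples share
#' the mean sorted profile (ties receive the mean of their target values).
#' Rank order within each sample-stratum is preserved.
#'
#' @param m,u Probes x samples intensity matrices (probe ids as rownames).
#' @param manifest Probe manifest with `probe_id` and `design_type` (I/II).
#' @return A list with normalized `m` and `u` matrices.
#' @export
dasen_normalize <- function(m, u, manifest) {
  if (!all(dim(m) == dim(u))) stop("M and U dimensions differ")
  if (ncol(m) < 2) stop("dasen normalization needs at least 2 samples")
  idx <- match(rownames(m), manifest$probe_id)
  if (anyNA(idx)) stop("manifest is missing probes present in the matrices")
  type <- manifest$design_type[idx]
  for (tt in unique(type)) {
    rows <- type == tt
    if (sum(rows) < 2) stop("design type ", tt, " stratum has < 2 probes")
    m[rows, ] <- quantile_normalize_stratum(m[rows, , drop = FALSE])
    u[rows, ] <- quantile_normalize_stratum(u[rows, , drop = FALSE])
  }
  list(m = m, u = u)
}

moments_to_shapes <- function(mean, var) {
  # method-of-moments for Beta(a, b); requires var < mean (1 - mean)
  if (!is.finite(var) || var <= 0 || var >= mean * (1 - mean))
    return(NULL)
  common <- mean * (1 - mean) / var - 1
  c(a = mean * common, b = (1 - mean) * common)
}

#' Fit a three-component beta mixture by EM
#'
#' Models a vector of methylation fractions as a mixture of three beta
#' distributions representing the unmethylated, hemimethylated and methylated
#' states. Initialization groups the data at the `thresholds` cutpoints and
#' sets each component by method of moments; the E-step computes posterior
#' responsibilities and the M-step performs a weighted method-of-moments
#' update. Iteration stops when the relative log-likelihood change falls
#' below `tol`, when `max_iter` is reached, or when an update would decrease
#' the log-likelihood (the last accepted parameters are kept, so the reported
#' log-likelihood trace is non-decreasing).
#'
#' @param values Numeric vector of fractions; values are clipped to
#'   `[1e-6, 1 - 1e-6]` and at least 50 are required.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param thresholds Two cutpoints defining the initial low/mid/high grouping.
#' @return An object of class `beta_mixture`: data.frame `components` with
#'   columns `a`, `b`, `weight`, `mean` (rows ordered by increasing mean),
#'   the `loglik` trace, and `iterations`.
#' @export
fit_beta_mixture <- function(values, tol = 1e-4, max_iter = 100,
                             thresholds = c(0.2, 0.75)) {
  x <- values[is.finite(values)]
  if (length(x) < 50) stop("need at least 50 values to fit the mixture")
  x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
  grp <- cut(x, c(-Inf, thresholds, Inf), labels = FALSE)
  if (any(tabulate(grp, 3) < 2)) {
    # compressed data may leave a fixed-threshold group empty; regroup by
    # nearest of three quantile centers instead
    centers <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
    grp <- apply(abs(outer(x, centers, "-")), 1, which.min)
  }
  a <- b <- w <- numeric(3)
  for (k in 1:3) {
    xk <- x[grp == k]
    if (length(xk) < 2 || stats::var(xk) == 0)
      stop("degenerate initialization: group ", k,
           " has fewer than 2 distinct values")
    sh <- moments_to_shapes(mean(xk), stats::var(xk))
    if (is.null(sh))
      stop("degenerate initialization: group ", k,
           " moments incompatible with a beta distribution")
    a[k] <- sh["a"]; b[k] <- sh["b"]; w[k] <- length(xk) / length(x)
  }
  dens <- function(a, b, w) {
    d <- vapply(1:3, function(k) w[k] * stats::dbeta(x, a[k], b[k]),
                numeric(length(x)))
    pmax(d, 1e-300)
  }
  d <- dens(a, b, w)
  ll <- sum(log(rowSums(d)))
  trace <- ll
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    r <- d / rowSums(d)
    w_new <- colMeans(r)
    a_new <- a; b_new <- b
    ok <- TRUE
    for (k in 1:3) {
      rs <- sum(r[, k])
      mk <- sum(r[, k] * x) / rs
      vk <- sum(r[, k] * (x - mk)^2) / rs
      sh <- moments_to_shapes(mk, vk)
      if (is.null(sh)) { ok <- FALSE; break }
      a_new[k] <- sh["a"]; b_new[k] <- sh["b"]
    }
    if (!ok) break
    d_new <- dens(a_new, b_new, w_new)
    ll_new <- sum(log(rowSums(d_new)))
    if (ll_new < ll - 1e-10) break    # safeguard: never accept a decrease
    a <- a_new; b <- b_new; w <- w_new; d <- d_new
    converged <- abs(ll_new - ll) < tol * abs(ll)
    ll <- ll_new
    trace <- c(trace, ll)
    if (converged) break
  }
  ord <- order(a / (a + b))
  comps <- data.frame(a = a[ord], b = b[ord], weight = w[ord],
                      mean = (a / (a + b))[ord])
  rownames(comps) <- c("U", "H", "M")
  structure(list(components = comps, loglik = trace, iterations = iter),
            class = "beta_mixture")
}

# posterior crossing point between two adjacent mixture components
state_boundary <- function(fit, k) {
  cm <- fit$components
  f <- function(x) cm$weight[k] * stats::dbeta(x, cm$a[k], cm$b[k]) -
    cm$weight[k + 1] * stats::dbeta(x, cm$a[k + 1], cm$b[k + 1])
  lo <- cm$mean[k]; hi <- cm$mean[k + 1]
  if (f(lo) > 0 && f(hi) < 0)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  else
    (lo + hi) / 2
}

bmiq_map_sample <- function(b2, fit1, fit2) {
  c1 <- fit1$components; c2 <- fit2$components
  t1 <- state_boundary(fit2, 1)    # U/H boundary on the type II scale
  t2 <- state_boundary(fit2, 2)    # H/M boundary
  out <- b2
  u_set <- b2 <= t1
  m_set <- b2 >= t2
  h_set <- !u_set & !m_set
  out[u_set] <- stats::qbeta(stats::pbeta(b2[u_set], c2$a[1], c2$b[1]),
                             c1$a[1], c1$b[1])
  out[m_set] <- stats::qbeta(stats::pbeta(b2[m_set], c2$a[3], c2$b[3]),
                             c1$a[3], c1$b[3])
  # transformed images of the boundaries anchor the linear H dilation
  u_img <- stats::qbeta(stats::pbeta(t1, c2$a[1], c2$b[1]), c1$a[1], c1$b[1])
  m_img <- stats::qbeta(stats::pbeta(t2, c2$a[3], c2$b[3]), c1$a[3], c1$b[3])
  if (m_img <= u_img) m_img <- u_img + 1e-8
  out[h_set] <- u_img + (b2[h_set] - t1) * (m_img - u_img) / (t2 - t1)
  pmin(pmax(out, 0), 1)
}

#' BMIQ correction of type II probe bias
#'
#' Per-sample beta-mixture quantile dilation: for every sample, three-state
#' beta mixtures are fitted separately to the type I and type II betas; each
#' type II value is assigned to the unmethylated (U), hemimethylated (H) or
#' methylated (M) state by the fitted type II mixture; U-state values are
#' mapped onto the type I U component by quantile matching
#' `b' = F1^-1(F2(b))` of the fitted beta CDFs, M-state values analogously
#' with the M components, and H-state values by the monotone linear dilation
#' that maps the transformed state boundaries onto the type I
#' hemimethylated range. Type I values are returned unchanged; the mapping is
#' monotone non-decreasing on each sample's type II values and stays in
#' `[0, 1]`.
#'
#' @param beta Probes x samples beta matrix (probe ids as rownames).
#' @param manifest Probe manifest with `probe_id` and `design_type`.
#' @return Corrected beta matrix of the same shape.
#' @export
bmiq_correct <- function(beta, manifest) {
  idx <- match(rownames(beta), manifest$probe_id)
  if (anyNA(idx)) stop("manifest is missing probes present in beta")
  type <- manifest$design_type[idx]
  if (!any(type == "I") || !any(type == "II"))
    stop("both probe design types must be present")
  out <- beta
  for (j in seq_len(ncol(beta))) {
    sample_id <- colnames(beta)[j]
    res <- tryCatch({
      fit1 <- fit_beta_mixture(beta[type == "I", j])
      fit2 <- fit_beta_mixture(beta[type == "II", j])
      bmiq_map_sample(beta[type == "II", j], fit1, fit2)
    }, error = function(e)
      stop("BMIQ failed for sample '", sample_id, "': ",
           conditionMessage(e), call. = FALSE))
    out[type == "II", j] <- res
  }
  out
}
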