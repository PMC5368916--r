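# ten-probe QC fixture with one planted failure per filter stage:
# probes 1-4 clean, 5-6 SNP-flagged, 7 chrX, 8 chrY,
# 9 beadcount 2 in one sample, 10 detection p 0.06 in one sample
make_qc_fixture <- function() {
  ids <- sprintf("cg%02d", 1:10)
  beta <- matrix(0.5, nrow = 10, ncol = 3,
                 dimnames = list(ids, paste0("s", 1:3)))
  manifest <- data.frame(
    probe_id = ids,
    chrom = c(rep("chr1", 6), "chrX", "chrY", "chr2", "chr3"),
    pos = 1:10, design_type = "II", cgi_relation = "open_sea", gene = "",
    snp_flag = c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0), stringsAsFactors = FALSE)
  bead <- matrix(10L, 10, 3, dimnames = dimnames(beta))
  bead["cg09", 2] <- 2L
  detp <- matrix(0.0001, 10, 3, dimnames = dimnames(beta))
  detp["cg10", 3] <- 0.06
  list(beta = beta, manifest = manifest, bead = bead, detp = detp)
}

# exact constrained-least-squares oracle: enumerate all active sets of
# {w_i = 0} x {sum(w) = 1 active or not}, solve each KKT system, return the
# feasible candidate with the smallest objective
qp_oracle <- function(R, b) {
  k <- ncol(R)
  G <- crossprod(R); h <- crossprod(R, b)
  best <- NULL; best_f <- Inf
  for (mask in 0:(2^k - 1)) {
    zero <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    free <- setdiff(seq_len(k), zero)
    if (length(free) == 0) {
      w <- numeric(k)
      f <- sum((R %*% w - b)^2)
      if (f < best_f) { best <- w; best_f <- f }
      next
    }
    for (sum_active in c(FALSE, TRUE)) {
      w <- numeric(k)
      sol <- try({
        if (sum_active) {
          K <- rbind(cbind(G[free, free, drop = FALSE], 1),
                     c(rep(1, length(free)), 0))
          s <- solve(K, c(h[free], 1))
          s[seq_along(free)]
        } else {
          solve(G[free, free, drop = FALSE], h[free])
        }
      }, silent = TRUE)
      if (inherits(sol, "try-error")) next
      w[free] <- sol
      if (any(w < -1e-9) || sum(w) > 1 + 1e-9) next
      f <- sum((R %*% w - b)^2)
      if (f < best_f) { best <- w; best_f <- f }
    }
  }
  best
}
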