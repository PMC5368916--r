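#' Probe quality-control filter cascade
#'
#' Applies the standard 450K probe filters in a fixed order: (1) low signal
#' quality — beadcount below `beadcount_min` in at least one sample; (2)
#' detection p-value above `p_threshold` in at least one sample; (3) probes
#' overlapping known SNPs; (4) probes on the sex chromosomes. Each removed
#' probe is attributed to the first stage that removes it, so stage counts
#' never double-count and sum with the retained count to the input count.
#'
#' @param beta Probes x samples beta matrix with probe ids as rownames.
#' @param manifest Probe manifest data.frame with columns `probe_id`, `chrom`
#'   and `snp_flag`, covering every probe in `beta`.
#' @param beadcounts,detection_p Matrices conforming to `beta` in dimension
#'   and probe/sample order.
#' @param p_threshold Detection p-value threshold (default 0.05).
#' @param beadcount_min Minimum acceptable beadcount (default 3).
#' @param any_sample If `TRUE` (default) a probe fails a quality criterion
#'   when any single sample fails it; if `FALSE`, when more than half do.
#' @return A list with `beta` (filtered matrix) and `report`, a `qc_report`
#'   list with per-stage removal counts and the retained total.
#' @export
filter_probes <- function(beta, manifest, beadcounts, detection_p,
                          p_threshold = 0.05, beadcount_min = 3,
                          any_sample = TRUE) {
  if (!is.matrix(beta)) beta <- as.matrix(beta)
  if (is.null(rownames(beta))) stop("beta must have probe ids as rownames")
  if (!all(dim(beadcounts) == dim(beta)) ||
      !all(dim(detection_p) == dim(beta)))
    stop("beadcounts and detection_p must match the beta matrix dimensions")
  if (p_threshold < 0 || p_threshold > 1)
    stop("p_threshold must be in [0, 1]")
  idx <- match(rownames(beta), manifest$probe_id)
  if (anyNA(idx)) stop("manifest is missing probes present in beta")
  man <- manifest[idx, ]

  fail_frac <- if (any_sample) 0 else 0.5
  bead_fail <- rowMeans(beadcounts < beadcount_min) > fail_frac
  detp_fail <- rowMeans(detection_p > p_threshold) > fail_frac
  snp_fail <- man$snp_flag == 1
  sex_fail <- man$chrom %in% c("chrX", "chrY")

  stage <- rep(NA_character_, nrow(beta))
  stage[sex_fail] <- "sex_chromosome"
  stage[snp_fail] <- "snp"
  stage[detp_fail] <- "detection_p"
  stage[bead_fail] <- "beadcount"   # overwrites: earliest stage wins

  keep <- is.na(stage)
  report <- structure(list(
    n_input = nrow(beta),
    n_beadcount = sum(stage == "beadcount", na.rm = TRUE),
    n_detection_p = sum(stage == "detection_p", na.rm = TRUE),
    n_snp = sum(stage == "snp", na.rm = TRUE),
    n_sex_chromosome = sum(stage == "sex_chromosome", na.rm = TRUE),
    n_retained = sum(keep),
    p_threshold = p_threshold, beadcount_min = beadcount_min),
    class = "qc_report")
  list(beta = beta[keep, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Probe QC report\n")
  cat(sprintf("  input probes:        %d\n", x$n_input))
  cat(sprintf("  removed beadcount<%g: %d\n", x$beadcount_min, x$n_beadcount))
  cat(sprintf("  removed detection p>%g: %d\n", x$p_threshold,
              x$n_detection_p))
  cat(sprintf("  removed SNP overlap:  %d\n", x$n_snp))
  cat(sprintf("  removed chrX/chrY:    %d\n", x$n_sex_chromosome))
  cat(sprintf("  retained:             %d\n", x$n_retained))
  invisible(x)
}
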