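#' Default per-group confounder model
#'
#' Group-level distributions for the maternal and fetal covariates carried on
#' the sample sheet. Defaults reflect a two-cohort GDM cord-blood study design:
#' insulin-treated GDM (I-GDM) mothers have a higher mean BMI (29.9 vs 25.3
#' kg/m2) and earlier delivery (gestational week 38.7 vs 39.5) than controls,
#' so maternal BMI and gestational age are genuine confounders of any
#' group-methylation association. HbA1c is only measured in GDM groups
#' (controls get NA).
#'
#' @return A named list with one entry per group (`control`, `dgdm`, `igdm`),
#'   each a list with elements `bmi` (mean, sd), `gestational_week` (mean, sd),
#'   `sex_prob_male`, `hba1c` (mean, sd or NA), `birth_weight` (mean, sd in g).
#' @export
default_confounder_model <- function() {
  list(
    control = list(bmi = c(25.3, 6.4), gestational_week = c(39.5, 1.4),
                   sex_prob_male = 0.5, hba1c = c(NA_real_, NA_real_),
                   birth_weight = c(3391, 576)),
    dgdm    = list(bmi = c(25.1, 4.1), gestational_week = c(39.1, 1.3),
                   sex_prob_male = 0.5, hba1c = c(5.5, 0.4),
                   birth_weight = c(3397, 558)),
    igdm    = list(bmi = c(29.9, 7.3), gestational_week = c(38.7, 1.5),
                   sex_prob_male = 0.5, hba1c = c(5.9, 0.6),
                   birth_weight = c(3465, 478))
  )
}

#' Simulation configuration for a two-cohort methylation study
#'
#' Defines the study conditions emulated by [simulate_cohort()]: two cohorts
#' (A: 20 I-GDM vs 18 controls; B: 24 I-GDM, 24 D-GDM, 46 controls), a
#' 450K-style probe set scaled down to `n_probes`, three-state beta-value
#' baseline mixtures, type II probe compression toward 0.5, cell-type
#' mixtures, group effects of a few percentage points shared by both cohorts,
#' and covariates drawn from a group-dependent confounder model.
#'
#' @param n_probes Number of probes on the simulated array.
#' @param group_sizes Named list, one entry per cohort, each a named integer
#'   vector of samples per group.
#' @param frac_differential Fraction of probes carrying a planted group effect.
#' @param effect_range_pp Two-element vector: range of absolute planted effect
#'   sizes in percentage points (signs are random). Must lie within [0, 100].
#' @param cohort_effect_scale Named vector of per-cohort multipliers applied
#'   to the planted effects (cohorts not named get 1). The default halves the
#'   effects in cohort A, emulating the asymmetric-power regime of a
#'   discovery/replication pair in which the smaller cohort carries only a
#'   weakly replicating share of the signal, so that the sensitive first-order
#'   combination yields many more hits than the robust second-order one.
#' @param beta_precision Beta-distribution precision (a+b) controlling
#'   within-group variability. The default 1200 gives a within-group SD of
#'   roughly 1-1.5 percentage points at intermediate methylation — the noise
#'   level at which group differences of one to a few percentage points are
#'   callable at genome-wide FDR with cohorts of this size, matching the
#'   power regime of published cord-blood 450K screens.
#' @param type2_bias Compression factor in (0, 1] applied to type II probes:
#'   `b' = 0.5 + (b - 0.5) * type2_bias`. 1 means no compression.
#' @param n_cell_types Number of cell types mixed per sample (1 disables
#'   mixing).
#' @param n_discriminating Number of cell-type discriminating probes.
#' @param mixing_concentration Dirichlet concentration vector (length
#'   `n_cell_types`) for per-sample cell proportions.
#' @param confounder_model Per-group covariate model, see
#'   [default_confounder_model()].
#' @param affected_groups Character vector of groups receiving the planted
#'   effects (subset of `c("dgdm", "igdm")`).
#' @param frac_type2 Fraction of type II probes (the 450K array is roughly
#'   70 percent type II).
#' @param frac_snp Fraction of SNP-flagged probes.
#' @param frac_chrx,frac_chry Fractions of probes on chrX / chrY.
#' @param bead_fail_rate,detp_fail_rate Per-cell rates of planted beadcount
#'   (< 3) and detection p-value (> 0.05) failures.
#' @param seed Integer seed; every output of the generator is a deterministic
#'   function of the configuration including this seed.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_probes = 10000,
                       group_sizes = list(
                         A = c(control = 18, igdm = 20),
                         B = c(control = 46, dgdm = 24, igdm = 24)),
                       frac_differential = 0.02,
                       effect_range_pp = c(1, 4.5),
                       cohort_effect_scale = c(A = 0.5, B = 1),
                       beta_precision = 1200,
                       type2_bias = 0.8,
                       n_cell_types = 6,
                       n_discriminating = 200,
                       mixing_concentration = rep(5, n_cell_types),
                       confounder_model = default_confounder_model(),
                       affected_groups = "igdm",
                       frac_type2 = 0.7,
                       frac_snp = 0.015,
                       frac_chrx = 0.025,
                       frac_chry = 0.004,
                       bead_fail_rate = 2e-4,
                       detp_fail_rate = 2e-4,
                       seed = 1L) {
  sizes <- unlist(group_sizes)
  if (length(sizes) == 0 || any(sizes <= 0) || any(sizes != round(sizes)))
    stop("all group sizes must be positive integers")
  if (length(effect_range_pp) != 2 ||
      any(effect_range_pp < -100) || any(effect_range_pp > 100))
    stop("effect_range_pp must lie within [-100, 100]")
  effect_range_pp <- sort(abs(effect_range_pp))
  if (frac_differential < 0 || frac_differential > 1)
    stop("frac_differential must be in [0, 1]")
  if (beta_precision <= 0) stop("beta_precision must be positive")
  if (type2_bias <= 0 || type2_bias > 1) stop("type2_bias must be in (0, 1]")
  if (n_cell_types > 1 && length(mixing_concentration) != n_cell_types)
    stop("mixing_concentration must have length n_cell_types")
  if (!all(affected_groups %in% c("dgdm", "igdm")))
    stop("affected_groups must be a subset of c('dgdm', 'igdm')")
  cfg <- list(n_probes = as.integer(n_probes), group_sizes = group_sizes,
              frac_differential = frac_differential,
              effect_range_pp = effect_range_pp,
              cohort_effect_scale = cohort_effect_scale,
              beta_precision = beta_precision, type2_bias = type2_bias,
              n_cell_types = as.integer(n_cell_types),
              n_discriminating = as.integer(n_discriminating),
              mixing_concentration = mixing_concentration,
              confounder_model = confounder_model,
              affected_groups = affected_groups,
              frac_type2 = frac_type2, frac_snp = frac_snp,
              frac_chrx = frac_chrx, frac_chry = frac_chry,
              bead_fail_rate = bead_fail_rate, detp_fail_rate = detp_fail_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

make_manifest <- function(cfg) {
  n <- cfg$n_probes
  probe_id <- sprintf("cg%08d", seq_len(n))
  n_x <- round(cfg$frac_chrx * n)
  n_y <- round(cfg$frac_chry * n)
  auto <- sample(paste0("chr", 1:22), n - n_x - n_y, replace = TRUE)
  chrom <- sample(c(auto, rep("chrX", n_x), rep("chrY", n_y)))
  cgi <- sample(c("island", "n_shore", "s_shore", "n_shelf", "s_shelf",
                  "open_sea"),
                n, replace = TRUE,
                prob = c(0.31, 0.12, 0.11, 0.05, 0.05, 0.36))
  gene <- ifelse(stats::runif(n) < 0.7,
                 sprintf("GENE%05d", sample.int(round(n / 3) + 10, n,
                                                replace = TRUE)), "")
  data.frame(
    probe_id = probe_id,
    chrom = chrom,
    pos = sample.int(2.4e8, n, replace = TRUE),
    design_type = ifelse(stats::runif(n) < cfg$frac_type2, "II", "I"),
    cgi_relation = cgi,
    gene = gene,
    snp_flag = as.integer(stats::runif(n) < cfg$frac_snp),
    stringsAsFactors = FALSE)
}

# 3-state baseline: mostly unmethylated / hemimethylated / mostly methylated,
# with weights resembling the bimodal 450K beta distribution.
draw_baseline_means <- function(n) {
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.40, 0.15, 0.45))
  m <- numeric(n)
  m[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 18)
  m[comp == 2] <- stats::rbeta(sum(comp == 2), 10, 10)
  m[comp == 3] <- stats::rbeta(sum(comp == 3), 18, 2)
  pmin(pmax(m, 0.01), 0.99)
}

make_sample_sheet <- function(cfg) {
  rows <- list()
  for (cohort in names(cfg$group_sizes)) {
    sizes <- cfg$group_sizes[[cohort]]
    for (grp in names(sizes)) {
      n <- sizes[[grp]]
      cm <- cfg$confounder_model[[grp]]
      if (is.null(cm)) stop("no confounder model for group ", grp)
      rows[[paste(cohort, grp)]] <- data.frame(
        sample_id = sprintf("%s_%s_%02d", cohort, grp, seq_len(n)),
        cohort = cohort,
        group = grp,
        maternal_bmi = round(stats::rnorm(n, cm$bmi[1], cm$bmi[2]), 1),
        gestational_week = round(stats::rnorm(n, cm$gestational_week[1],
                                              cm$gestational_week[2]), 1),
        fetal_sex = ifelse(stats::runif(n) < cm$sex_prob_male, "M", "F"),
        hba1c = if (is.na(cm$hba1c[1])) NA_real_ else
          round(stats::rnorm(n, cm$hba1c[1], cm$hba1c[2]), 1),
        birth_weight_g = round(stats::rnorm(n, cm$birth_weight[1],
                                            cm$birth_weight[2])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$maternal_bmi <- pmax(out$maternal_bmi, 16)
  out$gestational_week <- pmin(pmax(out$gestational_week, 32), 42)
  out
}

#' Simulate a two-cohort methylation array dataset
#'
#' Generates beta values, a probe manifest, a sample sheet, side channels
#' (beadcounts, detection p-values), a cell-type reference with true mixing
#' weights, and a ground-truth table of planted effects. The same differential
#' probes (the truth) are shared by both cohorts, emulating a reproducible
#' biological signal that a two-cohort meta-combination should recover.
#'
#' Per-sample betas are drawn from beta distributions around probe baselines
#' (a 3-component low/intermediate/high mixture); planted effects are added on
#' the raw beta scale (percentage points / 100) in the affected groups and
#' clipped; when `n_cell_types > 1` each sample is a convex (Dirichlet) mixture
#' over cell-type profiles that differ at the discriminating probes; type II
#' probes are finally compressed toward 0.5 by the `type2_bias` dilation.
#' Differential probes are planted only on clean autosomal, non-SNP,
#' non-discriminating probes with intermediate baselines so that the truth
#' table is not confounded with QC removal or cell composition.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `cohort_sim` with elements `beta` (probes x
#'   samples matrix), `manifest`, `samples`, `truth` (probe_id,
#'   is_differential, true_effect_pp, affected_groups), `beadcount`,
#'   `detection_p`, `cell_reference` (see [simulate_cell_reference()]),
#'   `cell_weights` (true per-sample mixing weights) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  manifest <- make_manifest(cfg)
  samples <- make_sample_sheet(cfg)
  n <- cfg$n_probes
  ns <- nrow(samples)
  baseline <- draw_baseline_means(n)

  # cell reference shares the baseline except at discriminating probes
  cell_ref <- NULL
  cell_w <- NULL
  disc_idx <- integer(0)
  if (cfg$n_cell_types > 1) {
    eligible <- which(manifest$snp_flag == 0 &
                        !(manifest$chrom %in% c("chrX", "chrY")))
    disc_idx <- sort(sample(eligible, min(cfg$n_discriminating,
                                          length(eligible))))
    profiles <- matrix(baseline, nrow = n, ncol = cfg$n_cell_types,
                       dimnames = list(manifest$probe_id,
                                       paste0("cell", seq_len(cfg$n_cell_types))))
    for (i in disc_idx) {
      lo <- stats::runif(1, 0.05, 0.35)
      hi <- lo + stats::runif(1, 0.5, min(0.6, 0.95 - lo))
      k <- sample(1:(cfg$n_cell_types - 1), 1)
      high_types <- sample.int(cfg$n_cell_types, k)
      profiles[i, ] <- lo + stats::runif(cfg$n_cell_types, 0, 0.04)
      profiles[i, high_types] <- hi + stats::runif(k, -0.04, 0.04)
    }
    profiles <- pmin(pmax(profiles, 0.01), 0.99)
    cell_ref <- structure(
      list(profiles = profiles,
           discriminating = manifest$probe_id[disc_idx]),
      class = "cell_reference")
    cell_w <- rdirichlet(ns, cfg$mixing_concentration)
    rownames(cell_w) <- samples$sample_id
    colnames(cell_w) <- colnames(profiles)
  }

  # plant effects on clean intermediate-baseline probes
  n_diff <- round(cfg$frac_differential * n)
  clean <- which(manifest$snp_flag == 0 &
                   !(manifest$chrom %in% c("chrX", "chrY")) &
                   baseline > 0.10 & baseline < 0.90)
  clean <- setdiff(clean, disc_idx)
  diff_idx <- sort(sample(clean, min(n_diff, length(clean))))
  effect <- numeric(n)
  if (length(diff_idx)) {
    mag <- stats::runif(length(diff_idx), cfg$effect_range_pp[1],
                        cfg$effect_range_pp[2])
    sgn <- sample(c(-1, 1), length(diff_idx), replace = TRUE)
    # flip sign where the shift would clip against a bound
    shifted <- baseline[diff_idx] + sgn * mag / 100
    sgn <- ifelse(shifted < 0.05 | shifted > 0.95, -sgn, sgn)
    effect[diff_idx] <- sgn * mag
  }
  truth <- data.frame(
    probe_id = manifest$probe_id,
    is_differential = seq_len(n) %in% diff_idx,
    true_effect_pp = effect,
    affected_groups = ifelse(seq_len(n) %in% diff_idx,
                             paste(cfg$affected_groups, collapse = ","), ""),
    stringsAsFactors = FALSE)

  beta <- matrix(0, nrow = n, ncol = ns,
                 dimnames = list(manifest$probe_id, samples$sample_id))
  prec <- cfg$beta_precision
  for (j in seq_len(ns)) {
    mj <- baseline
    if (!is.null(cell_ref))
      mj[disc_idx] <- cell_ref$profiles[disc_idx, , drop = FALSE] %*% cell_w[j, ]
    if (samples$group[j] %in% cfg$affected_groups) {
      sc <- cfg$cohort_effect_scale[samples$cohort[j]]
      if (is.na(sc)) sc <- 1
      mj <- mj + sc * effect / 100
    }
    mj <- pmin(pmax(mj, 0.001), 0.999)
    beta[, j] <- stats::rbeta(n, mj * prec, (1 - mj) * prec)
  }
  type2 <- manifest$design_type == "II"
  beta[type2, ] <- 0.5 + (beta[type2, , drop = FALSE] - 0.5) * cfg$type2_bias

  beadcount <- matrix(3L + stats::rpois(n * ns, 11), nrow = n,
                      dimnames = dimnames(beta))
  detection_p <- matrix(stats::rbeta(n * ns, 1, 2000), nrow = n,
                        dimnames = dimnames(beta))
  nb <- stats::rbinom(1, n * ns, cfg$bead_fail_rate)
  if (nb > 0)
    beadcount[sample.int(n * ns, nb)] <- sample(0:2, nb, replace = TRUE)
  nd <- stats::rbinom(1, n * ns, cfg$detp_fail_rate)
  if (nd > 0)
    detection_p[sample.int(n * ns, nd)] <- stats::runif(nd, 0.051, 0.5)

  structure(list(beta = beta, manifest = manifest, samples = samples,
                 truth = truth, beadcount = beadcount,
                 detection_p = detection_p, cell_reference = cell_ref,
                 cell_weights = cell_w, config = cfg),
            class = "cohort_sim")
}

#' Simulate a targeted pyrosequencing-style validation panel
#'
#' Generates per-sample per-CpG methylation percentages (0-100 scale) for a
#' set of candidate genes with planted per-CpG group effects, technical noise,
#' and (optionally) linear covariate effects so that group contrasts are
#' confounded by maternal BMI, gestational week and fetal sex. The default
#' technical noise SD of 1.5 percentage points matches the typical
#' replicate-to-replicate variability of bisulfite pyrosequencing (1-2
#' percentage points).
#'
#' @param config A [sim_config()]; supplies the confounder model and the seed
#'   (the panel uses `seed + 1` so it is independent of the array draw).
#' @param genes A named list: each element is a numeric vector of per-CpG
#'   effects in percentage points (positive = hypermethylated in the affected
#'   groups); the element name is the gene, its length the number of CpGs.
#' @param group_sizes Named vector of samples per group; the default mirrors a
#'   validation cohort of 56 controls, 64 D-GDM and 61 I-GDM.
#' @param noise_sd Technical noise SD in percentage points.
#' @param affected_groups Groups receiving the planted effects.
#' @param covariate_effects Named numeric vector with elements `bmi`
#'   (pp per kg/m2), `gestational_week` (pp per week) and `sex_male` (pp);
#'   zero by default, set nonzero to induce confounding.
#' @return A list of class `targeted_panel`: `panel` (long data.frame with
#'   columns sample_id, gene, cpg_index, methylation_pct), `samples` (sample
#'   sheet), `baseline` (per-gene baseline percentages) and the arguments.
#' @export
simulate_targeted_panel <- function(config, genes,
                                    group_sizes = c(control = 56, dgdm = 64,
                                                    igdm = 61),
                                    noise_sd = 1.5,
                                    affected_groups = c("dgdm", "igdm"),
                                    covariate_effects = c(
                                      bmi = 0, gestational_week = 0,
                                      sex_male = 0)) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.list(genes) || is.null(names(genes)) || any(names(genes) == ""))
    stop("genes must be a named list of per-CpG effect vectors")
  for (g in names(genes)) {
    eff <- genes[[g]]
    if (length(eff) < 1) stop("gene ", g, " must have at least one CpG")
    if (!is.numeric(eff)) stop("effects for gene ", g, " must be numeric")
  }
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(config$seed + 1L)
  rows <- list()
  for (grp in names(group_sizes)) {
    n <- group_sizes[[grp]]
    cm <- config$confounder_model[[grp]]
    rows[[grp]] <- data.frame(
      sample_id = sprintf("P_%s_%02d", grp, seq_len(n)),
      cohort = "P", group = grp,
      maternal_bmi = round(stats::rnorm(n, cm$bmi[1], cm$bmi[2]), 1),
      gestational_week = round(stats::rnorm(n, cm$gestational_week[1],
                                            cm$gestational_week[2]), 1),
      fetal_sex = ifelse(stats::runif(n) < cm$sex_prob_male, "M", "F"),
      hba1c = if (is.na(cm$hba1c[1])) NA_real_ else
        round(stats::rnorm(n, cm$hba1c[1], cm$hba1c[2]), 1),
      birth_weight_g = round(stats::rnorm(n, cm$birth_weight[1],
                                          cm$birth_weight[2])),
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  samples$maternal_bmi <- pmax(samples$maternal_bmi, 16)
  samples$gestational_week <- pmin(pmax(samples$gestational_week, 32), 42)

  ns <- nrow(samples)
  sex01 <- as.numeric(samples$fetal_sex == "M")
  cov_shift <- covariate_effects[["bmi"]] *
    (samples$maternal_bmi - mean(samples$maternal_bmi)) +
    covariate_effects[["gestational_week"]] *
    (samples$gestational_week - mean(samples$gestational_week)) +
    covariate_effects[["sex_male"]] * (sex01 - mean(sex01))
  exposed <- samples$group %in% affected_groups

  baseline <- lapply(genes, function(eff)
    stats::runif(length(eff), 20, 80))
  out <- list()
  for (g in names(genes)) {
    eff <- genes[[g]]
    for (k in seq_along(eff)) {
      mu <- baseline[[g]][k] + cov_shift + ifelse(exposed, eff[k], 0)
      val <- mu + stats::rnorm(ns, 0, noise_sd)
      out[[paste(g, k)]] <- data.frame(
        sample_id = samples$sample_id, gene = g, cpg_index = k,
        methylation_pct = pmin(pmax(val, 0), 100),
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  structure(list(panel = panel, samples = samples, baseline = baseline,
                 genes = genes, noise_sd = noise_sd,
                 affected_groups = affected_groups,
                 covariate_effects = covariate_effects),
            class = "targeted_panel")
}

#' Simulate a cell-type methylation reference
#'
#' Builds a probes-by-cell-types reference matrix in which a chosen subset of
#' discriminating probes separates the cell types by at least `margin` in
#' methylation fraction, as required for reference-based deconvolution.
#' Non-discriminating probes share a common baseline across types.
#'
#' @param n_cell_types Number of cell types (at least 2).
#' @param n_probes Total probes in the reference.
#' @param n_discriminating Number of discriminating probes
#'   (`<= n_probes`).
#' @param margin Minimum between-type spread (max - min) at each
#'   discriminating probe.
#' @param seed Integer seed.
#' @return An object of class `cell_reference`: list with `profiles`
#'   (probes x types matrix, rownames are probe ids) and `discriminating`
#'   (probe ids).
#' @export
simulate_cell_reference <- function(n_cell_types, n_probes, n_discriminating,
                                    margin = 0.5, seed = 1L) {
  if (n_cell_types < 2) stop("need at least 2 cell types")
  if (n_discriminating > n_probes)
    stop("n_discriminating must not exceed n_probes")
  if (margin <= 0 || margin >= 0.9) stop("margin must be in (0, 0.9)")
  set.seed(seed)
  baseline <- draw_baseline_means(n_probes)
  profiles <- matrix(baseline, nrow = n_probes, ncol = n_cell_types,
                     dimnames = list(sprintf("cg%08d", seq_len(n_probes)),
                                     paste0("cell", seq_len(n_cell_types))))
  disc <- sort(sample.int(n_probes, n_discriminating))
  for (i in disc) {
    lo <- stats::runif(1, 0.02, 0.9 - margin)
    hi <- lo + margin + stats::runif(1, 0, 0.95 - margin - lo)
    k <- sample(1:(n_cell_types - 1), 1)
    high_types <- sample.int(n_cell_types, k)
    jit <- min(0.03, (hi - lo - margin) / 2)
    profiles[i, ] <- lo + stats::runif(n_cell_types, 0, jit)
    profiles[i, high_types] <- hi - stats::runif(k, 0, jit)
  }
  profiles <- pmin(pmax(profiles, 0.01), 0.99)
  structure(list(profiles = profiles,
                 discriminating = rownames(profiles)[disc]),
            class = "cell_reference")
}

#' Write a cohort simulation to disk
#'
#' Writes the beta matrix, beadcounts and detection p-values as TSV, the
#' manifest and truth table as TSV, and the sample sheet as CSV, using the
#' column layouts consumed by the corresponding readers.
#'
#' @param sim A `cohort_sim` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    beta = file.path(dir, "beta.tsv"),
    beadcount = file.path(dir, "beadcount.tsv"),
    detection_p = file.path(dir, "detection_p.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    samples = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.tsv"))
  write_matrix_tsv(sim$beta, paths["beta"])
  write_matrix_tsv(sim$beadcount, paths["beadcount"])
  write_matrix_tsv(sim$detection_p, paths["detection_p"])
  write_table_file(sim$manifest, paths["manifest"])
  write_table_file(sim$samples, paths["samples"])
  write_table_file(sim$truth, paths["truth"])
  invisible(paths)
}
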