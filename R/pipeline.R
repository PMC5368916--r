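stage_seed <- function(seed, stage) {
  # fixed counter scheme so single stages can be re-run reproducibly
  offsets <- c(simulate = 0L, panel = 1L, qc = 2L, normalize = 3L, dmp = 4L,
               combine = 5L, cellmix = 6L, validate = 7L, tables = 8L)
  (as.integer(seed) + 10L * offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full two-cohort analysis pipeline
#'
#' Executes, in fixed order: synthetic-data generation (two cohorts sharing
#' one truth table), probe QC, BMIQ type II correction, per-cohort moderated
#' t-tests (I-GDM vs control), order-statistic combination across cohorts,
#' cell-type deconvolution with a between-group comparison, the targeted
#' validation panel (Mann-Whitney and adjusted regression), and cohort
#' characteristics tables. All stage outputs are written to `out_dir`
#' together with a machine-readable JSON run manifest (seed, parameters,
#' stage summaries); rerunning with the same configuration and seed
#' reproduces every output exactly.
#'
#' @param config A [sim_config()]; its seed is overridden by `seed`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed fanned out to per-stage sub-seeds by a fixed
#'   counter scheme.
#' @param fdr FDR threshold for the significant sets.
#' @param panel_genes Named list of per-CpG planted effects for the
#'   validation panel stage.
#' @param stages Named logical list toggling optional stages: `normalize`,
#'   `cellmix`, `validate`, `tables`.
#' @return Invisibly, a list with all stage results (`sim`, `qc`, `beta`,
#'   `dmp` per cohort, `combined`, `significant`, `cell`, `validation`,
#'   `characteristics`, `manifest`).
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir,
                         seed = config$seed,
                         fdr = 0.05,
                         panel_genes = list(
                           PRKCH = c(-1.1, -1.9, -1.2),
                           SLC17A4 = c(0.5, 5.3, -0.8),
                           ATP5A1 = c(-0.9, -2.2)),
                         stages = list(normalize = TRUE, cellmix = TRUE,
                                       validate = TRUE, tables = TRUE)) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_line <- function(...) message("[cordews] ", sprintf(...))

  config$seed <- as.integer(stage_seed(seed, "simulate"))
  sim <- run_stage("simulate", simulate_cohort(config))
  write_cohort_sim(sim, file.path(out_dir, "simulated"))
  log_line("simulate: %d probes x %d samples", nrow(sim$beta),
           ncol(sim$beta))

  qc <- run_stage("qc", filter_probes(sim$beta, sim$manifest, sim$beadcount,
                                      sim$detection_p))
  jsonlite::write_json(unclass(qc$report)[1:6],
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE)
  log_line("qc: retained %d of %d probes", qc$report$n_retained,
           qc$report$n_input)

  beta <- qc$beta
  if (isTRUE(stages$normalize)) {
    beta <- run_stage("normalize", bmiq_correct(beta, sim$manifest))
    log_line("normalize: BMIQ applied to %d samples", ncol(beta))
  } else {
    log_line("normalize: skipped by stage toggle")
  }
  write_matrix_tsv(beta, file.path(out_dir, "beta_normalized.tsv"))

  cohorts <- unique(sim$samples$cohort)
  dmp <- list()
  for (co in cohorts) {
    sel <- sim$samples$cohort == co &
      sim$samples$group %in% c("control", "igdm")
    grp <- factor(sim$samples$group[sel], levels = c("control", "igdm"))
    dmp[[co]] <- run_stage(
      "dmp", moderated_t_test(beta[, sim$samples$sample_id[sel]], grp))
    write_table_file(dmp[[co]],
                     file.path(out_dir, sprintf("dmp_cohort_%s.tsv", co)))
    log_line("dmp cohort %s: %d probes, %d BH-significant", co,
             nrow(dmp[[co]]), sum(dmp[[co]]$p_adj < fdr))
  }

  combined <- NULL; sig <- list(); concord <- NULL
  if (length(cohorts) >= 2) {
    combined <- run_stage("combine",
                          combine_cohorts(dmp[[cohorts[1]]],
                                          dmp[[cohorts[2]]]))
    write_table_file(combined, file.path(out_dir, "combined.tsv"))
    sig <- list(first = significant_set(combined, fdr, "first"),
                second = significant_set(combined, fdr, "second"))
    concord <- run_stage("combine",
                         cross_cohort_concordance(dmp[[cohorts[1]]],
                                                  dmp[[cohorts[2]]]))
    write_table_file(concord, file.path(out_dir, "concordance.tsv"))
    log_line("combine: %d first-order, %d second-order significant at FDR %g",
             length(sig$first), length(sig$second), fdr)
  }

  cell <- NULL
  if (isTRUE(stages$cellmix) && !is.null(sim$cell_reference)) {
    props <- run_stage("cellmix",
                       estimate_cell_proportions(beta, sim$cell_reference))
    comp <- lapply(cohorts, function(co) {
      sel <- sim$samples$cohort == co &
        sim$samples$group %in% c("control", "igdm")
      compare_cell_proportions(
        props[sim$samples$sample_id[sel], , drop = FALSE],
        factor(sim$samples$group[sel], levels = c("control", "igdm")))
    })
    names(comp) <- cohorts
    cell <- list(proportions = props, comparison = comp)
    write_table_file(data.frame(sample_id = rownames(props), props),
                     file.path(out_dir, "cell_proportions.tsv"))
    log_line("cellmix: proportions estimated for %d samples", nrow(props))
  }

  validation <- NULL
  if (isTRUE(stages$validate)) {
    pcfg <- config
    pcfg$seed <- as.integer(stage_seed(seed, "panel"))
    tp <- run_stage("validate", simulate_targeted_panel(pcfg, panel_genes))
    mw <- run_stage("validate", mw_compare_cpgs(tp$panel, tp$samples, "all"))
    adj <- run_stage("validate",
                     adjusted_effect_regression(tp$panel, tp$samples, "all"))
    validation <- list(panel = tp, mw = mw, adjusted = adj)
    write_table_file(tp$panel, file.path(out_dir, "panel.csv"))
    write_table_file(mw, file.path(out_dir, "validation_mw.tsv"))
    write_table_file(adj, file.path(out_dir, "validation_adjusted.tsv"))
    log_line("validate: %d genes, %d CpG tests", length(panel_genes),
             nrow(mw))
  }

  characteristics <- NULL
  if (isTRUE(stages$tables)) {
    vars <- c(maternal_bmi = "continuous", gestational_week = "continuous",
              birth_weight_g = "continuous", fetal_sex = "categorical")
    characteristics <- lapply(cohorts, function(co)
      build_characteristics_table(
        sim$samples[sim$samples$cohort == co, ], vars))
    names(characteristics) <- cohorts
    for (co in cohorts)
      write_table_file(characteristics[[co]],
                       file.path(out_dir,
                                 sprintf("characteristics_%s.tsv", co)))
    log_line("tables: characteristics written for %d cohorts",
             length(cohorts))
  }

  manifest <- list(
    package = "cordews",
    version = as.character(utils::packageVersion("cordews")),
    seed = seed,
    fdr = fdr,
    stages = stages,
    config = config[c("n_probes", "frac_differential", "effect_range_pp",
                      "beta_precision", "type2_bias", "n_cell_types",
                      "n_discriminating", "affected_groups", "frac_type2",
                      "bead_fail_rate", "detp_fail_rate")],
    group_sizes = lapply(config$group_sizes, as.list),
    qc = unclass(qc$report)[1:6],
    n_significant = lapply(sig, length))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(sim = sim, qc = qc, beta = beta, dmp = dmp,
                 combined = combined, significant = sig,
                 concordance = concord, cell = cell,
                 validation = validation,
                 characteristics = characteristics, manifest = manifest))
}
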